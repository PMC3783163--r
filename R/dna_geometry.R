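#' Ideal B-DNA duplexes and base-pair bookkeeping
#'
#' A \code{DuplexModel} is a coarse double-helical DNA model: per base pair
#' it carries a C1' atom, the glycosidic nitrogen and a backbone phosphate
#' on each strand -- enough geometry for the superposition recipes used in
#' model building, with no pretence of atomic realism. Base pairs are
#' numbered in attachment-site register coordinates: position 0 at the
#' crossover G, increasing toward the distal end of the arm.
#'
#' @name dna_geometry
NULL

#' Helical parameters for ideal B-DNA
#'
#' @param twist helical twist in degrees per base-pair step (must lie in
#'   (0, 60)).
#' @param rise rise in Angstrom per step (must lie in (2, 5)).
#' @return named numeric vector with class \code{HelicalParams}.
#' @export
helical_params <- function(twist = 34.3, rise = 3.38) {
  if (!(twist > 0 && twist < 60)) stop("helical_params: twist out of (0,60)")
  if (!(rise > 2 && rise < 5)) stop("helical_params: rise out of (2,5)")
  structure(c(twist = twist, rise = rise), class = "HelicalParams")
}

# Local (base-pair frame) coordinates of the coarse atom set. The frame has
# its origin on the helix axis at the C1'-C1' midpoint, x toward the major
# groove (glycosidic nitrogens), y along the C1'-C1' long axis, z the helix
# axis. Any consistent convention suffices for superposition-based recipes.
BP_LOCAL <- list(
  top = rbind("C1'" = c(0.0, 4.70, 0.0),
              N = c(1.50, 2.20, 0.0),
              P = c(-1.00, 7.60, 1.10)),
  bottom = rbind("C1'" = c(0.0, -4.70, 0.0),
                 N = c(1.50, -2.20, 0.0),
                 P = c(-1.00, -7.60, -1.10)))

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
GLYCOSIDIC_N <- c(A = "N9", G = "N9", C = "N1", T = "N1")

#' Build an ideal straight-axis B-DNA duplex
#'
#' Generates a coarse duplex along +z with base pair \code{i} (0-based) at
#' z = i * rise and azimuth i * twist. Successive base-pair frames are
#' related by exactly the constant helical screw, which is what makes the
#' step-transform closed forms hold.
#'
#' @param sequence top-strand sequence 5'->3' over A/C/G/T, length >= 2.
#' @param params a \code{\link{helical_params}} object.
#' @param top_chain,bottom_chain chain ids for the two strands.
#' @return A \code{DuplexModel}: list with \code{structure}
#'   (\code{StructureModel}), \code{sequence_top}, \code{bp} (position
#'   table), \code{params}, \code{top_chain}, \code{bottom_chain}.
#' @export
build_ideal_bdna <- function(sequence, params = helical_params(),
                             top_chain = "T", bottom_chain = "B") {
  sequence <- toupper(gsub("\\s", "", sequence))
  bases <- strsplit(sequence, "")[[1]]
  if (length(bases) < 2) stop("build_ideal_bdna: sequence shorter than 2 bp")
  bad <- setdiff(unique(bases), names(DNA_COMPLEMENT))
  if (length(bad)) stop("build_ideal_bdna: invalid characters in sequence: ",
                        paste(bad, collapse = ", "))
  n <- length(bases)
  twist <- params[["twist"]]; rise <- params[["rise"]]
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    phi <- (i - 1) * twist * pi / 180
    o <- c(0, 0, (i - 1) * rise)
    ex <- c(cos(phi), sin(phi), 0)
    ey <- c(-sin(phi), cos(phi), 0)
    ez <- c(0, 0, 1)
    place <- function(local) o + local[1] * ex + local[2] * ey + local[3] * ez
    top_base <- bases[i]; bot_base <- DNA_COMPLEMENT[[top_base]]
    mk <- function(strand, base, chain) {
      loc <- BP_LOCAL[[strand]]
      an <- rownames(loc); an[an == "N"] <- GLYCOSIDIC_N[[base]]
      xyz <- t(apply(loc, 1, place))
      data.frame(atom_name = an,
                 element = c("C", "N", "P"),
                 residue_name = paste0("D", base),
                 residue_number = i, chain_id = chain,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 is_hetero = FALSE, stringsAsFactors = FALSE)
    }
    rows[[2L * i - 1L]] <- mk("top", top_base, top_chain)
    rows[[2L * i]] <- mk("bottom", bot_base, bottom_chain)
  }
  atoms <- do.call(rbind, rows)
  roles <- stats::setNames(c("dna_top", "dna_bottom"),
                           c(top_chain, bottom_chain))
  st <- structure_model(atoms, roles)
  duplex_model(st, sequence, top_chain, bottom_chain, params)
}

#' Assemble a DuplexModel around an existing structure
#'
#' @param structure \code{StructureModel} holding the two strands.
#' @param sequence_top top-strand sequence 5'->3'.
#' @param top_chain,bottom_chain strand chain ids.
#' @param params helical parameters used to build it (or NULL for
#'   non-ideal duplexes).
#' @return A \code{DuplexModel}; positions default to 0..n-1 with the
#'   first top-strand residue at 0 (see \code{\link{assign_bp_numbering}}).
#' @export
duplex_model <- function(structure, sequence_top, top_chain = "T",
                         bottom_chain = "B", params = NULL) {
  stopifnot(inherits(structure, "StructureModel"))
  tr <- sort(unique(structure$atoms$residue_number[
    structure$atoms$chain_id == top_chain]))
  br <- sort(unique(structure$atoms$residue_number[
    structure$atoms$chain_id == bottom_chain]))
  if (length(tr) != length(br))
    stop("duplex_model: strands differ in residue count")
  if (length(tr) != nchar(sequence_top))
    stop("duplex_model: sequence length does not match residue count")
  bp <- data.frame(pos = seq_along(tr) - 1L, top_resno = tr,
                   bottom_resno = br)
  structure(list(structure = structure, sequence_top = sequence_top,
                 bp = bp, params = params, top_chain = top_chain,
                 bottom_chain = bottom_chain),
            class = "DuplexModel")
}

#' @export
apply_transform.DuplexModel <- function(t, x) {
  x$structure <- apply_transform(t, x$structure)
  x
}

#' @export
print.DuplexModel <- function(x, ...) {
  cat("DuplexModel:", nchar(x$sequence_top), "bp, positions",
      min(x$bp$pos), "..", max(x$bp$pos), "\n")
  invisible(x)
}

#' Assign attachment-site register numbering to a duplex
#'
#' The named top-strand residue becomes position 0 (the crossover G);
#' positions increase with top-strand residue order, i.e. toward the
#' distal (ZD-motif) end of the arm. Numbering is carried in the position
#' table and is invariant under rigid transformation.
#'
#' @param duplex a \code{DuplexModel}.
#' @param crossover_top_residue residue number (top strand) of the
#'   crossover base.
#' @return the renumbered \code{DuplexModel}.
#' @export
assign_bp_numbering <- function(duplex, crossover_top_residue) {
  stopifnot(inherits(duplex, "DuplexModel"))
  i <- match(crossover_top_residue, duplex$bp$top_resno)
  if (is.na(i)) {
    on_bottom <- crossover_top_residue %in% duplex$bp$bottom_resno
    hint <- if (on_bottom)
      " (residue found on the bottom strand; flip strands or renumber)"
    else ""
    stop("assign_bp_numbering: residue ", crossover_top_residue,
         " absent from top strand", hint)
  }
  duplex$bp$pos <- seq_len(nrow(duplex$bp)) - i
  duplex
}

# atoms of the base pairs at the given register positions, ordered by
# (position, strand, atom name) so two ideal duplexes match 1:1
bp_atoms <- function(duplex, positions) {
  missing <- setdiff(positions, duplex$bp$pos)
  if (length(missing))
    stop("positions absent from duplex: ", paste(missing, collapse = ", "))
  at <- duplex$structure$atoms
  out <- lapply(positions, function(p) {
    row <- duplex$bp[duplex$bp$pos == p, ]
    a <- rbind(
      cbind(at[at$chain_id == duplex$top_chain &
               at$residue_number == row$top_resno, ], strand = "top"),
      cbind(at[at$chain_id == duplex$bottom_chain &
               at$residue_number == row$bottom_resno, ], strand = "bottom"))
    a$pos <- p
    # canonical key: glycosidic nitrogens N1/N9 play the same role
    a$atom_key <- ifelse(a$atom_name %in% c("N1", "N9"), "N", a$atom_name)
    a[order(a$strand, a$atom_key), ]
  })
  do.call(rbind, out)
}

# pair two bp atom tables by (step offset within range, strand, canonical
# atom key); unmatched atoms are dropped with a message when any are
match_bp_atoms <- function(a, b, pos_a, pos_b) {
  ka <- paste(match(a$pos, pos_a), a$strand, a$atom_key)
  kb <- paste(match(b$pos, pos_b), b$strand, b$atom_key)
  common <- intersect(ka, kb)
  dropped <- (nrow(a) - length(common)) + (nrow(b) - length(common))
  if (dropped > 0)
    message("dropping ", dropped, " unmatched atoms from superposition")
  list(a = a[match(common, ka), , drop = FALSE],
       b = b[match(common, kb), , drop = FALSE])
}

#' Base-pair reference frames of a duplex
#'
#' Frames are built from the atoms themselves (not from construction
#' metadata), so they are rigid-invariant: origin at the C1'-C1' midpoint,
#' long axis along C1'(top) - C1'(bottom), major-groove axis toward the
#' glycosidic nitrogens, helix axis completing the right-handed triad.
#' Axes are returned as columns (helix, major groove, long).
#'
#' @param duplex a \code{DuplexModel}.
#' @return list with \code{origins} (n x 3) and \code{axes} (3 x 3 x n),
#'   rows/slices in position order.
#' @export
bp_frames <- function(duplex) {
  stopifnot(inherits(duplex, "DuplexModel"))
  pos <- sort(duplex$bp$pos)
  origins <- matrix(NA_real_, length(pos), 3)
  axes <- array(NA_real_, c(3, 3, length(pos)))
  for (k in seq_along(pos)) {
    a <- bp_atoms(duplex, pos[k])
    c1t <- unlist(a[a$strand == "top" & a$atom_name == "C1'",
                    c("x", "y", "z")])
    c1b <- unlist(a[a$strand == "bottom" & a$atom_name == "C1'",
                    c("x", "y", "z")])
    nt <- unlist(a[a$strand == "top" & grepl("^N", a$atom_name),
                   c("x", "y", "z")])
    nb <- unlist(a[a$strand == "bottom" & grepl("^N", a$atom_name),
                   c("x", "y", "z")])
    o <- (c1t + c1b) / 2
    b_long <- (c1t - c1b); b_long <- b_long / sqrt(sum(b_long^2))
    g <- (nt + nb) / 2 - o
    g <- g - sum(g * b_long) * b_long
    b_groove <- g / sqrt(sum(g^2))
    b_helix <- c(b_groove[2] * b_long[3] - b_groove[3] * b_long[2],
                 b_groove[3] * b_long[1] - b_groove[1] * b_long[3],
                 b_groove[1] * b_long[2] - b_groove[2] * b_long[1])
    origins[k, ] <- o
    axes[, , k] <- cbind(b_helix, b_groove, b_long)
  }
  list(positions = pos, origins = origins, axes = axes)
}

#' Rigid transform relating two base-pair ranges of one duplex
#'
#' Superposes (Kabsch) the atoms of \code{from_range} onto those of
#' \code{to_range}, position k of the source matched to position k of the
#' target. On ideal B-DNA this equals the (to - from)-step helical screw
#' exactly; on a deposited duplex it is the empirical register-shift
#' transform used to move a zinc-ribbon domain along the site (the
#' attP -> attB conversion derives it from base pairs 16-24 onto 11-19).
#'
#' @param duplex a numbered \code{DuplexModel}.
#' @param from_range,to_range inclusive position ranges \code{c(i, j)} of
#'   equal length.
#' @param atoms which atoms enter the fit: \code{"all"} (default) or
#'   \code{"backbone"} (P and C1' only).
#' @return A \code{RigidTransform} carrying attribute \code{"rmsd"}.
#' @export
derive_step_transform <- function(duplex, from_range, to_range,
                                  atoms = c("all", "backbone")) {
  atoms <- match.arg(atoms)
  stopifnot(inherits(duplex, "DuplexModel"))
  if (diff(from_range) != diff(to_range))
    stop("derive_step_transform: ranges of unequal length")
  fp <- seq.int(from_range[1], from_range[2])
  tp <- seq.int(to_range[1], to_range[2])
  fa <- bp_atoms(duplex, fp); ta <- bp_atoms(duplex, tp)
  if (atoms == "backbone") {
    fa <- fa[fa$atom_name %in% c("P", "C1'"), ]
    ta <- ta[ta$atom_name %in% c("P", "C1'"), ]
  }
  # pair atoms by (step offset, strand, canonical atom key); atoms present
  # in only one range (different base chemistry) are dropped
  m <- match_bp_atoms(fa, ta, fp, tp)
  fa <- m$a; ta <- m$b
  if (nrow(fa) < 3)
    stop("derive_step_transform: fewer than 3 matchable atoms between ranges")
  fit <- kabsch_fit(correspondence(as.matrix(fa[, c("x", "y", "z")]),
                                   as.matrix(ta[, c("x", "y", "z")])))
  structure(fit$transform, rmsd = fit$rmsd)
}

#' Analytic helical screw transform
#'
#' The closed-form screw relating base pairs n steps apart on an ideal
#' straight duplex built by \code{\link{build_ideal_bdna}} (axis +z through
#' the origin): rotation n * twist about z, translation n * rise along z.
#' Used as the independent oracle for \code{\link{derive_step_transform}}.
#'
#' @param n_steps signed number of base-pair steps.
#' @param params \code{\link{helical_params}}.
#' @return A \code{RigidTransform}.
#' @export
helical_screw <- function(n_steps, params = helical_params()) {
  rot <- axis_rotation("z", n_steps * params[["twist"]])
  rigid_transform(rot$rotation, c(0, 0, n_steps * params[["rise"]]))
}

#' Protein-DNA contact footprint
#'
#' A base pair is contacted iff any protein heavy atom lies within
#' \code{cutoff} of any of its atoms. The headline footprint is the
#' first-to-last contacted span (in bp), which is robust to an isolated
#' uncontacted base pair and matches the notion of contiguous coverage of
#' a half-site.
#'
#' @param model \code{StructureModel} containing the protein chain.
#' @param protein_chain chain id of the protein.
#' @param duplex a numbered \code{DuplexModel}.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5.0).
#' @return list with \code{contacts} (data frame pos/contacted),
#'   \code{span} (bp) and \code{n_contacted}.
#' @export
contact_footprint <- function(model, protein_chain, duplex, cutoff = 5.0) {
  stopifnot(inherits(model, "StructureModel"), inherits(duplex, "DuplexModel"))
  pa <- model$atoms[model$atoms$chain_id == protein_chain &
                    model$atoms$element != "H", , drop = FALSE]
  if (nrow(pa) == 0)
    stop("contact_footprint: no protein atoms in chain ", protein_chain)
  P <- as.matrix(pa[, c("x", "y", "z")])
  pos <- sort(duplex$bp$pos)
  contacted <- vapply(pos, function(p) {
    a <- bp_atoms(duplex, p)
    D <- as.matrix(a[, c("x", "y", "z")])
    if (cutoff <= 0) return(FALSE)
    # min pairwise distance bp-atoms vs protein atoms
    for (r in seq_len(nrow(D))) {
      d2 <- rowSums(sweep(P, 2, D[r, ])^2)
      if (min(d2) <= cutoff^2) return(TRUE)
    }
    FALSE
  }, logical(1))
  span <- if (any(contacted))
    diff(range(pos[contacted])) + 1L else 0L
  list(contacts = data.frame(pos = pos, contacted = contacted),
       span = as.integer(span), n_contacted = sum(contacted))
}
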