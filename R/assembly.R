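#' Half-site complexes and attachment-site model assembly
#'
#' The crystallized unit of the system is one integrase C-terminal domain
#' bound to one 25-bp attachment-site arm (a half-site complex). All
#' larger models are built from rigid copies of it: a full-site dimer
#' model places two copies on a bent dimer scaffold by superposing the
#' innermost base pairs (1-5) of each arm onto the scaffold; the attB
#' model shifts each zinc-ribbon domain 5 bp toward the crossover using
#' the register-shift screw derived from the arm's own DNA; hybrid attL /
#' attR models combine one P-derived and one B-derived half; synaptic
#' tetramer models place four halves on a four-segment scaffold.
#'
#' @name assembly
NULL

#' Construct a half-site complex
#'
#' @param protein \code{StructureModel} holding exactly one integrase
#'   chain.
#' @param duplex numbered \code{DuplexModel} (crossover at position 0).
#' @param arm_type one of \code{"P"}, \code{"P'"}, \code{"B"}, \code{"B'"}.
#' @param annotations domain annotations (from
#'   \code{\link{annotate_domains}}); if NULL, the LI scheme is applied.
#' @param ncs_copy_id identifier of the deposited copy this came from.
#' @param scheme annotation scheme used when \code{annotations} is NULL.
#' @return An object of class \code{HalfSiteComplex}.
#' @export
half_site_complex <- function(protein, duplex, arm_type = "P",
                              annotations = NULL, ncs_copy_id = NA,
                              scheme = li_domain_scheme()) {
  stopifnot(inherits(protein, "StructureModel"),
            inherits(duplex, "DuplexModel"))
  pch <- names(protein$chain_roles)[protein$chain_roles == "integrase"]
  if (length(pch) != 1)
    stop("half_site_complex: need exactly one integrase chain, found ",
         length(pch))
  if (!0 %in% duplex$bp$pos)
    stop("half_site_complex: duplex not numbered with crossover at 0")
  if (!arm_type %in% c("P", "P'", "B", "B'"))
    stop("half_site_complex: invalid arm_type ", arm_type)
  if (is.null(annotations))
    annotations <- annotate_domains(protein, pch, scheme,
                                    warn_missing = FALSE)
  structure(list(protein = protein, protein_chain = pch, duplex = duplex,
                 arm_type = arm_type, annotations = annotations,
                 ncs_copy_id = ncs_copy_id),
            class = "HalfSiteComplex")
}

#' @export
apply_transform.HalfSiteComplex <- function(t, x) {
  x$protein <- apply_transform(t, x$protein)
  x$duplex <- apply_transform(t, x$duplex)
  x
}

#' Merge a half-site complex into one structure
#'
#' @param half a \code{HalfSiteComplex}.
#' @param chain_map optional named character vector renaming chains.
#' @return A \code{StructureModel} with the protein and both DNA strands.
#' @export
as_structure <- function(half, chain_map = NULL) {
  stopifnot(inherits(half, "HalfSiteComplex"))
  m <- merge_structures(half$protein, half$duplex$structure)
  if (!is.null(chain_map)) m <- rename_chains(m, chain_map)
  m
}

#' @export
print.HalfSiteComplex <- function(x, ...) {
  cat("HalfSiteComplex: arm", x$arm_type, "-",
      nchar(x$duplex$sequence_top), "bp,",
      nrow(x$protein$atoms), "protein atoms (chain",
      paste0(x$protein_chain, ")"), "\n")
  invisible(x)
}

# residues of the protein chain belonging to the zinc-ribbon body
# (including the CC insertion and both anchors): everything in the ZD span
zd_residue_set <- function(half) {
  zd <- half$annotations[["ZD"]]
  cc <- half$annotations[["CC"]]
  if (is.null(zd)) stop("half-site lacks a ZD annotation")
  r <- zd$range
  span <- seq.int(r[1], r[2])
  if (!is.null(cc)) span <- sort(union(span, seq.int(cc$range[1], cc$range[2])))
  span
}

#' Scaffold with identifiable duplex segments
#'
#' Wraps a structure together with the duplex segments that half-site
#' complexes are superposed onto. For deposited scaffolds the segment
#' definition (which base pairs are registers 1-5) comes from a mapping
#' config; the synthetic generators return it directly.
#'
#' @param structure \code{StructureModel} of the scaffold.
#' @param segments named list of numbered \code{DuplexModel}s (2 for a
#'   dimer scaffold, 4 for a tetramer).
#' @param kind \code{"dimer"} or \code{"tetramer"}.
#' @param facing for tetramers, a 2-column matrix of segment-name pairs
#'   that face each other across the synapse.
#' @param scaffold_id identifier recorded in built models.
#' @param bend_angle optional bend angle (degrees) for bookkeeping.
#' @return An object of class \code{ScaffoldModel}.
#' @export
scaffold_model <- function(structure, segments, kind = c("dimer", "tetramer"),
                           facing = NULL, scaffold_id = "scaffold",
                           bend_angle = NA) {
  kind <- match.arg(kind)
  n_expect <- if (kind == "dimer") 2L else 4L
  if (length(segments) != n_expect)
    stop("scaffold_model: ", kind, " scaffold needs ", n_expect,
         " segments, got ", length(segments))
  if (kind == "tetramer" && is.null(facing))
    stop("scaffold_model: tetramer scaffold needs a facing map")
  structure(list(structure = structure, segments = segments, kind = kind,
                 facing = facing, scaffold_id = scaffold_id,
                 bend_angle = bend_angle),
            class = "ScaffoldModel")
}

# fit half's arm registers onto a scaffold segment's registers
fit_half_to_segment <- function(half, segment, fit_range = c(1L, 5L)) {
  pos <- seq.int(fit_range[1], fit_range[2])
  mv <- bp_atoms(half$duplex, pos)
  fx <- bp_atoms(segment, pos)
  m <- match_bp_atoms(mv, fx, pos, pos)
  mv <- m$a; fx <- m$b
  if (nrow(mv) < 3)
    stop("fit_half_to_segment: fewer than 3 matchable atoms between ",
         "half-site and scaffold segment over registers ",
         fit_range[1], "-", fit_range[2])
  kabsch_fit(correspondence(as.matrix(mv[, c("x", "y", "z")]),
                            as.matrix(fx[, c("x", "y", "z")])))
}

#' Build a full-site dimer model from one half-site complex
#'
#' Places two rigid copies of the half-site complex, one per scaffold
#' half, by superposing the arm's base pairs 1-5 onto the scaffold
#' segment's base pairs 1-5 (crossover-adjacent positions). A symmetric
#' attP model is two P arms; internal geometry of each copy is unchanged.
#'
#' @param half a \code{HalfSiteComplex}.
#' @param scaffold a dimer \code{ScaffoldModel}.
#' @param site_type \code{"attP"} (default) or \code{"attB"} when placing
#'   an already-shifted half.
#' @param fit_range registers entering the fit (default \code{c(1, 5)}).
#' @param rmsd_warn warn if a placement fit RMSD exceeds this (Angstrom).
#' @return An object of class \code{FullSiteModel}: \code{halves} (list of
#'   two placed \code{HalfSiteComplex}), \code{site_type},
#'   \code{scaffold_id}, \code{fit_rmsd}, \code{crossover_gap}.
#' @export
build_full_site <- function(half, scaffold, site_type = c("attP", "attB"),
                            fit_range = c(1L, 5L), rmsd_warn = 1.0) {
  site_type <- match.arg(site_type)
  stopifnot(inherits(half, "HalfSiteComplex"),
            inherits(scaffold, "ScaffoldModel"))
  if (scaffold$kind != "dimer")
    stop("build_full_site: scaffold is not a dimer scaffold")
  arms <- if (site_type == "attP") c("P", "P'") else c("B", "B'")
  halves <- vector("list", 2L)
  rms <- numeric(2L)
  for (k in 1:2) {
    fit <- fit_half_to_segment(half, scaffold$segments[[k]], fit_range)
    rms[k] <- fit$rmsd
    if (fit$rmsd > rmsd_warn)
      warning("build_full_site: placement fit RMSD ",
              format(fit$rmsd, digits = 3), " A on segment ", k,
              call. = FALSE)
    h <- apply_transform(fit$transform, half)
    h$arm_type <- arms[k]
    halves[[k]] <- h
  }
  names(halves) <- arms
  out <- structure(list(halves = halves, site_type = site_type,
                        scaffold_id = scaffold$scaffold_id,
                        fit_rmsd = rms, crossover_gap = NA_real_),
                   class = "FullSiteModel")
  out$crossover_gap <- crossover_gap(out)
  out
}

#' Crossover continuity of a full-site model
#'
#' Minimum distance between terminal backbone atoms (P, C1') of the two
#' arms' position-0 base pairs. For the coarse duplex representation a gap
#' below ~12 A indicates connectable arms.
#'
#' @param model a \code{FullSiteModel}.
#' @return distance in Angstrom.
#' @export
crossover_gap <- function(model) {
  stopifnot(inherits(model, "FullSiteModel"))
  term <- lapply(model$halves, function(h) {
    a <- bp_atoms(h$duplex, 0L)
    as.matrix(a[a$atom_name %in% c("P", "C1'"), c("x", "y", "z")])
  })
  A <- term[[1]]; B <- term[[2]]
  min(apply(A, 1, function(p) sqrt(min(rowSums(sweep(B, 2, p)^2)))))
}

#' @export
apply_transform.FullSiteModel <- function(t, x) {
  x$halves <- lapply(x$halves, function(h) apply_transform(t, h))
  x
}

#' @export
print.FullSiteModel <- function(x, ...) {
  cat("FullSiteModel:", x$site_type, "(",
      paste(vapply(x$halves, `[[`, "", "arm_type"), collapse = " + "),
      ") on", x$scaffold_id, "\n")
  invisible(x)
}

#' Shift the zinc-ribbon domains along the site (attP -> attB)
#'
#' Moves the ZD body (including the CC insertion and anchors) of each
#' subunit by the register-shift screw derived from that subunit's own
#' placed duplex: superposition of base pairs 16-24 onto base pairs
#' (16-n)-(24-n). With the default n = 5 this converts the attP-bound
#' architecture into the attB-bound one, relocating each ZD half a
#' helical turn toward the crossover. The recombinase domain, alphaE and
#' DNA are untouched; the RD-ZD linker atoms travel with the ZD body and
#' are not remodelled. Steric clashes introduced by the repositioning are
#' counted (heavy-atom pairs closer than \code{clash_cutoff}) and reported
#' in the result, never repaired.
#'
#' @param model an attP-type \code{FullSiteModel}.
#' @param n_bp register shift in base pairs (default 5, toward the
#'   crossover).
#' @param motif_range registers occupied by the ZD motif in the source
#'   model (default \code{c(16, 24)}).
#' @param clash_cutoff heavy-atom clash distance (default 2.5 A).
#' @return A \code{FullSiteModel} with \code{site_type = "attB"} and a
#'   \code{clash_count} field.
#' @export
shift_zd <- function(model, n_bp = 5L, motif_range = c(16L, 24L),
                     clash_cutoff = 2.5) {
  stopifnot(inherits(model, "FullSiteModel"))
  if (model$site_type != "attP")
    stop("shift_zd: model is not an attP-type model")
  if (n_bp == 0L) return(model)
  to_range <- motif_range - n_bp
  arms_new <- c("B", "B'")
  for (k in seq_along(model$halves)) {
    h <- model$halves[[k]]
    if (any(!c(to_range, motif_range) %in% h$duplex$bp$pos))
      stop("shift_zd: a ", n_bp, "-bp shift leaves the duplex (registers ",
           to_range[1], "-", motif_range[2], " needed)")
    tf <- derive_step_transform(h$duplex, motif_range, to_range)
    res <- zd_residue_set(h)
    at <- h$protein$atoms
    mov <- at$residue_number %in% res
    xyz <- apply_transform(tf, as.matrix(at[mov, c("x", "y", "z")]))
    at$x[mov] <- xyz[, 1]; at$y[mov] <- xyz[, 2]; at$z[mov] <- xyz[, 3]
    h$protein$atoms <- at
    h$arm_type <- arms_new[k]
    model$halves[[k]] <- h
  }
  names(model$halves) <- arms_new
  model$site_type <- "attB"
  model$clash_count <- count_clashes(model, zd_residue_set(model$halves[[1]]),
                                     clash_cutoff)
  model
}

# heavy-atom pairs closer than cutoff between the repositioned residue set
# (on any protein chain) and the rest of the model; contacts internal to
# the rigidly moved body are not clashes
count_clashes <- function(model, moved_residues, cutoff = 2.5) {
  prot_chains <- vapply(model$halves, `[[`, "", "protein_chain")
  at <- do.call(rbind, lapply(seq_along(model$halves), function(k) {
    a <- as_structure(model$halves[[k]])$atoms
    a$half <- k
    a
  }))
  at <- at[at$element != "H", ]
  is_moved <- at$chain_id %in% prot_chains &
    at$residue_number %in% moved_residues
  M <- as.matrix(at[is_moved, c("x", "y", "z"), drop = FALSE])
  O <- as.matrix(at[!is_moved, c("x", "y", "z"), drop = FALSE])
  if (nrow(M) == 0 || nrow(O) == 0) return(0L)
  n <- 0L
  for (i in seq_len(nrow(M)))
    n <- n + sum(rowSums(sweep(O, 2, M[i, ])^2) < cutoff^2)
  as.integer(n)
}

#' Build a hybrid attL / attR site model
#'
#' The product sites of integration are hybrids: attL = P + B' and
#' attR = B + P'. The two halves are taken from attP and attB full-site
#' models built on the same scaffold, so they already share a frame; the
#' result is the unsynapsed product-site model whose intramolecular
#' ZD-anchor distance decides autoinhibition.
#'
#' @param p_half a P-derived placed \code{HalfSiteComplex} (arm P or P').
#' @param b_half a B-derived placed \code{HalfSiteComplex} (arm B or B').
#' @param site_type \code{"attL"} (requires P + B') or \code{"attR"}
#'   (requires B + P').
#' @param scaffold_id recorded provenance label.
#' @return A \code{FullSiteModel} with an \code{intramolecular_distance}
#'   field (ZD-anchor Calpha to Calpha, Angstrom).
#' @export
build_hybrid_site <- function(p_half, b_half, site_type = c("attL", "attR"),
                              scaffold_id = "hybrid") {
  site_type <- match.arg(site_type)
  stopifnot(inherits(p_half, "HalfSiteComplex"),
            inherits(b_half, "HalfSiteComplex"))
  p_class <- substr(p_half$arm_type, 1, 1)
  b_class <- substr(b_half$arm_type, 1, 1)
  if (p_class == b_class)
    stop("build_hybrid_site: need one P-derived and one B-derived half, got ",
         p_half$arm_type, " + ", b_half$arm_type)
  need <- if (site_type == "attL") c("P", "B'") else c("B", "P'")
  got <- sort(c(p_half$arm_type, b_half$arm_type))
  if (!setequal(got, need))
    stop("build_hybrid_site: ", site_type, " requires arms ",
         paste(need, collapse = " + "), ", got ",
         paste(got, collapse = " + "))
  halves <- if (site_type == "attL") list(p_half, b_half)
            else list(b_half, p_half)
  names(halves) <- vapply(halves, `[[`, "", "arm_type")
  out <- structure(list(halves = halves, site_type = site_type,
                        scaffold_id = scaffold_id,
                        fit_rmsd = c(NA_real_, NA_real_),
                        crossover_gap = NA_real_),
                   class = "FullSiteModel")
  out$crossover_gap <- crossover_gap(out)
  out$intramolecular_distance <-
    sqrt(sum((zd_anchor_point(halves[[1]]) - zd_anchor_point(halves[[2]]))^2))
  out
}

#' Build a synaptic tetramer model
#'
#' Places the four half-site complexes of two full-site models onto the
#' four duplex segments of a tetramer scaffold by base-pair 1-5
#' superposition. The alignment controls which arm of the second site
#' faces which arm of the first: \code{"parallel"} puts site2 arm 1 on the
#' segment facing site1 arm 1; \code{"antiparallel"} swaps them.
#'
#' @param site1,site2 \code{FullSiteModel}s.
#' @param scaffold a tetramer \code{ScaffoldModel}.
#' @param alignment \code{"parallel"} or \code{"antiparallel"}.
#' @param fit_range registers entering each placement fit.
#' @return An object of class \code{SynapticModel}: \code{halves} (named
#'   by segment), \code{pairing} (e.g. \code{"PxB"}), \code{alignment},
#'   \code{juxtaposition} (data frame of facing/diagonal/intramolecular
#'   segment pairs), \code{scaffold_id}.
#' @export
build_synaptic <- function(site1, site2, scaffold,
                           alignment = c("parallel", "antiparallel"),
                           fit_range = c(1L, 5L)) {
  alignment <- match.arg(alignment)
  stopifnot(inherits(site1, "FullSiteModel"), inherits(site2, "FullSiteModel"),
            inherits(scaffold, "ScaffoldModel"))
  if (scaffold$kind != "tetramer")
    stop("build_synaptic: scaffold is not a tetramer scaffold")
  segs <- names(scaffold$segments)
  s1_segs <- segs[1:2]
  s2_segs <- if (alignment == "parallel") segs[3:4] else segs[4:3]
  halves <- list()
  for (k in 1:2) {
    fit <- fit_half_to_segment(site1$halves[[k]],
                               scaffold$segments[[s1_segs[k]]], fit_range)
    halves[[s1_segs[k]]] <- apply_transform(fit$transform, site1$halves[[k]])
  }
  for (k in 1:2) {
    fit <- fit_half_to_segment(site2$halves[[k]],
                               scaffold$segments[[s2_segs[k]]], fit_range)
    halves[[s2_segs[k]]] <- apply_transform(fit$transform, site2$halves[[k]])
  }
  halves <- halves[segs]
  partner <- stats::setNames(scaffold$facing[, 2], scaffold$facing[, 1])
  juxt <- rbind(
    data.frame(a = scaffold$facing[, 1], b = scaffold$facing[, 2],
               relation = "facing", stringsAsFactors = FALSE),
    data.frame(a = c(segs[1], segs[2]),
               b = unname(c(partner[segs[2]], partner[segs[1]])),
               relation = "diagonal", stringsAsFactors = FALSE),
    data.frame(a = c(segs[1], segs[3]), b = c(segs[2], segs[4]),
               relation = "intramolecular", stringsAsFactors = FALSE))
  pairing <- pairing_label(site1$site_type, site2$site_type)
  structure(list(halves = halves, pairing = pairing, alignment = alignment,
                 juxtaposition = juxt, scaffold_id = scaffold$scaffold_id,
                 site_types = c(site1$site_type, site2$site_type)),
            class = "SynapticModel")
}

pairing_label <- function(t1, t2) {
  code <- c(attP = "P", attB = "B", attL = "L", attR = "R")
  paste0(code[[t1]], "x", code[[t2]])
}

#' @export
apply_transform.SynapticModel <- function(t, x) {
  x$halves <- lapply(x$halves, function(h) apply_transform(t, h))
  x
}

#' @export
print.SynapticModel <- function(x, ...) {
  cat("SynapticModel:", x$pairing, paste0("(", x$alignment, ")"),
      "on", x$scaffold_id, "\n")
  invisible(x)
}

#' Decompose a synaptic model into its half-site complexes
#'
#' @param model a \code{SynapticModel}.
#' @return named list of placed \code{HalfSiteComplex} objects (names are
#'   scaffold segment labels; arm types preserved from the inputs).
#' @export
decompose_synaptic <- function(model) {
  stopifnot(inherits(model, "SynapticModel"))
  model$halves
}

#' Write an assembled model to a coordinate file
#'
#' Chains are renamed to a documented scheme: integrase subunits become
#' chains A, B, C, D in half-site order; DNA strands become E, F, G, H,
#' ... (top then bottom per half). A JSON provenance sidecar records the
#' scaffold, pairing and chain mapping.
#'
#' @param model \code{FullSiteModel} or \code{SynapticModel}.
#' @param path output coordinate file.
#' @param dialect \code{"pdb"} or \code{"mmcif"}.
#' @param sidecar write \code{<path>.json} provenance (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path, dialect = c("pdb", "mmcif"),
                        sidecar = TRUE) {
  dialect <- match.arg(dialect)
  halves <- model$halves
  prot_ids <- LETTERS[seq_along(halves)]
  dna_ids <- LETTERS[length(halves) + seq_len(2 * length(halves))]
  parts <- list(); mapping <- list()
  for (k in seq_along(halves)) {
    h <- halves[[k]]
    map <- stats::setNames(
      c(prot_ids[k], dna_ids[2 * k - 1], dna_ids[2 * k]),
      c(h$protein_chain, h$duplex$top_chain, h$duplex$bottom_chain))
    parts[[k]] <- as_structure(h, chain_map = map)
    mapping[[names(halves)[k] %||% as.character(k)]] <- as.list(map)
  }
  combined <- do.call(merge_structures, parts)
  write_structure(combined, path, dialect)
  if (sidecar) {
    prov <- list(class = class(model)[1],
                 site_type = model$site_type %||% NULL,
                 pairing = model$pairing %||% NULL,
                 alignment = model$alignment %||% NULL,
                 scaffold_id = model$scaffold_id, chain_mapping = mapping)
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}
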