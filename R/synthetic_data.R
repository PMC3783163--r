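#' Synthetic structures and sequences with known geometry
#'
#' Generators that stand in for deposited structures in tests: a coarse
#' B-DNA arm carrying rigid pseudo-domain clusters at analytically known
#' cylindrical offsets, bent dimer and four-segment tetramer scaffolds,
#' and attachment-site sequences with planted motifs. The pseudo-domains
#' are small rigid clusters, not protein mimics; they exist to exercise
#' superposition, register shifting and distance code against closed
#' forms.
#'
#' Default geometry mirrors the architecture of the real system: a 25-bp
#' arm, 36 deg/bp twist (the half-turn idealization that makes a 5-bp
#' shift exactly half a helical turn), 3.38 A rise, the zinc-ribbon
#' anchor attached at register 20 (within the 16-24 motif) at 25 A radial
#' offset with its azimuth perpendicular to the scaffold bend plane (so
#' the two ZDs of a site sit on opposite duplex faces), a 54 A coiled
#' coil, a 120 deg dimer bend and a 35 A synapse separation.
#'
#' @name synthetic_data
NULL

#' Specification for a mock half-site complex
#'
#' @param arm_length arm length in bp.
#' @param twist,rise helical parameters (deg/bp, A/bp).
#' @param zd_attach base-pair register the ZD pseudo-domain is attached to.
#' @param zd_radial,zd_axial,zd_azimuth cylindrical offsets of the ZD
#'   anchor from the helix axis (A, A, deg relative to the bp azimuth).
#' @param cc_length coiled-coil length: the CC tip is placed this far
#'   radially outward from the anchor.
#' @param rd_attach,rd_radial placement of the recombinase pseudo-domain.
#' @param contact_atoms place one pseudo-contact atom per base pair
#'   (1 A from the glycosidic nitrogen) so footprints cover the arm, as
#'   the real C-terminal domain contacts its entire half-site.
#' @param arm_seq top-strand arm sequence crossover -> distal (default:
#'   the synthetic attP P arm).
#' @param domains optional data frame overriding the pseudo-domain table
#'   (columns \code{name}, \code{attach}, \code{radial}, \code{axial},
#'   \code{azimuth}, \code{n_atoms}, \code{resno}).
#' @param seed integer seed recorded in the spec (generation is fully
#'   deterministic; the seed namespaces sequence generators).
#' @return An object of class \code{MockComplexSpec}.
#' @export
mock_halfsite_spec <- function(arm_length = 25L, twist = 36, rise = 3.38,
                               zd_attach = 20L, zd_radial = 25,
                               zd_axial = 0, zd_azimuth = 90,
                               cc_length = 54, rd_attach = 8L,
                               rd_radial = 15, contact_atoms = TRUE,
                               arm_seq = NULL, domains = NULL, seed = 1L) {
  if (is.null(arm_seq)) {
    arm_seq <- if (arm_length == 25L) "GTACAAGCTTTTTGGTGATACTAAA"
    else paste(rep(c("A", "C", "G", "T"),
                   length.out = arm_length), collapse = "")
  }
  if (nchar(arm_seq) != arm_length)
    stop("mock_halfsite_spec: arm_seq length != arm_length")
  if (zd_attach < 0 || zd_attach >= arm_length)
    stop("mock_halfsite_spec: zd_attach outside the arm")
  if (is.null(domains)) {
    domains <- data.frame(
      name = c("RD", "ZD", "ZD_anchor", "CC", "CC_tip"),
      attach = c(rd_attach, zd_attach, zd_attach, zd_attach, zd_attach),
      radial = c(rd_radial, zd_radial, zd_radial,
                 zd_radial + cc_length / 2, zd_radial + cc_length),
      axial = c(0, zd_axial, zd_axial, zd_axial, zd_axial),
      azimuth = c(0, zd_azimuth, zd_azimuth, zd_azimuth, zd_azimuth),
      n_atoms = c(4L, 4L, 1L, 2L, 1L),
      resno = c(200L, 270L, 338L, 350L, 374L),
      stringsAsFactors = FALSE)
  }
  if (any(domains$n_atoms < 1)) stop("mock_halfsite_spec: n_atoms < 1")
  if (any(domains$attach < 0 | domains$attach >= arm_length))
    stop("mock_halfsite_spec: domain attachment outside the arm")
  structure(list(arm_length = as.integer(arm_length),
                 params = helical_params(twist, rise),
                 domains = domains, contact_atoms = contact_atoms,
                 arm_seq = arm_seq, cc_length = cc_length,
                 seed = as.integer(seed)),
            class = "MockComplexSpec")
}

# closed-form position of a point attached to the straight arm at
# cylindrical offsets (arm frame: helix axis +z, bp0 at the origin)
mock_point <- function(spec, attach, radial, axial = 0, azimuth = 0) {
  phi <- (attach * spec$params[["twist"]] + azimuth) * pi / 180
  c(radial * cos(phi), radial * sin(phi),
    attach * spec$params[["rise"]] + axial)
}

#' Closed-form anchor geometry of a mock spec
#'
#' @param spec a \code{MockComplexSpec}.
#' @return list with \code{anchor} and \code{cc_tip} positions (arm
#'   frame) and \code{domain_centers} (named list).
#' @export
mock_closed_form <- function(spec) {
  stopifnot(inherits(spec, "MockComplexSpec"))
  centers <- lapply(seq_len(nrow(spec$domains)), function(i) {
    d <- spec$domains[i, ]
    mock_point(spec, d$attach, d$radial, d$axial, d$azimuth)
  })
  names(centers) <- spec$domains$name
  list(anchor = centers[["ZD_anchor"]], cc_tip = centers[["CC_tip"]],
       domain_centers = centers)
}

TETRA_OFFSETS <- 0.8 * rbind(c(1, 1, 1), c(1, -1, -1),
                             c(-1, 1, -1), c(-1, -1, 1))

#' Generate a mock half-site complex
#'
#' Ideal B-DNA arm (crossover at register 0) plus rigid pseudo-domain
#' clusters. The ZD anchor is a single Calpha named ALA 338 placed exactly
#' at the closed-form point, and the CC tip a Calpha named TYR 374, so the
#' LI annotation scheme applies unchanged. Deterministic: the same spec
#' always yields identical coordinates.
#'
#' @param spec a \code{\link{mock_halfsite_spec}}.
#' @param arm_type arm label (default "P").
#' @param protein_chain chain id for the pseudo-protein.
#' @return A \code{HalfSiteComplex}; the closed-form geometry is attached
#'   as attribute \code{"truth"} (see \code{\link{mock_closed_form}}).
#' @export
make_mock_halfsite <- function(spec = mock_halfsite_spec(), arm_type = "P",
                               protein_chain = "A") {
  stopifnot(inherits(spec, "MockComplexSpec"))
  duplex <- build_ideal_bdna(spec$arm_seq, spec$params)
  duplex <- assign_bp_numbering(duplex, 1L)
  rows <- list()
  for (i in seq_len(nrow(spec$domains))) {
    d <- spec$domains[i, ]
    ctr <- mock_point(spec, d$attach, d$radial, d$axial, d$azimuth)
    offs <- if (d$n_atoms == 1L) matrix(0, 1, 3)
    else TETRA_OFFSETS[rep_len(seq_len(4), d$n_atoms), , drop = FALSE]
    resname <- switch(d$name, ZD_anchor = "ALA", CC_tip = "TYR", "GLY")
    for (k in seq_len(d$n_atoms)) {
      rows[[length(rows) + 1L]] <- data.frame(
        atom_name = if (k == 1L) "CA" else paste0("C", k),
        element = "C", residue_name = resname,
        residue_number = d$resno + k - 1L, chain_id = protein_chain,
        x = ctr[1] + offs[k, 1], y = ctr[2] + offs[k, 2],
        z = ctr[3] + offs[k, 3], is_hetero = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (spec$contact_atoms) {
    fr <- bp_frames(duplex)
    at <- duplex$structure$atoms
    for (p in seq_len(spec$arm_length)) {
      n_top <- at[at$chain_id == duplex$top_chain &
                  at$residue_number == p & grepl("^N", at$atom_name), ]
      ctr <- c(n_top$x, n_top$y, n_top$z)
      k <- which(fr$positions == p - 1L)
      pos <- ctr + fr$axes[, 2, k] * 1.0
      rows[[length(rows) + 1L]] <- data.frame(
        atom_name = "CA", element = "C", residue_name = "GLY",
        residue_number = 100L + p - 1L, chain_id = protein_chain,
        x = pos[1], y = pos[2], z = pos[3], is_hetero = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  protein <- structure_model(do.call(rbind, rows),
                             stats::setNames("integrase", protein_chain))
  half <- half_site_complex(protein, duplex, arm_type = arm_type,
                            ncs_copy_id = "mock")
  attr(half, "truth") <- mock_closed_form(spec)
  half
}

rename_duplex_chains <- function(duplex, top, bottom) {
  map <- stats::setNames(c(top, bottom),
                         c(duplex$top_chain, duplex$bottom_chain))
  duplex$structure <- rename_chains(duplex$structure, map)
  duplex$top_chain <- top
  duplex$bottom_chain <- bottom
  duplex
}

#' Generate a mock dimer or tetramer scaffold
#'
#' The dimer scaffold is two ideal arms meeting at the crossover with a
#' given bend (180 deg = straight; the angle is the angle between the two
#' outgoing arm axes), related by an exact 2-fold about the x axis, with
#' the bend opening toward +x. The tetramer arranges two such bent sites
#' back to back across the synapse axis (x), the second site rotated
#' 180 deg about z, their centres separated by \code{separation}; facing
#' segment pairs are (A1, B1) and (A2, B2).
#'
#' The rigid placement transform of every segment is returned alongside,
#' so tests can compute expected post-assembly positions in closed form.
#'
#' @param kind \code{"dimer"} or \code{"tetramer"}.
#' @param bend_angle bend at the crossover, degrees in (0, 180].
#' @param spec \code{\link{mock_halfsite_spec}} providing arm geometry.
#' @param separation tetramer site-centre separation in Angstrom.
#' @param scaffold_id provenance label.
#' @return A \code{ScaffoldModel} with an extra \code{segment_transforms}
#'   field (named list of \code{RigidTransform}s).
#' @export
make_mock_scaffold <- function(kind = c("dimer", "tetramer"),
                               bend_angle = 120, spec = mock_halfsite_spec(),
                               separation = 35,
                               scaffold_id = paste0("mock_", kind[1])) {
  kind <- match.arg(kind)
  if (!(bend_angle > 0 && bend_angle <= 180))
    stop("make_mock_scaffold: bend_angle outside (0, 180]")
  rise <- spec$params[["rise"]]
  alpha <- (180 - bend_angle) / 2
  lift <- rigid_transform(diag(3), c(0, 0, rise / 2))
  t_arm1 <- compose_transforms(axis_rotation("y", alpha), lift)
  c2x <- rigid_transform(diag(c(1, -1, -1)))
  t_arm2 <- compose_transforms(c2x, t_arm1)
  base <- list(t_arm1, t_arm2)
  chain_pairs <- list(c("E", "F"), c("G", "H"), c("I", "J"), c("K", "L"))
  template <- assign_bp_numbering(build_ideal_bdna(spec$arm_seq, spec$params),
                                  1L)
  if (kind == "dimer") {
    tfs <- stats::setNames(base, c("arm1", "arm2"))
    facing <- NULL
  } else {
    shift_a <- rigid_transform(diag(3), c(separation / 2, 0, 0))
    shift_b <- rigid_transform(diag(3), c(-separation / 2, 0, 0))
    rz <- axis_rotation("z", 180)
    tfs <- list(
      A1 = compose_transforms(shift_a, base[[1]]),
      A2 = compose_transforms(shift_a, base[[2]]),
      B1 = compose_transforms(shift_b, compose_transforms(rz, base[[1]])),
      B2 = compose_transforms(shift_b, compose_transforms(rz, base[[2]])))
    facing <- rbind(c("A1", "B1"), c("A2", "B2"))
  }
  segments <- lapply(seq_along(tfs), function(k) {
    seg <- apply_transform(tfs[[k]], template)
    rename_duplex_chains(seg, chain_pairs[[k]][1], chain_pairs[[k]][2])
  })
  names(segments) <- names(tfs)
  structure_all <- do.call(merge_structures,
                           lapply(segments, `[[`, "structure"))
  sc <- scaffold_model(structure_all, segments, kind, facing = facing,
                       scaffold_id = scaffold_id, bend_angle = bend_angle)
  sc$segment_transforms <- tfs
  sc$separation <- if (kind == "tetramer") separation else NA_real_
  sc
}

#' Generate attachment sites with planted zinc-ribbon motifs
#'
#' For each site type in \code{registers} and each of \code{n} replicates,
#' builds a site of two random-background arms with the motif planted at
#' the stated register (on the arm's inward-reading strand, as in the real
#' sites). \code{mutation_rate} mutates each planted motif base to a
#' random different base with that probability.
#'
#' @param n replicates per site type.
#' @param motif motif string (default \code{\link{li_zd_motif}()}).
#' @param registers named integer vector, site type -> planted register.
#' @param mutation_rate per-base mutation probability within the motif.
#' @param seed RNG seed (same seed, same sites).
#' @param arm_length arm length in bp (default 25).
#' @return list of \code{AttSite}s, length \code{n * length(registers)}.
#' @export
make_mock_sites <- function(n, motif = li_zd_motif(),
                            registers = c(attP = 16L, attB = 11L),
                            mutation_rate = 0, seed = 1L,
                            arm_length = 25L) {
  L <- nchar(motif)
  if (any(registers + L - 1L > arm_length - 1L))
    stop("make_mock_sites: motif does not fit the half-site at the ",
         "requested register")
  if (n == 0) return(list())
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mutate <- function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(ch)) < mutation_rate
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1), "")
    paste(ch, collapse = "")
  }
  make_arm <- function(reg) {
    arm <- paste(sample(bases, arm_length, replace = TRUE), collapse = "")
    planted <- mutate(revcomp(motif))
    paste0(substr(arm, 1, reg), planted,
           substr(arm, reg + L + 1L, arm_length))
  }
  out <- list()
  for (ty in names(registers)) {
    for (i in seq_len(n)) {
      left <- make_arm(registers[[ty]])
      right <- make_arm(registers[[ty]])
      seq <- paste0(revcomp(left), right)
      out[[length(out) + 1L]] <- att_site(
        sprintf("%s_mock_%02d", ty, i), seq, site_type = ty)
    }
  }
  out
}

#' Generate a near-identical protein sequence pair
#'
#' A random sequence of the integrase's length and a copy with a fixed
#' number of point substitutions, for exercising the identity computation
#' at the near-identity regime of closely related phage integrases.
#'
#' @param length sequence length (default 452, the LI integrase length).
#' @param n_diffs number of substitutions (default 11).
#' @param seed RNG seed.
#' @return list with \code{a}, \code{b} and \code{positions}.
#' @export
make_mock_protein_pair <- function(length = 452L, n_diffs = 11L, seed = 1L) {
  stopifnot(n_diffs <= length)
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  a <- sample(aa, length, replace = TRUE)
  b <- a
  pos <- sort(sample.int(length, n_diffs))
  b[pos] <- vapply(a[pos], function(x) sample(setdiff(aa, x), 1), "")
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
       positions = pos)
}
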