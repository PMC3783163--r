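#' Coiled-coil reach model
#'
#' Encodes how far a pair of coiled-coil (CC) motifs can bridge. The CC of
#' the crystallized integrase spans 54 Angstrom from the zinc-ribbon
#' anchor (Calpha of Ala338 at the end of alphaJ) to the tip of the turn
#' (Tyr374), so two facing CCs can span at most about twice that,
#' d_max = 108 A. Below d_min (default 50 A) the facing zinc ribbons are
#' so close that CC pairs cannot adopt the geometry that stabilizes
#' synapsis: the lower bound is this package's explicit quantitative
#' encoding of the steric/geometric incompatibility of very close ZD
#' pairs, chosen between the blocked ~35 A self-pairing case and the
#' competent 77 A case, and is deliberately configurable; every verdict
#' reports the thresholds used.
#'
#' @param cc_length CC motif length in Angstrom (default 54).
#' @param d_max maximum bridgeable anchor-anchor distance (default
#'   2 * cc_length).
#' @param d_min minimum compatible anchor-anchor distance (default 50).
#' @return An object of class \code{ReachModel}.
#' @export
reach_model <- function(cc_length = 54, d_max = 2 * cc_length, d_min = 50) {
  if (!(d_min > 0 && d_min < d_max))
    stop("reach_model: need 0 < d_min < d_max")
  structure(list(cc_length = cc_length, d_max = d_max, d_min = d_min),
            class = "ReachModel")
}

#' Zinc-ribbon anchor point of a half-site complex
#'
#' The Calpha position of the annotated ZD anchor residue (Ala338 in the
#' LI scheme). All headline ZD-ZD distances are measured between these
#' points.
#'
#' @param half a \code{HalfSiteComplex}.
#' @return length-3 numeric position (Angstrom).
#' @export
zd_anchor_point <- function(half) {
  stopifnot(inherits(half, "HalfSiteComplex"))
  anchor_atom_point(half, "ZD_anchor")
}

anchor_atom_point <- function(half, which) {
  ann <- half$annotations[[which]]
  if (is.null(ann)) stop("half-site lacks a ", which, " annotation")
  resno <- ann$range[1]
  atom <- ann$metadata$atom %||% "CA"
  at <- half$protein$atoms
  hit <- at$chain_id == half$protein_chain & at$residue_number == resno &
    at$atom_name == atom
  if (!any(hit))
    stop(which, " residue ", resno, " (atom ", atom,
         ") absent or disordered in chain ", half$protein_chain,
         if (!is.na(half$ncs_copy_id)) paste0(" (copy ", half$ncs_copy_id, ")"))
  as.numeric(at[which(hit)[1], c("x", "y", "z")])
}

#' Coiled-coil span of a half-site complex
#'
#' Calpha(anchor) to Calpha(CC tip) distance: 54 A for the best-defined CC
#' of the deposited structure.
#'
#' @param half a \code{HalfSiteComplex}.
#' @return distance in Angstrom.
#' @export
cc_span <- function(half) {
  a <- anchor_atom_point(half, "ZD_anchor")
  b <- anchor_atom_point(half, "CC_tip")
  sqrt(sum((a - b)^2))
}

#' Measure the ZD-anchor distance architecture of a model
#'
#' For a full-site model, the single intramolecular anchor-anchor
#' distance; for a synaptic model, all pairwise anchor distances labelled
#' facing / diagonal / intramolecular from the juxtaposition map.
#'
#' @param model a \code{FullSiteModel} or \code{SynapticModel}.
#' @return A \code{DistanceReport}: data frame with columns \code{i},
#'   \code{j} (half-site labels), \code{arm_i}, \code{arm_j},
#'   \code{relation}, \code{distance}; attributes carry the model's
#'   site type / pairing / alignment.
#' @export
measure_architecture <- function(model) UseMethod("measure_architecture")

distance_report <- function(df, site_type = NULL, pairing = NULL,
                            alignment = NULL) {
  stopifnot(all(c("i", "j", "relation", "distance") %in% names(df)))
  if (any(df$distance < 0)) stop("distance_report: negative distance")
  structure(df, class = c("DistanceReport", "data.frame"),
            site_type = site_type, pairing = pairing, alignment = alignment)
}

#' @export
measure_architecture.FullSiteModel <- function(model) {
  h <- model$halves
  d <- sqrt(sum((zd_anchor_point(h[[1]]) - zd_anchor_point(h[[2]]))^2))
  distance_report(
    data.frame(i = names(h)[1], j = names(h)[2],
               arm_i = h[[1]]$arm_type, arm_j = h[[2]]$arm_type,
               relation = "intramolecular", distance = d,
               stringsAsFactors = FALSE),
    site_type = model$site_type)
}

#' @export
measure_architecture.SynapticModel <- function(model) {
  anchors <- lapply(model$halves, zd_anchor_point)
  juxt <- model$juxtaposition
  rows <- lapply(seq_len(nrow(juxt)), function(r) {
    a <- juxt$a[r]; b <- juxt$b[r]
    data.frame(i = a, j = b,
               arm_i = model$halves[[a]]$arm_type,
               arm_j = model$halves[[b]]$arm_type,
               relation = juxt$relation[r],
               distance = sqrt(sum((anchors[[a]] - anchors[[b]])^2)),
               stringsAsFactors = FALSE)
  })
  distance_report(do.call(rbind, rows), pairing = model$pairing,
                  alignment = model$alignment)
}

#' Classify synapsis competence from a distance report
#'
#' Applies the reach rules in order: (1) an attL/attR full-site report
#' whose intramolecular anchor distance is within CC reach (<= d_max) is
#' \code{autoinhibited} -- the product sites sequester their own CC motifs
#' before synapsis is even attempted; (2) a synaptic report with any
#' facing distance beyond d_max is \code{blocked_far}; (3) any facing
#' distance below d_min is \code{blocked_near}; (4) otherwise
#' \code{competent}.
#'
#' @param report a \code{DistanceReport}.
#' @param reach a \code{\link{reach_model}}.
#' @return A \code{SynapsisVerdict}: list with \code{pairing},
#'   \code{alignment}, \code{class} and \code{evidence} (the distances and
#'   thresholds that fired).
#' @export
classify_synapsis <- function(report, reach = reach_model()) {
  stopifnot(inherits(report, "DistanceReport"), inherits(reach, "ReachModel"))
  if (nrow(report) == 0) stop("classify_synapsis: empty distance report")
  site_type <- attr(report, "site_type")
  pairing <- attr(report, "pairing")
  alignment <- attr(report, "alignment")
  verdict <- function(class, evid) {
    structure(list(pairing = pairing %||% site_type,
                   alignment = alignment %||% NA_character_,
                   class = class,
                   evidence = evid,
                   d_min = reach$d_min, d_max = reach$d_max),
              class = "SynapsisVerdict")
  }
  if (!is.null(site_type) && site_type %in% c("attL", "attR")) {
    intra <- report[report$relation == "intramolecular", , drop = FALSE]
    if (nrow(intra) && any(intra$distance <= reach$d_max))
      return(verdict("autoinhibited",
                     cbind(intra[intra$distance <= reach$d_max, ],
                           rule = "intramolecular <= d_max")))
    return(verdict("competent", cbind(as.data.frame(report),
                                      rule = "intramolecular > d_max")))
  }
  facing <- report[report$relation == "facing", , drop = FALSE]
  if (nrow(facing) == 0)
    stop("classify_synapsis: no facing distances in a synaptic report")
  if (any(facing$distance > reach$d_max))
    return(verdict("blocked_far",
                   cbind(facing[facing$distance > reach$d_max, ],
                         rule = "facing > d_max")))
  if (any(facing$distance < reach$d_min))
    return(verdict("blocked_near",
                   cbind(facing[facing$distance < reach$d_min, ],
                         rule = "facing < d_min")))
  verdict("competent", cbind(as.data.frame(facing),
                             rule = "d_min <= facing <= d_max"))
}

#' @export
print.SynapsisVerdict <- function(x, ...) {
  cat(sprintf("SynapsisVerdict: %s%s -> %s  [d_min=%g, d_max=%g]\n",
              x$pairing,
              if (!is.na(x$alignment)) paste0(" (", x$alignment, ")") else "",
              x$class, x$d_min, x$d_max))
  invisible(x)
}

SITE_ARMS <- list(attP = c("P", "P'"), attB = c("B", "B'"),
                  attL = c("P", "B'"), attR = c("B", "P'"))
PAIRING_SITES <- list(PxB = c("attP", "attB"), PxP = c("attP", "attP"),
                      BxB = c("attB", "attB"), LxR = c("attL", "attR"),
                      LxL = c("attL", "attL"), RxR = c("attR", "attR"))

# face of an arm's ZD relative to its own site: P-derived distal ZDs and
# B-derived shifted ZDs sit on opposite duplex faces; primed arms invert.
ARM_FACE <- c("P" = 1L, "P'" = -1L, "B" = -1L, "B'" = 1L)

#' Enumerate synaptic alignments of a site pairing
#'
#' For each of the parallel and antiparallel alignments, reports which
#' half-site types end up juxtaposed across the synapse and a face
#' summary: whether all four ZDs sit on the same face of the complex (in
#' the convention where the second site is flipped into the synapse, so
#' its arm faces invert) and how many juxtaposed pairs are "productive"
#' (one P-derived with one B-derived arm). Parallel attL x attR is the
#' configuration with all four ZDs on one face; its antiparallel
#' alternative juxtaposes P with P' and B with B'.
#'
#' @param pairing one of \code{"PxB"}, \code{"PxP"}, \code{"BxB"},
#'   \code{"LxR"}, \code{"LxL"}, \code{"RxR"}.
#' @return list of two entries (parallel, antiparallel), each with
#'   \code{alignment}, \code{juxtaposed} (2-row data frame of arm types),
#'   \code{productive_pairs}, \code{same_face}.
#' @export
enumerate_alignments <- function(pairing) {
  if (!pairing %in% names(PAIRING_SITES))
    stop("enumerate_alignments: unknown pairing '", pairing, "'")
  sites <- PAIRING_SITES[[pairing]]
  arms1 <- SITE_ARMS[[sites[1]]]
  arms2 <- SITE_ARMS[[sites[2]]]
  out <- lapply(c("parallel", "antiparallel"), function(al) {
    a2 <- if (al == "parallel") arms2 else rev(arms2)
    juxt <- data.frame(site1_arm = arms1, site2_arm = a2,
                       stringsAsFactors = FALSE)
    juxt$productive <- substr(juxt$site1_arm, 1, 1) !=
      substr(juxt$site2_arm, 1, 1)
    faces <- c(ARM_FACE[arms1], -ARM_FACE[a2])
    list(alignment = al, juxtaposed = juxt,
         productive_pairs = sum(juxt$productive),
         same_face = length(unique(faces)) == 1L)
  })
  names(out) <- c("parallel", "antiparallel")
  out
}

#' Published ZD-ZD distances of the LI integrase models
#'
#' The anchor-anchor distances reported for the deposited-structure
#' models: 126 A intramolecular in the int-attP dimer model, 109 A in the
#' int-attB model, 77 A facing / 142 A diagonal in the attP x attB
#' synaptic model, 154 A facing in attP x attP and ~35 A facing in
#' attB x attB. These are published measurements shipped as inputs for the
#' classification rules; the package recomputes comparable distances from
#' coordinates when structures are available. No intramolecular value was
#' published for attL/attR (only that the CC motifs are within reach), so
#' those reports are not included here and are evaluated on models
#' instead.
#'
#' @return named list of \code{DistanceReport} objects
#'   (\code{attP}, \code{attB}, \code{PxB}, \code{PxP}, \code{BxB}).
#' @export
li_reported_distances <- function() {
  full <- function(site, arms, d)
    distance_report(data.frame(i = arms[1], j = arms[2], arm_i = arms[1],
                               arm_j = arms[2], relation = "intramolecular",
                               distance = d, stringsAsFactors = FALSE),
                    site_type = site)
  syn <- function(pairing, arms1, arms2, facing, diagonal = NULL) {
    df <- data.frame(i = c("A1", "A2"), j = c("B1", "B2"),
                     arm_i = arms1, arm_j = arms2, relation = "facing",
                     distance = facing, stringsAsFactors = FALSE)
    if (!is.null(diagonal))
      df <- rbind(df, data.frame(i = c("A1", "A2"), j = c("B2", "B1"),
                                 arm_i = arms1, arm_j = rev(arms2),
                                 relation = "diagonal", distance = diagonal,
                                 stringsAsFactors = FALSE))
    distance_report(df, pairing = pairing, alignment = "parallel")
  }
  list(
    attP = full("attP", c("P", "P'"), 126),
    attB = full("attB", c("B", "B'"), 109),
    PxB = syn("PxB", c("P", "P'"), c("B", "B'"), facing = c(77, 77),
              diagonal = c(142, 142)),
    PxP = syn("PxP", c("P", "P'"), c("P", "P'"), facing = c(154, 154)),
    BxB = syn("BxB", c("B", "B'"), c("B", "B'"), facing = c(35, 35)))
}

#' Render distance reports and verdicts as tables
#'
#' @param reports named list of \code{DistanceReport}s.
#' @param reach a \code{\link{reach_model}}.
#' @return data frame with one row per report: pairing, class, the
#'   distances summarised, and the thresholds.
#' @export
verdict_table <- function(reports, reach = reach_model()) {
  rows <- lapply(names(reports), function(nm) {
    rep <- reports[[nm]]
    v <- classify_synapsis(rep, reach)
    facing <- rep$distance[rep$relation == "facing"]
    intra <- rep$distance[rep$relation == "intramolecular"]
    data.frame(model = nm,
               pairing = v$pairing %||% NA_character_,
               class = v$class,
               facing_mean = if (length(facing)) mean(facing) else NA_real_,
               intramolecular = if (length(intra)) mean(intra) else NA_real_,
               d_min = reach$d_min, d_max = reach$d_max,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
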