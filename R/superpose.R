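#' Rigid transforms and least-squares superposition
#'
#' A \code{RigidTransform} is a proper rotation (3x3, det +1) plus a
#' translation in Angstrom. It is the currency of every model-building step
#' in the package: half-site placement on scaffolds, helical step
#' transforms, and the zinc-ribbon register shift are all rigid transforms
#' derived by least-squares superposition.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric translation (Angstrom).
#' @return An object of class \code{RigidTransform}.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite entries")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rigid_transform: rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rigid_transform: rotation must be proper (det +1), got det = ",
         format(det(rotation)))
  structure(list(rotation = rotation, translation = translation),
            class = "RigidTransform")
}

#' Identity transform
#' @return A \code{RigidTransform} that leaves points unchanged.
#' @export
transform_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Compose two rigid transforms
#'
#' \code{compose_transforms(a, b)} returns the transform that applies
#' \code{b} first, then \code{a}.
#'
#' @param a,b \code{RigidTransform} objects.
#' @return A \code{RigidTransform}.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "RigidTransform"), inherits(b, "RigidTransform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t A \code{RigidTransform}.
#' @return The inverse \code{RigidTransform}.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "RigidTransform"))
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Serialize / deserialize a transform as 12 numbers
#'
#' Row-major rotation followed by the translation, suitable for JSON
#' provenance records.
#' @param t A \code{RigidTransform}.
#' @return Numeric vector of length 12.
#' @export
transform_to_vector <- function(t) {
  stopifnot(inherits(t, "RigidTransform"))
  c(as.numeric(t(t$rotation)), t$translation)
}

#' @rdname transform_to_vector
#' @param v numeric vector of length 12 (row-major rotation, translation).
#' @export
transform_from_vector <- function(v) {
  stopifnot(length(v) == 12L)
  rigid_transform(matrix(v[1:9], 3, 3, byrow = TRUE), v[10:12])
}

#' Rotation about a coordinate axis
#'
#' Convenience constructor used by the synthetic-structure generators.
#' @param axis one of "x", "y", "z".
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return A \code{RigidTransform} with zero translation.
#' @export
axis_rotation <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  R <- switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE),
    y = matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE),
    z = matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  rigid_transform(R)
}

#' @export
print.RigidTransform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat("RigidTransform: rotation", format(ang, digits = 4), "deg,",
      "translation |t| =", format(sqrt(sum(x$translation^2)), digits = 4),
      "A\n")
  invisible(x)
}

#' Point correspondence for superposition
#'
#' Pairs an ordered set of moving points with an equally long ordered set
#' of fixed points.
#'
#' @param moving,fixed n x 3 numeric matrices (n >= 3).
#' @param labels optional character vector of point identifiers; duplicates
#'   are rejected.
#' @return An object of class \code{Correspondence}.
#' @export
correspondence <- function(moving, fixed, labels = NULL) {
  moving <- as_coord_matrix(moving)
  fixed <- as_coord_matrix(fixed)
  if (nrow(moving) != nrow(fixed))
    stop("correspondence: moving and fixed differ in length (",
         nrow(moving), " vs ", nrow(fixed), ")")
  if (nrow(moving) < 3L)
    stop("correspondence: need at least 3 point pairs, got ", nrow(moving))
  if (!is.null(labels)) {
    if (length(labels) != nrow(moving))
      stop("correspondence: labels length mismatch")
    if (anyDuplicated(labels))
      stop("correspondence: duplicated labels: ",
           paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(list(moving = moving, fixed = fixed, labels = labels),
            class = "Correspondence")
}

as_coord_matrix <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) %% 3 == 0)
    x <- matrix(x, ncol = 3, byrow = TRUE)
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("coordinates contain non-finite values")
  x
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rigid transform minimizing the RMSD between the moving
#' and fixed point sets, using the SVD formulation with the determinant
#' sign correction, so reflective inputs still yield a det +1 rotation.
#'
#' @param corr a \code{Correspondence}, or an n x 3 matrix of moving points
#'   (in which case \code{fixed} must be supplied).
#' @param fixed optional n x 3 matrix of fixed points.
#' @return A list with elements \code{transform} (\code{RigidTransform})
#'   and \code{rmsd} (Angstrom, evaluated after applying the transform).
#' @export
kabsch_fit <- function(corr, fixed = NULL) {
  if (!inherits(corr, "Correspondence")) corr <- correspondence(corr, fixed)
  M <- corr$moving; F <- corr$fixed
  cm <- colMeans(M); cf <- colMeans(F)
  Mc <- sweep(M, 2, cm); Fc <- sweep(F, 2, cf)
  # degenerate (collinear or coincident) configurations leave the rotation
  # underdetermined about the degenerate axis
  for (nm in c("moving", "fixed")) {
    X <- if (nm == "moving") Mc else Fc
    sv <- svd(X, nu = 0, nv = 0)$d
    if (sv[1] < 1e-9)
      stop("kabsch_fit: ", nm, " points are coincident (degenerate)")
    if (sv[2] / sv[1] < 1e-9)
      stop("kabsch_fit: ", nm, " points are collinear (degenerate)")
  }
  H <- crossprod(Mc, Fc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- rigid_transform(R, cf - as.numeric(R %*% cm))
  list(transform = tr, rmsd = rmsd(apply_transform(tr, M), F))
}

#' Root-mean-square deviation between paired point sets
#'
#' No fitting is performed; for fit-then-measure use \code{\link{kabsch_fit}}.
#' @param a,b n x 3 matrices (or length-3 vectors) of paired coordinates.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  if (nrow(a) != nrow(b))
    stop("rmsd: point lists differ in length (", nrow(a), " vs ", nrow(b), ")")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Apply a rigid transform
#'
#' Generic over coordinate matrices, structures, duplexes, half-site
#' complexes and assembled models; always returns a transformed copy and
#' leaves the input untouched.
#'
#' @param t A \code{RigidTransform}.
#' @param x object to transform.
#' @return A transformed copy of \code{x}.
#' @export
apply_transform <- function(t, x) UseMethod("apply_transform", x)

#' @export
apply_transform.default <- function(t, x) {
  stopifnot(inherits(t, "RigidTransform"))
  X <- as_coord_matrix(x)
  out <- sweep(X %*% t(t$rotation), 2, t$translation, "+")
  if (is.null(dim(x)) && length(x) == 3L) as.numeric(out) else out
}

#' Summary RMSD over non-crystallographic-symmetry copies
#'
#' Each copy after the first is superposed (Kabsch) onto the reference copy
#' on the named atom set restricted to the residue range, computed on the
#' intersection of residues ordered in all copies. The headline number is
#' the mean of the per-copy RMSDs; \code{all_pairs = TRUE} instead averages
#' over all unordered copy pairs.
#'
#' @param model a \code{StructureModel}.
#' @param chains character vector of chain ids (first is the reference
#'   unless \code{reference} is given).
#' @param resno_range inclusive residue-number range \code{c(start, end)}.
#' @param atom_names atoms entering the fit (default \code{"CA"}; use
#'   \code{"C1'"} for DNA).
#' @param reference chain id of the reference copy.
#' @param all_pairs average over all pairs instead of fits onto the
#'   reference.
#' @return list with \code{summary} (mean RMSD), \code{per_fit} (named
#'   numeric) and \code{n_atoms} used.
#' @export
ncs_summary_rmsd <- function(model, chains, resno_range,
                             atom_names = "CA", reference = chains[1],
                             all_pairs = FALSE) {
  stopifnot(inherits(model, "StructureModel"), length(chains) >= 2)
  at <- model$atoms
  sel <- function(ch) {
    a <- at[at$chain_id == ch &
            at$residue_number >= resno_range[1] &
            at$residue_number <= resno_range[2] &
            at$atom_name %in% atom_names, , drop = FALSE]
    a[order(a$residue_number, a$atom_name), , drop = FALSE]
  }
  keys <- lapply(chains, function(ch) {
    a <- sel(ch); paste(a$residue_number, a$atom_name)
  })
  common <- Reduce(intersect, keys)
  if (length(common) < 3)
    stop("ncs_summary_rmsd: fewer than 3 atoms common to all copies")
  xyz <- lapply(chains, function(ch) {
    a <- sel(ch)
    a <- a[match(common, paste(a$residue_number, a$atom_name)), ]
    as.matrix(a[, c("x", "y", "z")])
  })
  names(xyz) <- chains
  pairs <- if (all_pairs) utils::combn(chains, 2, simplify = FALSE)
           else lapply(setdiff(chains, reference), function(ch) c(reference, ch))
  per <- vapply(pairs, function(p) {
    kabsch_fit(correspondence(xyz[[p[2]]], xyz[[p[1]]]))$rmsd
  }, numeric(1))
  names(per) <- vapply(pairs, paste, character(1), collapse = "-")
  list(summary = mean(per), per_fit = per, n_atoms = length(common))
}
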