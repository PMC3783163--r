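test_that("kabsch_fit recovers known transforms and handles degeneracies", {
  set.seed(42)
  # identity case
  P <- matrix(stats::rnorm(30, sd = 10), 10, 3)
  fit <- kabsch_fit(correspondence(P, P))
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)

  # construct-and-recover: 37 deg about z plus translation (1,2,3)
  R37 <- axis_rotation("z", 37)$rotation
  tr <- rigid_transform(R37, c(1, 2, 3))
  fit <- kabsch_fit(correspondence(P, apply_transform(tr, P)))
  expect_lt(max(abs(fit$transform$rotation - R37)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - c(1, 2, 3))), 1e-9)
  expect_lt(fit$rmsd, 1e-9)

  # chirality: reflected target still yields a proper rotation, rmsd > 0
  refl <- P %*% diag(c(1, 1, -1))
  fit <- kabsch_fit(correspondence(P, refl))
  expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0)

  # degeneracies named in the error
  expect_error(kabsch_fit(correspondence(P[1:2, ], P[1:2, ])), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_fit(correspondence(line, line)), "collinear")
  expect_error(correspondence(P, P[1:5, ]), "differ in length")
  expect_error(correspondence(P[1:4, ], P[1:4, ], labels = c("a", "a", "b", "c")),
               "duplicated")
})

test_that("kabsch_fit is equivariant and optimal against randomized search", {
  set.seed(7)
  P <- matrix(stats::rnorm(18, sd = 8), 6, 3)
  Q <- P + matrix(stats::rnorm(18, sd = 1), 6, 3)
  base <- kabsch_fit(correspondence(P, Q))
  # equivariance: pre-rotating the moving set composes with the fit
  R <- random_rotation()
  fit2 <- kabsch_fit(correspondence(P %*% t(R), Q))
  recomposed <- compose_transforms(fit2$transform,
                                   rigid_transform(R, c(0, 0, 0)))
  expect_lt(max(abs(recomposed$rotation - base$transform$rotation)), 1e-8)
  expect_lt(max(abs(recomposed$translation - base$transform$translation)),
            1e-7)
  expect_equal(fit2$rmsd, base$rmsd, tolerance = 1e-9)

  # optimality: no random rotation (with optimal translation) beats it
  cm <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cm); Qc <- sweep(Q, 2, cq)
  best_rand <- Inf
  for (i in 1:2000) {
    Rr <- random_rotation()
    best_rand <- min(best_rand, sqrt(mean(rowSums((Pc %*% t(Rr) - Qc)^2))))
  }
  expect_lte(base$rmsd, best_rand + 1e-12)
})

test_that("kabsch_fit agrees with the bio3d reference implementation", {
  set.seed(11)
  for (i in 1:5) {
    P <- matrix(stats::rnorm(24, sd = 10), 8, 3)
    Q <- apply_transform(random_transform(), P) +
      matrix(stats::rnorm(24, sd = 0.3), 8, 3)
    ours <- kabsch_fit(correspondence(P, Q))
    ref <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.numeric(t(Q)), mobile = as.numeric(t(P))))
    ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - Q)^2)))
    expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
  }
})

test_that("transform algebra composes, inverts and serializes", {
  set.seed(3)
  a <- random_transform(); b <- random_transform()
  P <- matrix(stats::rnorm(15), 5, 3)
  expect_equal(apply_transform(compose_transforms(a, b), P),
               apply_transform(a, apply_transform(b, P)), tolerance = 1e-10)
  expect_equal(apply_transform(invert_transform(a), apply_transform(a, P)),
               P, tolerance = 1e-9)
  expect_equal(apply_transform(transform_identity(), P), P)
  # distances preserved
  Pt <- apply_transform(a, P)
  expect_equal(as.numeric(dist(Pt)), as.numeric(dist(P)), tolerance = 1e-9)
  # unit x under 90 deg rotation about z -> unit y
  expect_equal(apply_transform(axis_rotation("z", 90), c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  v <- transform_to_vector(a)
  a2 <- transform_from_vector(v)
  expect_equal(a2$rotation, a$rotation, tolerance = 1e-12)
  expect_equal(a2$translation, a$translation, tolerance = 1e-12)
  # improper rotations are rejected
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
})

test_that("rmsd measures without fitting and validates lengths", {
  expect_equal(rmsd(matrix(1:9, 3, 3), matrix(1:9, 3, 3)), 0)
  a <- rbind(c(0, 0, 0), c(5, 5, 5))
  b <- rbind(c(1, 0, 0), c(6, 5, 5))
  expect_equal(rmsd(a, b), 1.0)
  expect_error(rmsd(a, rbind(b, c(0, 0, 0))), "length")
})

test_that("ncs_summary_rmsd follows the fit-onto-reference convention", {
  set.seed(5)
  base <- matrix(stats::rnorm(60, sd = 6), 20, 3)
  mk <- function(chain, noise) {
    X <- apply_transform(random_transform(),
                         base + matrix(stats::rnorm(60, sd = noise), 20, 3))
    data.frame(atom_name = "CA", element = "C", residue_name = "ALA",
               residue_number = 1:20, chain_id = chain,
               x = X[, 1], y = X[, 2], z = X[, 3], is_hetero = FALSE,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk("A", 0), mk("B", 0), mk("C", 0.5))
  model <- structure_model(atoms,
                           c(A = "integrase", B = "integrase", C = "integrase"))
  res <- ncs_summary_rmsd(model, c("A", "B", "C"), c(1, 20))
  # exact copy fits to ~0; noisy copy dominates the mean
  expect_lt(res$per_fit[["A-B"]], 1e-9)
  expect_gt(res$per_fit[["A-C"]], 0.1)
  expect_equal(res$summary, mean(res$per_fit))
  all_pairs <- ncs_summary_rmsd(model, c("A", "B", "C"), c(1, 20),
                                all_pairs = TRUE)
  expect_equal(length(all_pairs$per_fit), 3L)
})
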