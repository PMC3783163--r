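test_that("mock half-sites place anchors at the closed-form points", {
  spec <- mock_halfsite_spec(zd_attach = 20, zd_radial = 25, zd_azimuth = 90)
  h <- make_mock_halfsite(spec)
  truth <- attr(h, "truth")
  expect_equal(zd_anchor_point(h), truth$anchor, tolerance = 1e-9)
  expect_equal(cc_span(h), spec$cc_length, tolerance = 1e-9)
  # determinism: same spec, identical coordinates
  h2 <- make_mock_halfsite(spec)
  expect_identical(coords(as_structure(h)), coords(as_structure(h2)))
  # zero offsets put the anchor on the helix axis at the bp origin
  h0 <- make_mock_halfsite(mock_halfsite_spec(zd_radial = 0, zd_axial = 0))
  expect_equal(zd_anchor_point(h0), c(0, 0, 20 * 3.38), tolerance = 1e-9)
  expect_error(mock_halfsite_spec(zd_attach = 40), "outside")
})

test_that("generator closed forms agree with pipeline measurements", {
  # randomized sweep: anchor geometry as measured through the assembled
  # models must match the closed form through the segment transforms
  set.seed(101)
  for (i in 1:25) {
    spec <- mock_halfsite_spec(
      zd_attach = sample(10:23, 1), zd_radial = stats::runif(1, 5, 35),
      zd_axial = stats::runif(1, -5, 5), zd_azimuth = stats::runif(1, 0, 360),
      cc_length = stats::runif(1, 30, 60))
    bend <- stats::runif(1, 60, 180)
    h <- make_mock_halfsite(spec)
    truth <- attr(h, "truth")
    expect_equal(zd_anchor_point(h), truth$anchor, tolerance = 1e-6)
    sc <- make_mock_scaffold("dimer", bend_angle = bend, spec = spec)
    m <- build_full_site(h, sc)
    exp1 <- apply_transform(sc$segment_transforms[[1]], truth$anchor)
    exp2 <- apply_transform(sc$segment_transforms[[2]], truth$anchor)
    expect_equal(zd_anchor_point(m$halves[[1]]), exp1, tolerance = 1e-6)
    expect_equal(zd_anchor_point(m$halves[[2]]), exp2, tolerance = 1e-6)
    expect_equal(measure_architecture(m)$distance,
                 sqrt(sum((exp1 - exp2)^2)), tolerance = 1e-6)
  }
})

test_that("mock scaffolds have the constructed symmetry", {
  sc <- make_mock_scaffold("dimer", bend_angle = 120)
  # invariant under its construction 2-fold (x axis)
  c2 <- rigid_transform(diag(c(1, -1, -1)))
  X1 <- coords(sc$segments[[1]]$structure)
  X2 <- coords(sc$segments[[2]]$structure)
  expect_lt(max(abs(apply_transform(c2, X1) - X2)), 1e-9)
  expect_error(make_mock_scaffold("dimer", bend_angle = 0), "bend_angle")
  expect_error(make_mock_scaffold("dimer", bend_angle = 181), "bend_angle")

  # straightening the bend monotonically increases the anchor separation
  # (anchors sit perpendicular to the bend plane, so only the axial
  # extension changes), as the closed form predicts
  spec <- mock_halfsite_spec()
  h <- make_mock_halfsite(spec)
  dists <- vapply(c(60, 90, 120, 150, 180), function(b) {
    m <- build_full_site(h, make_mock_scaffold("dimer", bend_angle = b,
                                               spec = spec))
    measure_architecture(m)$distance
  }, numeric(1))
  expect_true(all(diff(dists) > 0))
})

test_that("tetramer scaffolds separate facing segments by the set distance", {
  spec <- mock_halfsite_spec()
  sep <- 42
  tet <- make_mock_scaffold("tetramer", spec = spec, separation = sep)
  expect_identical(tet$kind, "tetramer")
  expect_identical(names(tet$segments), c("A1", "A2", "B1", "B2"))
  # closed form: segment B1 is segment A1 rotated 180 about z then shifted;
  # an anchor on the axis at bp a maps accordingly
  h <- make_mock_halfsite(mock_halfsite_spec(zd_radial = 0))
  truth <- attr(h, "truth")
  pa <- apply_transform(tet$segment_transforms[["A1"]], truth$anchor)
  pb <- apply_transform(tet$segment_transforms[["B1"]], truth$anchor)
  alpha <- (180 - tet$bend_angle) / 2 * pi / 180
  z <- truth$anchor[3] + 3.38 / 2
  expect_equal(sqrt(sum((pa - pb)^2)), 2 * abs(z * sin(alpha)) + sep,
               tolerance = 1e-9)
})

test_that("mock sites carry planted motifs at the stated registers", {
  sites <- make_mock_sites(3, registers = c(attP = 16L, attB = 11L))
  expect_length(sites, 6L)
  for (s in sites) {
    reg <- if (s$site_type == "attP") 16L else 11L
    hits <- scan_zd_motif(s, max_mismatch = 0)
    expect_true(reg %in% hits$register)
  }
  # planted truth: register shift +5 on every generated pair
  ps <- Filter(function(s) s$site_type == "attP", sites)
  bs <- Filter(function(s) s$site_type == "attB", sites)
  for (k in seq_along(ps)) {
    sh <- register_shift(best_zd_hit(ps[[k]], max_mismatch = 0),
                         best_zd_hit(bs[[k]], max_mismatch = 0))
    expect_identical(sh, 5L)
  }
  # reproducibility and edge cases
  s1 <- make_mock_sites(2, seed = 9)
  s2 <- make_mock_sites(2, seed = 9)
  expect_identical(vapply(s1, `[[`, "", "sequence"),
                   vapply(s2, `[[`, "", "sequence"))
  expect_length(make_mock_sites(0), 0L)
  expect_error(make_mock_sites(1, registers = c(attP = 20L)), "fit")

  # heavy mutation: exact-match scans are usually empty
  noisy <- make_mock_sites(20, registers = c(attP = 16L),
                           mutation_rate = 0.5, seed = 33)
  n_hit <- sum(vapply(noisy, function(s)
    nrow(scan_zd_motif(s, max_mismatch = 0)) > 0, logical(1)))
  # P(intact planted motif) = 0.5^9 ~ 0.002; background exact hits are
  # vanishingly rare, so >= 18/20 empty is a conservative bound
  expect_lte(n_hit, 2L)
})

test_that("mock protein pairs have the requested substitution count", {
  p <- make_mock_protein_pair(length = 120, n_diffs = 7, seed = 2)
  diffs <- sum(strsplit(p$a, "")[[1]] != strsplit(p$b, "")[[1]])
  expect_identical(diffs, 7L)
  expect_identical(nchar(p$a), 120L)
})
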