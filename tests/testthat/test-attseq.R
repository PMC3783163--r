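test_that("att sites partition into arms in register orientation", {
  sites <- li_att_sites()
  expect_length(sites, 2L)
  attP <- sites[[grep("attP", names(sites))]]
  expect_identical(attP$site_type, "attP")
  expect_identical(nchar(attP$sequence), 50L)
  expect_identical(nchar(attP$arm_left), 25L)
  # both arms start at the crossover G
  expect_identical(substr(attP$arm_left, 1, 1), "G")
  expect_identical(substr(attP$arm_right, 1, 1), "G")
  expect_error(att_site("x", "ACGTN"), "invalid characters")
  expect_error(att_site("x", "ACGTA"), "odd-length")
  expect_error(att_site("x", "ACGTAC", crossover = 6), "crossover")
})

test_that("the shipped attP carries the ZD motif at registers 16-24", {
  sites <- li_att_sites()
  attP <- sites[[grep("attP", names(sites))]]
  attB <- sites[[grep("attB", names(sites))]]
  hp <- scan_zd_motif(attP, max_mismatch = 0)
  # exact hit on the P arm: register 16, spanning 16-24, inward strand
  expect_true(any(hp$register == 16 & hp$span_end == 24 & hp$strand == "-"))
  hb <- scan_zd_motif(attB, max_mismatch = 0)
  expect_true(any(hb$register == 11 & hb$span_end == 19))
  # with one mismatch allowed, both arms of each site report the motif
  hp1 <- scan_zd_motif(attP, max_mismatch = 1)
  expect_setequal(unique(hp1$half_site), c("left", "right"))
})

test_that("motif scanning agrees with brute-force enumeration", {
  set.seed(19)
  sites <- make_mock_sites(10, mutation_rate = 0.15, seed = 19)
  extra <- lapply(1:10, function(i) att_site(
    paste0("rand", i),
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = ""),
    site_type = "unknown"))
  for (s in c(sites, extra)) {
    for (mm in c(0L, 2L)) {
      got <- scan_zd_motif(s, max_mismatch = mm)
      want <- brute_force_hits(s, li_zd_motif(), mm)
      if (is.null(want)) {
        expect_identical(nrow(got), 0L)
      } else {
        got_s <- got[order(got$mismatches, got$register, got$half_site,
                           got$strand), c("half_site", "strand", "register",
                                          "mismatches")]
        rownames(got_s) <- rownames(want) <- NULL
        expect_identical(got_s, want)
      }
    }
  }
  # edge cases
  s <- att_site("tiny", "GTACGTACGTACGTACGTAC")
  expect_error(scan_zd_motif(s, motif = ""), "empty motif")
  expect_error(scan_zd_motif(s, motif = strrep("A", 20)), "longer than")
  # motif equal to an entire half-site: one exact hit at register 0
  whole <- scan_zd_motif(s, motif = s$arm_right, max_mismatch = 0)
  exact <- whole[whole$mismatches == 0 & whole$half_site == "right" &
                 whole$strand == "+", ]
  expect_identical(exact$register, 0L)
})

test_that("register shift is signed, antisymmetric and site-aware", {
  sites <- li_att_sites()
  attP <- sites[[grep("attP", names(sites))]]
  attB <- sites[[grep("attB", names(sites))]]
  ph <- best_zd_hit(attP, max_mismatch = 0)
  bh <- best_zd_hit(attB, max_mismatch = 0)
  expect_identical(register_shift(ph, bh), 5L)
  expect_identical(register_shift(bh, ph), -5L)
  expect_error(register_shift(ph, ph), "same site")
  # identical sites shift by 0; constructed offset 3 recovered
  s1 <- make_mock_sites(1, registers = c(attP = 14L), seed = 4)[[1]]
  s2 <- make_mock_sites(1, registers = c(attB = 11L), seed = 5)[[1]]
  expect_identical(register_shift(best_zd_hit(s1, max_mismatch = 0),
                                  best_zd_hit(s2, max_mismatch = 0)), 3L)
})

test_that("conservation profiles normalize and flag planted positions", {
  # identical sequences: information approaches 2 bits everywhere
  prof <- conservation_profile(rep("ACGTACGTAC", 10), pseudocount = 1e-6)
  expect_true(all(prof$information > 1.99))
  expect_equal(colSums(prof$frequencies), rep(1, 10), tolerance = 1e-12)
  # uniform column: ~0 bits
  prof0 <- conservation_profile(c("A", "C", "G", "T"), pseudocount = 1e-6)
  expect_lt(prof0$information[1], 0.01)
  # planted conservation: T fixed at three positions, uniform elsewhere
  set.seed(77)
  L <- 12; fixed <- c(3, 7, 10)
  seqs <- vapply(1:60, function(i) {
    ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    ch[fixed] <- "T"
    paste(ch, collapse = "")
  }, character(1))
  prof <- conservation_profile(seqs)
  top3 <- order(prof$information, decreasing = TRUE)[1:3]
  expect_setequal(top3, fixed)
  expect_error(conservation_profile(c("ACGT", "ACG")), "ragged")
  expect_error(conservation_profile("ACGT"), "at least 2")
})

test_that("half-site symmetry compares arms read outward from the crossover", {
  # perfect palindrome: revcomp(left half) == right half
  arm <- "GTACAAGCTT"
  pal <- att_site("pal", paste0(rc_chr(arm), arm))
  sym <- half_site_symmetry(pal)
  expect_identical(sym$identity_fraction, 1.0)
  expect_identical(sym$positions, 0:9)
  # no agreement
  none <- att_site("none", paste0(rc_chr("AAAAA"), "CCCCC"))
  expect_identical(half_site_symmetry(none)$identity_fraction, 0.0)
  # constructed agreement at exactly {0, 3, 7}
  left <- "GAGTACCTAG"; right <- "GCATCAATCA"
  # positions 0,3,7 equal (G,T,T); force the rest distinct
  stopifnot(which(strsplit(left, "")[[1]] ==
                  strsplit(right, "")[[1]]) - 1 == c(0, 3, 7))
  s <- att_site("c", paste0(rc_chr(left), right))
  expect_identical(half_site_symmetry(s)$positions, c(0L, 3L, 7L))
  # the shipped attP is pseudo-palindromic: similar but not identical arms
  attP <- li_att_sites()[[1]]
  frac <- half_site_symmetry(attP)$identity_fraction
  expect_gt(frac, 0.7)
  expect_lt(frac, 1.0)
})

test_that("pairwise identity counts substitutions through global alignment", {
  self <- pairwise_identity("MKTAYIAKQR", "MKTAYIAKQR")
  expect_identical(self$differences, 0L)
  expect_equal(self$identity, 100)
  one <- pairwise_identity("ACD", "ACE")
  expect_identical(one$differences, 1L)
  # symmetry of the difference count
  a <- make_mock_protein_pair(length = 200, n_diffs = 9, seed = 6)
  ab <- pairwise_identity(a$a, a$b)
  ba <- pairwise_identity(a$b, a$a)
  expect_identical(ab$differences, ba$differences)
  expect_identical(ab$differences, 9L)
  # the near-identity regime of closely related phage integrases:
  # 11 substitutions over 452 residues is ~98% identity
  p <- make_mock_protein_pair(length = 452, n_diffs = 11, seed = 1)
  res <- pairwise_identity(p$a, p$b)
  expect_identical(res$differences, 11L)
  expect_equal(res$identity, 100 * (452 - 11) / 452, tolerance = 1e-9)
  expect_equal(round(res$identity), 98)
  # scoring robustness: the count is stable under a different gap scheme
  res2 <- pairwise_identity(p$a, p$b, gap_open = 10, gap_extend = 2)
  expect_identical(res2$differences, 11L)
  # a deletion counts as gap columns
  del <- pairwise_identity("MKTAYIAKQR", "MKTAYKQR")
  expect_identical(del$differences, 2L)
  expect_error(pairwise_identity("ACB1", "ACD"), "amino-acid")
  expect_error(pairwise_identity("", "ACD"), "amino-acid")
})
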