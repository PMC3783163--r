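# Shared test utilities: random rigid transforms and an independent
# brute-force motif enumerator (deliberately written as naive loops so it
# shares no code with the scan implementation).

random_rotation <- function() {
  # uniform random rotation via normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_transform <- function() {
  rigid_transform(random_rotation(), stats::rnorm(3, sd = 20))
}

rc_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# independent enumeration of motif hits over both strands of both arms
brute_force_hits <- function(site, motif, max_mismatch) {
  L <- nchar(motif)
  mchars <- strsplit(motif, "")[[1]]
  out <- NULL
  for (half in c("left", "right")) {
    arm <- if (half == "left") site$arm_left else site$arm_right
    n <- nchar(arm)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") arm else rc_chr(arm)
      schars <- strsplit(s, "")[[1]]
      for (start in 1:(n - L + 1)) {
        mm <- 0L
        for (k in 1:L) if (schars[start + k - 1] != mchars[k]) mm <- mm + 1L
        if (mm <= max_mismatch) {
          reg <- if (strand == "+") start - 1L else n - (start + L - 1L)
          out <- rbind(out, data.frame(half_site = half, strand = strand,
                                       register = reg, mismatches = mm,
                                       stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(out)) return(out)
  out[order(out$mismatches, out$register, out$half_site, out$strand), ]
}

# a complete synthetic integrase chain (one CA per residue 133..452) for
# annotation tests
full_ctd_chain <- function(chain = "A") {
  res <- 133:452
  structure_model(data.frame(
    atom_name = "CA", element = "C", residue_name = "ALA",
    residue_number = res, chain_id = chain,
    x = res * 1.1, y = 0, z = 0, is_hetero = FALSE,
    stringsAsFactors = FALSE),
    stats::setNames("integrase", chain))
}
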