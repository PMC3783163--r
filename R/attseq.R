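#' Attachment-site sequence analysis
#'
#' Attachment sites are represented 5'->3' on the top strand with the
#' crossover dinucleotide at the centre. Each half-site (arm) is expressed
#' in register coordinates: position 0 at the crossover base of the arm,
#' increasing toward the distal end -- the same numbering the structural
#' modules use, so that the attP zinc-ribbon motif literally occupies
#' registers 16-24 and the attB motif registers 11-19, making the 5-bp
#' register-shift arithmetic transparent.
#'
#' @name attseq
NULL

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Construct an attachment site
#'
#' @param name site name.
#' @param sequence top-strand sequence 5'->3' (even length; the two arms
#'   partition the site around the central crossover dinucleotide unless
#'   \code{crossover} is given).
#' @param site_type one of \code{"attP"}, \code{"attB"}, \code{"attL"},
#'   \code{"attR"}, \code{"unknown"}.
#' @param crossover 1-based position of the first crossover base (default:
#'   sequence centre).
#' @return An object of class \code{AttSite} with fields \code{name},
#'   \code{sequence}, \code{crossover}, \code{site_type}, and the two arms
#'   in register orientation (\code{arm_left}, \code{arm_right}: 5'->3'
#'   crossover -> distal on the arm's outward-reading strand).
#' @export
att_site <- function(name, sequence, site_type = "unknown",
                     crossover = NULL) {
  sequence <- toupper(gsub("\\s", "", sequence))
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c("A", "C", "G", "T"))
  if (length(bad)) stop("att_site: invalid characters: ",
                        paste(bad, collapse = ", "))
  n <- nchar(sequence)
  if (is.null(crossover)) {
    if (n %% 2 != 0) stop("att_site: odd-length site needs explicit crossover")
    crossover <- n / 2
  }
  if (crossover < 2 || crossover >= n)
    stop("att_site: crossover dinucleotide outside the sequence")
  if (!site_type %in% c("attP", "attB", "attL", "attR", "unknown"))
    stop("att_site: invalid site_type ", site_type)
  arm_left <- revcomp(substr(sequence, 1, crossover))
  arm_right <- substr(sequence, crossover + 1, n)
  structure(list(name = name, sequence = sequence, crossover = crossover,
                 site_type = site_type, arm_left = arm_left,
                 arm_right = arm_right),
            class = "AttSite")
}

#' @export
print.AttSite <- function(x, ...) {
  cat("AttSite", x$name, paste0("(", x$site_type, "):"), nchar(x$sequence),
      "bp, crossover at", x$crossover, "\n")
  invisible(x)
}

#' Read attachment sites from a FASTA file
#'
#' Site type is parsed from the record name (first token containing attP /
#' attB / attL / attR, case-insensitive).
#'
#' @param path FASTA file.
#' @param crossover passed through to \code{\link{att_site}}.
#' @return named list of \code{AttSite}s.
#' @export
read_att_sites <- function(path, crossover = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    nm <- names(set)[i]
    ty <- regmatches(nm, regexpr("att[PBLR]", nm, ignore.case = TRUE))
    ty <- if (length(ty)) paste0("att", toupper(substr(ty, 4, 4))) else "unknown"
    att_site(nm, as.character(set[[i]]), site_type = ty,
             crossover = crossover)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' The LI integrase zinc-ribbon recognition motif
#'
#' The 9-bp sequence read by the zinc-ribbon domain, written 5'->3' on the
#' strand running from the distal end of the arm toward the crossover.
#' @return character scalar \code{"TTTAGTATC"}.
#' @export
li_zd_motif <- function() "TTTAGTATC"

#' Synthetic LI attachment-site sequences
#'
#' Reads the attP/attB site file shipped with the package. The sequences
#' are a synthetic reconstruction: every base stated in the structural
#' analysis is honoured (crossover G0/T1 step, the A/T-rich recombinase-
#' domain contact region at registers 9-11, G13/G14/T15 in the
#' linker-binding segment, the zinc-ribbon motif at attP registers 16-24
#' and attB registers 11-19, attB conservation at C11/G15/T17-19, variable
#' attB registers 13-14), while unconstrained positions are fixed
#' arbitrary choices. They are suitable for register arithmetic and motif
#' scanning, not for base-resolution claims about the natural sites.
#'
#' @return named list of \code{AttSite}s (attP, attB).
#' @export
li_att_sites <- function() {
  path <- system.file("extdata", "li_att_sites_synthetic.fasta",
                      package = "attarch")
  read_att_sites(path)
}

count_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Scan a half-site for the zinc-ribbon motif
#'
#' Slides the motif over both strands of each arm and reports every
#' window with at most \code{max_mismatch} mismatches, in register
#' coordinates. A hit's \code{register} is the crossover-proximal edge of
#' the window (so the canonical attP hit has register 16 and spans 16-24).
#' Hits are sorted by (mismatches, register).
#'
#' @param site an \code{AttSite}.
#' @param motif DNA string (default \code{\link{li_zd_motif}()}).
#' @param max_mismatch maximum mismatches per hit (default 0).
#' @return data frame of \code{MotifHit}s: \code{site}, \code{half_site}
#'   (left/right), \code{strand} (\code{"+"} = arm outward strand,
#'   \code{"-"} = its complement), \code{register}, \code{span_start},
#'   \code{span_end}, \code{mismatches}.
#' @export
scan_zd_motif <- function(site, motif = li_zd_motif(), max_mismatch = 0L) {
  stopifnot(inherits(site, "AttSite"))
  motif <- toupper(motif)
  if (nchar(motif) == 0) stop("scan_zd_motif: empty motif")
  L <- nchar(motif)
  hits <- list()
  for (half in c("left", "right")) {
    arm <- if (half == "left") site$arm_left else site$arm_right
    n <- nchar(arm)
    if (L > n) stop("scan_zd_motif: motif longer than half-site")
    for (strand in c("+", "-")) {
      s <- if (strand == "+") arm else revcomp(arm)
      for (start in seq_len(n - L + 1L)) {
        window <- substr(s, start, start + L - 1L)
        mm <- count_mismatches(window, motif)
        if (mm <= max_mismatch) {
          # registers covered by this window on the arm
          reg_lo <- if (strand == "+") start - 1L else n - (start + L - 1L)
          hits[[length(hits) + 1L]] <- data.frame(
            site = site$name, half_site = half, strand = strand,
            register = reg_lo, span_start = reg_lo,
            span_end = reg_lo + L - 1L, mismatches = mm,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits)
  else data.frame(site = character(), half_site = character(),
                  strand = character(), register = integer(),
                  span_start = integer(), span_end = integer(),
                  mismatches = integer(), stringsAsFactors = FALSE)
  out[order(out$mismatches, out$register), , drop = FALSE]
}

#' Best motif hit of a site
#'
#' Lowest-mismatch (then most crossover-proximal) hit across both arms.
#' @inheritParams scan_zd_motif
#' @return single-row MotifHit data frame, or NULL when nothing matches.
#' @export
best_zd_hit <- function(site, motif = li_zd_motif(), max_mismatch = 1L) {
  h <- scan_zd_motif(site, motif, max_mismatch)
  if (nrow(h) == 0) return(NULL)
  h[1, , drop = FALSE]
}

#' Register shift between motif hits of two sites
#'
#' Positive values mean the second (attB) site's motif sits closer to the
#' crossover: the canonical attP (register 16) vs attB (register 11)
#' comparison yields +5.
#'
#' @param p_hit,b_hit single-row MotifHit data frames from two different
#'   sites (typically attP and attB).
#' @return signed shift in base pairs (\code{p_register - b_register}).
#' @export
register_shift <- function(p_hit, b_hit) {
  stopifnot(is.data.frame(p_hit), is.data.frame(b_hit),
            nrow(p_hit) == 1, nrow(b_hit) == 1)
  if (identical(p_hit$site, b_hit$site))
    stop("register_shift: both hits come from the same site (",
         p_hit$site, ")")
  as.integer(p_hit$register - b_hit$register)
}

#' Per-position conservation profile of aligned sites
#'
#' Base frequencies with a pseudocount and the per-position information
#' content in bits (2 - entropy for the 4-letter alphabet).
#'
#' @param aligned_sites character vector of equal-length DNA strings
#'   (>= 2).
#' @param anchor register label of the first column (default 0).
#' @param pseudocount added per base per column (default 0.5).
#' @return A \code{ConservationProfile}: list with \code{frequencies}
#'   (4 x L matrix, rows A/C/G/T), \code{information} (bits per position)
#'   and \code{positions}.
#' @export
conservation_profile <- function(aligned_sites, anchor = 0L,
                                 pseudocount = 0.5) {
  if (length(aligned_sites) < 2)
    stop("conservation_profile: need at least 2 sequences")
  lens <- nchar(aligned_sites)
  if (length(unique(lens)) != 1)
    stop("conservation_profile: ragged input (lengths ",
         paste(unique(lens), collapse = ", "), ")")
  L <- lens[1]
  mat <- do.call(rbind, strsplit(toupper(aligned_sites), ""))
  bases <- c("A", "C", "G", "T")
  freq <- sapply(seq_len(L), function(j) {
    counts <- table(factor(mat[, j], levels = bases))
    (counts + pseudocount) / (nrow(mat) + 4 * pseudocount)
  })
  rownames(freq) <- bases
  info <- apply(freq, 2, function(f) 2 + sum(f * log2(f)))
  structure(list(frequencies = freq, information = info,
                 positions = anchor + seq_len(L) - 1L),
            class = "ConservationProfile")
}

#' Half-site symmetry of an attachment site
#'
#' Compares the two arms position by position in register orientation
#' (read outward from the crossover on corresponding strands).
#'
#' @param site an \code{AttSite} with equal-length arms.
#' @return list with \code{positions} (registers identical in both arms)
#'   and \code{identity_fraction}.
#' @export
half_site_symmetry <- function(site) {
  stopifnot(inherits(site, "AttSite"))
  a <- strsplit(site$arm_left, "")[[1]]
  b <- strsplit(site$arm_right, "")[[1]]
  if (length(a) != length(b))
    stop("half_site_symmetry: arms of unequal length (",
         length(a), " vs ", length(b), ")")
  same <- which(a == b) - 1L
  list(positions = same, identity_fraction = length(same) / length(a))
}

#' Pairwise protein identity by global alignment
#'
#' Needleman-Wunsch global alignment through Biostrings with simple
#' match/mismatch scoring and affine gaps. At the near-identity levels
#' this package cares about (distinguishing proteins a few substitutions
#' apart) the difference count is insensitive to the scoring scheme.
#'
#' @param seq_a,seq_b amino-acid sequences (20 standard letters).
#' @param match,mismatch,gap_open,gap_extend scoring parameters (defaults
#'   1 / 0 / 5 / 1; gap penalties are positive costs).
#' @return list with \code{differences} (mismatches + gap columns),
#'   \code{identity} (percent of alignment columns identical),
#'   \code{alignment_length}.
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = 0,
                              gap_open = 5, gap_extend = 1) {
  aa <- "ACDEFGHIKLMNPQRSTVWY"
  ok <- function(s) nchar(s) > 0 &&
    !grepl(paste0("[^", aa, "]"), toupper(gsub("\\s", "", s)))
  seq_a <- toupper(gsub("\\s", "", seq_a))
  seq_b <- toupper(gsub("\\s", "", seq_b))
  if (!ok(seq_a) || !ok(seq_b))
    stop("pairwise_identity: sequences must be non-empty and contain only ",
         "the 20 standard amino-acid letters")
  letters20 <- strsplit(aa, "")[[1]]
  m <- matrix(mismatch, 20, 20, dimnames = list(letters20, letters20))
  diag(m) <- match
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = m,
    gapOpening = gap_open, gapExtension = gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  n <- length(ap)
  matches <- sum(ap == as_ & ap != "-")
  list(differences = n - matches, identity = 100 * matches / n,
       alignment_length = n)
}
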