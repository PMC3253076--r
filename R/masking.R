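#' Masking configuration
#'
#' Thresholds for excluding alignment columns before variant calling:
#' low-quality sites (either haplotype's phred below `min_phred`; the
#' conventional cutoff is 50, and the comparison is strict, so phred 50
#' passes and 49 fails) and simple/low-complexity sequence found by a
#' DUST-style trinucleotide over-representation score in sliding windows.
#'
#' @param min_phred Quality threshold; a column is quality-masked when
#'   either row's base has phred < `min_phred`.  Set 0 to disable.
#' @param dust_window Window length in bases (>= 3) for the complexity
#'   scan; windows advance by half their length.
#' @param dust_threshold Score above which a window is masked; the score is
#'   `10 * sum(c_t * (c_t - 1) / 2) / (n_triplets - 1)` over triplet counts
#'   `c_t` in the window.  Set `Inf` to disable complexity masking.
#' @param mask_n Label columns containing N as AMBIGUOUS.
#' @return An object of class `mask_config`.
#' @export
mask_config <- function(min_phred = 50L, dust_window = 64L,
                        dust_threshold = 20, mask_n = TRUE) {
  stopifnot(.is_count(min_phred), dust_window >= 3, dust_threshold >= 0,
            is.logical(mask_n))
  structure(list(min_phred = as.integer(min_phred),
                 dust_window = as.integer(dust_window),
                 dust_threshold = dust_threshold, mask_n = mask_n),
            class = "mask_config")
}

#' Column labels, in precedence order (highest first)
#' @noRd
.MASK_LEVELS <- c("GAP", "AMBIGUOUS", "QUAL_MASKED", "COMPLEXITY_MASKED",
                  "CLEAN")

#' DUST-style low-complexity scan of an ungapped sequence
#'
#' Scores overlapping windows (step = half window, last window anchored at
#' the sequence end) by trinucleotide over-representation and flags every
#' base of any window whose score exceeds the threshold.  Conservative by
#' construction: a flagged window is masked whole.
#'
#' @param seq Ungapped sequence string.
#' @param window Window length in bases.
#' @param threshold Score threshold (see [mask_config()]).
#' @return Logical vector, one element per base, `TRUE` where masked.
#' @export
dust_mask <- function(seq, window = 64L, threshold = 20) {
  n <- nchar(seq)
  flag <- logical(n)
  if (!is.finite(threshold) || n < 3L) return(flag)
  code <- match(.s2c(seq), .BASES) - 1L       # NA for non-ACGT
  trip <- code[1:(n - 2L)] * 16L + code[2:(n - 1L)] * 4L + code[3:n] + 1L
  win <- min(window, n)
  step <- max(1L, win %/% 2L)
  starts <- unique(c(seq.int(1L, n - win + 1L, by = step), n - win + 1L))
  for (s in starts) {
    tw <- trip[s:min(s + win - 3L, n - 2L)]
    tw <- tw[!is.na(tw)]
    m <- length(tw)
    if (m < 2L) next
    cnt <- tabulate(tw, nbins = 64L)
    score <- 10 * sum(cnt * (cnt - 1L) / 2) / (m - 1L)
    if (score > threshold) flag[s:(s + win - 1L)] <- TRUE
  }
  flag
}

#' Mask a pairwise alignment by quality and sequence complexity
#'
#' Classifies every alignment column as one of `GAP` (either row gapped),
#' `AMBIGUOUS` (either base N), `QUAL_MASKED` (either row's phred below the
#' threshold), `COMPLEXITY_MASKED` (inside a DUST-flagged window on either
#' ungapped row, projected onto columns) or `CLEAN`, with precedence
#' GAP > AMBIGUOUS > QUAL_MASKED > COMPLEXITY_MASKED.  Only CLEAN columns
#' count as aligned sites.  The quality rule is symmetric: a site is
#' excluded when *either* haplotype is unreliable.
#'
#' @param aln A [pairwise_alignment()].
#' @param qualA,qualB Integer phred tracks, one value per ungapped base of
#'   each row; `NULL` means "all high quality" (no quality masking).
#' @param cfg A [mask_config()].
#' @return An object of class `masked_alignment`: the alignment plus
#'   per-column `labels`, the CLEAN-column count `aligned_sites`, and the
#'   pre-precedence per-column logical flags used by downstream callers.
#' @export
mask_alignment <- function(aln, qualA = NULL, qualB = NULL,
                           cfg = mask_config()) {
  stopifnot(inherits(aln, "pairwise_alignment"), inherits(cfg, "mask_config"))
  rA <- .s2raw(aln$rowA); rB <- .s2raw(aln$rowB)
  n <- length(rA)
  gapA <- rA == .GAP; gapB <- rB == .GAP
  gap <- gapA | gapB

  seqA <- .ungap(aln$rowA); seqB <- .ungap(aln$rowB)
  nA <- nchar(seqA); nB <- nchar(seqB)
  if (is.null(qualA)) qualA <- rep.int(.Machine$integer.max, nA)
  if (is.null(qualB)) qualB <- rep.int(.Machine$integer.max, nB)
  if (length(qualA) != nA)
    stop("quality track A has ", length(qualA), " values but row A has ",
         nA, " bases")
  if (length(qualB) != nB)
    stop("quality track B has ", length(qualB), " values but row B has ",
         nB, " bases")

  qcolA <- rep.int(NA_integer_, n); qcolA[!gapA] <- qualA
  qcolB <- rep.int(NA_integer_, n); qcolB[!gapB] <- qualB
  lowq <- (!is.na(qcolA) & qcolA < cfg$min_phred) |
          (!is.na(qcolB) & qcolB < cfg$min_phred)

  amb <- if (cfg$mask_n) (rA == charToRaw("N")) | (rB == charToRaw("N"))
         else logical(n)

  cplx <- logical(n)
  if (is.finite(cfg$dust_threshold)) {
    fA <- dust_mask(seqA, cfg$dust_window, cfg$dust_threshold)
    fB <- dust_mask(seqB, cfg$dust_window, cfg$dust_threshold)
    cA <- logical(n); cA[!gapA] <- fA
    cB <- logical(n); cB[!gapB] <- fB
    cplx <- cA | cB
  }

  labels <- rep.int("CLEAN", n)
  labels[cplx] <- "COMPLEXITY_MASKED"
  labels[lowq] <- "QUAL_MASKED"
  labels[amb] <- "AMBIGUOUS"
  labels[gap] <- "GAP"

  structure(list(region_id = aln$region_id, rowA = aln$rowA, rowB = aln$rowB,
                 startA = aln$startA, startB = aln$startB,
                 blocks = aln$blocks, labels = labels,
                 aligned_sites = sum(labels == "CLEAN"),
                 flags = list(gap = gap, ambiguous = amb, low_quality = lowq,
                              complexity = cplx),
                 config = cfg),
            class = "masked_alignment")
}

.ungap <- function(row) gsub("-", "", row, fixed = TRUE)

#' @export
print.masked_alignment <- function(x, ...) {
  cat("Masked alignment '", x$region_id, "': ", length(x$labels),
      " columns, ", x$aligned_sites, " aligned (CLEAN) sites\n", sep = "")
  print(masked_fraction(x))
  invisible(x)
}

#' Per-label column counts of a masked alignment
#'
#' @param m A `masked_alignment`.
#' @return Named integer vector over all five labels; the counts partition
#'   the columns and always sum to the gapped alignment length.
#' @export
masked_fraction <- function(m) {
  stopifnot(inherits(m, "masked_alignment"))
  cnt <- table(factor(m$labels, levels = .MASK_LEVELS))
  stats::setNames(as.integer(cnt), .MASK_LEVELS)
}

#' Write masked runs as BED
#'
#' One record per maximal run of non-CLEAN columns, either in alignment
#' column space or projected onto haplotype-A coordinates (columns that are
#' gap in A attach to the preceding A base).  BED output is 0-based
#' half-open.
#'
#' @param m A `masked_alignment`.
#' @param path Output file.
#' @param space `"column"` or `"hapA"`.
#' @return Invisibly, `path`.
#' @export
write_mask_bed <- function(m, path, space = c("column", "hapA")) {
  space <- match.arg(space)
  masked <- m$labels != "CLEAN"
  r <- rle(masked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) { writeLines(character(0), path); return(invisible(path)) }
  s <- starts[keep]; e <- ends[keep]
  lab <- vapply(seq_along(s), function(i) {
    paste(unique(m$labels[s[i]:e[i]]), collapse = ",")
  }, "")
  if (space == "hapA") {
    posA <- .posA_of_column(m)
    s <- pmax(posA[s], 1L); e <- pmax(posA[e], 1L)
  }
  bed <- data.frame(chrom = m$region_id, start = s - 1L, end = e, name = lab)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Haplotype-A position of each column; columns gapped in A carry the
# position of the last preceding A base (0 before the first).
.posA_of_column <- function(m) {
  cumsum(.s2raw(m$rowA) != .GAP)
}
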