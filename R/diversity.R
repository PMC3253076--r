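#' Per-region diversity summary
#'
#' Pairwise heterozygosity between the two haplotypes of one region:
#' `pi = n_snps / aligned_sites` (substitutions per site), with the
#' denominator counting only CLEAN columns — i.e. sites surviving quality
#' and complexity masking.  No multiple-hit correction is applied; at the
#' divergence of two haplotypes of one individual (pi ~ 1e-2) the
#' correction would be far below the reporting precision.
#'
#' @param x A [variant_catalog()], or a single integer SNP count when
#'   building a summary from published per-locus counts (then supply
#'   `aligned_sites` etc. directly).
#' @param region_id,aligned_sites,n_indels,indel_min,indel_max Used only
#'   for the count-based form.
#' @return A one-row data frame of class `region_diversity` with columns
#'   `region_id`, `aligned_sites`, `n_snps`, `pi`, `n_indels`,
#'   `indel_min`, `indel_max`.
#' @examples
#' region_diversity(1518, "Crh", 138103)   # pi x 1000 of 11.0
#' @export
region_diversity <- function(x, region_id = "region", aligned_sites = NULL,
                             n_indels = NA_integer_,
                             indel_min = NA_integer_,
                             indel_max = NA_integer_) {
  if (inherits(x, "variant_catalog")) {
    spec <- indel_spectrum(x)
    return(region_diversity(nrow(x$snps), region_id = x$region_id,
                            aligned_sites = x$aligned_sites,
                            n_indels = nrow(x$indels),
                            indel_min = spec$min, indel_max = spec$max))
  }
  stopifnot(.is_count(x), !is.null(aligned_sites))
  if (aligned_sites <= 0)
    stop("pi undefined: region '", region_id, "' has no aligned sites")
  out <- data.frame(region_id = region_id,
                    aligned_sites = as.integer(aligned_sites),
                    n_snps = as.integer(x),
                    pi = x / aligned_sites,
                    n_indels = as.integer(n_indels),
                    indel_min = as.integer(indel_min),
                    indel_max = as.integer(indel_max))
  class(out) <- c("region_diversity", "data.frame")
  out
}

#' Pool per-region diversity into a study-wide summary
#'
#' Pooling is site-weighted: the pooled pi is total SNPs over total aligned
#' sites, never the mean of per-region pi values, so splitting or reordering
#' regions cannot change it.  The SNP:indel ratio is total SNPs over total
#' indel events (undefined, `NA`, when no indels were counted).
#'
#' @param regions A data frame of stacked [region_diversity()] rows (or a
#'   list of them).
#' @return An object of class `diversity_summary`.
#' @export
pool_regions <- function(regions) {
  if (is.list(regions) && !is.data.frame(regions))
    regions <- do.call(rbind, regions)
  stopifnot(is.data.frame(regions), nrow(regions) >= 1L)
  total_sites <- sum(regions$aligned_sites)
  total_snps <- sum(regions$n_snps)
  total_indels <- if (all(is.na(regions$n_indels))) NA_integer_
                  else sum(regions$n_indels, na.rm = TRUE)
  structure(list(
    regions = regions,
    total_sites = total_sites,
    total_snps = total_snps,
    total_indels = total_indels,
    pooled_pi = total_snps / total_sites,
    snp_indel_ratio = if (!is.na(total_indels) && total_indels > 0)
      total_snps / total_indels else NA_real_,
    pi_min = min(regions$pi), pi_max = max(regions$pi)),
    class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("Diversity over", nrow(x$regions), "regions:",
      x$total_snps, "SNPs /", x$total_sites, "aligned sites\n")
  cat(sprintf("  pooled pi = %.4g (range %.4g-%.4g); %s indels%s\n",
              x$pooled_pi, x$pi_min, x$pi_max,
              ifelse(is.na(x$total_indels), "NA", x$total_indels),
              ifelse(is.na(x$snp_indel_ratio), "",
                     sprintf(", SNP:indel = %.1f", x$snp_indel_ratio))))
  invisible(x)
}

# Half-up decimal rounding (sprintf/round use round-half-even).
.round_half_up <- function(x, digits = 0L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Render a diversity summary as a per-locus table
#'
#' Columns: Region, Aligned sites, SNPs, pi (x 10^-3, one decimal,
#' half-up), Indels, Indel size range.  A Total row holds column sums and
#' the site-weighted pooled pi.
#'
#' @param summary A [pool_regions()] result.
#' @param path Optional TSV output file.
#' @return The rendered data frame (invisibly if `path` is given).
#' @export
diversity_table <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "diversity_summary"))
  r <- summary$regions
  rng <- ifelse(is.na(r$indel_min), NA_character_,
                paste0(r$indel_min, "-", r$indel_max, " bp"))
  tab <- data.frame(
    Region = c(r$region_id, "Total"),
    `Aligned sites` = c(r$aligned_sites, summary$total_sites),
    SNPs = c(r$n_snps, summary$total_snps),
    `pi (x10^-3)` = sprintf("%.1f", .round_half_up(
      c(r$pi, summary$pooled_pi) * 1e3, 1L)),
    Indels = c(r$n_indels, summary$total_indels),
    `Indel size range` = c(rng, if (all(is.na(r$indel_min))) NA_character_
      else paste0(min(r$indel_min, na.rm = TRUE), "-",
                  max(r$indel_max, na.rm = TRUE), " bp")),
    check.names = FALSE)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Kimura two-parameter distance with standard error
#'
#' Estimates substitutions per site between two aligned nucleotide rows
#' from the transition proportion P and transversion proportion Q over the
#' comparable columns:
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, with the Kimura (1980)
#' delta-method standard error
#' `SE = sqrt((a^2 P + c^2 Q - (a P + c Q)^2) / n)` where
#' `a = 1/(1 - 2P - Q)`, `b = 1/(1 - 2Q)`, `c = (a + b)/2`.
#'
#' @param x A `masked_alignment` (only CLEAN both-base columns are
#'   compared) or a gapped/ungapped sequence string.
#' @param y Second sequence string when `x` is a string.
#' @return An object of class `k2p_result`: `n_sites`, `P`, `Q`, `K`, `SE`.
#' @examples
#' a <- strrep("A", 1000)
#' b <- paste0(strrep("G", 100), strrep("C", 50), strrep("A", 850))
#' kimura2p(a, b)   # P = 0.1, Q = 0.05
#' @export
kimura2p <- function(x, y = NULL) {
  if (inherits(x, "masked_alignment")) {
    rA <- .s2raw(x$rowA); rB <- .s2raw(x$rowB)
    keep <- x$labels == "CLEAN"
    rA <- rA[keep]; rB <- rB[keep]
  } else {
    stopifnot(is.character(x), is.character(y))
    rA <- .s2raw(toupper(x)); rB <- .s2raw(toupper(y))
    if (length(rA) != length(rB)) stop("sequences of unequal length")
    keep <- rA %in% .BASE_RAW & rB %in% .BASE_RAW
    rA <- rA[keep]; rB <- rB[keep]
  }
  n <- length(rA)
  if (n < 1L) stop("no comparable (both-base, unmasked) columns")
  diff <- rA != rB
  # transitions: A<->G, C<->T; purines are A,G
  pur <- charToRaw("AG")
  ts <- diff & ((rA %in% pur) == (rB %in% pur))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturation: Kimura 2-parameter distance undefined for P = ",
         signif(P, 4), ", Q = ", signif(Q, 4))
  K <- -0.5 * log(w1 * sqrt(w2))
  a <- 1 / w1; b <- 1 / w2; cc <- (a + b) / 2
  SE <- sqrt((a^2 * P + cc^2 * Q - (a * P + cc * Q)^2) / n)
  structure(list(n_sites = n, P = P, Q = Q, K = K, SE = SE),
            class = "k2p_result")
}

#' @export
print.k2p_result <- function(x, ...) {
  cat(sprintf(
    "K2P distance: %.4f +/- %.4f substitutions/site (%d sites; P = %.4g, Q = %.4g)\n",
    .round_half_up(x$K, 4L), .round_half_up(x$SE, 4L), x$n_sites, x$P, x$Q))
  invisible(x)
}
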