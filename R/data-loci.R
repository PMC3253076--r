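#' Published per-locus SNP and indel counts for the 13 prairie-vole loci
#'
#' The per-locus aligned-site, SNP and indel-event counts from the
#' published survey of nucleotide diversity between the alternative
#' haplotype BAC assemblies of a single prairie vole, shipped as plain TSV.
#' Feeding these counts through [region_diversity()] and [pool_regions()]
#' reproduces the published per-locus and pooled pi values; the package's
#' worked example and acceptance script use them as input.
#'
#' @param path TSV path; defaults to the shipped table.
#' @return Data frame with columns `region_id`, `aligned_sites`, `n_snps`,
#'   `n_indels`, `indel_min`, `indel_max`.
#' @export
vole_loci_counts <- function(path = system.file("extdata",
                                                "vole_loci_counts.tsv",
                                                package = "haplodiv")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Diversity summary for a published count table
#'
#' Convenience wrapper: one [region_diversity()] row per table row, pooled
#' with [pool_regions()].
#'
#' @param counts Data frame in the [vole_loci_counts()] layout.
#' @return A `diversity_summary`.
#' @examples
#' s <- diversity_from_counts(vole_loci_counts())
#' diversity_table(s)
#' @export
diversity_from_counts <- function(counts = vole_loci_counts()) {
  rows <- lapply(seq_len(nrow(counts)), function(i)
    region_diversity(counts$n_snps[i], region_id = counts$region_id[i],
                     aligned_sites = counts$aligned_sites[i],
                     n_indels = counts$n_indels[i],
                     indel_min = counts$indel_min[i],
                     indel_max = counts$indel_max[i]))
  pool_regions(do.call(rbind, rows))
}
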