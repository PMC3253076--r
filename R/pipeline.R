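#' Pipeline configuration
#'
#' Single place for every tunable threshold of the end-to-end run, with the
#' defaults used throughout: strict phred-50 masking, DUST window 64 /
#' threshold 20, indels dropped when fully inside complexity-masked
#' sequence.
#'
#' @param min_phred Quality masking threshold (see [mask_config()]).
#' @param dust_window,dust_threshold DUST parameters.
#' @param mask_n Treat N columns as ambiguous.
#' @param count_masked_indels Keep indel events inside complexity-masked
#'   regions (see [call_indels()]).
#' @param codon_min_phred Codon admissibility threshold for coding
#'   analysis.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_phred = 50L, dust_window = 64L,
                            dust_threshold = 20, mask_n = TRUE,
                            count_masked_indels = FALSE,
                            codon_min_phred = 50L) {
  structure(list(mask = mask_config(min_phred, dust_window, dust_threshold,
                                    mask_n),
                 count_masked_indels = count_masked_indels,
                 codon_min_phred = as.integer(codon_min_phred)),
            class = "pipeline_config")
}

#' Read a region manifest
#'
#' TSV with header columns `region_id`, `alignment`, `qual_a`, `qual_b`
#' and optional `cds` (BED) and `proteins` (aligned FASTA); empty cells
#' mean "not available for this region".  Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path Manifest TSV.
#' @return Data frame with one row per region.
#' @export
read_region_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("region_id", "alignment", "qual_a", "qual_b")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(man$region_id))
    stop("duplicate region_id in manifest")
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | grepl("^/", p), p,
                            file.path(base, p))
  for (col in intersect(c("alignment", "qual_a", "qual_b", "cds",
                          "proteins"), names(man)))
    man[[col]] <- fix(man[[col]])
  man
}

.read_bed_cds <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  bed$strand <- if (ncol(bed) >= 6L) bed[[6L]] else "+"
  bed
}

#' Run the full per-region pipeline from a manifest
#'
#' For every region: load the pairwise alignment and quality tracks, mask,
#' call SNPs and indels, and summarise diversity; where a CDS annotation is
#' given, classify coding SNPs and count NG86 sites; where a protein
#' alignment is given, call and classify focal-lineage substitutions.
#' Everything is deterministic — rerunning on the same inputs reproduces
#' the report byte for byte.
#'
#' @param manifest Data frame from [read_region_manifest()] (or built in
#'   code with the same columns).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: per-region VCFs, the per-locus
#'   diversity table (`diversity.tsv`) and a JSON report
#'   (`report.json`) are written there.
#' @param keep_going On a region failure, record the error and continue
#'   instead of aborting.
#' @return An object of class `pipeline_report`: `catalogs` (named list),
#'   `diversity` ([pool_regions()] result), `coding` (or `NULL`),
#'   `lineage` (or `NULL`), `errors` (named list), `config`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = NULL, keep_going = FALSE) {
  stopifnot(is.data.frame(manifest))
  if (!nrow(manifest)) stop("no regions in manifest")
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  catalogs <- list(); regions <- list(); pairs <- list()
  lineage_calls <- list(); errors <- list()

  for (i in seq_len(nrow(manifest))) {
    rid <- manifest$region_id[i]
    res <- tryCatch({
      aln <- load_alignment(manifest$alignment[i], region_id = rid)
      qa <- if (!is.na(manifest$qual_a[i])) read_qual(manifest$qual_a[i])
      qb <- if (!is.na(manifest$qual_b[i])) read_qual(manifest$qual_b[i])
      m <- mask_alignment(aln, qa, qb, cfg = config$mask)
      cat_i <- variant_catalog(m, count_masked = config$count_masked_indels)
      catalogs[[rid]] <- cat_i
      regions[[rid]] <- region_diversity(cat_i)
      if ("cds" %in% names(manifest) && !is.na(manifest$cds[i])) {
        bed <- .read_bed_cds(manifest$cds[i])
        for (g in unique(bed$chrom)) {
          pairs[[paste(rid, g, sep = ":")]] <- build_codon_alignment(
            m, bed[bed$chrom == g, , drop = FALSE], qa, qb,
            min_phred = config$codon_min_phred,
            gene_id = paste(rid, g, sep = ":"))
        }
      }
      if ("proteins" %in% names(manifest) && !is.na(manifest$proteins[i])) {
        sa <- read_species_alignment(manifest$proteins[i])
        lineage_calls[[rid]] <- call_focal_substitutions(sa)
      }
      if (!is.null(out_dir))
        write_vcf(catalogs[[rid]], file.path(out_dir,
                                             paste0(rid, ".vcf")))
      NULL
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- paste0("region '", rid, "': ", conditionMessage(res))
      if (!keep_going) stop(msg, call. = FALSE)
      errors[[rid]] <- msg
      message("skipping ", msg)
    }
  }

  if (!length(regions))
    stop("no regions completed successfully")
  diversity <- pool_regions(do.call(rbind, unname(regions)))
  coding <- if (length(pairs)) coding_summary(pairs) else NULL
  lineage <- if (length(lineage_calls))
    summarize_lineage(do.call(rbind, unname(lineage_calls))) else NULL

  report <- structure(list(catalogs = catalogs, diversity = diversity,
                           coding = coding, lineage = lineage,
                           errors = errors, config = config),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    diversity_table(diversity, file.path(out_dir, "diversity.tsv"))
    jsonlite::write_json(report_as_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Flatten a pipeline report to plain lists for JSON export
#' @param report A `pipeline_report`.
#' @return A nested list of plain vectors and data frames.
#' @export
report_as_list <- function(report) {
  d <- report$diversity
  list(
    regions = d$regions,
    pooled = list(total_sites = d$total_sites, total_snps = d$total_snps,
                  total_indels = d$total_indels, pooled_pi = d$pooled_pi,
                  snp_indel_ratio = d$snp_indel_ratio,
                  pi_min = d$pi_min, pi_max = d$pi_max),
    coding = if (!is.null(report$coding)) as.data.frame(report$coding),
    lineage = if (!is.null(report$lineage))
      list(per_protein = report$lineage$per_protein,
           total = as.list(report$lineage$total),
           n_dedup = report$lineage$n_dedup),
    errors = report$errors,
    config = list(min_phred = report$config$mask$min_phred,
                  dust_window = report$config$mask$dust_window,
                  dust_threshold = report$config$mask$dust_threshold,
                  mask_n = report$config$mask$mask_n,
                  count_masked_indels = report$config$count_masked_indels,
                  codon_min_phred = report$config$codon_min_phred))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report:", length(x$catalogs), "region(s)")
  if (length(x$errors)) cat(",", length(x$errors), "failed")
  cat("\n")
  print(x$diversity)
  if (!is.null(x$coding)) {
    tot <- x$coding[x$coding$gene_id == "Total", ]
    cat(sprintf("  coding: %d syn / %d nonsyn SNPs (dS = %.3g, dN = %.3g)\n",
                tot$n_syn, tot$n_nonsyn, tot$dS, tot$dN))
  }
  if (!is.null(x$lineage))
    cat(sprintf("  lineage: %d conservative / %d radical focal substitutions\n",
                x$lineage$total[["n_conservative"]],
                x$lineage$total[["n_radical"]]))
  invisible(x)
}
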