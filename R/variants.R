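#' Call SNPs from a masked alignment
#'
#' A SNP is a CLEAN column at which the two haplotypes carry different
#' bases.  Masked columns (quality, complexity, ambiguity, gap) never yield
#' SNPs, so raising the phred threshold can only shrink the call set.
#'
#' @param m A [mask_alignment()] result.
#' @return Data frame with columns `region_id`, `column` (1-based alignment
#'   column), `posA` (1-based haplotype-A position), `alleleA`, `alleleB`,
#'   sorted by column.
#' @export
call_snps <- function(m) {
  stopifnot(inherits(m, "masked_alignment"))
  rA <- .s2raw(m$rowA); rB <- .s2raw(m$rowB)
  idx <- which(m$labels == "CLEAN" & rA != rB)
  posA <- .posA_of_column(m)
  data.frame(region_id = rep.int(m$region_id, length(idx)),
             column = idx, posA = posA[idx] + (m$startA - 1L),
             alleleA = rawToChar(rA[idx], multiple = TRUE),
             alleleB = rawToChar(rB[idx], multiple = TRUE))
}

#' Call indel events from a masked alignment
#'
#' One event per maximal run of gap characters in a single row; the event
#' length is the run length, so a 3-bp deletion counts once.  Quality
#' masking does not apply (a gap has no base quality), but events lying
#' entirely inside complexity-masked sequence are dropped by default
#' because repeat tracts produce alignment-ambiguous gaps; set
#' `count_masked = TRUE` to keep them.
#'
#' @param m A `masked_alignment`.
#' @param count_masked Keep events fully inside complexity-masked columns.
#' @return Data frame with columns `region_id`, `column` (first gap column),
#'   `length`, `carrier` ("A" or "B", the row holding the gap), `posA`
#'   (first deleted haplotype-A base for B-carrier events; the preceding
#'   anchor base for A-carrier events) and `anchor` (haplotype-A base just
#'   before the event, `NA` at alignment start).
#' @export
call_indels <- function(m, count_masked = FALSE) {
  stopifnot(inherits(m, "masked_alignment"))
  posA <- .posA_of_column(m)
  one_row <- function(gaps, carrier) {
    r <- rle(gaps)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    s <- starts[keep]; l <- r$lengths[keep]
    data.frame(column = s, length = l, carrier = carrier)
  }
  rA <- .s2raw(m$rowA); rB <- .s2raw(m$rowB)
  ev <- rbind(one_row(rA == .GAP, "A"), one_row(rB == .GAP, "B"))
  if (is.null(ev) || !nrow(ev))
    return(data.frame(region_id = character(0), column = integer(0),
                      length = integer(0), carrier = character(0),
                      posA = integer(0), anchor = character(0)))
  ev <- ev[order(ev$column), , drop = FALSE]
  if (!count_masked) {
    inside <- vapply(seq_len(nrow(ev)), function(i) {
      cols <- ev$column[i]:(ev$column[i] + ev$length[i] - 1L)
      all(m$flags$complexity[cols])
    }, logical(1))
    ev <- ev[!inside, , drop = FALSE]
  }
  if (!nrow(ev))
    return(data.frame(region_id = character(0), column = integer(0),
                      length = integer(0), carrier = character(0),
                      posA = integer(0), anchor = character(0)))
  # posA: for a gap-in-B event the first columns hold A bases; for a
  # gap-in-A event posA is the preceding A base (the anchor position).
  pA <- integer(nrow(ev)); anch <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    st <- ev$column[i]
    if (ev$carrier[i] == "B") {
      pA[i] <- posA[st]
      anch[i] <- if (posA[st] > 1L)
        substr(.ungap(m$rowA), posA[st] - 1L, posA[st] - 1L) else NA_character_
    } else {
      pA[i] <- posA[st]           # preceding A base (0 at alignment start)
      anch[i] <- if (posA[st] >= 1L)
        substr(.ungap(m$rowA), posA[st], posA[st]) else NA_character_
    }
  }
  out <- data.frame(region_id = rep.int(m$region_id, nrow(ev)),
                    column = ev$column, length = ev$length,
                    carrier = ev$carrier,
                    posA = pA + (m$startA - 1L), anchor = anch)
  rownames(out) <- NULL
  out
}

#' Build a per-region variant catalog
#'
#' Bundles the SNP and indel calls of one region with its aligned-site
#' count; the unit consumed by [region_diversity()] and [write_vcf()].
#'
#' @param m A `masked_alignment`.
#' @param count_masked Passed to [call_indels()].
#' @return An object of class `variant_catalog` with fields `region_id`,
#'   `snps`, `indels`, `aligned_sites`, and the haplotype-A sequence
#'   (`seqA`, for VCF anchoring) plus haplotype-B row for reconstruction.
#' @export
variant_catalog <- function(m, count_masked = FALSE) {
  stopifnot(inherits(m, "masked_alignment"))
  snps <- call_snps(m)
  indels <- call_indels(m, count_masked = count_masked)
  if (is.unsorted(snps$column, strictly = TRUE))
    stop("internal error: SNP columns not strictly increasing")
  structure(list(region_id = m$region_id, snps = snps, indels = indels,
                 aligned_sites = m$aligned_sites,
                 seqA = .ungap(m$rowA), rowB = m$rowB, rowA = m$rowA,
                 startA = m$startA),
            class = "variant_catalog")
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat("Variant catalog '", x$region_id, "': ", nrow(x$snps), " SNPs, ",
      nrow(x$indels), " indel events over ", x$aligned_sites,
      " aligned sites\n", sep = "")
  invisible(x)
}

#' Indel length spectrum
#'
#' @param catalog A `variant_catalog` (or any data frame with a `length`
#'   column).
#' @return List with `histogram` (named integer vector, length -> count,
#'   ascending), `min` and `max` (both `NA` for an empty catalog), and a
#'   `range_label` rendered like "1-3054 bp".
#' @export
indel_spectrum <- function(catalog) {
  lens <- if (inherits(catalog, "variant_catalog")) catalog$indels$length
          else catalog$length
  if (!length(lens))
    return(list(histogram = integer(0), min = NA_integer_,
                max = NA_integer_, range_label = NA_character_))
  tab <- table(lens)
  hist <- stats::setNames(as.integer(tab), names(tab))
  list(histogram = hist, min = min(lens), max = max(lens),
       range_label = paste0(min(lens), "-", max(lens), " bp"))
}

# Left-align an indel within homopolymer/repeat context against the
# haplotype-A reference: while the base before the event equals the last
# base of the inserted/deleted run, rotate the run one step left.
.left_align <- function(pos, alleles, ref_chars) {
  while (pos > 1L && ref_chars[pos - 1L] == alleles[length(alleles)]) {
    alleles <- c(ref_chars[pos - 1L], alleles[-length(alleles)])
    pos <- pos - 1L
  }
  list(pos = pos, alleles = alleles)
}

#' Write a variant catalog as VCF 4.3
#'
#' Haplotype A is the reference.  SNPs become single-base REF/ALT records;
#' indels are left-aligned within homopolymer context and written with the
#' preceding reference base as anchor.  An indel with no preceding base
#' (alignment start) is emitted with the following-base convention and a
#' warning.
#'
#' @param catalog A [variant_catalog()].
#' @param path Output file.
#' @param refname Contig name written to the header and CHROM field
#'   (default: the region id).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(catalog, path, refname = catalog$region_id) {
  stopifnot(inherits(catalog, "variant_catalog"))
  refc <- .s2c(catalog$seqA)
  off <- catalog$startA - 1L
  recs <- list()

  sn <- catalog$snps
  if (nrow(sn))
    recs[[length(recs) + 1L]] <-
      data.frame(pos = sn$posA, ref = sn$alleleA, alt = sn$alleleB)

  ind <- catalog$indels
  rowB <- .s2c(catalog$rowB)
  for (i in seq_len(nrow(ind))) {
    st <- ind$column[i]; len <- ind$length[i]
    if (ind$carrier[i] == "B") {
      # deletion relative to A: REF = anchor + deleted bases, ALT = anchor
      p <- ind$posA[i] - off                   # first deleted base, local
      run <- refc[p:(p + len - 1L)]
      la <- .left_align(p, run, refc)
      p <- la$pos; run <- la$alleles
      if (p > 1L) {
        recs[[length(recs) + 1L]] <- data.frame(
          pos = p - 1L + off,
          ref = .c2s(c(refc[p - 1L], run)), alt = refc[p - 1L])
      } else {
        warning("deletion at reference start in '", catalog$region_id,
                "': using following-base anchor")
        fol <- refc[p + len]
        recs[[length(recs) + 1L]] <- data.frame(
          pos = p + off, ref = .c2s(c(run, fol)), alt = fol)
      }
    } else {
      # insertion relative to A: inserted bases live in row B
      run <- rowB[st:(st + len - 1L)]
      p <- ind$posA[i] - off + 1L              # ref base after the anchor
      la <- .left_align(p, run, refc)
      p <- la$pos; run <- la$alleles
      if (p > 1L) {
        recs[[length(recs) + 1L]] <- data.frame(
          pos = p - 1L + off,
          ref = refc[p - 1L], alt = .c2s(c(refc[p - 1L], run)))
      } else {
        warning("insertion at reference start in '", catalog$region_id,
                "': using following-base anchor")
        recs[[length(recs) + 1L]] <- data.frame(
          pos = 1L + off, ref = refc[1L], alt = .c2s(c(run, refc[1L])))
      }
    }
  }

  hdr <- c("##fileformat=VCFv4.3",
           paste0("##contig=<ID=", refname, ",length=",
                  length(refc) + off, ">"),
           paste0("##source=haplodiv"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (length(recs)) {
    df <- do.call(rbind, recs)
    df <- df[order(df$pos, df$ref, df$alt), , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", refname, df$pos,
                    df$ref, df$alt)
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
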