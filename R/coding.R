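#' Translate codons under a genetic code table
#' @param codons Character vector of 3-mers.
#' @param code Named character vector codon -> amino acid ("*" for stop);
#'   default the standard code.
#' @return Character vector of residues (`NA` for codons containing
#'   non-ACGT characters).
#' @export
translate_codons <- function(codons, code = Biostrings::GENETIC_CODE) {
  unname(code[codons])
}

#' Build an in-frame codon alignment for one gene
#'
#' Extracts the CDS of haplotype A from the masked alignment via BED-like
#' intervals (0-based half-open on haplotype-A coordinates), takes the
#' haplotype-B bases at the same alignment columns, and flags each codon
#' admissible only when all six underlying bases are unambiguous A/C/G/T
#' with phred at or above the threshold — codons with one or more sub-
#' threshold sites are excluded whole.  Minus-strand CDS are
#' reverse-complemented into reading-frame orientation.
#'
#' @param m A `masked_alignment`.
#' @param cds Data frame with columns `start`, `end` (0-based half-open,
#'   haplotype-A space) and `strand` ("+"/"-"); rows are exons of one CDS,
#'   joined in genomic order.
#' @param qualA,qualB Phred tracks of the ungapped rows (`NULL` = all
#'   high quality).
#' @param min_phred Codon admissibility threshold (strict `<` comparison,
#'   so phred exactly at the threshold passes).
#' @param gene_id Identifier carried into downstream records.
#' @return An object of class `codon_alignment`: `codonsA`, `codonsB`
#'   (character vectors of 3-mers, gaps as "-"), `admissible` (logical).
#' @export
build_codon_alignment <- function(m, cds, qualA = NULL, qualB = NULL,
                                  min_phred = 50L, gene_id = "gene") {
  stopifnot(inherits(m, "masked_alignment"),
            all(c("start", "end") %in% names(cds)))
  strand <- if ("strand" %in% names(cds)) unique(cds$strand) else "+"
  if (length(strand) != 1L) stop("mixed strands within one CDS")
  seqA <- .ungap(m$rowA); nA <- nchar(seqA)
  nB <- nchar(.ungap(m$rowB))
  if (is.null(qualA)) qualA <- rep.int(.Machine$integer.max, nA)
  if (is.null(qualB)) qualB <- rep.int(.Machine$integer.max, nB)
  stopifnot(length(qualA) == nA, length(qualB) == nB)

  cds <- cds[order(cds$start), , drop = FALSE]
  posA <- unlist(lapply(seq_len(nrow(cds)), function(i)
    (cds$start[i] + 1L):cds$end[i]))        # BED half-open -> 1-based
  if (any(posA < 1L | posA > nA))
    stop("CDS interval outside haplotype-A range 1..", nA)
  if (length(posA) %% 3L != 0L)
    stop("CDS length ", length(posA), " is not a multiple of 3")

  colA <- which(.s2raw(m$rowA) != .GAP)      # column of each A base
  cols <- colA[posA]
  chA <- .s2c(m$rowA)[cols]
  chB <- .s2c(m$rowB)[cols]
  posB <- cumsum(.s2raw(m$rowB) != .GAP)     # B position per column
  qA <- qualA[posA]
  qB <- ifelse(chB == "-", NA_integer_, qualB[posB[cols]])

  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")
    chA <- rev(unname(comp[chA])); chB <- rev(unname(comp[chB]))
    qA <- rev(qA); qB <- rev(qB)
  }

  n_codon <- length(chA) %/% 3L
  grp <- rep(seq_len(n_codon), each = 3L)
  codonsA <- vapply(split(chA, grp), .c2s, "")
  codonsB <- vapply(split(chB, grp), .c2s, "")
  base_ok <- chA %in% .BASES & chB %in% .BASES
  qual_ok <- qA >= min_phred & !is.na(qB) & qB >= min_phred
  admissible <- vapply(split(base_ok & qual_ok, grp), all, logical(1))

  structure(list(gene_id = gene_id, codonsA = unname(codonsA),
                 codonsB = unname(codonsB),
                 admissible = unname(admissible),
                 strand = strand),
            class = "codon_alignment")
}

#' Codon alignment straight from two in-frame CDS strings
#'
#' Convenience constructor for simulated or pre-extracted CDS pairs.
#'
#' @param cdsA,cdsB In-frame CDS strings of equal length (multiple of 3).
#' @param gene_id Identifier.
#' @param admissible Optional logical per codon; default: all codons whose
#'   six bases are A/C/G/T.
#' @return A `codon_alignment`.
#' @export
codon_alignment <- function(cdsA, cdsB, gene_id = "gene", admissible = NULL) {
  cdsA <- toupper(cdsA); cdsB <- toupper(cdsB)
  stopifnot(nchar(cdsA) == nchar(cdsB), nchar(cdsA) %% 3L == 0L)
  n <- nchar(cdsA) %/% 3L
  grp <- rep(seq_len(n), each = 3L)
  chA <- .s2c(cdsA); chB <- .s2c(cdsB)
  codonsA <- unname(vapply(split(chA, grp), .c2s, ""))
  codonsB <- unname(vapply(split(chB, grp), .c2s, ""))
  if (is.null(admissible))
    admissible <- unname(vapply(split(chA %in% .BASES & chB %in% .BASES, grp),
                                all, logical(1)))
  structure(list(gene_id = gene_id, codonsA = codonsA, codonsB = codonsB,
                 admissible = admissible, strand = "+"),
            class = "codon_alignment")
}

#' Classify coding SNPs as synonymous or nonsynonymous
#'
#' Each base difference inside an admissible codon yields one record,
#' classified by swapping that base alone into the haplotype-A codon
#' context: synonymous iff the encoded amino acid is unchanged.  Codons
#' differing at k > 1 positions yield k records, each judged with the
#' other positions held at the haplotype-A state.  A swap creating a stop
#' codon is nonsynonymous and flagged, never dropped.
#'
#' @param pair A `codon_alignment`.
#' @param code Genetic code table (codon -> residue, "*" = stop).
#' @return Data frame with columns `gene_id`, `codon_index`,
#'   `pos_in_codon` (1-3), `alleleA`, `alleleB`, `aaA`, `aaB`, `class`
#'   ("synonymous"/"nonsynonymous"), `creates_stop`.
#' @export
classify_coding_snps <- function(pair, code = Biostrings::GENETIC_CODE) {
  stopifnot(inherits(pair, "codon_alignment"))
  recs <- list()
  for (i in which(pair$admissible)) {
    ca <- pair$codonsA[i]; cb <- pair$codonsB[i]
    if (ca == cb) next
    a <- .s2c(ca); b <- .s2c(cb)
    for (p in which(a != b)) {
      mut <- a; mut[p] <- b[p]
      aaA <- unname(code[ca]); aaB <- unname(code[.c2s(mut)])
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = pair$gene_id, codon_index = i, pos_in_codon = p,
        alleleA = a[p], alleleB = b[p], aaA = aaA, aaB = aaB,
        class = if (aaA == aaB) "synonymous" else "nonsynonymous",
        creates_stop = aaB == "*" && aaA != "*")
    }
  }
  if (!length(recs))
    return(data.frame(gene_id = character(0), codon_index = integer(0),
                      pos_in_codon = integer(0), alleleA = character(0),
                      alleleB = character(0), aaA = character(0),
                      aaB = character(0), class = character(0),
                      creates_stop = logical(0)))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Nei-Gojobori (1986) synonymous/nonsynonymous site counts
#'
#' For each admissible haplotype-A codon, the synonymous site count is the
#' sum over its three positions of the fraction of the three alternative
#' bases whose single swap preserves the amino acid; mutations to stop
#' codons count as nonsynonymous.  N = 3 - S per codon, so S + N always
#' equals three times the admissible codon count.
#'
#' @param pair A `codon_alignment`.
#' @param code Genetic code table.
#' @return List with `S_sites`, `N_sites`, `n_codons` (admissible codons).
#' @export
ng86_site_counts <- function(pair, code = Biostrings::GENETIC_CODE) {
  stopifnot(inherits(pair, "codon_alignment"))
  idx <- which(pair$admissible)
  if (!length(idx)) stop("no admissible codons in gene '", pair$gene_id, "'")
  S <- sum(vapply(pair$codonsA[idx], .codon_syn_sites, 0, code = code))
  list(S_sites = S, N_sites = 3 * length(idx) - S, n_codons = length(idx))
}

.codon_syn_sites <- function(codon, code) {
  a <- .s2c(codon)
  aa <- unname(code[codon])
  s <- 0
  for (p in 1:3) {
    for (alt in setdiff(.BASES, a[p])) {
      mut <- a; mut[p] <- alt
      if (unname(code[.c2s(mut)]) == aa) s <- s + 1 / 3
    }
  }
  s
}

#' Summarise coding variation per gene and pooled
#'
#' dS = synonymous SNPs / synonymous sites, dN = nonsynonymous SNPs /
#' nonsynonymous sites; the pooled row sums numerators and denominators
#' across genes (so duplicating every gene's data leaves dS and dN
#' unchanged).
#'
#' @param pairs A list of `codon_alignment` objects, or `NULL` when
#'   supplying `snps` and `sites` directly.
#' @param snps Stacked [classify_coding_snps()] output.
#' @param sites Data frame with columns `gene_id`, `S_sites`, `N_sites`.
#' @param code Genetic code table.
#' @return Data frame of class `coding_summary`, one row per gene plus a
#'   "Total" row: `gene_id`, `n_syn`, `n_nonsyn`, `S_sites`, `N_sites`,
#'   `dS`, `dN`.
#' @export
coding_summary <- function(pairs = NULL, snps = NULL, sites = NULL,
                           code = Biostrings::GENETIC_CODE) {
  if (!is.null(pairs)) {
    snps <- do.call(rbind, lapply(pairs, classify_coding_snps, code = code))
    sites <- do.call(rbind, lapply(pairs, function(p) {
      sc <- ng86_site_counts(p, code = code)
      data.frame(gene_id = p$gene_id, S_sites = sc$S_sites,
                 N_sites = sc$N_sites)
    }))
  }
  stopifnot(!is.null(snps), !is.null(sites))
  per <- lapply(seq_len(nrow(sites)), function(i) {
    g <- sites$gene_id[i]
    sg <- snps[snps$gene_id == g, , drop = FALSE]
    data.frame(gene_id = g,
               n_syn = sum(sg$class == "synonymous"),
               n_nonsyn = sum(sg$class == "nonsynonymous"),
               S_sites = sites$S_sites[i], N_sites = sites$N_sites[i])
  })
  per <- do.call(rbind, per)
  tot <- data.frame(gene_id = "Total",
                    n_syn = sum(per$n_syn), n_nonsyn = sum(per$n_nonsyn),
                    S_sites = sum(per$S_sites), N_sites = sum(per$N_sites))
  out <- rbind(per, tot)
  out$dS <- ifelse(out$S_sites > 0, out$n_syn / out$S_sites, NA_real_)
  out$dN <- ifelse(out$N_sites > 0, out$n_nonsyn / out$N_sites, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("coding_summary", "data.frame")
  out
}
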