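#' Construct a pairwise alignment object
#'
#' Two gapped rows of equal length over \{A,C,G,T,N,-\}; row A is treated as
#' the reference haplotype throughout the package.  Columns that are gap in
#' both rows are disallowed.
#'
#' @param rowA,rowB Gapped sequences (single strings).
#' @param region_id Locus identifier.
#' @param startA,startB 1-based coordinate of the first aligned base of each
#'   row on its source sequence.
#' @param blocks Optional data frame of source-block metadata (for AXT/MAF
#'   input); blocks are concatenated, the unaligned sequence between blocks
#'   never enters the alignment and is excluded from all denominators.
#' @return An object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(rowA, rowB, region_id = "region",
                               startA = 1L, startB = 1L, blocks = NULL) {
  rowA <- toupper(rowA); rowB <- toupper(rowB)
  if (nchar(rowA) != nchar(rowB))
    stop("alignment rows have unequal gapped lengths (",
         nchar(rowA), " vs ", nchar(rowB), ")")
  rA <- .s2raw(rowA); rB <- .s2raw(rowB)
  ok <- charToRaw("ACGTN-")
  bad <- !(rA %in% ok) | !(rB %in% ok)
  if (any(bad))
    stop("invalid alignment character at column ", which(bad)[1L])
  if (any(rA == .GAP & rB == .GAP))
    stop("column gap in both rows at column ",
         which(rA == .GAP & rB == .GAP)[1L])
  structure(list(region_id = region_id, rowA = rowA, rowB = rowB,
                 startA = as.integer(startA), startB = as.integer(startB),
                 blocks = blocks),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Pairwise alignment '", x$region_id, "': ", nchar(x$rowA),
      " columns\n", sep = "")
  invisible(x)
}

#' Number of columns of a pairwise alignment
#' @param aln A `pairwise_alignment` (or `masked_alignment`).
#' @return Integer column count.
#' @export
alignment_ncol <- function(aln) nchar(aln$rowA)

.read_aligned_fasta <- function(path, region_id) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 2L)
    stop("aligned FASTA must contain exactly 2 rows, found ", length(ss),
         " in ", path)
  pairwise_alignment(as.character(ss[[1L]]), as.character(ss[[2L]]),
                     region_id = region_id)
}

.read_axt <- function(path, region_id) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  # Blocks: header line of >= 9 whitespace fields, then the two rows.
  i <- 1L; A <- character(0); B <- character(0); blocks <- list()
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(hdr) < 9L)
      stop("malformed AXT header at line ", i, " of ", path)
    if (i + 2L > length(lines))
      stop("truncated AXT block at line ", i, " of ", path)
    a <- toupper(trimws(lines[i + 1L])); b <- toupper(trimws(lines[i + 2L]))
    if (nchar(a) != nchar(b))
      stop("AXT block rows of unequal length at line ", i + 1L, " of ", path)
    blocks[[length(blocks) + 1L]] <- data.frame(
      chrA = hdr[2L], startA = as.integer(hdr[3L]), endA = as.integer(hdr[4L]),
      chrB = hdr[5L], startB = as.integer(hdr[6L]), endB = as.integer(hdr[7L]),
      strand = hdr[8L], ncol = nchar(a))
    A <- c(A, a); B <- c(B, b)
    i <- i + 3L
  }
  if (!length(blocks)) stop("no AXT blocks found in ", path)
  blocks <- do.call(rbind, blocks)
  pairwise_alignment(.c2s(A), .c2s(B), region_id = region_id,
                     startA = blocks$startA[1L], startB = blocks$startB[1L],
                     blocks = blocks)
}

.read_maf <- function(path, region_id) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  starts <- grep("^a( |$)", lines)
  if (!length(starts)) stop("no MAF blocks found in ", path)
  A <- character(0); B <- character(0); blocks <- list()
  for (s in starts) {
    j <- s + 1L; srows <- list()
    while (j <= length(lines) && grepl("^s ", lines[j])) {
      f <- strsplit(trimws(lines[j]), "\\s+")[[1L]]
      if (length(f) != 7L)
        stop("malformed MAF 's' line at line ", j, " of ", path)
      srows[[length(srows) + 1L]] <- f
      j <- j + 1L
    }
    if (length(srows) != 2L)
      stop("MAF block at line ", s, " of ", path, " has ", length(srows),
           " sequence rows; exactly 2 required")
    a <- srows[[1L]]; b <- srows[[2L]]
    if (nchar(a[7L]) != nchar(b[7L]))
      stop("MAF block rows of unequal length at line ", s, " of ", path)
    blocks[[length(blocks) + 1L]] <- data.frame(
      chrA = a[2L], startA = as.integer(a[3L]) + 1L,  # MAF is 0-based
      endA = as.integer(a[3L]) + as.integer(a[4L]),
      chrB = b[2L], startB = as.integer(b[3L]) + 1L,
      endB = as.integer(b[3L]) + as.integer(b[4L]),
      strand = b[5L], ncol = nchar(a[7L]))
    A <- c(A, toupper(a[7L])); B <- c(B, toupper(b[7L]))
  }
  blocks <- do.call(rbind, blocks)
  pairwise_alignment(.c2s(A), .c2s(B), region_id = region_id,
                     startA = blocks$startA[1L], startB = blocks$startB[1L],
                     blocks = blocks)
}

#' Load a two-row pairwise alignment
#'
#' Reads aligned FASTA (exactly two records), AXT or MAF.  Multi-block AXT
#' and MAF files are concatenated block by block with coordinates preserved
#' in the `blocks` field; unaligned sequence between blocks never appears
#' in the alignment.
#'
#' @param path Input file.
#' @param format One of `"auto"`, `"aligned-fasta"`, `"axt"`, `"maf"`; with
#'   `"auto"` the format is guessed from the file extension (.axt, .maf,
#'   anything else is treated as FASTA).
#' @param region_id Locus identifier attached to the alignment.
#' @return A [pairwise_alignment()].
#' @export
load_alignment <- function(path,
                           format = c("auto", "aligned-fasta", "axt", "maf"),
                           region_id = NULL) {
  format <- match.arg(format)
  if (is.null(region_id))
    region_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, axt = "axt", maf = "maf", "aligned-fasta")
  }
  switch(format,
         "aligned-fasta" = .read_aligned_fasta(path, region_id),
         "axt" = .read_axt(path, region_id),
         "maf" = .read_maf(path, region_id))
}

#' Write a pairwise alignment as aligned FASTA
#' @param aln A `pairwise_alignment`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(c(hapA = aln$rowA, hapB = aln$rowB))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a per-base phred quality track
#'
#' Accepts whitespace-separated integer `.qual` files (any line structure)
#' or FASTQ (single record; qualities decoded from the phred+33 string).
#'
#' @param path Input file.
#' @return Integer vector, one phred value per base.
#' @export
read_qual <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "@")) {
    # Biostrings notes dropped metadata columns on FASTQ input; harmless here
    qs <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (length(qs) != 1L)
      stop("FASTQ quality file must contain exactly one record: ", path)
    return(as.integer(as(Biostrings::quality(qs), "IntegerList")[[1L]]))
  }
  vals <- scan(path, what = integer(), quiet = TRUE)
  if (!length(vals)) stop("no quality values found in ", path)
  vals
}

#' Write a `.qual` integer quality track
#' @param qual Integer vector of phred values.
#' @param path Output file.
#' @param per_line Values per output line.
#' @return Invisibly, `path`.
#' @export
write_qual <- function(qual, path, per_line = 20L) {
  grp <- ceiling(seq_along(qual) / per_line)
  writeLines(vapply(split(qual, grp), paste, "", collapse = " "), path)
  invisible(path)
}
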