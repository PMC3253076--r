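mask_off <- mask_config(min_phred = 0L, dust_threshold = Inf)

test_that("identical rows yield no SNPs; a single CLEAN mismatch yields one record", {
  aln <- pairwise_alignment("ACGTACGT", "ACGTACGT", "r")
  expect_equal(nrow(call_snps(mask_alignment(aln, cfg = mask_off))), 0L)

  aln2 <- pairwise_alignment("ACGTACGT", "ACGTGCGT", "r")
  sn <- call_snps(mask_alignment(aln2, cfg = mask_off))
  expect_equal(nrow(sn), 1L)
  expect_equal(sn$column, 5L)
  expect_equal(sn$posA, 5L)
  expect_identical(sn$alleleA, "A")
  expect_identical(sn$alleleB, "G")
})

test_that("mismatches at quality-masked columns are never reported", {
  aln <- pairwise_alignment("ACGTACGT", "ACGTGCGT", "r")
  qB <- rep(60L, 8); qB[5] <- 49L
  m <- mask_alignment(aln, rep(60L, 8), qB)
  expect_equal(nrow(call_snps(m)), 0L)
})

test_that("indel events are maximal gap runs counted once", {
  aln <- pairwise_alignment("ACGTACGTAA", "AC---CGTAA", "r")
  ind <- call_indels(mask_alignment(aln, cfg = mask_off))
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$length, 3L)
  expect_identical(ind$carrier, "B")
  expect_equal(ind$column, 3L)

  aln2 <- pairwise_alignment("ACGTACG", "A-GT-CG", "r")
  ind2 <- call_indels(mask_alignment(aln2, cfg = mask_off))
  expect_equal(nrow(ind2), 2L)
  expect_true(all(ind2$length == 1L))
})

test_that("calls match the simulator truth exactly with masking off", {
  for (seed in 1:10) {
    sc <- sim_and_call(8000, seed)
    expect_identical(sc$snps$column, sc$sim$true_snps$column)
    expect_identical(sc$snps$alleleA, sc$sim$true_snps$alleleA)
    expect_identical(sc$snps$alleleB, sc$sim$true_snps$alleleB)
    expect_identical(sc$indels[, c("column", "length", "carrier")],
                     sc$sim$true_indels)
  }
})

test_that("no called SNP carries a mask label and raising min_phred shrinks the call set", {
  sim <- simulate_haplotype_pair(haplotype_sim_config(
    6000, snp_rate = 0.01, indel_rate = 0.002, qual_low_fraction = 0.1,
    low_complexity_tracts = list(list(start = 1000L, length = 60L,
                                      repeat_unit = "CA")),
    seed = 17))
  aln <- pairwise_alignment(sim$alnA, sim$alnB, "masked")
  counts <- integer(0)
  for (th in c(0L, 50L, 61L)) {
    m <- mask_alignment(aln, sim$qualA, sim$qualB,
                        mask_config(min_phred = th))
    sn <- call_snps(m)
    expect_true(all(m$labels[sn$column] == "CLEAN"))
    counts <- c(counts, nrow(sn))
  }
  expect_true(all(diff(counts) <= 0))
})

test_that("indels fully inside complexity-masked tracts are dropped unless requested", {
  # force an indel inside a repeat tract by construction
  rowA <- paste0(strrep("GATC", 10), strrep("A", 30), strrep("TGCA", 10))
  rowB <- paste0(strrep("GATC", 10), strrep("A", 12), "---",
                 strrep("A", 15), strrep("TGCA", 10))
  aln <- pairwise_alignment(rowA, rowB, "tract")
  m <- mask_alignment(aln, cfg = mask_config(dust_window = 16))
  expect_true(all(m$flags$complexity[53:55]))
  expect_equal(nrow(call_indels(m)), 0L)
  expect_equal(nrow(call_indels(m, count_masked = TRUE)), 1L)
})

test_that("indel spectrum histogram, mode and range render correctly", {
  spec <- indel_spectrum(data.frame(length = c(1L, 1L, 3L)))
  expect_identical(spec$histogram, c("1" = 2L, "3" = 1L))
  expect_equal(spec$min, 1L)
  expect_equal(spec$max, 3L)
  expect_identical(spec$range_label, "1-3 bp")

  empty <- indel_spectrum(data.frame(length = integer(0)))
  expect_length(empty$histogram, 0L)
  expect_true(is.na(empty$min) && is.na(empty$max))

  sim <- simulate_haplotype_pair(haplotype_sim_config(
    2e5, snp_rate = 0, indel_rate = 0.02,
    indel_length_geometric_p = 0.6, seed = 21))
  h <- indel_spectrum(sim$true_indels)$histogram
  expect_identical(names(h)[which.max(h)], "1")
})

test_that("VCF records follow the 4.x anchoring conventions", {
  # deletion of CT after posA 7 (anchor G): POS=7 REF=GCT ALT=G
  rowA <- "ACGTACGCTA"
  rowB <- "ACGTACG--A"
  aln <- pairwise_alignment(rowA, rowB, "vcfdel")
  cat1 <- variant_catalog(mask_alignment(aln, cfg = mask_off))
  f <- tempfile(fileext = ".vcf")
  write_vcf(cat1, f)
  body <- grep("^#", readLines(f), invert = TRUE, value = TRUE)
  expect_length(body, 1L)
  fld <- strsplit(body, "\t")[[1]]
  expect_equal(as.integer(fld[2]), 7L)
  expect_identical(fld[4], "GCT")
  expect_identical(fld[5], "G")

  # SNP record: POS=5 REF=A ALT=G
  aln2 <- pairwise_alignment("ACGTACGT", "ACGTGCGT", "vcfsnp")
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(variant_catalog(mask_alignment(aln2, cfg = mask_off)), f2)
  fld2 <- strsplit(grep("^#", readLines(f2), invert = TRUE,
                        value = TRUE), "\t")[[1]]
  expect_equal(as.integer(fld2[2]), 5L)
  expect_identical(fld2[4], "A")
  expect_identical(fld2[5], "G")
})

test_that("indels are left-aligned within homopolymer context", {
  # deletion of one A out of AAAA: shifts to the leftmost placement
  rowA <- "GCAAAATC"
  rowB <- "GCAAA-TC"
  aln <- pairwise_alignment(rowA, rowB, "la")
  f <- tempfile(fileext = ".vcf")
  write_vcf(variant_catalog(mask_alignment(aln, cfg = mask_off)), f)
  fld <- strsplit(grep("^#", readLines(f), invert = TRUE,
                       value = TRUE), "\t")[[1]]
  expect_equal(as.integer(fld[2]), 2L)
  expect_identical(fld[4], "CA")
  expect_identical(fld[5], "C")
})

test_that("applying the written VCF to haplotype A reconstructs haplotype B", {
  skip_if_not_installed("vcfR")
  for (seed in c(2, 9, 31)) {
    sc <- sim_and_call(5000, seed)
    cat1 <- variant_catalog(sc$m)
    f <- tempfile(fileext = ".vcf")
    write_vcf(cat1, f)
    v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
    fix <- vcfR::getFIX(v)
    rebuilt <- oracle_apply_vcf(sc$sim$seqA, as.integer(fix[, "POS"]),
                                fix[, "REF"], fix[, "ALT"])
    expect_identical(rebuilt, sc$sim$seqB)
    expect_equal(nrow(fix),
                 nrow(cat1$snps) + nrow(cat1$indels))
  }
})
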