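BASES <- c("A", "C", "G", "T")
ALL_CODONS <- apply(expand.grid(BASES, BASES, BASES), 1, paste0,
                    collapse = "")

test_that("single-swap classification agrees with an independent genetic-code oracle over all 64 x 9 mutants", {
  skip_if_not_installed("seqinr")
  for (codon in ALL_CODONS) {
    a <- strsplit(codon, "")[[1]]
    for (p in 1:3) for (alt in setdiff(BASES, a[p])) {
      mut <- a; mut[p] <- alt
      pair <- codon_alignment(codon, paste(mut, collapse = ""), "enum")
      rec <- classify_coding_snps(pair)
      expect_equal(nrow(rec), 1L)
      same_aa <- oracle_translate(codon) ==
        oracle_translate(paste(mut, collapse = ""))
      expect_identical(rec$class,
                       if (same_aa) "synonymous" else "nonsynonymous")
    }
  }
})

test_that("canonical codon pairs classify per the standard code", {
  syn <- classify_coding_snps(codon_alignment("GAA", "GAG"))
  expect_identical(syn$class, "synonymous")
  expect_identical(syn$aaA, "E")

  nonsyn <- classify_coding_snps(codon_alignment("AAA", "GAA"))
  expect_identical(nonsyn$class, "nonsynonymous")
  expect_identical(nonsyn$aaA, "K")
  expect_identical(nonsyn$aaB, "E")

  stopgain <- classify_coding_snps(codon_alignment("TAC", "TAA"))
  expect_identical(stopgain$class, "nonsynonymous")
  expect_true(stopgain$creates_stop)
})

test_that("codons differing at k positions yield k single-swap records in A context", {
  rec <- classify_coding_snps(codon_alignment("AAA", "GAG"))
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$pos_in_codon, c(1L, 3L))
  # swaps judged one at a time against AAA: AAA->GAA (K->E), AAA->AAG (K->K)
  expect_identical(rec$class, c("nonsynonymous", "synonymous"))
})

test_that("NG86 site counts match enumeration for the canonical cases", {
  expect_equal(ng86_site_counts(codon_alignment("TTT", "TTT"))$S_sites,
               1 / 3)
  expect_equal(ng86_site_counts(codon_alignment("TGG", "TGG"))$S_sites, 0)
  # a run of 4-fold degenerate codons: one synonymous site each
  ggg <- strrep("GGG", 7)
  sc <- ng86_site_counts(codon_alignment(ggg, ggg))
  expect_equal(sc$S_sites, 7)
  expect_equal(sc$N_sites, 14)
  expect_equal(sc$S_sites + sc$N_sites, 3 * sc$n_codons)
})

test_that("NG86 totals agree with a brute-force enumeration over every codon", {
  skip_if_not_installed("seqinr")
  for (codon in sample(ALL_CODONS, 16)) {
    sc <- ng86_site_counts(codon_alignment(codon, codon))
    a <- strsplit(codon, "")[[1]]
    syn <- 0
    for (p in 1:3) for (alt in setdiff(BASES, a[p])) {
      mut <- a; mut[p] <- alt
      if (oracle_translate(codon) ==
          oracle_translate(paste(mut, collapse = ""))) syn <- syn + 1 / 3
    }
    expect_equal(sc$S_sites, syn)
  }
})

test_that("codon quality filter drops exactly codons containing a sub-threshold base", {
  sim <- simulate_haplotype_pair(haplotype_sim_config(
    90, snp_rate = 0, indel_rate = 0, seed = 2))
  aln <- pairwise_alignment(sim$alnA, sim$alnB, "cds")
  m <- mask_alignment(aln, cfg = mask_config(dust_threshold = Inf,
                                             min_phred = 0L))
  qA <- rep(60L, 90); qB <- rep(60L, 90)
  qB[14] <- 49L            # codon 5 (bases 13-15) inadmissible
  qA[40] <- 50L            # exactly at threshold: passes
  cds <- data.frame(start = 0L, end = 90L, strand = "+")
  pair <- build_codon_alignment(m, cds, qA, qB, min_phred = 50L)
  expect_equal(length(pair$admissible), 30L)
  expect_false(pair$admissible[5])
  expect_true(all(pair$admissible[-5]))
})

test_that("minus-strand CDS are read in reverse complement", {
  rowA <- "TTTAAAGGG"
  aln <- pairwise_alignment(rowA, rowA, "minus")
  m <- mask_alignment(aln, cfg = mask_config(dust_threshold = Inf,
                                             min_phred = 0L))
  cds <- data.frame(start = 0L, end = 9L, strand = "-")
  pair <- build_codon_alignment(m, cds, gene_id = "g")
  expect_identical(pair$codonsA, c("CCC", "TTT", "AAA"))
})

test_that("out-of-frame or out-of-range CDS annotations are rejected", {
  aln <- pairwise_alignment("ACGTACGT", "ACGTACGT", "bad")
  m <- mask_alignment(aln, cfg = mask_config(dust_threshold = Inf))
  expect_error(build_codon_alignment(m, data.frame(start = 0L, end = 8L)),
               "not a multiple of 3")
  expect_error(build_codon_alignment(m, data.frame(start = 3L, end = 12L)),
               "outside")
})

test_that("coding summary reproduces published-scale dS from counts and is scale-invariant", {
  snps <- data.frame(gene_id = "all",
                     class = rep(c("synonymous", "nonsynonymous"),
                                 c(201L, 75L)))
  sites <- data.frame(gene_id = "all", S_sites = 20303, N_sites = 50000)
  cs <- coding_summary(snps = snps, sites = sites)
  tot <- cs[cs$gene_id == "Total", ]
  expect_equal(tot$n_syn, 201L)
  expect_equal(tot$dS, 201 / 20303)
  expect_equal(round(tot$dS * 1e3, 1), 9.9)

  # doubling every gene's data leaves dS and dN unchanged
  snps2 <- rbind(snps, transform(snps, gene_id = "copy"))
  sites2 <- rbind(sites, transform(sites, gene_id = "copy"))
  cs2 <- coding_summary(snps = snps2, sites = sites2)
  expect_equal(cs2$dS[cs2$gene_id == "Total"], tot$dS)
  expect_equal(cs2$dN[cs2$gene_id == "Total"], tot$dN)
})

test_that("planted synonymous-only divergence yields zero nonsynonymous calls", {
  # third-position swaps within 4-fold degenerate codon families
  cdsA <- strrep("GGTCCTGCTACT", 6)
  cdsB <- strrep("GGCCCGGCAACG", 6)
  pair <- codon_alignment(cdsA, cdsB, "syn_only")
  rec <- classify_coding_snps(pair)
  expect_equal(nrow(rec), 4L * 6L)
  expect_true(all(rec$class == "synonymous"))
  cs <- coding_summary(pairs = list(pair))
  expect_equal(cs$n_nonsyn[cs$gene_id == "Total"], 0L)
})

test_that("zero SNPs give dS = dN = 0 and empty genes error on site counting", {
  pair <- codon_alignment("GAAGTT", "GAAGTT", "quiet")
  cs <- coding_summary(pairs = list(pair))
  expect_equal(cs$dS[cs$gene_id == "Total"], 0)
  expect_equal(cs$dN[cs$gene_id == "Total"], 0)
  gappy <- codon_alignment("---", "AAA", "gap")
  expect_error(ng86_site_counts(gappy), "no admissible codons")
})
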