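AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

test_that("the shipped property table is complete and its checksum is pinned", {
  path <- system.file("extdata", "aa_properties.tsv", package = "haplodiv")
  expect_identical(unname(tools::md5sum(path)),
                   "b344d30926da97a37313a871a46fb7df")
  tab <- aa_property_table()
  expect_setequal(tab$residue, AA20)
  expect_setequal(unique(tab$charge), c("positive", "negative", "neutral"))
  expect_identical(sort(tab$residue[tab$charge == "positive"]),
                   c("H", "K", "R"))
  expect_identical(sort(tab$residue[tab$charge == "negative"]),
                   c("D", "E"))
  expect_length(unique(tab$polarity), 2L)
  expect_length(unique(tab$polarity_volume), 6L)
})

test_that("canonical replacements classify as expected", {
  kr <- classify_substitution("K", "R")
  expect_equal(kr$n_property_changes, 0L)
  expect_identical(kr$class, "conservative")

  dk <- classify_substitution("D", "K")
  expect_gte(dk$n_property_changes, 2L)
  expect_identical(dk$class, "radical")

  expect_error(classify_substitution("K", "K"), "identical")
  expect_error(classify_substitution("K", "X"), "nonstandard")
})

test_that("classification is symmetric over all 380 ordered residue pairs", {
  tab <- aa_property_table()
  for (a in AA20) for (b in setdiff(AA20, a)) {
    ab <- classify_substitution(a, b, tab)
    ba <- classify_substitution(b, a, tab)
    expect_identical(ab$n_property_changes, ba$n_property_changes)
    expect_identical(ab$class, ba$class)
    expect_identical(ab$class,
                     if (ab$n_property_changes >= 2L) "radical"
                     else "conservative")
  }
})

make_aln <- function(focal, sib1, sib2, mid, far) {
  species_alignment(c(focal = focal, sib1 = sib1, sib2 = sib2,
                      mid_outgroup = mid, far_outgroup = far),
                    protein_id = "p1")
}

test_that("the strict unanimity rule calls exactly the qualifying columns", {
  # col1: focal A vs unanimous S -> call; col2: sib1 shares focal state ->
  # no call; col3: gap in far outgroup -> skipped
  aln <- make_aln("AAC", "SAC", "SSC", "SSC", "SS-")
  calls <- call_focal_substitutions(aln)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$column, 1L)
  expect_identical(calls$ancestral, "S")
  expect_identical(calls$derived, "A")
  skipped <- attr(calls, "skipped")
  expect_equal(unname(skipped["gap_or_ambiguous"]), 1L)
  expect_equal(unname(skipped["not_unanimous"]), 1L)
})

test_that("every strict-rule call is a Fitch-forced change on the focal branch (exhaustive over a 3-letter alphabet)", {
  alph <- c("A", "R", "N")
  taxa <- c("focal", "sib1", "sib2", "mid_outgroup", "far_outgroup")
  grid <- expand.grid(rep(list(alph), 5), stringsAsFactors = FALSE)
  names(grid) <- taxa
  n_checked <- 0L
  for (i in seq_len(nrow(grid))) {
    leaves <- as.list(grid[i, ])
    aln <- make_aln(leaves$focal, leaves$sib1, leaves$sib2,
                    leaves$mid_outgroup, leaves$far_outgroup)
    called <- nrow(call_focal_substitutions(aln)) == 1L
    others <- unlist(leaves[-1L])
    strict <- length(unique(others)) == 1L && leaves$focal != others[[1L]]
    expect_identical(called, strict)
    if (called) {
      free <- oracle_parsimony_cost(leaves, alph, FALSE)
      constrained <- oracle_parsimony_cost(leaves, alph, TRUE)
      expect_gt(constrained, free)
      n_checked <- n_checked + 1L
    }
  }
  # 3 unanimous non-focal residues x 2 differing focal residues
  expect_equal(n_checked, 6L)
})

test_that("noise-free planted recovery is exact and classified correctly", {
  # 7 conservative + 3 radical pairs chosen via the property table
  planted <- data.frame(
    site = c(4L, 8L, 12L, 16L, 20L, 24L, 28L, 32L, 36L, 40L),
    from_aa = c("K", "I", "D", "S", "F", "N", "A", "D", "K", "D"),
    to_aa   = c("R", "L", "E", "T", "Y", "Q", "P", "K", "E", "V"))
  tab <- aa_property_table()
  truth_class <- vapply(seq_len(nrow(planted)), function(i)
    classify_substitution(planted$from_aa[i], planted$to_aa[i],
                          tab)$class, "")
  expect_equal(sum(truth_class == "conservative"), 7L)
  expect_equal(sum(truth_class == "radical"), 3L)

  ps <- simulate_protein_phylogeny(protein_sim_config(
    60, background_rate = 0, planted_focal_substitutions = planted,
    seed = 12))
  calls <- call_focal_substitutions(species_alignment(ps$alignment,
                                                      protein_id = "p"))
  expect_equal(nrow(calls), 10L)
  expect_identical(calls$class, truth_class)
  s <- summarize_lineage(calls)
  expect_equal(unname(s$total["n_conservative"]), 7L)
  expect_equal(unname(s$total["n_radical"]), 3L)
  expect_equal(unname(s$total["n_total"]), 10L)
})

test_that("with background noise, planted recovery matches the simulator's own event log", {
  planted <- data.frame(site = seq(10L, 200L, by = 10L),
                        from_aa = rep(c("K", "D"), 10L),
                        to_aa = rep(c("R", "K"), 10L))
  recovered <- integer(0)
  for (seed in 1:50) {
    ps <- simulate_protein_phylogeny(protein_sim_config(
      5000, background_rate = 0.02,
      planted_focal_substitutions = planted, seed = seed))
    # planted sites are protected, so the log must show no collisions and
    # every planted change must be recoverable
    expect_false(any(ps$events$site %in% planted$site))
    calls <- call_focal_substitutions(species_alignment(ps$alignment))
    hit <- calls[calls$column %in% planted$site, ]
    expect_identical(hit$derived,
                     planted$to_aa[match(hit$column, planted$site)])
    recovered <- c(recovered, nrow(hit))
    s <- summarize_lineage(calls)
    expect_equal(unname(s$total["n_conservative"] + s$total["n_radical"]),
                 nrow(calls))
  }
  # expected collision loss enumerated from the event logs is zero
  expect_equal(mean(recovered), nrow(planted))
})

test_that("percent identity is computed over mutually ungapped columns", {
  expect_equal(percent_identity("ACD", "ACD"), 100)
  expect_equal(percent_identity("ACD", "ACE"), 200 / 3)
  expect_equal(percent_identity("A-CD", "AXCD"), 100)
  expect_error(percent_identity("---", "A-C"), "no mutually ungapped")
})

test_that("lineage summary handles empty input and deduplicates replacement types", {
  empty <- summarize_lineage(data.frame(protein_id = character(0),
                                        ancestral = character(0),
                                        derived = character(0),
                                        class = character(0)))
  expect_equal(unname(empty$total["n_total"]), 0L)

  calls <- data.frame(protein_id = c("p", "p", "p"),
                      column = c(3L, 9L, 15L),
                      ancestral = c("K", "K", "D"),
                      derived = c("R", "R", "K"),
                      n_property_changes = c(0L, 0L, 2L),
                      class = c("conservative", "conservative", "radical"))
  s <- summarize_lineage(calls)
  expect_equal(unname(s$total["n_total"]), 3L)
  expect_equal(s$n_dedup, 2L)
})

test_that("species alignments validate taxa against the tree", {
  expect_error(species_alignment(c(a = "A", b = "A", c = "A", d = "A",
                                   e = "A")), "match tree leaves")
  expect_error(make_aln("AA", "A", "A", "A", "A"), "unequal")
})
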