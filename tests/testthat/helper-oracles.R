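# Independent oracles used across the suite.  Each one is deliberately a
# different code path (different package or brute-force formulation) from
# the implementation it checks.

# Genetic-code oracle: seqinr's own translation tables (the implementation
# uses Biostrings::GENETIC_CODE).
oracle_translate <- function(codon) {
  seqinr::translate(seqinr::s2c(tolower(codon)))
}

# Brute-force DUST-style window scorer over an explicit character vector,
# using table() rather than integer triplet codes.
oracle_dust_score <- function(chars) {
  trips <- vapply(seq_len(length(chars) - 2L), function(i)
    paste(chars[i:(i + 2L)], collapse = ""), "")
  trips <- trips[!grepl("[^ACGT]", trips)]
  cnt <- as.integer(table(trips))
  10 * sum(cnt * (cnt - 1) / 2) / (length(trips) - 1)
}

# Sankoff small-parsimony cost on the fixed 5-taxon topology
# (far,(mid,(focal,(sib1,sib2)))).  States are characters from `alphabet`.
# With force_no_focal_change = TRUE the focal terminal branch is
# constrained to carry no change; a focal-branch change is Fitch-forced
# iff the constrained minimum exceeds the unconstrained one.
oracle_parsimony_cost <- function(leaves, alphabet,
                                  force_no_focal_change = FALSE) {
  best <- Inf
  for (root in alphabet) for (n1 in alphabet)
    for (n2 in alphabet) for (n3 in alphabet) {
      if (force_no_focal_change && n2 != leaves[["focal"]]) next
      cost <- (root != leaves[["far_outgroup"]]) + (root != n1) +
        (n1 != leaves[["mid_outgroup"]]) + (n1 != n2) +
        (n2 != leaves[["focal"]]) + (n2 != n3) +
        (n3 != leaves[["sib1"]]) + (n3 != leaves[["sib2"]])
      if (cost < best) best <- cost
    }
  best
}

# Apply the records of a (sorted) VCF body to the reference to rebuild the
# alternate haplotype; the strong round-trip oracle for write_vcf().
oracle_apply_vcf <- function(ref, pos, refal, altal) {
  chars <- strsplit(ref, "")[[1]]
  out <- list()
  cur <- 1L
  for (i in order(pos)) {
    p <- pos[i]
    stopifnot(p >= cur)
    out[[length(out) + 1L]] <- chars[seq_len(p - cur) + cur - 1L]
    stopifnot(paste(chars[p:(p + nchar(refal[i]) - 1L)], collapse = "") ==
                refal[i])
    out[[length(out) + 1L]] <- strsplit(altal[i], "")[[1]]
    cur <- p + nchar(refal[i])
  }
  out[[length(out) + 1L]] <- chars[seq_len(length(chars) - cur + 1L) +
                                     cur - 1L]
  paste(unlist(out), collapse = "")
}

# Small convenience: simulate, align and call with all masking disabled.
sim_and_call <- function(length, seed, snp_rate = 8.4e-3,
                         indel_rate = snp_rate / 5, ...) {
  sim <- simulate_haplotype_pair(haplotype_sim_config(
    length, snp_rate = snp_rate, indel_rate = indel_rate, seed = seed, ...))
  aln <- pairwise_alignment(sim$alnA, sim$alnB, paste0("sim", seed))
  m <- mask_alignment(aln, sim$qualA, sim$qualB,
                      mask_config(min_phred = 0L, dust_threshold = Inf))
  list(sim = sim, m = m, snps = call_snps(m), indels = call_indels(m))
}
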