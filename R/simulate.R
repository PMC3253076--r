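#' Configuration for the haplotype-pair simulator
#'
#' Describes a pair of haplotypes diverged from a common ancestral sequence
#' by point substitutions and insertion/deletion events, with per-base phred
#' quality tracks and optional planted low-complexity tracts.  The defaults
#' reproduce the divergence regime observed between alternative haplotype
#' assemblies of a single prairie vole: a per-site SNP rate of 8.4e-3 with
#' indel events about five-fold rarer, and an indel length law heavily
#' skewed towards 1-bp events.
#'
#' @param length Ancestral sequence length in sites (>= 1).
#' @param snp_rate Per-site probability that the two haplotypes carry
#'   different bases.
#' @param indel_rate Per-site probability of initiating an indel event.
#' @param indel_length_geometric_p Parameter of the truncated geometric
#'   length law (support 1..`max_indel_length`); the mode is always 1 bp.
#' @param max_indel_length Longest indel event, in bp.
#' @param low_complexity_tracts List of `list(start, length, repeat_unit)`
#'   entries; each tract overwrites the ancestral sequence with tandem
#'   copies of `repeat_unit` starting at 1-based position `start`.
#' @param qual_high Phred value assigned to high-quality bases (default 60,
#'   above the conventional phred-50 masking cutoff).
#' @param qual_low_fraction Fraction of bases drawn at the low quality value.
#' @param qual_low_value Phred value of low-quality bases (default 40, below
#'   the cutoff).
#' @param seed Integer seed; identical seeds give byte-identical output.
#'
#' @return An object of class `haplotype_sim_config`.
#' @seealso [simulate_haplotype_pair()]
#' @export
haplotype_sim_config <- function(length,
                                 snp_rate = 8.4e-3,
                                 indel_rate = snp_rate / 5,
                                 indel_length_geometric_p = 0.6,
                                 max_indel_length = 100L,
                                 low_complexity_tracts = list(),
                                 qual_high = 60L,
                                 qual_low_fraction = 0,
                                 qual_low_value = 40L,
                                 seed = 1L) {
  stopifnot(.is_count(length, 1L))
  if (!.is_prob(snp_rate)) stop("snp_rate must be a probability in [0, 1]")
  if (!.is_prob(indel_rate)) stop("indel_rate must be a probability in [0, 1]")
  stopifnot(.is_prob(qual_low_fraction),
            indel_length_geometric_p > 0, indel_length_geometric_p <= 1,
            .is_count(max_indel_length, 1L), .is_count(seed))
  for (tr in low_complexity_tracts) {
    if (!all(c("start", "length", "repeat_unit") %in% names(tr)))
      stop("each low-complexity tract needs start, length and repeat_unit")
    if (tr$start < 1L || tr$start + tr$length - 1L > length)
      stop("low-complexity tract [", tr$start, ", ",
           tr$start + tr$length - 1L, "] exceeds sequence bounds 1..", length)
  }
  structure(list(length = as.integer(length), snp_rate = snp_rate,
                 indel_rate = indel_rate,
                 indel_length_geometric_p = indel_length_geometric_p,
                 max_indel_length = as.integer(max_indel_length),
                 low_complexity_tracts = low_complexity_tracts,
                 qual_high = as.integer(qual_high),
                 qual_low_fraction = qual_low_fraction,
                 qual_low_value = as.integer(qual_low_value),
                 seed = as.integer(seed)),
            class = "haplotype_sim_config")
}

# Truncated geometric on 1..max via inverse CDF; mode is always 1.
.rtrunc_geom <- function(n, p, max_len) {
  if (n == 0L) return(integer(0))
  u <- stats::runif(n) * (1 - (1 - p)^max_len)
  as.integer(pmin(max_len, 1L + floor(log1p(-u) / log1p(-p))))
}

#' Simulate a diverged haplotype pair with known truth
#'
#' Draws a uniform ancestral sequence, overwrites any configured
#' low-complexity tracts, plants SNPs as independent per-site events, then
#' plants non-overlapping indel events (insertions and deletions with equal
#' probability, truncated-geometric lengths) at sites free of planted SNPs.
#' Indel events are kept at least one ungapped column apart within a row, so
#' each truth record is a maximal gap run in exactly one haplotype.  Phred
#' quality tracks are i.i.d. two-point draws straddling the masking cutoff.
#'
#' @param config A [haplotype_sim_config()].
#' @return An object of class `sim_truth`: ungapped sequences `seqA`/`seqB`,
#'   the true gapped alignment `alnA`/`alnB`, integer quality tracks
#'   `qualA`/`qualB`, and truth tables `true_snps` (column, alleleA, alleleB)
#'   and `true_indels` (column, length, carrier) in 1-based alignment-column
#'   coordinates, where `carrier` names the haplotype holding the gap.
#' @examples
#' sim <- simulate_haplotype_pair(haplotype_sim_config(2000, seed = 7))
#' nrow(sim$true_snps)
#' @export
simulate_haplotype_pair <- function(config) {
  stopifnot(inherits(config, "haplotype_sim_config"))
  set.seed(config$seed)
  L <- config$length

  anc <- sample(.BASES, L, replace = TRUE)
  for (tr in config$low_complexity_tracts) {
    unit <- .s2c(toupper(tr$repeat_unit))
    idx <- tr$start:(tr$start + tr$length - 1L)
    anc[idx] <- rep_len(unit, tr$length)
  }

  is_snp <- stats::runif(L) < config$snp_rate
  snp_sites <- which(is_snp)

  # Candidate indel initiation sites exclude planted SNP sites.
  cand <- which(stats::runif(L) < config$indel_rate & !is_snp)
  n_cand <- length(cand)
  cand_len <- .rtrunc_geom(n_cand, config$indel_length_geometric_p,
                           config$max_indel_length)
  cand_ins <- stats::runif(n_cand) < 0.5

  # Greedy left-to-right acceptance keeping events apart and deletions clear
  # of SNP sites and the sequence end.
  ev_site <- integer(0); ev_len <- integer(0); ev_ins <- logical(0)
  blocked_until <- 0L
  for (k in seq_len(n_cand)) {
    s <- cand[k]; l <- cand_len[k]; ins <- cand_ins[k]
    if (s <= blocked_until + 1L) next
    if (!ins) {
      if (s + l - 1L > L) next
      if (any(is_snp[s:(s + l - 1L)])) next
      blocked_until <- s + l - 1L
    } else {
      blocked_until <- s
    }
    ev_site <- c(ev_site, s); ev_len <- c(ev_len, l); ev_ins <- c(ev_ins, ins)
  }

  # Haplotype B differs from the ancestor (= haplotype A) at SNP sites.
  hapB_site <- anc
  if (length(snp_sites)) {
    shift <- sample(3L, length(snp_sites), replace = TRUE)
    hapB_site[snp_sites] <-
      .BASES[(match(anc[snp_sites], .BASES) - 1L + shift) %% 4L + 1L]
  }

  # Alignment-column bookkeeping: insertions after site s open a gap in A.
  ins_after <- integer(L)
  if (any(ev_ins)) ins_after[ev_site[ev_ins]] <- ev_len[ev_ins]
  col_of_site <- seq_len(L) + c(0L, cumsum(ins_after))[seq_len(L)]
  n_col <- L + sum(ins_after)

  alnA <- character(n_col); alnB <- character(n_col)
  alnA[col_of_site] <- anc
  alnB[col_of_site] <- hapB_site

  ev_col <- integer(length(ev_site))
  for (k in seq_along(ev_site)) {
    s <- ev_site[k]; l <- ev_len[k]
    if (ev_ins[k]) {
      cols <- (col_of_site[s] + 1L):(col_of_site[s] + l)
      alnA[cols] <- "-"
      alnB[cols] <- sample(.BASES, l, replace = TRUE)
    } else {
      cols <- col_of_site[s:(s + l - 1L)]
      alnB[cols] <- "-"
    }
    ev_col[k] <- cols[1L]
  }
  true_indels <- data.frame(column = ev_col, length = ev_len,
                            carrier = c("B", "A")[ev_ins + 1L])
  true_indels <- true_indels[order(true_indels$column), , drop = FALSE]
  rownames(true_indels) <- NULL

  true_snps <- data.frame(column = col_of_site[snp_sites],
                          alleleA = anc[snp_sites],
                          alleleB = hapB_site[snp_sites])

  seqA <- .c2s(anc)
  seqB <- .c2s(alnB[alnB != "-"])

  rq <- function(n) {
    q <- rep.int(config$qual_high, n)
    low <- stats::runif(n) < config$qual_low_fraction
    q[low] <- config$qual_low_value
    q
  }
  qualA <- rq(nchar(seqA))
  qualB <- rq(nchar(seqB))

  structure(list(seqA = seqA, seqB = seqB,
                 alnA = .c2s(alnA), alnB = .c2s(alnB),
                 qualA = qualA, qualB = qualB,
                 true_snps = true_snps, true_indels = true_indels,
                 config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated haplotype pair:", nchar(x$seqA), "bp (A),",
      nchar(x$seqB), "bp (B),", nchar(x$alnA), "columns\n")
  cat("  true SNPs:", nrow(x$true_snps),
      " true indel events:", nrow(x$true_indels), "\n")
  invisible(x)
}

#' Write simulator output to disk
#'
#' Emits the two ungapped haplotypes as FASTA, the true alignment as aligned
#' FASTA, whitespace-separated integer `.qual` tracks, the truth tables as
#' TSV, and a JSON echo of the configuration.
#'
#' @param sim A `sim_truth` from [simulate_haplotype_pair()].
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix.
#' @return Invisibly, the named vector of paths written.
#' @export
write_sim_truth <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  haps <- Biostrings::DNAStringSet(c(hapA = sim$seqA, hapB = sim$seqB))
  Biostrings::writeXStringSet(haps, p(".fasta"))
  aln <- Biostrings::DNAStringSet(c(hapA = sim$alnA, hapB = sim$alnB))
  Biostrings::writeXStringSet(aln, p(".aln.fasta"))
  write_qual(sim$qualA, p(".a.qual"))
  write_qual(sim$qualB, p(".b.qual"))
  utils::write.table(sim$true_snps, p(".snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$true_indels, p(".indels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$low_complexity_tracts <- lapply(cfg$low_complexity_tracts, as.list)
  jsonlite::write_json(unclass(cfg), p(".config.json"), auto_unbox = TRUE)
  invisible(c(fasta = p(".fasta"), aln = p(".aln.fasta"),
              qualA = p(".a.qual"), qualB = p(".b.qual"),
              snps = p(".snps.tsv"), indels = p(".indels.tsv"),
              config = p(".config.json")))
}

.AA20 <- .s2c("ACDEFGHIKLMNPQRSTVWY")

#' Fixed five-taxon tree used by the protein simulator and lineage caller
#'
#' Rooted topology `(far_outgroup,(mid_outgroup,(focal,(sib1,sib2))));`
#' mirroring the rodent/rabbit phylogeny used for focal-lineage inference:
#' the focal species, two sister taxa, a mid-distance outgroup and a far
#' outgroup.
#'
#' @return An [ape::read.tree()] `phylo` object with 5 leaves.
#' @export
default_species_tree <- function() {
  ape::read.tree(text =
    "(far_outgroup,(mid_outgroup,(focal,(sib1,sib2))));")
}

#' Configuration for the protein-phylogeny simulator
#'
#' @param n_sites Number of aligned residues.
#' @param background_rate Per-branch, per-site substitution probability on
#'   every branch of the tree (substitutions to a uniformly drawn different
#'   residue).
#' @param planted_focal_substitutions Data frame with columns `site`,
#'   `from_aa`, `to_aa`: replacements forced onto the focal terminal branch.
#'   Planted sites are protected from background mutation on every branch,
#'   so each one is a change unique to the focal lineage.
#' @param tree Rooted 5-leaf tree (default [default_species_tree()]).
#' @param seed Integer seed.
#' @return An object of class `protein_sim_config`.
#' @export
protein_sim_config <- function(n_sites,
                               background_rate = 0,
                               planted_focal_substitutions = NULL,
                               tree = default_species_tree(),
                               seed = 1L) {
  stopifnot(.is_count(n_sites, 1L), .is_prob(background_rate),
            inherits(tree, "phylo"), .is_count(seed))
  if (length(tree$tip.label) != 5L ||
      !setequal(tree$tip.label,
                c("focal", "sib1", "sib2", "mid_outgroup", "far_outgroup")))
    stop("tree must have exactly the 5 leaves focal, sib1, sib2, ",
         "mid_outgroup, far_outgroup")
  pl <- planted_focal_substitutions
  if (is.null(pl))
    pl <- data.frame(site = integer(0), from_aa = character(0),
                     to_aa = character(0))
  stopifnot(all(c("site", "from_aa", "to_aa") %in% names(pl)))
  if (anyDuplicated(pl$site)) stop("planted sites must be unique")
  if (any(pl$site < 1L | pl$site > n_sites))
    stop("planted site outside 1..n_sites")
  if (any(pl$from_aa == pl$to_aa))
    stop("planted substitution with to_aa equal to from_aa")
  if (!all(c(pl$from_aa, pl$to_aa) %in% .AA20))
    stop("planted residues must be standard amino acids")
  structure(list(n_sites = as.integer(n_sites),
                 background_rate = background_rate,
                 planted_focal_substitutions = pl,
                 tree = tree, seed = as.integer(seed)),
            class = "protein_sim_config")
}

#' Simulate a five-species protein alignment with planted focal changes
#'
#' Evolves a uniform random root sequence down the fixed tree: on each
#' branch every non-planted site mutates independently with probability
#' `background_rate` to a uniformly chosen different residue.  Planted
#' focal substitutions set the root (hence all non-focal taxa) to `from_aa`
#' and the focal leaf to `to_aa`; no background event ever touches a planted
#' site, so planted replacements are unique to the focal lineage.
#'
#' @param config A [protein_sim_config()].
#' @return An object of class `protein_sim`: `alignment` (named character
#'   vector of the 5 gapless rows), `truth` (the planted table), `events`
#'   (full per-branch mutation log with columns branch, site, from, to),
#'   and `tree`.
#' @export
simulate_protein_phylogeny <- function(config) {
  stopifnot(inherits(config, "protein_sim_config"))
  set.seed(config$seed)
  n <- config$n_sites
  pl <- config$planted_focal_substitutions

  root <- sample(.AA20, n, replace = TRUE)
  root[pl$site] <- pl$from_aa
  protected <- rep(FALSE, n)
  protected[pl$site] <- TRUE

  events <- list()
  evolve <- function(seq, branch) {
    hit <- which(stats::runif(n) < config$background_rate & !protected)
    if (length(hit)) {
      old <- seq[hit]
      new <- .AA20[(match(old, .AA20) - 1L +
                    sample(19L, length(hit), replace = TRUE)) %% 20L + 1L]
      seq[hit] <- new
      events[[length(events) + 1L]] <<-
        data.frame(branch = branch, site = hit, from = old, to = new)
    }
    seq
  }

  # Topology (far,(mid,(focal,(sib1,sib2)))): internal nodes evolved in order.
  far <- evolve(root, "far_outgroup")
  n1 <- evolve(root, "internal_mid")          # ancestor of mid + ingroup
  mid <- evolve(n1, "mid_outgroup")
  n2 <- evolve(n1, "internal_focal")          # ancestor of focal + sibs
  focal <- evolve(n2, "focal")
  n3 <- evolve(n2, "internal_sibs")
  sib1 <- evolve(n3, "sib1")
  sib2 <- evolve(n3, "sib2")

  focal[pl$site] <- pl$to_aa

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(0), site = integer(0),
               from = character(0), to = character(0))
  rownames(ev) <- NULL

  structure(list(
    alignment = c(focal = .c2s(focal), sib1 = .c2s(sib1), sib2 = .c2s(sib2),
                  mid_outgroup = .c2s(mid), far_outgroup = .c2s(far)),
    truth = pl, events = ev, tree = config$tree, config = config),
    class = "protein_sim")
}

#' Write a simulated protein alignment as FASTA (plus truth TSV and tree)
#'
#' @param sim A `protein_sim`.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_protein_sim <- function(sim, dir, prefix = "protsim") {
  stopifnot(inherits(sim, "protein_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$alignment),
                              p(".fasta"))
  ape::write.tree(sim$tree, p(".nwk"))
  utils::write.table(sim$truth, p(".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta = p(".fasta"), tree = p(".nwk"), truth = p(".truth.tsv")))
}
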