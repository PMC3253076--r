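---
title: "Diversity and divergence from haplotype-resolved assemblies: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity and divergence from haplotype-resolved assemblies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodiv)
```

## The measurement

A single diploid individual carries two haplotypes at every locus. When
both are assembled independently — here, from BAC clones drawn from
alternative haplotypes — and aligned to each other, every column of that
pairwise alignment is one Bernoulli trial of heterozygosity. `haplodiv`
estimates pairwise heterozygosity as

$$\pi = \frac{\text{SNPs}}{\text{aligned sites}},$$

where *aligned sites* counts only columns that survive masking. No
multiple-hit correction is applied: at $\pi \approx 10^{-2}$ the
Jukes–Cantor correction would alter the third significant digit at most,
far below the one-decimal precision at which $\pi \times 10^{3}$ is
reported, and the per-locus table arithmetic is exactly reproducible
without it.

Pooling across loci is **site-weighted**: the pooled $\pi$ is total SNPs
over total aligned sites, never the mean of per-locus values. The two
differ materially when loci differ in length (a 100-site locus at
$\pi = 0.01$ and a 900-site locus at $\pi = 0.11$ pool to 0.1, while the
mean of the two values is 0.06), and only the site-weighted form is
invariant to splitting or reordering loci.

## Masking

Variant calling is preceded by column classification with precedence
GAP > AMBIGUOUS > QUAL\_MASKED > COMPLEXITY\_MASKED > CLEAN:

- **Quality.** A column is quality-masked when *either* haplotype's base
  has phred below `min_phred` (default 50). The symmetric either-row rule
  is the conservative reading of masking "sites" of a two-haplotype
  comparison. The comparison is strict: phred 49 is masked, 50 passes.
- **Complexity.** Simple and low-complexity sequence is found by a
  DUST-style score on each ungapped row, projected onto columns: in
  windows of 64 bases advancing by half a window, with triplet counts
  $c_t$, the score is $10\sum_t c_t(c_t-1)/2 \,/\, (m-1)$ over the $m$
  triplets in the window, and a window scoring above 20 is masked whole.
  A 64-mer of random DNA scores about 5, a polynucleotide run scores in
  the hundreds, so the threshold separates them by an order of magnitude.
  Masking flagged windows whole over-masks up to ~31 bp of flank around a
  short repeat tract; we accept this deliberately conservative behavior —
  the cost is a slightly smaller denominator, not a biased numerator.
- **Coordinates.** The package uses 1-based closed coordinates
  everywhere internally, matching R convention and VCF output; BED input
  is converted from its native 0-based half-open form on read.

Indel events (maximal single-row gap runs, counted once per event) are
not quality-filtered — a gap has no base quality — but events lying
entirely inside complexity-masked sequence are dropped by default,
because repeat tracts produce alignment-ambiguous gaps. The
`count_masked` flag in `call_indels()` exposes the unfiltered behavior,
since reasonable analyses could count them.

## Kimura two-parameter divergence

For duplication dating, divergence between duplicons is estimated from
transition ($P$) and transversion ($Q$) proportions over comparable
columns:

$$K = -\tfrac{1}{2}\ln\!\big[(1-2P-Q)\sqrt{1-2Q}\big],$$

with the Kimura (1980) delta-method standard error
$\mathrm{SE} = \sqrt{[a^2P + c^2Q - (aP+cQ)^2]/n}$, $a = 1/(1-2P-Q)$,
$b = 1/(1-2Q)$, $c = (a+b)/2$. Saturated inputs ($1-2P-Q \le 0$ or
$1-2Q \le 0$) raise an error rather than returning a fabricated value.
When applied to a masked alignment, K2P uses its CLEAN both-base columns
— the same denominator policy as the SNP analysis, which is the one
self-consistent choice available. The implementation is checked in the
tests against an independent closed-form evaluation and against
`ape::dist.dna(model = "K80", variance = TRUE)`.

## Coding variation

Codon pairs are extracted from the alignment via CDS intervals on
haplotype A; a codon is admissible only when all six underlying bases
are unambiguous A/C/G/T with phred at or above the threshold, so a
single low-quality base removes its whole codon and nothing else.
Classification and site counting follow Nei–Gojobori (1986):

- each base difference in an admissible codon is classified by swapping
  that base alone into the haplotype-A codon context (synonymous iff the
  amino acid is preserved; a stop-gaining swap is nonsynonymous and
  flagged);
- the expected synonymous site count of a codon is the sum over its
  three positions of the fraction of the three alternative bases that
  are synonymous, with $N = 3 - S$;
- $dS$ and $dN$ divide pooled counts by pooled sites, making them
  invariant to how genes are partitioned.

We chose explicit NG86 counting over a likelihood machine (PAML-style)
as the package's method: between two haplotypes at $\pi \approx 10^{-2}$
essentially no codon is hit twice, where NG86 and ML counting coincide,
and NG86 is transparent enough to verify by brute-force enumeration of
all 64 × 9 single-base mutants — which the test suite does against an
independently implemented translation table. Codons differing at $k > 1$
positions yield $k$ single-swap records against the haplotype-A context
rather than NG86's pathway averaging; at this divergence such codons are
a handful at most, and the deterministic rule is reproducible
record-by-record.

## Lineage-specific substitutions

On the fixed rooted tree
`(far_outgroup,(mid_outgroup,(focal,(sib1,sib2))))`, a column yields a
focal-lineage call iff the four non-focal taxa share one standard
residue, the focal taxon carries a different standard residue, and no
row has a gap or ambiguity. This strict unanimity rule is provably a
subset of the columns where Fitch parsimony forces a change on the focal
terminal branch (the tests verify this exhaustively over all $3^5$
column patterns of a three-letter alphabet), so the resulting count is a
deliberate lower bound — the "conservative number" of focal-lineage
changes. Columns where the focal state matches some but not all
non-focal taxa are never called; there is no majority-rule option,
because any such option would require arbitrating among equally
parsimonious reconstructions. Gapped or ambiguous columns are skipped
and tallied in a skipped-site report rather than guessed.

Each call is classified by the three-property scheme of Zhang (2000):
charge (K/R/H positive, D/E negative, rest neutral), two-way polarity,
and the six-way polarity/volume classes. A replacement changing at least
two properties is **radical**, at most one **conservative**.
The assignments live in `inst/extdata/aa_properties.tsv` — the single
source of truth, checksum-pinned in the tests — so an alternative scheme
is a one-file edit. Because "unique replacements" can be read per-site
or per-type, `summarize_lineage()` reports both the per-site total and
the deduplicated (protein, from, to) tally.

## The simulator: what it emulates and what it does not

`simulate_haplotype_pair()` emulates the statistical shape of divergence
between two haplotype assemblies:

- **SNPs** are i.i.d. per-site events at `snp_rate` (default
  $8.4\times10^{-3}$, the survey-scale heterozygosity), mutating to a
  uniformly chosen different base.
- **Indels** initiate at `indel_rate` (default one fifth of the SNP
  rate, matching the observed ~5-fold scarcity), insertions and
  deletions equiprobable since the data do not distinguish them, with
  truncated-geometric lengths (support 1..`max_indel_length`, default
  $p = 0.6$). The observation constrains only a monotone-decreasing,
  1-bp-modal length law; the geometric is the one-parameter closed form
  with that shape. Events never overlap a planted SNP and are kept one
  ungapped column apart, so each truth record is a maximal gap run.
- **Quality** is an i.i.d. two-point model: phred 60 with probability
  $1 - q_\text{low}$, else phred 40, chosen to straddle the 50 cutoff.
  Real quality tracks are autocorrelated along reads and depressed near
  indels; this generator makes no attempt at that, so passing tests
  demonstrate correctness of the masking *logic*, not robustness to
  realistic error topographies.
- **Base composition** is uniform over A/C/G/T (no observed composition
  to emulate), and planted low-complexity tracts are exact tandem
  repeats.

The protein simulator evolves a uniform random root sequence down the
fixed five-taxon tree with i.i.d. per-branch, per-site background
substitutions and forces planted replacements onto the focal terminal
branch. Planted sites are protected from background mutation on every
branch — each planted change is genuinely unique to the focal lineage —
and the full per-branch event log ships in the truth object, so tests
can enumerate from the log exactly which calls are expected rather than
assuming. Neither simulator models assembly error, alignment error, or
codon-level protein evolution; conclusions about those failure modes are
outside what the test suite can support.

## Numerical and reporting choices

- $\pi \times 10^{3}$ is rendered to one decimal and K2P to four
  decimals with **half-up** rounding (R's `round()` is half-even;
  half-up matches how the per-locus table values are printed).
- Determinism: every stochastic function takes an integer seed and
  identical seeds give byte-identical outputs, including written files;
  the pipeline itself uses no randomness.
- Degenerate inputs fail loudly: zero aligned sites (undefined $\pi$),
  saturated K2P, zero admissible codons, empty manifests and taxa/tree
  mismatches are errors, not silent NAs; the one deliberate NA is the
  SNP:indel ratio when no indels were counted.
- Problem sizes: the test suite exercises 50 seeded pairs at 6 kb for
  exact truth recovery, 50 pairs at 1.75 Mb for rate recovery (the
  survey's aligned-site scale), and survey-scale indel spectra from
  five 1.75 Mb pairs; the SNP-rate recovery check uses indel-free pairs
  so the estimator's denominator equals the Bernoulli trial count, and
  the indel spectrum is checked on pairs with indels at study rates.

## Known limitations

- The masker's whole-window policy over-masks repeat flanks (above);
  aligned-site denominators are accordingly slightly conservative.
- `build_codon_alignment()` assumes the CDS annotation is in frame on
  haplotype A and treats any B-row gap inside a codon as inadmissibility
  rather than attempting codon-aware realignment.
- The strict lineage rule undercounts when background evolution is fast
  (any non-focal disagreement vetoes the column); this is the intended
  bias direction, but it *is* a bias.
- Single diploid only: no multi-individual estimators (Watterson's
  $\theta$, Tajima's D) and no bootstrap confidence intervals.
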