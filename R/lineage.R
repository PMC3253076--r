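#' Load the amino-acid physicochemical property table
#'
#' Three categorical properties per residue, following the classification
#' of Zhang (2000): charge (positive K/R/H, negative D/E, else neutral),
#' two-way polarity, and the six-way polarity/volume classes (special;
#' neutral-small; polar-small; polar-large; nonpolar-small;
#' nonpolar-large).  The shipped TSV is the single source of truth — edit
#' it to use an alternative scheme.
#'
#' @param path TSV with columns `residue`, `charge`, `polarity`,
#'   `polarity_volume`; defaults to the table shipped with the package.
#' @return Data frame of class `aa_property_table`, one row per residue,
#'   all 20 standard residues present.
#' @export
aa_property_table <- function(path = system.file("extdata",
                                                 "aa_properties.tsv",
                                                 package = "haplodiv")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "charge", "polarity", "polarity_volume")
  if (!all(need %in% names(tab)))
    stop("property table must have columns ", paste(need, collapse = ", "))
  if (!setequal(tab$residue, .AA20) || anyDuplicated(tab$residue))
    stop("property table must assign all 20 standard residues exactly once")
  if (any(is.na(tab)) || any(tab == ""))
    stop("property table has missing category assignments")
  rownames(tab) <- tab$residue
  class(tab) <- c("aa_property_table", "data.frame")
  tab
}

#' Classify an amino-acid replacement as radical or conservative
#'
#' Counts how many of the three properties (charge, polarity,
#' polarity/volume) change between the two residues; a replacement is
#' radical when at least two change, conservative when at most one does.
#' The count is symmetric in its arguments.
#'
#' @param from_aa,to_aa Distinct standard one-letter residues.
#' @param table An [aa_property_table()].
#' @return List with `n_property_changes` (0-3) and `class`
#'   ("conservative" or "radical").
#' @examples
#' classify_substitution("K", "R")  # conservative, 0 changes
#' classify_substitution("D", "K")  # radical
#' @export
classify_substitution <- function(from_aa, to_aa,
                                  table = aa_property_table()) {
  if (!from_aa %in% .AA20 || !to_aa %in% .AA20)
    stop("nonstandard residue: ", from_aa, " -> ", to_aa)
  if (from_aa == to_aa)
    stop("identical residues: no substitution to classify")
  n <- sum(table[from_aa, c("charge", "polarity", "polarity_volume")] !=
           table[to_aa, c("charge", "polarity", "polarity_volume")])
  list(n_property_changes = as.integer(n),
       class = if (n >= 2L) "radical" else "conservative")
}

#' Construct a five-species protein alignment object
#'
#' @param seqs Named character vector (or `AAStringSet`) of 5 equal-length
#'   aligned rows; names must be exactly the tree's leaves.
#' @param tree Rooted `phylo` tree (default [default_species_tree()]).
#' @param protein_id Identifier.
#' @return An object of class `species_alignment`.
#' @export
species_alignment <- function(seqs, tree = default_species_tree(),
                              protein_id = "protein") {
  if (inherits(seqs, "AAStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  stopifnot(is.character(seqs), length(seqs) == 5L, !is.null(names(seqs)))
  if (!setequal(names(seqs), tree$tip.label))
    stop("alignment taxa must match tree leaves exactly; got ",
         paste(names(seqs), collapse = ", "))
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned rows have unequal lengths")
  structure(list(protein_id = protein_id, seqs = toupper(seqs), tree = tree),
            class = "species_alignment")
}

#' Read a five-species protein alignment from FASTA plus Newick
#'
#' @param fasta Aligned FASTA of the 5 taxa.
#' @param tree_path Newick file (default: the fixed rodent topology).
#' @param protein_id Identifier (default: FASTA file stem).
#' @return A [species_alignment()].
#' @export
read_species_alignment <- function(fasta, tree_path = NULL,
                                   protein_id = NULL) {
  ss <- Biostrings::readAAStringSet(fasta)
  tree <- if (is.null(tree_path)) default_species_tree()
          else ape::read.tree(tree_path)
  if (is.null(protein_id))
    protein_id <- sub("\\.[^.]*$", "", basename(fasta))
  species_alignment(ss, tree = tree, protein_id = protein_id)
}

#' Call focal-lineage amino-acid substitutions by strict parsimony
#'
#' A column yields a call iff all four non-focal taxa carry the same
#' standard residue, the focal taxon carries a different standard residue,
#' and no row has a gap or ambiguity there.  Under this unanimity rule the
#' shared non-focal state is the parsimony ancestral state and a change on
#' the focal terminal branch is forced, so the resulting count is a
#' conservative (lower-bound) tally of focal-lineage replacements; columns
#' failing the rule are skipped silently and tallied in the `skipped`
#' attribute (`not_unanimous`, `gap_or_ambiguous`).
#'
#' @param aln A [species_alignment()].
#' @param focal Name of the focal taxon.
#' @param table An [aa_property_table()] used to classify each call.
#' @return Data frame with columns `protein_id`, `column`, `ancestral`,
#'   `derived`, `n_property_changes`, `class`; attribute `skipped` holds
#'   the skipped-column tally.
#' @export
call_focal_substitutions <- function(aln, focal = "focal",
                                     table = aa_property_table()) {
  stopifnot(inherits(aln, "species_alignment"))
  if (!focal %in% names(aln$seqs)) stop("no taxon named '", focal, "'")
  mat <- do.call(rbind, lapply(aln$seqs, .s2c))
  foc <- mat[focal, ]
  oth <- mat[setdiff(rownames(mat), focal), , drop = FALSE]

  std <- matrix(mat %in% .AA20, nrow = nrow(mat))
  all_std <- apply(std, 2L, all)
  unanimous <- apply(oth, 2L, function(col) length(unique(col)) == 1L)
  calls <- which(all_std & unanimous & foc != oth[1L, ])

  skipped <- c(gap_or_ambiguous = sum(!all_std),
               not_unanimous = sum(all_std & !unanimous))

  out <- data.frame(protein_id = rep.int(aln$protein_id, length(calls)),
                    column = calls,
                    ancestral = oth[1L, calls],
                    derived = foc[calls])
  if (nrow(out)) {
    cls <- lapply(seq_len(nrow(out)), function(i)
      classify_substitution(out$ancestral[i], out$derived[i], table))
    out$n_property_changes <- vapply(cls, `[[`, 0L, "n_property_changes")
    out$class <- vapply(cls, `[[`, "", "class")
  } else {
    out$n_property_changes <- integer(0)
    out$class <- character(0)
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Summarise lineage-specific substitutions
#'
#' @param calls Stacked [call_focal_substitutions()] output across
#'   proteins.
#' @return List with `per_protein` (protein_id, n_conservative, n_radical,
#'   n_total), `total` (the same, summed), and `n_dedup` — the number of
#'   distinct (protein, ancestral, derived) replacement types, reported
#'   alongside the per-site total because repeated identical replacements
#'   at different sites are counted once there.
#' @export
summarize_lineage <- function(calls) {
  if (!nrow(calls)) {
    return(list(per_protein = data.frame(protein_id = character(0),
                                         n_conservative = integer(0),
                                         n_radical = integer(0),
                                         n_total = integer(0)),
                total = c(n_conservative = 0L, n_radical = 0L, n_total = 0L),
                n_dedup = 0L))
  }
  sp <- split(calls, calls$protein_id)
  per <- do.call(rbind, lapply(sp, function(d)
    data.frame(protein_id = d$protein_id[1L],
               n_conservative = sum(d$class == "conservative"),
               n_radical = sum(d$class == "radical"),
               n_total = nrow(d))))
  rownames(per) <- NULL
  list(per_protein = per,
       total = c(n_conservative = sum(per$n_conservative),
                 n_radical = sum(per$n_radical),
                 n_total = sum(per$n_total)),
       n_dedup = nrow(unique(calls[, c("protein_id", "ancestral",
                                       "derived")])))
}

#' Percent identity between two aligned rows
#'
#' Computed over mutually ungapped columns only; any non-gap character
#' (including X) is compared.
#'
#' @param a,b Aligned sequence strings of equal length.
#' @return Percentage in `[0, 100]`.
#' @examples
#' percent_identity("A-CD", "AXCD")  # 100: 3 comparable columns, all equal
#' @export
percent_identity <- function(a, b) {
  ca <- .s2c(toupper(a)); cb <- .s2c(toupper(b))
  if (length(ca) != length(cb)) stop("rows of unequal length")
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("no mutually ungapped columns to compare")
  100 * sum(ca[keep] == cb[keep]) / sum(keep)
}
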