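#' Two-gene sequence observations for the synteny check
#'
#' Sequences (contigs or scaffolds) carrying exactly two full-length
#' reference homologs are collected; for each, the pair's chromosome
#' agreement and rank distance on the reference gene order is recorded.
#' These observations are the raw material of the synteny-based scaffolding
#' error estimate: wrong joins create gene pairs that are far apart (or on
#' different chromosomes) in the reference.
#'
#' @param full_length Data.frame from [call_full_length()].
#' @param gene_order Data.frame from [read_gene_order()].
#' @param sequence_kind Label recorded per observation (`"contig"` or
#'   `"scaffold"`).
#' @return Data.frame with columns `sequence_id`, `sequence_kind`, `gene_a`,
#'   `gene_b`, `same_chromosome`, `order_distance` (`NA` when the two genes
#'   lie on different reference chromosomes).
#' @export
gene_pair_observations <- function(full_length, gene_order,
                                   sequence_kind = "contig") {
  go <- gene_order
  rows <- lapply(split(full_length$query_id, full_length$target_id),
                 function(genes) genes)
  rows <- rows[lengths(rows) == 2L]
  if (length(rows) == 0L)
    return(data.frame(sequence_id = character(0), sequence_kind = character(0),
                      gene_a = character(0), gene_b = character(0),
                      same_chromosome = logical(0), order_distance = numeric(0)))
  idx <- match(c(vapply(rows, `[`, "", 1L), vapply(rows, `[`, "", 2L)),
               go$query_id)
  n <- length(rows)
  chr_a <- go$chromosome[idx[seq_len(n)]]
  chr_b <- go$chromosome[idx[n + seq_len(n)]]
  rk_a <- go$order_index[idx[seq_len(n)]]
  rk_b <- go$order_index[idx[n + seq_len(n)]]
  if (anyNA(idx)) abort("full-length gene absent from the gene order table")
  same <- chr_a == chr_b
  data.frame(sequence_id = names(rows), sequence_kind = sequence_kind,
             gene_a = vapply(rows, `[`, "", 1L),
             gene_b = vapply(rows, `[`, "", 2L),
             same_chromosome = same,
             order_distance = ifelse(same, abs(rk_a - rk_b), NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Neighbour-gene predicate
#'
#' A gene pair counts as *neighbouring* when both genes come from the same
#' reference chromosome and their rank distance is at most `max_dist`
#' (50 genes in the original analysis). Cross-chromosome pairs are
#' non-neighbours, not excluded: the denominator of the neighbour
#' proportion is all two-gene sequences.
#'
#' @param observations Data.frame from [gene_pair_observations()].
#' @param max_dist Maximum rank distance (inclusive).
#' @return Logical vector, one value per observation.
#' @export
is_neighbour <- function(observations, max_dist = 50) {
  observations$same_chromosome &
    !is.na(observations$order_distance) &
    observations$order_distance <= max_dist
}

#' Proportion of neighbouring gene pairs
#'
#' @inheritParams is_neighbour
#' @return `count(neighbour) / count(all)`.
#' @export
neighbour_proportion <- function(observations, max_dist = 50) {
  if (nrow(observations) == 0L)
    abort("no two-gene sequence observations")
  mean(is_neighbour(observations, max_dist))
}

#' Bootstrap test for reduced synteny in scaffolds
#'
#' Tests whether the neighbour-gene proportion observed in scaffolds could
#' have arisen by sampling error from the contig population. The contig
#' observations are resampled with replacement (same size) `B` times and
#' the one-sided p-value is the fraction of resamples whose neighbour
#' proportion is *equal to or lower than* the scaffold proportion.
#'
#' @param contig_observations Data.frame from [gene_pair_observations()]
#'   for the contig assembly.
#' @param scaffold_proportion Observed neighbour proportion in scaffolds.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling.
#' @param max_dist Neighbour rank-distance threshold.
#' @return A list with `p_value`, `contig_proportion`,
#'   `scaffold_proportion`, `B` and `n` (number of contig observations).
#' @export
bootstrap_test <- function(contig_observations, scaffold_proportion,
                           B = 1000, seed = 1L, max_dist = 50) {
  stopifnot(B >= 1)
  n <- nrow(contig_observations)
  if (n == 0L) abort("contig observation set is empty")
  flags <- is_neighbour(contig_observations, max_dist)
  props <- with_seed(seed, {
    draws <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    colMeans(matrix(flags[draws], nrow = n))
  })
  list(p_value = mean(props <= scaffold_proportion),
       contig_proportion = mean(flags),
       scaffold_proportion = scaffold_proportion,
       B = B, n = n)
}

#' Assign scaffolds to BAC clones
#'
#' A scaffold is assigned to a BAC when it has at least one nucleotide hit
#' with percent identity strictly above `min_ident` spanning at least
#' `min_span` bp. When several BACs qualify, the BAC with the largest total
#' aligned span across all its hits to that scaffold wins; ties go to the
#' lexicographically smallest BAC id.
#'
#' @param scaffold_hits Hit data.frame (see [read_hits_tsv()]) with
#'   scaffolds as queries and BACs as targets; `aln_len` is the aligned
#'   span in bp.
#' @param min_ident Identity threshold (strict `>`).
#' @param min_span Minimum aligned span of the qualifying hit (bp,
#'   inclusive).
#' @return Data.frame with columns `scaffold_id`, `bac_id`,
#'   `total_aligned_span`.
#' @export
match_scaffolds_to_bacs <- function(scaffold_hits, min_ident = 99,
                                    min_span = 2500) {
  qual <- scaffold_hits[scaffold_hits$pct_identity > min_ident &
                          scaffold_hits$aln_len >= min_span, , drop = FALSE]
  if (nrow(qual) == 0L)
    return(data.frame(scaffold_id = character(0), bac_id = character(0),
                      total_aligned_span = numeric(0)))
  # total span over *all* hits of each qualifying scaffold-BAC pair
  key_all <- paste(scaffold_hits$query_id, scaffold_hits$target_id, sep = "\r")
  span <- tapply(scaffold_hits$aln_len, key_all, sum)
  key_q <- unique(paste(qual$query_id, qual$target_id, sep = "\r"))
  cand <- do.call(rbind, strsplit(key_q, "\r", fixed = TRUE))
  cand <- data.frame(scaffold_id = cand[, 1L], bac_id = cand[, 2L],
                     total_aligned_span = as.vector(span[key_q]),
                     stringsAsFactors = FALSE)
  cand <- cand[order(cand$scaffold_id, -cand$total_aligned_span,
                     cand$bac_id), , drop = FALSE]
  out <- cand[!duplicated(cand$scaffold_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contig-to-BAC concordance
#'
#' A contig is concordant with a BAC when some hit between them has percent
#' identity strictly above `min_ident` and spans strictly more than
#' `min_frac` of the contig length.
#'
#' @param contig_id,bac_id Ids of the contig and the BAC to test.
#' @param bac_hits Hit data.frame with contigs as queries and BACs as
#'   targets.
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param min_ident Identity threshold (strict).
#' @param min_frac Minimum covered fraction of the contig (strict).
#' @return Logical scalar.
#' @export
contig_bac_concordance <- function(contig_id, bac_id, bac_hits,
                                   contig_lengths, min_ident = 99,
                                   min_frac = 0.5) {
  len <- contig_lengths[[contig_id]]
  if (is.null(len)) abort("unknown contig id: ", contig_id)
  h <- bac_hits[bac_hits$query_id == contig_id &
                  bac_hits$target_id == bac_id, , drop = FALSE]
  any(h$pct_identity > min_ident & h$aln_len > min_frac * len)
}

#' Scaffold Reliability Index per scaffold
#'
#' For each scaffold assigned to a BAC, the proportion of its contigs with
#' a concordant hit to that BAC is computed and normalized by scaffold
#' length (per Kb by default): longer scaffolds legitimately span multiple
#' BACs, so the raw proportion penalizes them; normalization makes
#' assemblies with different length distributions comparable within one
#' unit choice.
#'
#' @param composition Scaffold composition data.frame (see [read_agp()]).
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param assignments Data.frame from [match_scaffolds_to_bacs()].
#' @param bac_hits Contig-vs-BAC hit data.frame.
#' @param min_ident,min_frac Concordance thresholds, see
#'   [contig_bac_concordance()].
#' @param length_unit `"kb"` (default) or `"bp"`; recorded in the output.
#' @return Data.frame with one row per assigned scaffold: `scaffold_id`,
#'   `bac_id`, `n_contigs`, `n_concordant`, `proportion`, `length_bp`,
#'   `sri`, `length_unit`.
#' @export
sri_records <- function(composition, contig_lengths, assignments, bac_hits,
                        min_ident = 99, min_frac = 0.5,
                        length_unit = c("kb", "bp")) {
  length_unit <- match.arg(length_unit)
  div <- if (length_unit == "kb") 1000 else 1
  rows <- lapply(seq_len(nrow(assignments)), function(i) {
    sid <- assignments$scaffold_id[i]
    bid <- assignments$bac_id[i]
    parts <- composition[composition$scaffold_id == sid, , drop = FALSE]
    if (nrow(parts) == 0L) abort("scaffold absent from composition: ", sid)
    conc <- vapply(parts$contig_id, contig_bac_concordance, NA,
                   bac_id = bid, bac_hits = bac_hits,
                   contig_lengths = contig_lengths,
                   min_ident = min_ident, min_frac = min_frac)
    len <- sum(unlist(contig_lengths[parts$contig_id])) +
      sum(parts$gap_after)
    prop <- mean(conc)
    data.frame(scaffold_id = sid, bac_id = bid, n_contigs = nrow(parts),
               n_concordant = sum(conc), proportion = prop,
               length_bp = len, sri = prop / (len / div),
               length_unit = length_unit, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(scaffold_id = character(0), bac_id = character(0),
                      n_contigs = integer(0), n_concordant = integer(0),
                      proportion = numeric(0), length_bp = numeric(0),
                      sri = numeric(0), length_unit = character(0))
  rownames(out) <- NULL
  out
}

#' Restrict a composition to scaffolds with at least two contigs
#'
#' Single-contig "scaffolds" carry no joins, so their reliability is not
#' informative about the scaffolding process; the SRI summaries operate on
#' multi-contig scaffolds.
#'
#' @param composition Scaffold parts data.frame.
#' @return The composition rows belonging to scaffolds with `>= 2` parts.
#' @export
multi_contig_scaffolds <- function(composition) {
  keep <- names(which(table(composition$scaffold_id) >= 2L))
  composition[composition$scaffold_id %in% keep, , drop = FALSE]
}

#' Median Scaffold Reliability Index
#'
#' @param records Data.frame from [sri_records()].
#' @param column Which column to take the median of (`"sri"` or the
#'   un-normalized `"proportion"`).
#' @return The median value.
#' @export
median_sri <- function(records, column = "sri") {
  if (nrow(records) == 0L) abort("no SRI records")
  stats::median(records[[column]])
}
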