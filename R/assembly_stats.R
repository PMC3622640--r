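#' Filter sequences by minimum length
#'
#' Short contigs (below 200 bp in the original 7B analysis) are removed
#' before scaffolding and reporting; the boundary length itself is kept.
#'
#' @param lengths Numeric vector of sequence lengths, or a
#'   [Biostrings::DNAStringSet].
#' @param min_len Minimum length in bp (kept iff `length >= min_len`).
#' @return The input with short entries removed, order preserved.
#' @export
filter_by_length <- function(lengths, min_len = 200) {
  stopifnot(min_len >= 0)
  if (methods::is(lengths, "XStringSet"))
    return(lengths[Biostrings::width(lengths) >= min_len])
  lengths[lengths >= min_len]
}

#' N50 of a set of sequence lengths
#'
#' The length `L` such that sequences of length `>= L` contain at least half
#' of the total assembly bases: sort lengths in decreasing order and return
#' the first length at which the cumulative sum reaches `total/2`.
#'
#' @param lengths Positive numeric vector of sequence lengths.
#' @return The N50 in bp.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) abort("n50 of an empty length set is undefined")
  if (any(lengths <= 0)) abort("all lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Assembly summary statistics
#'
#' The contiguity summary reported for contig and scaffold assemblies:
#' sequence count, total length, mean, maximum and N50.
#'
#' @param lengths Numeric vector of sequence lengths, or a
#'   [Biostrings::DNAStringSet].
#' @return A one-row data.frame with columns `n_sequences`, `total_bp`,
#'   `mean_bp`, `max_bp`, `n50_bp`.
#' @export
summarize_assembly <- function(lengths) {
  if (methods::is(lengths, "XStringSet")) lengths <- Biostrings::width(lengths)
  if (length(lengths) == 0L) abort("cannot summarize an empty assembly")
  data.frame(n_sequences = length(lengths),
             total_bp = sum(lengths),
             mean_bp = mean(lengths),
             max_bp = max(lengths),
             n50_bp = n50(lengths))
}

#' Fold coverage from read-pair counts
#'
#' Sequencing depth over a chromosome arm, treating the count as read
#' *pairs*: `n_pairs * 2 * read_len / arm_size`.
#'
#' @param n_pairs Number of read pairs.
#' @param read_len_bp Read length in bp.
#' @param arm_size_bp Size of the target chromosome arm in bp.
#' @return Fold coverage (x).
#' @export
coverage_estimate <- function(n_pairs, read_len_bp, arm_size_bp) {
  stopifnot(n_pairs > 0, read_len_bp > 0)
  if (arm_size_bp <= 0) abort("arm size must be positive")
  n_pairs * 2 * read_len_bp / arm_size_bp
}

#' Fraction of a chromosome arm represented by an assembly
#'
#' @param total_bp Assembled bases.
#' @param arm_size_bp Molecular size of the arm in bp.
#' @return Percentage of the arm covered.
#' @export
arm_fraction <- function(total_bp, arm_size_bp) {
  stopifnot(total_bp >= 0)
  if (arm_size_bp <= 0) abort("arm size must be positive")
  100 * total_bp / arm_size_bp
}
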