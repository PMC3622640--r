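#' Classify mate pairs by mapping status, orientation and insert size
#'
#' Adds the derived per-pair columns used throughout the mate-pair QC:
#'
#' * `status`: `both_mapped`, `singleton` (exactly one read mapped) or
#'   `unaligned` (neither read mapped).
#' * `same_target`: both reads mapped to the same sequence.
#' * `orientation`: for same-target pairs, the strands of the two reads in
#'   left-to-right coordinate order — `RF` (the geometry expected of a true
#'   circularization mate pair), `FR` (paired-end geometry, the short-insert
#'   contamination class) or `FF_RR` (same-strand geometry, the signature of
#'   an MDA inversion chimera); `NA` otherwise.
#' * `insert_estimate`: outermost span `max(end) - min(start)` covering both
#'   reads, i.e. the implied fragment length; `NA` unless same-target.
#'
#' @param pairs Data.frame of pair mappings as returned by
#'   [read_pair_mappings()].
#' @return `pairs` with the four derived columns appended.
#' @export
classify_pairs <- function(pairs) {
  n <- nrow(pairs)
  status <- rep("unaligned", n)
  status[xor(pairs$mapped1, pairs$mapped2)] <- "singleton"
  both <- pairs$mapped1 & pairs$mapped2
  status[both] <- "both_mapped"
  same <- both & pairs$target1 == pairs$target2
  same[is.na(same)] <- FALSE

  orientation <- rep(NA_character_, n)
  insert <- rep(NA_real_, n)
  if (any(same)) {
    s1 <- pairs$start1[same]; s2 <- pairs$start2[same]
    first_left <- s1 < s2 | (s1 == s2 & pairs$end1[same] <= pairs$end2[same])
    left <- ifelse(first_left, pairs$strand1[same], pairs$strand2[same])
    right <- ifelse(first_left, pairs$strand2[same], pairs$strand1[same])
    ori <- ifelse(left == right, "FF_RR", ifelse(left == "R", "RF", "FR"))
    orientation[same] <- ori
    insert[same] <- pmax(pairs$end1[same], pairs$end2[same]) -
      pmin(s1, s2)
  }
  pairs$status <- status
  pairs$same_target <- same
  pairs$orientation <- orientation
  pairs$insert_estimate <- insert
  pairs
}

#' Summarize a mate-pair library
#'
#' Produces the per-library read-class table (pairs / singletons / unaligned
#' proportions over all pairs), the orientation breakdown (RF / FR / FF_RR
#' proportions over same-sequence pairs only, as in the insert-size
#' distribution figures), and one insert-size histogram per orientation
#' class.
#'
#' @param pairs Data.frame of pair mappings (classified or not; classified
#'   columns are recomputed if absent).
#' @param bin_width Histogram bin width in bp (default 50, resolving both
#'   the ~500 bp short-insert contamination peak and multi-kb mate-pair
#'   peaks).
#' @return A list with elements `n_pairs`, `status_counts`,
#'   `status_proportions`, `orientation_counts`, `orientation_proportions`,
#'   and `histograms` (a data.frame with columns `orientation`, `bin_start`,
#'   `bin_end`, `count`).
#' @export
summarize_library <- function(pairs, bin_width = 50) {
  if (nrow(pairs) == 0L) abort("cannot summarize an empty library")
  if (is.null(pairs$status)) pairs <- classify_pairs(pairs)
  status_levels <- c("both_mapped", "singleton", "unaligned")
  ori_levels <- c("RF", "FR", "FF_RR")
  status_counts <- table(factor(pairs$status, levels = status_levels))
  same <- pairs[pairs$same_target, , drop = FALSE]
  ori_counts <- table(factor(same$orientation, levels = ori_levels))
  hist_df <- do.call(rbind, lapply(ori_levels, function(o) {
    ins <- same$insert_estimate[same$orientation == o]
    if (length(ins) == 0L) return(NULL)
    bin <- floor(ins / bin_width)
    tab <- table(bin)
    data.frame(orientation = o,
               bin_start = as.numeric(names(tab)) * bin_width,
               bin_end = (as.numeric(names(tab)) + 1) * bin_width,
               count = as.vector(tab), stringsAsFactors = FALSE)
  }))
  if (is.null(hist_df))
    hist_df <- data.frame(orientation = character(0), bin_start = numeric(0),
                          bin_end = numeric(0), count = numeric(0))
  list(n_pairs = nrow(pairs),
       status_counts = as.vector(status_counts) |> stats::setNames(status_levels),
       status_proportions = (as.vector(status_counts) / nrow(pairs)) |>
         stats::setNames(status_levels),
       orientation_counts = as.vector(ori_counts) |> stats::setNames(ori_levels),
       orientation_proportions = if (nrow(same))
         (as.vector(ori_counts) / nrow(same)) |> stats::setNames(ori_levels)
       else stats::setNames(rep(NA_real_, 3L), ori_levels),
       histograms = hist_df)
}

#' Randomly subsample mate pairs
#'
#' Each pair is kept independently with probability `fraction`, emulating
#' the reduced-coverage experiment (1-75% of the original mate-pair data).
#'
#' @param pairs Data.frame of pair mappings.
#' @param fraction Keep probability in `[0, 1]`.
#' @param seed Integer seed; the draw is reproducible and leaves the
#'   caller's RNG state untouched.
#' @return The subsampled data.frame (row order preserved).
#' @export
subsample_pairs <- function(pairs, fraction, seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 1) return(pairs)
  keep <- with_seed(seed, stats::runif(nrow(pairs)) < fraction)
  pairs[keep, , drop = FALSE]
}
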