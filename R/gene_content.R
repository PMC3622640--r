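#' Rule 1: protein-level quality gate
#'
#' A query protein is retained — with *all* of its hits — if and only if at
#' least one of its hits has alignment length `>= min_len_aa` and percent
#' identity `>= min_ident`. Proteins with no qualifying hit are dropped
#' entirely. The gate is protein-level: a retained protein keeps even its
#' short or low-identity hits, which still contribute to coverage.
#'
#' @param hits Hit data.frame (see [read_hits_tsv()]).
#' @param min_len_aa Minimum alignment length of the qualifying hit (aa).
#' @param min_ident Minimum percent identity of the qualifying hit.
#' @return The filtered hit data.frame.
#' @export
rule1_quality_gate <- function(hits, min_len_aa = 30, min_ident = 70) {
  if (nrow(hits) == 0L) return(hits)
  ok <- hits$aln_len >= min_len_aa & hits$pct_identity >= min_ident
  keep_q <- unique(hits$query_id[ok])
  hits[hits$query_id %in% keep_q, , drop = FALSE]
}

#' Rule 2: remove duplicated hits on one sequence
#'
#' Within one (query, target) pair, hits identical on query start, query
#' end, mismatches, gap length and percent identity are collapsed to a
#' single hit. Such exact duplicates arise when a target sequence carries
#' repeated copies of the same exon, or from redundant alignment reporting.
#' Equal hits on *different* targets are not duplicates.
#'
#' @param hits Hit data.frame.
#' @return Hit data.frame with duplicates removed (first occurrence kept).
#' @export
rule2_dedupe <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$query_id, hits$target_id, hits$q_start, hits$q_end,
               hits$mismatches, hits$gap_length, hits$pct_identity,
               sep = "\r")
  hits[!duplicated(key), , drop = FALSE]
}

#' Rule 3: resolve cross-protein overlaps on the target
#'
#' For each query protein the mean e-value of all its (post rule 2) hits is
#' computed. Whenever two hits from *different* proteins on the same target
#' sequence overlap by more than `max_overlap` bp of target coordinates, the
#' hit belonging to the protein with the higher mean e-value is discarded.
#'
#' The rule is applied as a mark-and-sweep against the full incoming hit
#' set: a hit is removed iff some overlapping competitor from a
#' better-supported protein exists, whether or not that competitor is itself
#' removed by a third hit. This makes the outcome independent of processing
#' order. Ties on mean e-value are broken by higher percent identity, then
#' by lexicographically smaller query id.
#'
#' @param hits Hit data.frame (rules 1-2 applied).
#' @param max_overlap Overlaps of up to this many bp are tolerated
#'   (default 5; the removal threshold is strictly greater).
#' @return The filtered hit data.frame.
#' @export
rule3_resolve_overlaps <- function(hits, max_overlap = 5) {
  if (nrow(hits) <= 1L) return(hits)
  mean_e <- tapply(hits$e_value, hits$query_id, mean)
  me <- as.vector(mean_e[hits$query_id])
  drop <- rep(FALSE, nrow(hits))
  for (tid in unique(hits$target_id)) {
    idx <- which(hits$target_id == tid)
    if (length(idx) < 2L) next
    ir <- IRanges::IRanges(start = hits$t_start[idx] + 1L,
                           end = hits$t_end[idx])
    ov <- IRanges::findOverlaps(ir, minoverlap = max_overlap + 1L,
                                drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov) == 0L) next
    a <- idx[S4Vectors::queryHits(ov)]
    b <- idx[S4Vectors::subjectHits(ov)]
    diff_q <- hits$query_id[a] != hits$query_id[b]
    a <- a[diff_q]; b <- b[diff_q]
    # b loses iff its protein has the higher mean e-value (ties: lower
    # identity, then larger query id)
    b_loses <- me[b] > me[a] |
      (me[b] == me[a] & (hits$pct_identity[b] < hits$pct_identity[a] |
        (hits$pct_identity[b] == hits$pct_identity[a] &
           hits$query_id[b] > hits$query_id[a])))
    drop[ifelse(b_loses, b, a)] <- TRUE
  }
  hits[!drop, , drop = FALSE]
}

#' Apply hit-filter rules 1-3 in order
#'
#' @inheritParams rule1_quality_gate
#' @inheritParams rule3_resolve_overlaps
#' @return The filtered hit data.frame.
#' @export
filter_hits <- function(hits, min_len_aa = 30, min_ident = 70,
                        max_overlap = 5) {
  rule3_resolve_overlaps(
    rule2_dedupe(rule1_quality_gate(hits, min_len_aa, min_ident)),
    max_overlap)
}

#' Per-gene total and adjusted coverage
#'
#' For each query protein: *total coverage* is the summed hit length
#' relative to protein length (repeated exon hits count repeatedly, so it
#' may exceed 1 — a signature of repeat-associated coding sequence);
#' *adjusted coverage* is the number of unique covered residues over
#' protein length (union, never above 1). Per-target adjusted coverage is
#' computed the same way from each target sequence's hits alone.
#'
#' @param hits Filtered hit data.frame.
#' @param protein_lengths Named numeric vector: query id -> protein length
#'   (aa). Every query in `hits` must be present.
#' @return Data.frame with one row per query: `query_id`, `protein_length`,
#'   `total_coverage`, `adjusted_coverage`, plus a `per_sequence` list
#'   column of data.frames (`target_id`, `adjusted`, `covers_first`,
#'   `covers_last`) giving each target's own coverage of the protein and
#'   whether its hits reach residue 1 and the last residue.
#' @export
gene_coverages <- function(hits, protein_lengths) {
  missing <- setdiff(unique(hits$query_id), names(protein_lengths))
  if (length(missing))
    abort("no protein length for query id(s): ",
          paste(utils::head(missing, 5L), collapse = ", "))
  by_q <- split(seq_len(nrow(hits)), hits$query_id)
  rows <- lapply(names(by_q), function(q) {
    i <- by_q[[q]]
    L <- protein_lengths[[q]]
    ir <- IRanges::IRanges(start = hits$q_start[i], end = hits$q_end[i])
    red <- IRanges::reduce(ir)
    per_t <- lapply(split(i, hits$target_id[i]), function(j) {
      irt <- IRanges::reduce(IRanges::IRanges(start = hits$q_start[j],
                                              end = hits$q_end[j]))
      c(adj = sum(IRanges::width(irt)) / L,
        first = as.numeric(min(IRanges::start(irt)) == 1L),
        last = as.numeric(max(IRanges::end(irt)) == L))
    })
    ps <- data.frame(target_id = names(per_t),
                     adjusted = vapply(per_t, `[[`, 0, "adj"),
                     covers_first = vapply(per_t, `[[`, 0, "first") == 1,
                     covers_last = vapply(per_t, `[[`, 0, "last") == 1,
                     stringsAsFactors = FALSE, row.names = NULL)
    out <- data.frame(query_id = q, protein_length = L,
                      total_coverage = sum(hits$q_end[i] - hits$q_start[i] + 1) / L,
                      adjusted_coverage = sum(IRanges::width(red)) / L,
                      stringsAsFactors = FALSE)
    out$per_sequence <- list(ps)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Rule 4: exclude repeat-like and spurious genes
#'
#' Genes with total coverage strictly greater than `max_total` (typical of
#' transposable-element-associated coding regions hit many times over) or
#' adjusted coverage strictly below `min_adjusted` (spurious marginal
#' homology) are removed from all downstream analyses. Both boundaries are
#' kept: total exactly `max_total` and adjusted exactly `min_adjusted`
#' survive.
#'
#' @param coverages Data.frame from [gene_coverages()].
#' @param max_total Total-coverage ceiling (strict).
#' @param min_adjusted Adjusted-coverage floor (strict).
#' @return The filtered coverage data.frame.
#' @export
rule4_gene_exclusion <- function(coverages, max_total = 5, min_adjusted = 0.10) {
  keep <- coverages$total_coverage <= max_total &
    coverages$adjusted_coverage >= min_adjusted
  coverages[keep, , drop = FALSE]
}

#' Gene Fragmentation Index
#'
#' AC (assembly coverage) is the mean adjusted coverage over genes with
#' hits pooled assembly-wide — the theoretical optimum in which every gene
#' sits on a single sequence. SC (sequence coverage) is the mean over genes
#' of the per-sequence coverage; with `sc_mode = "max"` (default) each gene
#' contributes its best single sequence, with `sc_mode = "mean_pairs"` the
#' mean is over all gene-by-sequence pairs. The index
#' `GFI = (AC - SC) / AC` is 0 when every gene is fully contained in one
#' sequence and grows as the gene space fragments across sequences.
#'
#' @param coverages Coverage data.frame (after [rule4_gene_exclusion()]).
#' @param sc_mode How SC averages per-sequence coverage; see above.
#' @return A one-row data.frame with `AC`, `SC`, `GFI` and `n_genes`.
#' @export
gfi <- function(coverages, sc_mode = c("max", "mean_pairs")) {
  sc_mode <- match.arg(sc_mode)
  if (nrow(coverages) == 0L) abort("no genes left to compute a GFI from")
  ac <- mean(coverages$adjusted_coverage)
  if (ac == 0) abort("assembly coverage is zero; GFI undefined")
  sc <- if (sc_mode == "max") {
    mean(vapply(coverages$per_sequence, function(ps) max(ps$adjusted), 0))
  } else {
    mean(unlist(lapply(coverages$per_sequence, function(ps) ps$adjusted)))
  }
  data.frame(AC = ac, SC = sc, GFI = (ac - sc) / ac,
             n_genes = nrow(coverages))
}

#' Call full-length genes
#'
#' A gene is *full length* on a sequence when that single sequence covers at
#' least `threshold` of the protein (`mode = "coverage"`); the stricter
#' `mode = "start_stop"` additionally requires the sequence's hits to reach
#' both residue 1 and the final residue of the protein.
#'
#' @param coverages Coverage data.frame (after [rule4_gene_exclusion()]).
#' @param mode `"coverage"` or `"start_stop"`.
#' @param threshold Minimum single-sequence adjusted coverage (inclusive).
#' @return Data.frame with one row per full-length gene: `query_id`,
#'   `target_id` (the qualifying sequence with the highest coverage) and
#'   `coverage` on it.
#' @export
call_full_length <- function(coverages, mode = c("coverage", "start_stop"),
                             threshold = 0.70) {
  mode <- match.arg(mode)
  rows <- lapply(seq_len(nrow(coverages)), function(i) {
    ps <- coverages$per_sequence[[i]]
    ok <- ps$adjusted >= threshold
    if (mode == "start_stop") ok <- ok & ps$covers_first & ps$covers_last
    if (!any(ok)) return(NULL)
    best <- which(ok)[which.max(ps$adjusted[ok])]
    data.frame(query_id = coverages$query_id[i],
               target_id = ps$target_id[best],
               coverage = ps$adjusted[best], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(0), target_id = character(0),
                      coverage = numeric(0))
  rownames(out) <- NULL
  out
}

#' Histogram of sequences by full-length gene count
#'
#' Counts how many sequences contain 1, 2, 3, ... full-length genes — the
#' multigene summary showing how scaffolding links genes into ordered
#' groups.
#'
#' @param full_length Data.frame from [call_full_length()].
#' @return Data.frame with columns `n_genes` and `n_sequences`, ascending;
#'   zero rows if there are no full-length genes.
#' @export
multigene_histogram <- function(full_length) {
  if (nrow(full_length) == 0L)
    return(data.frame(n_genes = integer(0), n_sequences = integer(0)))
  per_seq <- table(full_length$target_id)
  tab <- table(as.vector(per_seq))
  data.frame(n_genes = as.integer(names(tab)),
             n_sequences = as.integer(tab))
}
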