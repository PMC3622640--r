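hit_evalue <- function(aln_len) 10^(-pmin(1.5 * aln_len, 170))

#' Emit ground-truth protein hits for the synthetic genes
#'
#' Stands in for a translated search of the reference proteins against the
#' assembly: each exon that lies on a contig yields exactly one hit with
#' exact coordinates, 100% identity and a length-dependent e-value. With
#' `noise_rate > 0`, spurious short/low-identity hits and exact duplicate
#' rows are added (each at `noise_rate` times the true hit count) to
#' exercise the quality gate and the de-duplication filter.
#'
#' @param truth Truth ledger from [generate_genome()].
#' @param origins Contig origin table from [fragment_into_contigs()].
#' @param noise_rate Non-negative noise proportion.
#' @param seed Integer seed (used only when `noise_rate > 0`).
#' @return A hit data.frame in the [read_hits_tsv()] layout.
#' @export
truth_hits <- function(truth, origins, noise_rate = 0, seed = 1L) {
  ex <- truth$exons
  if (nrow(ex) == 0L) return(empty_hits())
  idx <- findInterval(ex$g_start, origins$g_start)
  inside <- idx >= 1L & ex$g_start >= origins$g_start[pmax(idx, 1L)] &
    ex$g_end <= origins$g_end[pmax(idx, 1L)]
  if (!all(inside))
    abort("internal error: exon outside every contig origin")
  strand <- truth$genes$strand[match(ex$gene_id, truth$genes$gene_id)]
  aa <- ex$q_end - ex$q_start + 1L
  hits <- data.frame(
    query_id = ex$gene_id,
    target_id = origins$contig_id[idx],
    pct_identity = 100,
    aln_len = aa,
    mismatches = 0,
    gap_length = 0,
    q_start = ex$q_start,
    q_end = ex$q_end,
    t_start = ex$g_start - origins$g_start[idx],
    t_end = ex$g_end - origins$g_start[idx],
    t_strand = strand,
    e_value = hit_evalue(aa),
    bit_score = 2 * aa,
    stringsAsFactors = FALSE)
  if (noise_rate > 0) {
    hits <- with_seed(seed, {
      n_noise <- round(noise_rate * nrow(hits))
      if (n_noise > 0) {
        gi <- sample(nrow(truth$genes), n_noise, replace = TRUE)
        ci <- sample(nrow(origins), n_noise, replace = TRUE)
        len <- sample(5:25, n_noise, replace = TRUE)
        plen <- truth$genes$protein_length[gi]
        qs <- pmax(1L, floor(stats::runif(n_noise, 1, plen - len)))
        clen <- origins$g_end[ci] - origins$g_start[ci]
        ts <- floor(stats::runif(n_noise, 0, pmax(1, clen - 3 * len)))
        spurious <- data.frame(
          query_id = truth$genes$gene_id[gi],
          target_id = origins$contig_id[ci],
          pct_identity = round(stats::runif(n_noise, 30, 65), 1),
          aln_len = len, mismatches = sample(1:10, n_noise, replace = TRUE),
          gap_length = sample(0:3, n_noise, replace = TRUE),
          q_start = qs, q_end = qs + len - 1L,
          t_start = ts, t_end = ts + 3L * len,
          t_strand = sample(c("+", "-"), n_noise, replace = TRUE),
          e_value = stats::runif(n_noise, 0.01, 10),
          bit_score = round(stats::runif(n_noise, 20, 40), 1),
          stringsAsFactors = FALSE)
        dup <- hits[sample(nrow(hits), n_noise, replace = TRUE), , drop = FALSE]
        hits <- rbind(hits, spurious, dup)
      }
      hits
    })
  }
  rownames(hits) <- NULL
  hits
}

# zero-row hit table with the canonical column layout
empty_hits <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(hit_cols)), hit_cols))
  num <- setdiff(hit_cols, c("query_id", "target_id", "t_strand"))
  df[num] <- lapply(df[num], as.numeric)
  df
}

#' Lift contig-level hits to scaffold coordinates
#'
#' Re-expresses hits against the scaffolds a composition defines: a hit on
#' a `+` part keeps its orientation at the part's scaffold offset; a hit on
#' a `-` part is coordinate-flipped within the part and its strand
#' inverted. Hits on contigs not placed in any scaffold are returned
#' unchanged (still against the contig).
#'
#' @param hits Hit data.frame (contig targets).
#' @param composition Scaffold parts data.frame.
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @return Hit data.frame with scaffold (or unplaced-contig) targets.
#' @export
lift_hits_to_scaffolds <- function(hits, composition, contig_lengths) {
  comp <- composition
  part_len <- unlist(contig_lengths[comp$contig_id])
  # scaffold-local offset of each part
  off <- numeric(nrow(comp))
  pos <- 0; prev_s <- ""
  for (i in seq_len(nrow(comp))) {
    if (comp$scaffold_id[i] != prev_s) { pos <- 0; prev_s <- comp$scaffold_id[i] }
    off[i] <- pos
    pos <- pos + part_len[i] + comp$gap_after[i]
  }
  m <- match(hits$target_id, comp$contig_id)
  placed <- !is.na(m)
  out <- hits
  if (any(placed)) {
    i <- which(placed); j <- m[i]
    minus_part <- comp$orientation[j] == "-"
    ts <- ifelse(minus_part, part_len[j] - hits$t_end[i], hits$t_start[i])
    te <- ifelse(minus_part, part_len[j] - hits$t_start[i], hits$t_end[i])
    out$t_start[i] <- off[j] + ts
    out$t_end[i] <- off[j] + te
    out$t_strand[i] <- ifelse(minus_part,
                              ifelse(hits$t_strand[i] == "+", "-", "+"),
                              hits$t_strand[i])
    out$target_id[i] <- comp$scaffold_id[j]
  }
  out
}

#' Reference gene-order table from the truth ledger
#'
#' @param truth Truth ledger from [generate_genome()].
#' @return Data.frame in the [read_gene_order()] layout.
#' @export
gene_order_table <- function(truth) {
  data.frame(query_id = truth$genes$gene_id,
             chromosome = truth$genes$chromosome,
             order_index = truth$genes$order_index,
             protein_length = truth$genes$protein_length,
             stringsAsFactors = FALSE)
}

# truth-derived alignment rows between genome intervals a (queries) and b
# (targets): one 100%-identity hit per overlapping pair
interval_hits <- function(a_ids, a_start, a_end, b_ids, b_start, b_end) {
  ia <- IRanges::IRanges(start = a_start + 1L, end = a_end)
  ib <- IRanges::IRanges(start = b_start + 1L, end = b_end)
  ov <- IRanges::findOverlaps(ia, ib)
  qa <- S4Vectors::queryHits(ov); qb <- S4Vectors::subjectHits(ov)
  os <- pmax(a_start[qa], b_start[qb])
  oe <- pmin(a_end[qa], b_end[qb])
  data.frame(query_id = a_ids[qa], target_id = b_ids[qb],
             pct_identity = 100, aln_len = oe - os,
             mismatches = 0, gap_length = 0,
             q_start = os - a_start[qa] + 1L, q_end = oe - a_start[qa],
             t_start = os - b_start[qb], t_end = oe - b_start[qb],
             t_strand = "+", e_value = 0, bit_score = 2 * (oe - os),
             stringsAsFactors = FALSE)
}

#' Truth-derived contig-vs-BAC alignment table
#'
#' One synthetic 100%-identity nucleotide hit per (contig, BAC) pair whose
#' genomic origins overlap, standing in for an alignment of assembly
#' contigs against independently sequenced BAC clones.
#'
#' @param origins Contig origin table.
#' @param bac_intervals BAC interval table from [extract_bacs()].
#' @return Hit data.frame (contigs as queries, BACs as targets).
#' @export
contig_bac_hits <- function(origins, bac_intervals) {
  interval_hits(origins$contig_id, origins$g_start, origins$g_end,
                bac_intervals$bac_id, bac_intervals$g_start,
                bac_intervals$g_end)
}

#' Truth-derived scaffold-vs-BAC alignment table
#'
#' Each member contig's overlap with a BAC is reported as one hit of the
#' scaffold against that BAC (span = overlap length), mirroring how a
#' nucleotide search of scaffolds against BAC sequences reports one local
#' alignment per shared contig.
#'
#' @param composition Scaffold parts data.frame.
#' @param origins Contig origin table.
#' @param bac_intervals BAC interval table.
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @return Hit data.frame (scaffolds as queries, BACs as targets).
#' @export
scaffold_bac_hits <- function(composition, origins, bac_intervals,
                              contig_lengths) {
  ch <- contig_bac_hits(origins, bac_intervals)
  ch <- ch[ch$query_id %in% composition$contig_id, , drop = FALSE]
  lift <- lift_hits_to_scaffolds(
    # reuse the lift by treating the BAC hit's contig-local span as target
    # coordinates on the contig
    data.frame(query_id = ch$target_id, target_id = ch$query_id,
               pct_identity = ch$pct_identity, aln_len = ch$aln_len,
               mismatches = 0, gap_length = 0,
               q_start = ch$t_start + 1L, q_end = ch$t_end,
               t_start = ch$q_start - 1L, t_end = ch$q_end,
               t_strand = "+", e_value = 0, bit_score = ch$bit_score,
               stringsAsFactors = FALSE),
    composition, contig_lengths)
  # back to scaffold-as-query orientation
  data.frame(query_id = lift$target_id, target_id = lift$query_id,
             pct_identity = lift$pct_identity, aln_len = lift$aln_len,
             mismatches = 0, gap_length = 0,
             q_start = lift$t_start + 1L, q_end = lift$t_end,
             t_start = lift$q_start - 1L, t_end = lift$q_end,
             t_strand = lift$t_strand, e_value = 0,
             bit_score = lift$bit_score, stringsAsFactors = FALSE)
}
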