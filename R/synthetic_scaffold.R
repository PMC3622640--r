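#' Build scaffolds from contigs with a controlled wrong-join rate
#'
#' Stands in for a read-pair scaffolder run at a given stringency. A random
#' reserve of contigs is withheld as foreign-insert donors; the remaining
#' contigs are chained in genome order into scaffolds of random size. At
#' each extension step one of three things happens: a correct join to the
#' next chained contig in `+` orientation; an *inversion error* (the next
#' chained contig joined in `-` orientation); or an *insertion error* (a
#' donor contig from elsewhere in the genome is spliced in, corrupting both
#' the join into it and the join out of it). Inversions and insertions are
#' drawn equally often, at per-step probabilities solved so that the
#' overall fraction of incorrect joins equals `join_error_rate`. Donors not
#' consumed by insertions are emitted as single-contig scaffolds, so every
#' contig appears exactly once. Every join carries a ground-truth
#' correctness flag; a join is correct when it connects consecutive
#' chained contigs in `+` orientation (with an empty reserve, i.e.
#' `join_error_rate = 0`, this is exact genomic adjacency).
#'
#' @param origins Contig origin table from [fragment_into_contigs()]
#'   (genome order).
#' @param join_error_rate Target fraction of incorrect joins, in `[0, 1]`.
#' @param seed Integer seed.
#' @param size_range Range `c(min, max)` of contigs per scaffold.
#' @param wrong_gap Gap length (bp) recorded around inserted contigs, where
#'   no true genomic gap exists.
#' @return A list with `composition` (scaffold parts data.frame, see
#'   [read_agp()]) and `joins` (data.frame `scaffold_id`, `upstream_contig`,
#'   `downstream_contig`, `correct`).
#' @export
build_scaffolds <- function(origins, join_error_rate, seed,
                            size_range = c(2L, 6L), wrong_gap = 100) {
  stopifnot(join_error_rate >= 0, join_error_rate <= 1)
  n <- nrow(origins)
  if (n == 0L) abort("no contigs to scaffold")
  with_seed(seed, {
    # per-step probabilities: inversion (1 bad join, 1 join) and insertion
    # (2 bad joins, 2 joins counting the resume join) at equal frequency a;
    # solving (a + 2a) / (1 + a) = rate gives a = rate / (3 - rate)
    a <- join_error_rate / (3 - join_error_rate)
    n_reserve <- if (a > 0) min(n - 1L, ceiling(1.3 * a * n) + 5L) else 0L
    reserve <- if (n_reserve > 0L) sample(n, n_reserve) else integer(0)
    main <- setdiff(seq_len(n), reserve)
    ri <- 0L
    pos <- 1L
    comp <- list(); joins <- list()
    scaf_i <- 0L
    add_join <- function(sid, up, down, ok)
      joins[[length(joins) + 1L]] <<- data.frame(
        scaffold_id = sid, upstream_contig = origins$contig_id[up],
        downstream_contig = origins$contig_id[down], correct = ok,
        stringsAsFactors = FALSE)
    while (pos <= length(main)) {
      scaf_i <- scaf_i + 1L
      sid <- sprintf("scaf%04d", scaf_i)
      target_size <- sample(size_range[1L]:size_range[2L], 1L)
      cur <- main[pos]; pos <- pos + 1L
      parts <- data.frame(scaffold_id = sid,
                          contig_id = origins$contig_id[cur],
                          orientation = "+", gap_after = 0,
                          stringsAsFactors = FALSE)
      add_part <- function(idx, ori, gap_before) {
        parts$gap_after[nrow(parts)] <<- gap_before
        parts <<- rbind(parts, data.frame(
          scaffold_id = sid, contig_id = origins$contig_id[idx],
          orientation = ori, gap_after = 0, stringsAsFactors = FALSE))
      }
      while (nrow(parts) < target_size && pos <= length(main)) {
        u <- stats::runif(1L)
        insert <- u < a && ri < length(reserve)
        flip <- !insert && u < 2 * a
        if (insert) {
          ri <- ri + 1L
          w <- reserve[ri]
          add_part(w, sample(c("+", "-"), 1L), wrong_gap)
          add_join(sid, cur, w, FALSE)
          # always lay the resume join (scaffold may overshoot its target
          # size by one part): an insertion corrupts exactly two joins
          if (pos <= length(main)) {
            nxt <- main[pos]; pos <- pos + 1L
            add_part(nxt, "+", wrong_gap)
            add_join(sid, w, nxt, FALSE)
            cur <- nxt
          } else break
        } else if (flip) {
          nxt <- main[pos]; pos <- pos + 1L
          add_part(nxt, "-", origins$g_start[nxt] - origins$g_end[cur])
          add_join(sid, cur, nxt, FALSE)
          cur <- nxt
        } else {
          nxt <- main[pos]; pos <- pos + 1L
          add_part(nxt, "+", origins$g_start[nxt] - origins$g_end[cur])
          add_join(sid, cur, nxt, TRUE)
          cur <- nxt
        }
      }
      comp[[scaf_i]] <- parts
    }
    # unconsumed donors become singleton scaffolds
    for (w in reserve[seq_len(length(reserve)) > ri]) {
      scaf_i <- scaf_i + 1L
      comp[[scaf_i]] <- data.frame(
        scaffold_id = sprintf("scaf%04d", scaf_i),
        contig_id = origins$contig_id[w], orientation = "+",
        gap_after = 0, stringsAsFactors = FALSE)
    }
    joins_df <- if (length(joins)) do.call(rbind, joins) else
      data.frame(scaffold_id = character(0), upstream_contig = character(0),
                 downstream_contig = character(0), correct = logical(0))
    comp_df <- do.call(rbind, comp)
    rownames(comp_df) <- NULL
    list(composition = comp_df, joins = joins_df)
  })
}

#' Scaffold lengths implied by a composition
#'
#' @param composition Scaffold parts data.frame.
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @return Named numeric vector of scaffold lengths (contigs plus gaps).
#' @export
scaffold_lengths <- function(composition, contig_lengths) {
  lens <- unlist(contig_lengths[composition$contig_id]) +
    composition$gap_after
  tapply(lens, composition$scaffold_id, sum)
}
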