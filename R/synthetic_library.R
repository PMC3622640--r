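#' Simulate one mate-pair library with MDA-style artifacts
#'
#' Draws `n_pairs` read pairs from the synthetic genome as a mixture of
#' three classes and reports where each read maps on the *contigs* (a read
#' is mapped iff it lies entirely inside one unique segment; reads landing
#' in repeat copies or straddling a repeat junction are unmapped, which is
#' what produces singletons and unaligned pairs):
#'
#' * `MP_RF` — true mate pairs: fragment length Normal(`mean`, `sd`),
#'   outward-facing geometry that maps reverse-forward;
#' * `PE_FR` — paired-end contamination: short log-normal inserts (median
#'   ~500 bp, truncated at 1000 bp), forward-reverse geometry;
#' * `CHIMERA_FFRR` — MDA inversion chimeras: one read's segment inverted
#'   relative to its mate, so both reads map on the same strand, with
#'   log-normal-like short spans.
#'
#' Which physical read is reported first is randomized per pair, so
#' orientation classification cannot rely on read order.
#'
#' @param genome One-record [Biostrings::DNAStringSet] or its length in bp.
#' @param origins Contig origin table from [fragment_into_contigs()].
#' @param insert_spec List with `mean`, `sd`, `read_len`, `n_pairs`.
#' @param chimera_rate,pe_contamination_rate Class proportions; the
#'   remainder are true mate pairs.
#' @param seed Integer seed.
#' @param library_id Library name used in pair ids.
#' @return A list with `pairs` (data.frame in [read_pair_mappings()] layout)
#'   and `truth` (data.frame `pair_id`, `true_class`).
#' @export
simulate_mp_library <- function(genome, origins, insert_spec,
                                chimera_rate = 0.38,
                                pe_contamination_rate = 0.30,
                                seed = 1L, library_id = "mp") {
  L <- if (is.numeric(genome)) genome else Biostrings::width(genome)[1L]
  rl <- insert_spec$read_len
  n <- insert_spec$n_pairs
  if (insert_spec$mean <= 2 * rl)
    abort("insert mean must exceed 2 * read_len")
  if (insert_spec$mean + 4 * insert_spec$sd >= L)
    abort("insert spec incompatible with genome length")
  if (chimera_rate + pe_contamination_rate > 1)
    abort("class proportions exceed 1")
  with_seed(seed, {
    cls <- sample(c("MP_RF", "PE_FR", "CHIMERA_FFRR"), n, replace = TRUE,
                  prob = c(1 - chimera_rate - pe_contamination_rate,
                           pe_contamination_rate, chimera_rate))
    ins <- numeric(n)
    i_mp <- cls == "MP_RF"; i_pe <- cls == "PE_FR"; i_ch <- cls == "CHIMERA_FFRR"
    ins[i_mp] <- pmin(pmax(round(stats::rnorm(sum(i_mp), insert_spec$mean,
                                              insert_spec$sd)),
                           2 * rl + 2), L - 1)
    ins[i_pe] <- pmin(pmax(round(stats::rlnorm(sum(i_pe), log(500), 0.45)),
                           rl + 10), 1000)
    ins[i_ch] <- pmin(pmax(round(stats::rlnorm(sum(i_ch), log(500), 0.6)),
                           rl + 10), 2000)
    frag_start <- floor(stats::runif(n, 0, L - ins))

    # genome intervals of the left and right read of each fragment
    ls <- frag_start;            le <- frag_start + rl
    rs <- frag_start + ins - rl; re <- frag_start + ins
    # strands by class: MP outward-facing -> left R / right F; PE inward ->
    # left F / right R; chimera -> both on one random strand
    l_strand <- ifelse(i_mp, "R", "F")
    r_strand <- ifelse(i_mp, "F", "R")
    ch_strand <- sample(c("F", "R"), n, replace = TRUE)
    l_strand[i_ch] <- ch_strand[i_ch]
    r_strand[i_ch] <- ch_strand[i_ch]

    # project reads onto contigs
    map_read <- function(gs, ge) {
      idx <- findInterval(gs, origins$g_start)
      ok <- idx >= 1L & gs >= origins$g_start[pmax(idx, 1L)] &
        ge <= origins$g_end[pmax(idx, 1L)]
      idx[!ok] <- NA_integer_
      list(target = origins$contig_id[idx],
           start = gs - origins$g_start[idx],
           end = ge - origins$g_start[idx],
           mapped = !is.na(idx))
    }
    m_l <- map_read(ls, le)
    m_r <- map_read(rs, re)

    # randomize which physical read is reported as read 1
    swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
    pick <- function(a, b) ifelse(swap, b, a)
    pairs <- data.frame(
      pair_id = sprintf("%s_%06d", library_id, seq_len(n)),
      library_id = library_id,
      target1 = pick(m_l$target, m_r$target),
      start1 = pick(m_l$start, m_r$start),
      end1 = pick(m_l$end, m_r$end),
      strand1 = pick(l_strand, r_strand),
      mapped1 = pick(m_l$mapped, m_r$mapped),
      target2 = pick(m_r$target, m_l$target),
      start2 = pick(m_r$start, m_l$start),
      end2 = pick(m_r$end, m_l$end),
      strand2 = pick(r_strand, l_strand),
      mapped2 = pick(m_r$mapped, m_l$mapped),
      stringsAsFactors = FALSE)
    pairs$strand1[!pairs$mapped1] <- NA_character_
    pairs$strand2[!pairs$mapped2] <- NA_character_
    list(pairs = pairs,
         truth = data.frame(pair_id = pairs$pair_id, true_class = cls,
                            stringsAsFactors = FALSE))
  })
}
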