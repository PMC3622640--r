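# In-code fixture builders shared across test files.

# one hit row with overridable fields
make_hit <- function(query_id = "q1", target_id = "c1", pct_identity = 95,
                     aln_len = 50, mismatches = 2, gap_length = 0,
                     q_start = 1, q_end = 50, t_start = 0, t_end = 150,
                     t_strand = "+", e_value = 1e-20, bit_score = 100) {
  data.frame(query_id = query_id, target_id = target_id,
             pct_identity = pct_identity, aln_len = aln_len,
             mismatches = mismatches, gap_length = gap_length,
             q_start = q_start, q_end = q_end, t_start = t_start,
             t_end = t_end, t_strand = t_strand, e_value = e_value,
             bit_score = bit_score, stringsAsFactors = FALSE)
}

# one pair-mapping row; pass target = NA for an unmapped read
make_pair <- function(pair_id = "p1", library_id = "lib",
                      t1 = "c1", s1 = 100, e1 = 145, st1 = "R",
                      t2 = "c1", s2 = 1900, e2 = 1945, st2 = "F") {
  data.frame(pair_id = pair_id, library_id = library_id,
             target1 = t1, start1 = s1, end1 = e1, strand1 = st1,
             mapped1 = !is.na(t1),
             target2 = t2, start2 = s2, end2 = e2, strand2 = st2,
             mapped2 = !is.na(t2),
             stringsAsFactors = FALSE)
}

# synteny observations from a logical neighbour-flag vector
make_observations <- function(neighbour_flags, kind = "contig") {
  data.frame(sequence_id = sprintf("s%04d", seq_along(neighbour_flags)),
             sequence_kind = kind,
             gene_a = "ga", gene_b = "gb",
             same_chromosome = TRUE,
             order_distance = ifelse(neighbour_flags, 10, 100),
             stringsAsFactors = FALSE)
}

# random BLAST-style table designed to exercise rules 2-3 (duplicates,
# overlaps, e-value ties)
random_hit_table <- function(n, seed) {
  set.seed(seed)
  qs <- sample(1:100, n, replace = TRUE)
  ts <- sample(0:500, n, replace = TRUE)
  span <- sample(10:100, n, replace = TRUE)
  h <- make_hit(query_id = sample(paste0("q", 1:5), n, replace = TRUE),
                target_id = sample(paste0("c", 1:3), n, replace = TRUE),
                pct_identity = sample(c(70, 80, 90, 99), n, replace = TRUE),
                aln_len = pmax(10, span %/% 3),
                mismatches = sample(0:3, n, replace = TRUE),
                gap_length = sample(0:2, n, replace = TRUE),
                q_start = qs, q_end = qs + pmax(1, span %/% 3),
                t_start = ts, t_end = ts + span,
                e_value = sample(c(1e-50, 1e-30, 1e-10, 1e-5), n,
                                 replace = TRUE))
  # inject exact duplicates to exercise the de-duplication rule
  ndup <- max(1L, n %/% 10L)
  rbind(h, h[sample(n, ndup, replace = TRUE), , drop = FALSE])
}

# brute-force reference for rule 2 (first occurrence kept)
oracle_rule2 <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (hits$query_id[i] == hits$query_id[j] &&
          hits$target_id[i] == hits$target_id[j] &&
          hits$q_start[i] == hits$q_start[j] &&
          hits$q_end[i] == hits$q_end[j] &&
          hits$mismatches[i] == hits$mismatches[j] &&
          hits$gap_length[i] == hits$gap_length[j] &&
          hits$pct_identity[i] == hits$pct_identity[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  hits[keep, , drop = FALSE]
}

# brute-force reference for rule 3: pairwise check of every hit against
# every other hit in the incoming table
oracle_rule3 <- function(hits, max_overlap = 5) {
  me <- tapply(hits$e_value, hits$query_id, mean)
  n <- nrow(hits)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (hits$target_id[i] != hits$target_id[j]) next
      if (hits$query_id[i] == hits$query_id[j]) next
      ov <- min(hits$t_end[i], hits$t_end[j]) -
        max(hits$t_start[i], hits$t_start[j])
      if (ov <= max_overlap) next
      ei <- me[[hits$query_id[i]]]; ej <- me[[hits$query_id[j]]]
      i_loses <- ei > ej ||
        (ei == ej && (hits$pct_identity[i] < hits$pct_identity[j] ||
          (hits$pct_identity[i] == hits$pct_identity[j] &&
             hits$query_id[i] > hits$query_id[j])))
      if (i_loses) { drop[i] <- TRUE; break }
    }
  }
  hits[!drop, , drop = FALSE]
}

# brute-force N50: largest length L in the multiset such that sequences of
# length >= L hold at least half the total bases
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  min(lengths)
}

# small, fast simulation parameters for pipeline-level tests
small_params <- function(seed = 1L, ...) {
  sim_params(genome_length = 5e5, repeat_fraction = 0.6,
             repeat_unit_length = 1500, n_genes = 40,
             insert_specs = list(
               mp2k = list(mean = 2000, sd = 200, read_len = 45,
                           n_pairs = 800),
               mp5k = list(mean = 5000, sd = 500, read_len = 35,
                           n_pairs = 800)),
             rng_seed = seed, ...)
}
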