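test_that("two-gene sequences yield observations with rank distances", {
  fl <- data.frame(query_id = c("g1", "g2", "g3", "g4", "g5"),
                   target_id = c("s1", "s1", "s2", "s2", "s3"),
                   coverage = 1)
  go <- data.frame(query_id = paste0("g", 1:5),
                   chromosome = c("chr1", "chr1", "chr1", "chr2", "chr1"),
                   order_index = c(10L, 45L, 100L, 3L, 7L),
                   protein_length = 100L)
  obs <- gene_pair_observations(fl, go, "scaffold")
  # s3 has a single gene and contributes nothing
  expect_equal(sort(obs$sequence_id), c("s1", "s2"))
  s1 <- obs[obs$sequence_id == "s1", ]
  expect_true(s1$same_chromosome)
  expect_equal(s1$order_distance, 35)
  s2 <- obs[obs$sequence_id == "s2", ]
  expect_false(s2$same_chromosome)
  expect_true(is.na(s2$order_distance))
  # cross-chromosome pairs count as non-neighbours, not excluded
  expect_equal(is_neighbour(obs), c(TRUE, FALSE))
})

test_that("neighbour predicate boundary is <= 50 ranks on one chromosome", {
  obs <- data.frame(sequence_id = c("a", "b", "c"), sequence_kind = "contig",
                    gene_a = "x", gene_b = "y",
                    same_chromosome = c(TRUE, TRUE, FALSE),
                    order_distance = c(50, 51, NA))
  expect_equal(is_neighbour(obs), c(TRUE, FALSE, FALSE))
  expect_equal(neighbour_proportion(make_observations(rep(TRUE, 5))), 1)
  expect_equal(neighbour_proportion(make_observations(rep(FALSE, 5))), 0)
  expect_equal(neighbour_proportion(
    make_observations(rep(c(TRUE, FALSE), c(12, 13)))), 0.48)
})

test_that("bootstrap test matches its definition at the extremes", {
  all_n <- make_observations(rep(TRUE, 30))
  expect_equal(bootstrap_test(all_n, 0, B = 500, seed = 1)$p_value, 0)
  expect_equal(bootstrap_test(all_n, 1, B = 500, seed = 1)$p_value, 1)
  expect_error(bootstrap_test(all_n[0, ], 0.5, B = 10, seed = 1), "empty")
  # seeded reproducibility
  mixed <- make_observations(runif(100) < 0.6)
  p1 <- bootstrap_test(mixed, 0.5, B = 200, seed = 7)
  p2 <- bootstrap_test(mixed, 0.5, B = 200, seed = 7)
  expect_identical(p1, p2)
})

test_that("bootstrap p is near one half at the contig point estimate", {
  set.seed(31)
  obs <- make_observations(runif(2000) < 0.6)
  prop <- neighbour_proportion(obs)
  bt <- bootstrap_test(obs, prop, B = 10000, seed = 5)
  expect_lt(abs(bt$p_value - 0.5), 0.05)
})

test_that("scaffold-to-BAC matching applies both thresholds strictly", {
  hit <- function(sid, bid, pid, span)
    make_hit(sid, bid, pct_identity = pid, aln_len = span,
             t_start = 0, t_end = span)
  expect_equal(match_scaffolds_to_bacs(hit("s1", "b1", 99.5, 3000))$bac_id,
               "b1")
  expect_equal(nrow(match_scaffolds_to_bacs(hit("s1", "b1", 99.0, 3000))),
               0L)
  expect_equal(nrow(match_scaffolds_to_bacs(hit("s1", "b1", 99.5, 2400))),
               0L)
  # ambiguity: the BAC with the largest total aligned span wins
  amb <- rbind(hit("s1", "b1", 99.5, 2600),
               hit("s1", "b2", 99.5, 2500),
               hit("s1", "b2", 99.5, 2500))
  expect_equal(match_scaffolds_to_bacs(amb)$bac_id, "b2")
})

test_that("contig concordance requires >99% identity over >50% of length", {
  lens <- c(c1 = 1000)
  h <- make_hit("c1", "b1", pct_identity = 99.2, aln_len = 600)
  expect_true(contig_bac_concordance("c1", "b1", h, lens))
  h$aln_len <- 500
  expect_false(contig_bac_concordance("c1", "b1", h, lens))
  expect_false(contig_bac_concordance("c1", "b1", h[0, ], lens))
})

test_that("SRI is the concordant proportion per unit scaffold length", {
  comp <- data.frame(scaffold_id = "s1", contig_id = paste0("c", 1:4),
                     orientation = "+", gap_after = c(100, 100, 100, 0))
  lens <- c(c1 = 3000, c2 = 3000, c3 = 2000, c4 = 1700)  # +300 gaps = 10 kb
  assign <- data.frame(scaffold_id = "s1", bac_id = "b1",
                       total_aligned_span = 9000)
  hits <- do.call(rbind, lapply(paste0("c", 1:3), function(cid)
    make_hit(cid, "b1", pct_identity = 100, aln_len = lens[[cid]])))
  r <- sri_records(comp, lens, assign, hits)
  expect_equal(r$n_contigs, 4L)
  expect_equal(r$n_concordant, 3L)
  expect_equal(r$proportion, 0.75)
  expect_equal(r$length_bp, 10000)
  expect_equal(r$sri, 0.075)

  # one-contig scaffold of 2 kb, fully concordant
  solo <- data.frame(scaffold_id = "s2", contig_id = "c9",
                     orientation = "+", gap_after = 0)
  r2 <- sri_records(solo, c(c9 = 2000),
                    data.frame(scaffold_id = "s2", bac_id = "b1",
                               total_aligned_span = 2000),
                    make_hit("c9", "b1", pct_identity = 100, aln_len = 2000))
  expect_equal(r2$sri, 0.5)

  # no concordant contig: SRI 0
  r3 <- sri_records(solo, c(c9 = 2000),
                    data.frame(scaffold_id = "s2", bac_id = "b1",
                               total_aligned_span = 2000),
                    make_hit("c9", "b1", pct_identity = 90, aln_len = 2000))
  expect_equal(r3$sri, 0)
})

test_that("median SRI equals sort-and-pick", {
  r <- data.frame(sri = c(0.5, 0.1, 0.9), proportion = c(1, 0.2, 0.6))
  expect_equal(median_sri(r), 0.5)
  expect_equal(median_sri(r, "proportion"), 0.6)
  expect_error(median_sri(r[0, ]), "no SRI")
  set.seed(2)
  x <- runif(51)
  expect_equal(median_sri(data.frame(sri = x)), sort(x)[26])
})

test_that("error-free scaffolding preserves synteny and BAC concordance", {
  p <- small_params(seed = 17)
  gg <- generate_genome(p)
  fc <- fragment_into_contigs(gg$genome, gg$truth)
  cl <- setNames(fc$origins$g_end - fc$origins$g_start, fc$origins$contig_id)
  sc <- build_scaffolds(fc$origins, 0, seed = 17)
  plen <- setNames(gg$truth$genes$protein_length, gg$truth$genes$gene_id)
  go <- gene_order_table(gg$truth)

  hits_c <- truth_hits(gg$truth, fc$origins)
  hits_s <- lift_hits_to_scaffolds(hits_c, sc$composition, cl)
  fl_c <- call_full_length(rule4_gene_exclusion(
    gene_coverages(filter_hits(hits_c), plen)), "coverage")
  fl_s <- call_full_length(rule4_gene_exclusion(
    gene_coverages(filter_hits(hits_s), plen)), "coverage")
  obs_c <- gene_pair_observations(fl_c, go, "contig")
  obs_s <- gene_pair_observations(fl_s, go, "scaffold")
  # error-free joins cannot break true adjacency
  if (nrow(obs_c) > 0 && nrow(obs_s) > 0)
    expect_gte(neighbour_proportion(obs_s), neighbour_proportion(obs_c))

  # with full BAC tiling, every concordance check passes at error rate 0
  tiles <- tile_bacs(p$genome_length, 80000, 40000)
  sb <- scaffold_bac_hits(sc$composition, fc$origins, tiles$intervals, cl)
  cb <- contig_bac_hits(fc$origins, tiles$intervals)
  assign <- match_scaffolds_to_bacs(sb)
  expect_gt(nrow(assign), 0)
  r <- sri_records(sc$composition, cl, assign, cb)
  expect_true(all(r$proportion == 1))
})
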