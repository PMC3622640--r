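test_that("rule 1 retains or drops whole proteins", {
  h <- rbind(
    make_hit("qA", aln_len = 35, pct_identity = 80, q_start = 1, q_end = 35),
    make_hit("qA", aln_len = 10, pct_identity = 50, q_start = 50, q_end = 59),
    make_hit("qB", aln_len = 29, pct_identity = 95, q_start = 1, q_end = 29))
  out <- rule1_quality_gate(h)
  # the qualifying 35 aa hit rescues qA's weak hit too; qB's best hit is
  # one residue short of the gate and the whole protein goes
  expect_equal(out$query_id, c("qA", "qA"))
  expect_equal(nrow(rule1_quality_gate(h[0, ])), 0L)
})

test_that("rule 2 collapses duplicates only within one target sequence", {
  a <- make_hit("q1", "c1")
  b <- make_hit("q1", "c1")           # byte-identical duplicate
  c_mm <- make_hit("q1", "c1", mismatches = 5)
  d_t2 <- make_hit("q1", "c2")        # same hit on another target
  expect_equal(nrow(rule2_dedupe(rbind(a, b))), 1L)
  expect_equal(nrow(rule2_dedupe(rbind(a, c_mm))), 2L)
  expect_equal(nrow(rule2_dedupe(rbind(a, d_t2))), 2L)
})

test_that("rule 3 discards cross-protein overlaps > 5 bp by mean e-value", {
  protA <- make_hit("qA", "c1", t_start = 100, t_end = 400, e_value = 1e-50)
  protB5 <- make_hit("qB", "c1", t_start = 395, t_end = 700, e_value = 1e-10)
  both <- rule3_resolve_overlaps(rbind(protA, protB5))
  expect_equal(nrow(both), 2L)       # 5 bp overlap is tolerated

  protB10 <- make_hit("qB", "c1", t_start = 390, t_end = 700, e_value = 1e-10)
  kept <- rule3_resolve_overlaps(rbind(protA, protB10))
  expect_equal(kept$query_id, "qA")  # 10 bp overlap: weaker protein loses

  # equal mean e-values: higher identity wins, then smaller query id
  tie1 <- make_hit("qA", "c1", t_start = 100, t_end = 400,
                   e_value = 1e-20, pct_identity = 90)
  tie2 <- make_hit("qB", "c1", t_start = 390, t_end = 700,
                   e_value = 1e-20, pct_identity = 95)
  expect_equal(rule3_resolve_overlaps(rbind(tie1, tie2))$query_id, "qB")
  tie2$pct_identity <- 90
  expect_equal(rule3_resolve_overlaps(rbind(tie1, tie2))$query_id, "qA")
})

test_that("filter pipeline matches the naive pairwise oracle", {
  for (seed in 1:100) {
    h <- random_hit_table(sample(5:60, 1), seed)
    got <- rule3_resolve_overlaps(rule2_dedupe(h))
    want <- oracle_rule3(oracle_rule2(h))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("total and adjusted coverage follow the union arithmetic", {
  h <- rbind(make_hit("g", q_start = 1, q_end = 50),
             make_hit("g", q_start = 41, q_end = 90, t_start = 300,
                      t_end = 450))
  cov <- gene_coverages(h, c(g = 100))
  expect_equal(cov$total_coverage, 1.0)
  expect_equal(cov$adjusted_coverage, 0.90)

  full <- gene_coverages(make_hit("g", q_start = 1, q_end = 100), c(g = 100))
  expect_equal(full$total_coverage, 1.0)
  expect_equal(full$adjusted_coverage, 1.0)

  # repeat-like gene: six full-length hits on six targets
  six <- do.call(rbind, lapply(1:6, function(i)
    make_hit("g", paste0("c", i), q_start = 1, q_end = 100)))
  cov6 <- gene_coverages(six, c(g = 100))
  expect_equal(cov6$total_coverage, 6.0)
  expect_equal(cov6$adjusted_coverage, 1.0)
  # ... which rule 4 then excludes, while the boundaries survive
  expect_equal(nrow(rule4_gene_exclusion(cov6)), 0L)
  cov6$total_coverage <- 5.0
  cov6$adjusted_coverage <- 0.10
  expect_equal(nrow(rule4_gene_exclusion(cov6)), 1L)
  cov6$adjusted_coverage <- 0.09
  expect_equal(nrow(rule4_gene_exclusion(cov6)), 0L)
})

test_that("GFI is zero for one-sequence genes and follows (AC-SC)/AC", {
  one_seq <- gene_coverages(
    rbind(make_hit("g1", "c1", q_start = 1, q_end = 80),
          make_hit("g2", "c2", q_start = 1, q_end = 60)),
    c(g1 = 100, g2 = 100))
  r <- gfi(one_seq)
  expect_equal(r$GFI, 0)
  expect_equal(r$AC, r$SC)

  # a gene split over two contigs: AC pools residues, SC sees the best part
  split <- gene_coverages(
    rbind(make_hit("g1", "c1", q_start = 1, q_end = 50),
          make_hit("g1", "c2", q_start = 51, q_end = 100)),
    c(g1 = 100))
  r2 <- gfi(split)
  expect_equal(r2$AC, 1.0)
  expect_equal(r2$SC, 0.5)
  expect_equal(r2$GFI, 0.5)
  # the alternative SC averaging over all gene-sequence pairs
  r3 <- gfi(split, sc_mode = "mean_pairs")
  expect_equal(r3$SC, 0.5)

  expect_error(gfi(one_seq[0, ]), "no genes")
})

test_that("joining the halves of a split gene strictly decreases the GFI", {
  hits_split <- rbind(
    make_hit("g1", "c1", q_start = 1, q_end = 50, t_start = 0, t_end = 150),
    make_hit("g1", "c2", q_start = 51, q_end = 100, t_start = 0,
             t_end = 150),
    make_hit("g2", "c3", q_start = 1, q_end = 100))
  plen <- c(g1 = 100, g2 = 100)
  before <- gfi(gene_coverages(hits_split, plen))
  comp <- data.frame(scaffold_id = "s1", contig_id = c("c1", "c2"),
                     orientation = "+", gap_after = c(50, 0))
  joined <- lift_hits_to_scaffolds(hits_split, comp,
                                   c(c1 = 200, c2 = 200, c3 = 400))
  after <- gfi(gene_coverages(joined, plen))
  expect_gte(after$SC, before$SC)
  expect_lt(after$GFI, before$GFI)
  expect_equal(after$GFI, 0)
  # AC is untouched by scaffolding
  expect_equal(after$AC, before$AC)
})

test_that("full-length calling honours threshold and start-stop modes", {
  cov70 <- gene_coverages(make_hit("g", q_start = 1, q_end = 70), c(g = 100))
  expect_equal(nrow(call_full_length(cov70, "coverage")), 1L)
  cov69 <- gene_coverages(make_hit("g", q_start = 1, q_end = 69), c(g = 100))
  expect_equal(nrow(call_full_length(cov69, "coverage")), 0L)

  # 99% coverage missing residue 1: full length by coverage, not start-stop
  cov99 <- gene_coverages(make_hit("g", q_start = 2, q_end = 100), c(g = 100))
  expect_equal(nrow(call_full_length(cov99, "coverage")), 1L)
  expect_equal(nrow(call_full_length(cov99, "start_stop")), 0L)
  covfull <- gene_coverages(make_hit("g", q_start = 1, q_end = 100),
                            c(g = 100))
  expect_equal(nrow(call_full_length(covfull, "start_stop")), 1L)
})

test_that("multigene histogram counts sequences by full-length gene load", {
  hits <- rbind(
    make_hit("g1", "s1", q_start = 1, q_end = 100, t_start = 0, t_end = 300),
    make_hit("g2", "s1", q_start = 1, q_end = 100, t_start = 400,
             t_end = 700),
    make_hit("g3", "s1", q_start = 1, q_end = 100, t_start = 800,
             t_end = 1100),
    make_hit("g4", "s2", q_start = 1, q_end = 100))
  fl <- call_full_length(
    gene_coverages(hits, c(g1 = 100, g2 = 100, g3 = 100, g4 = 100)),
    "coverage")
  hist <- multigene_histogram(fl)
  expect_equal(hist$n_sequences[hist$n_genes == 3], 1L)
  expect_equal(hist$n_sequences[hist$n_genes == 1], 1L)
  expect_equal(sum(hist$n_sequences), 2L)
  expect_equal(nrow(multigene_histogram(fl[0, ])), 0L)
})
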