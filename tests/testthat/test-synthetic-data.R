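test_that("genome generation realizes the requested repeat fraction", {
  p <- sim_params(genome_length = 1e6, n_genes = 10, rng_seed = 5)
  gg <- generate_genome(p)
  expect_true(abs(gg$truth$repeat_fraction - 0.8) <= 0.02)
  frac <- sum(gg$truth$repeats$end - gg$truth$repeats$start) / 1e6
  expect_equal(frac, gg$truth$repeat_fraction)

  p0 <- sim_params(genome_length = 1e5, repeat_fraction = 0, n_genes = 5,
                   rng_seed = 5)
  gg0 <- generate_genome(p0)
  expect_equal(nrow(gg0$truth$repeats), 0L)
})

test_that("genome generation is deterministic and does not leak RNG state", {
  p <- sim_params(genome_length = 2e5, n_genes = 5, rng_seed = 9)
  set.seed(1); before <- runif(1)
  g1 <- generate_genome(p)
  g2 <- generate_genome(p)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$genes, g2$truth$genes)
  set.seed(1)
  expect_identical(runif(1), before)
})

test_that("genes sit in non-repeat space, non-overlapping, ranked by position", {
  p <- sim_params(genome_length = 1e6, n_genes = 50, rng_seed = 3)
  gg <- generate_genome(p)
  genes <- gg$truth$genes
  expect_equal(nrow(genes), 50L)
  expect_true(all(diff(genes$g_start) > 0))
  expect_identical(genes$order_index, seq_len(50L))
  expect_true(all(genes$g_end[-50] <= genes$g_start[-1]))
  # exons never intersect a repeat copy
  ex <- IRanges::IRanges(gg$truth$exons$g_start + 1L, gg$truth$exons$g_end)
  rp <- IRanges::IRanges(gg$truth$repeats$start + 1L, gg$truth$repeats$end)
  expect_equal(length(IRanges::findOverlaps(ex, rp)), 0L)
  # exon query coordinates tile each protein exactly
  for (gid in sample(genes$gene_id, 10)) {
    e <- gg$truth$exons[gg$truth$exons$gene_id == gid, ]
    expect_equal(e$q_start, c(1, utils::head(e$q_end, -1) + 1))
    expect_equal(max(e$q_end),
                 genes$protein_length[genes$gene_id == gid])
  }
})

test_that("fragmentation yields unique-region contigs that are genome substrings", {
  p <- sim_params(genome_length = 1e5, repeat_fraction = 0.3,
                  repeat_unit_length = 10000, n_genes = 3, rng_seed = 2)
  gg <- generate_genome(p)
  expect_equal(nrow(gg$truth$repeats), 3L)
  fc <- fragment_into_contigs(gg$genome, gg$truth)
  expect_equal(length(fc$contigs), 4L)
  gseq <- as.character(gg$genome[[1]])
  for (i in seq_len(nrow(fc$origins))) {
    expect_identical(as.character(fc$contigs[[i]]),
                     substring(gseq, fc$origins$g_start[i] + 1,
                               fc$origins$g_end[i]))
  }

  # repeat-free genome collapses to a single contig equal to the genome
  p0 <- sim_params(genome_length = 5e4, repeat_fraction = 0, n_genes = 2,
                   rng_seed = 2)
  gg0 <- generate_genome(p0)
  fc0 <- fragment_into_contigs(gg0$genome, gg0$truth)
  expect_equal(length(fc0$contigs), 1L)
  expect_identical(as.character(fc0$contigs[[1]]),
                   as.character(gg0$genome[[1]]))
})

test_that("scaffold joins realize the requested error rate", {
  p <- sim_params(genome_length = 1.5e6, repeat_fraction = 0.5,
                  repeat_unit_length = 500, n_genes = 0, rng_seed = 4)
  gg <- generate_genome(p)
  fc <- fragment_into_contigs(gg$genome, gg$truth)
  expect_gt(nrow(fc$origins), 1000)

  sc0 <- build_scaffolds(fc$origins, 0, seed = 10)
  expect_true(all(sc0$joins$correct))
  # correct joins connect genome-adjacent contigs in + orientation
  ord <- fc$origins$contig_id
  expect_true(all(match(sc0$joins$downstream_contig, ord) ==
                    match(sc0$joins$upstream_contig, ord) + 1L))
  expect_true(all(sc0$composition$orientation == "+"))

  sc1 <- build_scaffolds(fc$origins, 1, seed = 10)
  expect_gt(nrow(sc1$joins), 10)
  expect_true(all(!sc1$joins$correct))

  sc3 <- build_scaffolds(fc$origins, 0.3, seed = 10)
  n <- nrow(sc3$joins)
  expect_gt(n, 700)
  obs <- mean(!sc3$joins$correct)
  expect_lt(abs(obs - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # every contig placed exactly once
  expect_equal(sort(sc3$composition$contig_id), sort(fc$origins$contig_id))
})

test_that("simulated libraries have the stated class geometry and determinism", {
  p <- sim_params(genome_length = 2e5, repeat_fraction = 0, n_genes = 0,
                  rng_seed = 6)
  gg <- generate_genome(p)
  fc <- fragment_into_contigs(gg$genome, gg$truth)
  spec <- list(mean = 3000, sd = 300, read_len = 35, n_pairs = 2000)

  # no contamination: every same-contig pair classifies RF
  pure <- simulate_mp_library(gg$genome, fc$origins, spec,
                              chimera_rate = 0, pe_contamination_rate = 0,
                              seed = 21)
  cls <- classify_pairs(pure$pairs)
  expect_true(all(cls$orientation[cls$same_target] == "RF"))

  # seeded rerun is identical
  again <- simulate_mp_library(gg$genome, fc$origins, spec,
                               chimera_rate = 0, pe_contamination_rate = 0,
                               seed = 21)
  expect_identical(pure, again)

  expect_error(
    simulate_mp_library(gg$genome, fc$origins,
                        list(mean = 3000, sd = 300, read_len = 2000,
                             n_pairs = 10), 0, 0, 1),
    "read_len")
  expect_error(
    simulate_mp_library(gg$genome, fc$origins,
                        list(mean = 1.9e5, sd = 1e4, read_len = 35,
                             n_pairs = 10), 0, 0, 1),
    "incompatible")
})

test_that("orientation classification recovers the true pair class", {
  # on a repeat-free genome every read maps, so the geometry alone
  # determines the orientation class; agreement with truth is exact up to
  # class-overlapping insert draws, which the construction rules out
  p <- sim_params(genome_length = 3e5, repeat_fraction = 0, n_genes = 0,
                  rng_seed = 6)
  gg <- generate_genome(p)
  fc <- fragment_into_contigs(gg$genome, gg$truth)
  lib <- simulate_mp_library(gg$genome, fc$origins,
                             list(mean = 3000, sd = 300, read_len = 35,
                                  n_pairs = 5000),
                             chimera_rate = 0.38,
                             pe_contamination_rate = 0.30, seed = 8)
  cls <- classify_pairs(lib$pairs)
  map <- c(MP_RF = "RF", PE_FR = "FR", CHIMERA_FFRR = "FF_RR")
  agree <- cls$orientation == map[lib$truth$true_class]
  expect_gte(mean(agree), 0.999)
})

test_that("truth hits give exact per-contig coverage arithmetic", {
  p <- small_params(seed = 13)
  gg <- generate_genome(p)
  fc <- fragment_into_contigs(gg$genome, gg$truth)
  hits <- truth_hits(gg$truth, fc$origins)
  expect_true(all(hits$pct_identity == 100))
  plen <- setNames(gg$truth$genes$protein_length, gg$truth$genes$gene_id)
  cov <- gene_coverages(hits, plen)
  # noise-free synthetic assembly contains every exon: adjusted coverage 1
  expect_true(all(cov$adjusted_coverage == 1))
  # per-contig coverages of a split gene sum to exactly 1
  for (i in seq_len(nrow(cov))) {
    expect_equal(sum(cov$per_sequence[[i]]$adjusted), 1)
  }
  split_genes <- vapply(cov$per_sequence, nrow, 0L) > 1
  expect_gt(sum(split_genes), 0)

  # noise adds spurious sub-threshold hits and duplicates
  noisy <- truth_hits(gg$truth, fc$origins, noise_rate = 0.5, seed = 2)
  expect_gt(nrow(noisy), nrow(hits))
  extra <- noisy[seq(nrow(hits) + 1, nrow(noisy)), ]
  spurious <- extra$pct_identity < 70
  expect_true(all(extra$aln_len[spurious] < 30))
  expect_gt(sum(duplicated(noisy)), 0)
})

test_that("BAC extraction yields genome substrings, deterministically", {
  p <- sim_params(genome_length = 2e5, repeat_fraction = 0.4,
                  repeat_unit_length = 2000, n_genes = 0, rng_seed = 3)
  gg <- generate_genome(p)
  b0 <- extract_bacs(gg$genome, 0, c(1000, 2000), seed = 1)
  expect_equal(length(b0$bacs), 0L)
  b <- extract_bacs(gg$genome, 5, c(1000, 2000), seed = 1)
  gseq <- as.character(gg$genome[[1]])
  for (i in 1:5)
    expect_identical(as.character(b$bacs[[i]]),
                     substring(gseq, b$intervals$g_start[i] + 1,
                               b$intervals$g_end[i]))
  expect_identical(extract_bacs(gg$genome, 5, c(1000, 2000), seed = 1), b)

  tiles <- tile_bacs(2e5, 50000, 25000)
  expect_true(all(tiles$intervals$g_end - tiles$intervals$g_start <= 50000))
  # tiling leaves no gap
  cov <- IRanges::reduce(IRanges::IRanges(tiles$intervals$g_start + 1,
                                          tiles$intervals$g_end))
  expect_equal(sum(IRanges::width(cov)), 2e5)
})
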