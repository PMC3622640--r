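#' Generate a complete ground-truthed synthetic dataset
#'
#' Runs every generator stage in dependency order under per-stage child
#' seeds: genome with repeats and genes, contigs broken at repeats,
#' scaffolds with a controlled wrong-join rate, one mate-pair library per
#' insert spec, truth-derived protein hits against contigs and scaffolds,
#' the reference gene order, BAC extracts and truth-derived BAC alignment
#' tables.
#'
#' @param params A [sim_params()] object.
#' @param out_dir Optional directory; when given, all artifacts are written
#'   there (`genome.fasta`, `contigs.fasta`, `scaffolds.agp`, `pairs.tsv`,
#'   `hits_contigs.tsv`, `hits_scaffolds.tsv`, `gene_order.tsv`,
#'   `bacs.fasta`, `bac_hits_contigs.tsv`, `bac_hits_scaffolds.tsv`,
#'   `truth.json`, `params.json`).
#' @param n_bacs Number of BAC analogues to extract (50, as in the original
#'   validation set).
#' @param bac_length_range BAC length range in bp.
#' @param noise_rate Noise proportion for the protein hit table (see
#'   [truth_hits()]).
#' @return A list with all in-memory artifacts: `genome`, `truth`,
#'   `contigs`, `origins`, `contig_lengths`, `composition`, `joins`,
#'   `pairs`, `pair_truth`, `hits_contigs`, `hits_scaffolds`, `gene_order`,
#'   `bacs`, `bac_intervals`, `bac_hits_contigs`, `bac_hits_scaffolds`,
#'   `params`.
#' @export
simulate_dataset <- function(params = sim_params(), out_dir = NULL,
                             n_bacs = 50, bac_length_range = c(30000, 60000),
                             noise_rate = 0) {
  seed <- params$rng_seed
  gg <- generate_genome(params)
  fc <- fragment_into_contigs(gg$genome, gg$truth)
  contig_lengths <- stats::setNames(fc$origins$g_end - fc$origins$g_start,
                                    fc$origins$contig_id)
  sc <- build_scaffolds(fc$origins, params$scaffold_join_error_rate,
                        stage_seed(seed, "scaffolds"))
  libs <- lapply(names(params$insert_specs), function(nm)
    simulate_mp_library(gg$genome, fc$origins, params$insert_specs[[nm]],
                        params$chimera_rate, params$pe_contamination_rate,
                        stage_seed(seed, paste0("library:", nm)), nm))
  pairs <- do.call(rbind, lapply(libs, `[[`, "pairs"))
  pair_truth <- do.call(rbind, lapply(libs, `[[`, "truth"))
  hits_c <- truth_hits(gg$truth, fc$origins, noise_rate,
                       stage_seed(seed, "hits"))
  hits_s <- lift_hits_to_scaffolds(hits_c, sc$composition, contig_lengths)
  go <- gene_order_table(gg$truth)
  bb <- extract_bacs(gg$genome, n_bacs, bac_length_range,
                     stage_seed(seed, "bacs"))
  bh_c <- contig_bac_hits(fc$origins, bb$intervals)
  bh_s <- scaffold_bac_hits(sc$composition, fc$origins, bb$intervals,
                            contig_lengths)
  ds <- list(genome = gg$genome, truth = gg$truth,
             contigs = fc$contigs, origins = fc$origins,
             contig_lengths = contig_lengths,
             composition = sc$composition, joins = sc$joins,
             pairs = pairs, pair_truth = pair_truth,
             hits_contigs = hits_c, hits_scaffolds = hits_s,
             gene_order = go, bacs = bb$bacs, bac_intervals = bb$intervals,
             bac_hits_contigs = bh_c, bac_hits_scaffolds = bh_s,
             params = params)
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_fasta(ds$genome, fp("genome.fasta"))
  write_fasta(ds$contigs, fp("contigs.fasta"))
  write_agp(ds$composition, ds$contig_lengths, fp("scaffolds.agp"))
  write_pair_mappings(ds$pairs, fp("pairs.tsv"))
  write_hits_tsv(ds$hits_contigs, fp("hits_contigs.tsv"))
  write_hits_tsv(ds$hits_scaffolds, fp("hits_scaffolds.tsv"))
  write_gene_order(ds$gene_order, fp("gene_order.tsv"))
  write_fasta(ds$bacs, fp("bacs.fasta"))
  write_hits_tsv(ds$bac_hits_contigs, fp("bac_hits_contigs.tsv"))
  write_hits_tsv(ds$bac_hits_scaffolds, fp("bac_hits_scaffolds.tsv"))
  truth_out <- list(repeats = ds$truth$repeats, genes = ds$truth$genes,
                    exons = ds$truth$exons,
                    repeat_fraction = ds$truth$repeat_fraction,
                    joins = ds$joins,
                    pair_truth = ds$pair_truth,
                    bac_intervals = ds$bac_intervals)
  jsonlite::write_json(truth_out, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  jsonlite::write_json(unclass(ds$params), fp("params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the full evaluation pipeline on a synthetic dataset
#'
#' Computes every stage summary the assembly evaluation produces: contig
#' and scaffold contiguity statistics (with the 200 bp contig length
#' filter applied for the filtered row), mate-pair read-class and
#' orientation summaries per library, gene content (filter rules, AC/SC,
#' GFI, full-length calls in both modes, multigene histogram) for contigs
#' and scaffolds, the synteny bootstrap test, and BAC-based scaffold
#' reliability with its median SRI.
#'
#' @param params A [sim_params()] object (drives the simulation).
#' @param out_dir Optional directory; when given, the dataset plus one TSV
#'   and one JSON summary per stage are written there.
#' @param noise_rate Noise proportion for the protein hit table.
#' @param min_contig_len Length filter applied to the filtered contig
#'   statistics row.
#' @param bootstrap_B Bootstrap resamples for the synteny test.
#' @return A list with elements `dataset`, `stats`, `mp`, `gene_content`,
#'   `reliability`.
#' @export
run_pipeline <- function(params = sim_params(), out_dir = NULL,
                         noise_rate = 0, min_contig_len = 200,
                         bootstrap_B = 1000) {
  ds <- simulate_dataset(params, out_dir = out_dir, noise_rate = noise_rate)
  seed <- params$rng_seed

  clen <- as.vector(ds$contig_lengths)
  slen <- as.vector(scaffold_lengths(ds$composition, ds$contig_lengths))
  stats_tab <- rbind(
    cbind(assembly = "contigs_all", summarize_assembly(clen)),
    cbind(assembly = "contigs_filtered",
          summarize_assembly(filter_by_length(clen, min_contig_len))),
    cbind(assembly = "scaffolds", summarize_assembly(slen)))

  mp <- lapply(split(ds$pairs, ds$pairs$library_id), summarize_library)
  mp$all <- summarize_library(ds$pairs)

  gene_content <- lapply(
    list(contigs = ds$hits_contigs, scaffolds = ds$hits_scaffolds),
    function(h) {
      plen <- stats::setNames(ds$gene_order$protein_length,
                              ds$gene_order$query_id)
      cov <- rule4_gene_exclusion(gene_coverages(filter_hits(h), plen))
      fl_cov <- call_full_length(cov, "coverage")
      fl_ss <- call_full_length(cov, "start_stop")
      list(coverages = cov, gfi = gfi(cov),
           full_length_coverage = fl_cov, full_length_start_stop = fl_ss,
           multigene = multigene_histogram(fl_cov))
    })

  obs_c <- gene_pair_observations(gene_content$contigs$full_length_coverage,
                                  ds$gene_order, "contig")
  obs_s <- gene_pair_observations(gene_content$scaffolds$full_length_coverage,
                                  ds$gene_order, "scaffold")
  boot <- if (nrow(obs_c) > 0 && nrow(obs_s) > 0)
    bootstrap_test(obs_c, neighbour_proportion(obs_s), B = bootstrap_B,
                   seed = stage_seed(seed, "bootstrap"))
  else list(p_value = NA_real_, contig_proportion = NA_real_,
            scaffold_proportion = NA_real_, B = bootstrap_B,
            n = nrow(obs_c))
  multi <- multi_contig_scaffolds(ds$composition)
  assign <- match_scaffolds_to_bacs(
    ds$bac_hits_scaffolds[ds$bac_hits_scaffolds$query_id %in%
                            multi$scaffold_id, , drop = FALSE])
  sri <- sri_records(multi, ds$contig_lengths, assign,
                     ds$bac_hits_contigs)
  reliability <- list(
    contig_observations = obs_c, scaffold_observations = obs_s,
    bootstrap = boot, sri = sri,
    median_sri = if (nrow(sri)) median_sri(sri) else NA_real_,
    median_sri_proportion = if (nrow(sri)) median_sri(sri, "proportion")
    else NA_real_)

  res <- list(dataset = ds, stats = stats_tab, mp = mp,
              gene_content = gene_content, reliability = reliability)
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

write_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_tsv(res$stats, fp("assembly_stats.tsv"))
  mp_tab <- do.call(rbind, lapply(names(res$mp), function(nm) {
    s <- res$mp[[nm]]
    data.frame(library = nm, n_pairs = s$n_pairs,
               t(s$status_proportions), t(s$orientation_proportions))
  }))
  write_tsv(mp_tab, fp("mp_summary.tsv"))
  hist_tab <- do.call(rbind, lapply(names(res$mp), function(nm)
    cbind(library = nm, res$mp[[nm]]$histograms)))
  write_tsv(hist_tab, fp("mp_insert_histograms.tsv"))
  for (asm in names(res$gene_content)) {
    gc <- res$gene_content[[asm]]
    cov <- gc$coverages
    cov$per_sequence <- NULL
    write_tsv(cov, fp(paste0("gene_coverage_", asm, ".tsv")))
    write_tsv(gc$multigene, fp(paste0("multigene_", asm, ".tsv")))
  }
  write_tsv(res$reliability$sri, fp("sri.tsv"))
  gc_sum <- lapply(res$gene_content, function(gc)
    c(as.list(gc$gfi),
      list(full_length_coverage = nrow(gc$full_length_coverage),
           full_length_start_stop = nrow(gc$full_length_start_stop))))
  jsonlite::write_json(
    list(assembly_stats = res$stats, gene_content = gc_sum,
         bootstrap = res$reliability$bootstrap,
         median_sri = res$reliability$median_sri,
         median_sri_proportion = res$reliability$median_sri_proportion),
    fp("summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(out_dir)
}

#' Link-support surrogate scaffolder
#'
#' Builds scaffolds from mate-pair link evidence alone, for the
#' coverage-reduction experiment: every both-mapped pair whose reads hit
#' two different contigs contributes one link; contig pairs supported by at
#' least `k` links are joined, and connected components become scaffolds.
#' Contig order within a component is laid out from the ground-truth genome
#' order — this is explicitly a surrogate for a real scaffolder's
#' ordering/orientation inference, adequate for studying how link support
#' responds to coverage, not for evaluating ordering accuracy.
#'
#' @param pairs Pair-mapping data.frame.
#' @param origins Contig origin table (supplies the layout order).
#' @param k Minimum number of supporting links per join (stringency).
#' @param default_gap Gap recorded between joined contigs (bp).
#' @return A scaffold composition data.frame (singleton contigs omitted).
#' @export
surrogate_scaffolds <- function(pairs, origins, k = 5, default_gap = 100) {
  both <- pairs$mapped1 & pairs$mapped2 & pairs$target1 != pairs$target2
  both[is.na(both)] <- FALSE
  p <- pairs[both, , drop = FALSE]
  if (nrow(p) == 0L)
    return(data.frame(scaffold_id = character(0), contig_id = character(0),
                      orientation = character(0), gap_after = numeric(0)))
  a <- pmin(p$target1, p$target2)
  b <- pmax(p$target1, p$target2)
  tab <- table(paste(a, b, sep = "\r"))
  strong <- names(tab)[tab >= k]
  if (length(strong) == 0L)
    return(data.frame(scaffold_id = character(0), contig_id = character(0),
                      orientation = character(0), gap_after = numeric(0)))
  edges <- do.call(rbind, strsplit(strong, "\r", fixed = TRUE))
  # union-find over contig ids
  parent <- stats::setNames(origins$contig_id, origins$contig_id)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges)))
    parent[[find(edges[i, 1L])]] <- find(edges[i, 2L])
  comp <- vapply(origins$contig_id, find, "")
  groups <- split(origins$contig_id, comp)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L)
    return(data.frame(scaffold_id = character(0), contig_id = character(0),
                      orientation = character(0), gap_after = numeric(0)))
  out <- do.call(rbind, lapply(seq_along(groups), function(i) {
    ids <- groups[[i]]
    ids <- ids[order(match(ids, origins$contig_id))]   # genome-order layout
    data.frame(scaffold_id = sprintf("link_scaf%04d", i), contig_id = ids,
               orientation = "+",
               gap_after = c(rep(default_gap, length(ids) - 1L), 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mate-pair coverage reduction sweep
#'
#' Emulates the reduced-coverage experiment: the pooled mate-pair data is
#' independently subsampled to each fraction (three replicate draws per
#' fraction), scaffolds are rebuilt with the link-support surrogate at
#' stringency `k`, and contiguity plus full-length gene metrics are
#' recorded per run.
#'
#' @param dataset A dataset from [simulate_dataset()].
#' @param fractions Fractions of pairs to retain.
#' @param n_replicates Replicate subsample draws per fraction.
#' @param k Link-support stringency of the surrogate scaffolder.
#' @param seed Integer seed (replicate draws derive child seeds from it).
#' @return Data.frame with one row per fraction and replicate: `fraction`,
#'   `replicate`, `n_pairs`, `n_scaffolds`, `scaffold_n50`,
#'   `n_full_length`.
#' @export
coverage_sweep <- function(dataset,
                           fractions = c(0.01, 0.1, 0.25, 0.4, 0.5, 0.6,
                                         0.75, 1.0),
                           n_replicates = 3, k = 5, seed = 1L) {
  plen <- stats::setNames(dataset$gene_order$protein_length,
                          dataset$gene_order$query_id)
  rows <- list()
  for (f in fractions) for (r in seq_len(n_replicates)) {
    sub <- subsample_pairs(dataset$pairs, f,
                           stage_seed(seed, sprintf("sweep:%g:%d", f, r)))
    comp <- surrogate_scaffolds(sub, dataset$origins, k = k)
    if (nrow(comp)) {
      slen <- as.vector(scaffold_lengths(comp, dataset$contig_lengths))
      hits_s <- lift_hits_to_scaffolds(dataset$hits_contigs, comp,
                                       dataset$contig_lengths)
      cov <- rule4_gene_exclusion(gene_coverages(filter_hits(hits_s), plen))
      fl <- call_full_length(cov, "coverage")
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, replicate = r, n_pairs = nrow(sub),
        n_scaffolds = length(slen), scaffold_n50 = n50(slen),
        n_full_length = nrow(fl))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, replicate = r, n_pairs = nrow(sub),
        n_scaffolds = 0L, scaffold_n50 = NA_real_, n_full_length = NA_integer_)
    }
  }
  do.call(rbind, rows)
}
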