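#' Parameters of the synthetic chromosome-arm simulation
#'
#' Bundles and validates every knob of the synthetic data generator. The
#' defaults emulate, at desk scale, the conditions of flow-sorted,
#' MDA-amplified wheat chromosome arm data: ~80% repetitive DNA in copies
#' of a ~4.6 Kb repeat unit (so contigs broken at repeats have the observed
#' ~1 Kb scale), multi-exon genes confined to the non-repetitive space,
#' three mate-pair libraries with nominal 2/3/5 Kb inserts and 45/35/35 bp
#' reads, ~30% short-insert paired-end contamination, and ~38% same-strand
#' chimeric pairs from MDA inversion artifacts.
#'
#' @param genome_length Genome (chromosome-arm analogue) length in bp.
#' @param repeat_fraction Proportion of the genome occupied by repeat
#'   copies (must be < 1).
#' @param repeat_unit_length Length of one repeat copy in bp.
#' @param n_genes Number of genes to place in non-repeat space.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param gene_length_aa Range `c(min, max)` of protein lengths (aa).
#' @param insert_specs Named list of mate-pair library specifications, each
#'   a list with `mean` (bp), `sd` (bp), `read_len` (bp) and `n_pairs`.
#' @param chimera_rate Proportion of pairs that are MDA inversion chimeras
#'   (mapping FF/RR).
#' @param pe_contamination_rate Proportion of pairs that are short-insert
#'   paired-end contaminants (mapping FR).
#' @param scaffold_join_error_rate Probability that any one scaffold join
#'   is wrong (non-adjacent contig or flipped orientation).
#' @param rng_seed Integer global seed; per-stage child seeds are derived
#'   from it via [stage_seed()].
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(genome_length = 2e6,
                       repeat_fraction = 0.8,
                       repeat_unit_length = 4600,
                       n_genes = 120,
                       exons_per_gene = c(1L, 5L),
                       gene_length_aa = c(80L, 300L),
                       insert_specs = list(
                         mp2k = list(mean = 2000, sd = 200, read_len = 45,
                                     n_pairs = 3000),
                         mp3k = list(mean = 3000, sd = 300, read_len = 35,
                                     n_pairs = 3000),
                         mp5k = list(mean = 5000, sd = 500, read_len = 35,
                                     n_pairs = 3000)),
                       chimera_rate = 0.38,
                       pe_contamination_rate = 0.30,
                       scaffold_join_error_rate = 0.05,
                       rng_seed = 1L) {
  p <- list(genome_length = genome_length, repeat_fraction = repeat_fraction,
            repeat_unit_length = repeat_unit_length, n_genes = n_genes,
            exons_per_gene = as.integer(exons_per_gene),
            gene_length_aa = as.integer(gene_length_aa),
            insert_specs = insert_specs, chimera_rate = chimera_rate,
            pe_contamination_rate = pe_contamination_rate,
            scaffold_join_error_rate = scaffold_join_error_rate,
            rng_seed = as.integer(rng_seed))
  props <- c(repeat_fraction, chimera_rate, pe_contamination_rate,
             scaffold_join_error_rate)
  if (any(props < 0 | props > 1)) abort("all proportions must lie in [0, 1]")
  if (repeat_fraction >= 1) abort("repeat_fraction must be < 1")
  if (chimera_rate + pe_contamination_rate > 1)
    abort("chimera_rate + pe_contamination_rate must be <= 1")
  if (genome_length < 1 || repeat_unit_length < 1 || n_genes < 0)
    abort("genome_length, repeat_unit_length must be positive; n_genes >= 0")
  if (length(p$exons_per_gene) != 2L || p$exons_per_gene[1L] < 1L ||
      diff(p$exons_per_gene) < 0L)
    abort("exons_per_gene must be an increasing range with min >= 1")
  if (length(p$gene_length_aa) != 2L || p$gene_length_aa[1L] < 10L ||
      diff(p$gene_length_aa) < 0L)
    abort("gene_length_aa must be an increasing range with min >= 10")
  for (nm in names(insert_specs)) {
    s <- insert_specs[[nm]]
    if (!all(c("mean", "sd", "read_len", "n_pairs") %in% names(s)))
      abort("insert spec '", nm, "' must name mean, sd, read_len, n_pairs")
    if (s$mean <= 2 * s$read_len)
      abort("insert spec '", nm, "': mean insert must exceed 2 * read_len")
  }
  class(p) <- "sim_params"
  p
}
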