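random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic repeat-rich genome with known gene and repeat layout
#'
#' Builds one chromosome-arm analogue: `k = round(repeat_fraction *
#' genome_length / repeat_unit_length)` identical copies of a single random
#' repeat unit (repeat families collapse in assembly precisely because
#' copies are near-identical) are dropped at random positions, and genes
#' with exon/intron structure are placed left-to-right in the remaining
#' unique space. A gene's exons always lie in unique sequence, but
#' consecutive exons may fall in different unique segments, i.e. the intron
#' spans one or more repeat copies — the configuration that fragments genes
#' across contigs once the assembly breaks at repeats.
#'
#' @param params A [sim_params()] object.
#' @return A list with:
#'   * `genome`: a one-record named [Biostrings::DNAStringSet];
#'   * `truth`: the ground-truth ledger, a list with `repeats` (0-based
#'     half-open intervals), `genes` (`gene_id`, `g_start`, `g_end`,
#'     `strand`, `order_index`, `protein_length`, `chromosome`), `exons`
#'     (`gene_id`, `exon_index`, `g_start`, `g_end`, `q_start`, `q_end`
#'     with query coordinates 1-based inclusive aa), and the realized
#'     `repeat_fraction`.
#' @export
generate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(stage_seed(params$rng_seed, "genome"), {
    L <- params$genome_length
    unit <- params$repeat_unit_length
    k <- round(params$repeat_fraction * L / unit)
    if (k * unit >= L) abort("repeat copies leave no unique sequence")
    unique_bp <- L - k * unit

    # distribute the unique bases among the k+1 gaps around repeat copies by
    # uniform stick-breaking: inter-repeat distances come out exponential-like
    # with a long tail, as for randomly interspersed transposon insertions
    gaps <- if (k > 0)
      diff(c(0, round(c(sort(stats::runif(k)), 1) * unique_bp)))
    else unique_bp
    rep_starts <- cumsum(gaps[seq_len(k)]) + (seq_len(k) - 1L) * unit
    repeats <- data.frame(start = rep_starts, end = rep_starts + unit)

    # unique segments = complement of the repeat intervals
    seg_start <- c(0, repeats$end)
    seg_end <- c(repeats$start, L)
    keep <- seg_end > seg_start
    segments <- data.frame(start = seg_start[keep], end = seg_end[keep])

    genes_exons <- place_genes(params, segments)

    # realize residues: unique background, then stamp the repeat unit copies
    base <- random_dna(L)
    if (k > 0) {
      unit_seq <- random_dna(unit)
      base_parts <- character(2L * k + 1L)
      pos <- 0
      for (i in seq_len(k)) {
        base_parts[2L * i - 1L] <- substr(base, pos + 1L, repeats$start[i])
        base_parts[2L * i] <- unit_seq
        pos <- repeats$end[i]
      }
      base_parts[2L * k + 1L] <- substr(base, pos + 1L, L)
      base <- paste(base_parts, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(stats::setNames(base, "genome1"))

    truth <- list(repeats = repeats,
                  genes = genes_exons$genes,
                  exons = genes_exons$exons,
                  repeat_fraction = k * unit / L,
                  genome_length = L)
    list(genome = genome, truth = truth)
  })
}

# Place n_genes genes left-to-right into the unique segments. Exons are
# placed at a moving cursor; an exon that does not fit in the remaining
# space of the current segment advances to the next segment that can hold
# it (introns thereby spanning repeat copies).
place_genes <- function(params, segments) {
  n <- params$n_genes
  empty_genes <- data.frame(gene_id = character(0), g_start = numeric(0),
                            g_end = numeric(0), strand = character(0),
                            order_index = integer(0),
                            protein_length = integer(0),
                            chromosome = character(0))
  empty_exons <- data.frame(gene_id = character(0), exon_index = integer(0),
                            g_start = numeric(0), g_end = numeric(0),
                            q_start = numeric(0), q_end = numeric(0))
  if (n == 0L) return(list(genes = empty_genes, exons = empty_exons))
  seg_i <- 1L
  pos <- segments$start[1L]
  advance <- function(needed) {
    # move the cursor to the first position (current or later segment) with
    # `needed` bp of room; returns FALSE when the genome is exhausted
    while (seg_i <= nrow(segments) && segments$end[seg_i] - pos < needed) {
      seg_i <<- seg_i + 1L
      if (seg_i <= nrow(segments)) pos <<- segments$start[seg_i]
    }
    seg_i <= nrow(segments)
  }
  genes <- vector("list", n)
  exons <- list()
  for (g in seq_len(n)) {
    gid <- sprintf("gene%03d", g)
    aa <- sample(params$gene_length_aa[1L]:params$gene_length_aa[2L], 1L)
    n_ex <- sample(params$exons_per_gene[1L]:params$exons_per_gene[2L], 1L)
    ex_aa <- if (n_ex == 1L) aa else
      as.vector(stats::rmultinom(1L, aa - 5L * n_ex, rep(1, n_ex))) + 5L
    # inter-gene spacer: a mixture of short (gene island) and long jumps,
    # so genes form clusters spread across the arm as in gene-sparse
    # repeat-rich genomes
    pos <- pos + if (stats::runif(1L) < 0.4) sample(50:300, 1L) else
      round(stats::runif(1L, 1000, 5000))
    q_pos <- 0L
    ex_rows <- vector("list", n_ex)
    for (e in seq_len(n_ex)) {
      need <- 3L * ex_aa[e]
      if (!advance(need))
        abort("genes do not fit into the unique sequence space; ",
              "reduce n_genes or gene_length_aa")
      ex_rows[[e]] <- data.frame(gene_id = gid, exon_index = e,
                                 g_start = pos, g_end = pos + need,
                                 q_start = q_pos + 1L, q_end = q_pos + ex_aa[e])
      pos <- pos + need
      q_pos <- q_pos + ex_aa[e]
      if (e < n_ex) pos <- pos + sample(20:150, 1L)  # intra-segment intron
    }
    ex_df <- do.call(rbind, ex_rows)
    exons[[g]] <- ex_df
    genes[[g]] <- data.frame(gene_id = gid,
                             g_start = min(ex_df$g_start),
                             g_end = max(ex_df$g_end),
                             strand = sample(c("+", "-"), 1L),
                             order_index = g,
                             protein_length = aa,
                             chromosome = "ref1",
                             stringsAsFactors = FALSE)
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
}

#' Fragment the genome into contigs at repeat copies
#'
#' Emulates the collapse of repeat copies during short-read assembly: each
#' maximal unique (non-repeat) segment of the genome becomes one contig;
#' repeat sequence is lost. With no repeats, the single contig is the whole
#' genome.
#'
#' @param genome One-record [Biostrings::DNAStringSet] from
#'   [generate_genome()].
#' @param truth Truth ledger from [generate_genome()].
#' @param break_policy Only `"break_at_repeats"` is implemented.
#' @return A list with `contigs` (a named [Biostrings::DNAStringSet]) and
#'   `origins` (data.frame `contig_id`, `g_start`, `g_end`, 0-based
#'   half-open genome coordinates, in genome order).
#' @export
fragment_into_contigs <- function(genome, truth,
                                  break_policy = "break_at_repeats") {
  if (break_policy != "break_at_repeats")
    abort("unknown break policy: ", break_policy)
  L <- truth$genome_length
  rep_ir <- IRanges::IRanges(start = truth$repeats$start + 1L,
                             end = truth$repeats$end)
  uniq <- IRanges::setdiff(IRanges::IRanges(1L, L), rep_ir)
  origins <- data.frame(
    contig_id = sprintf("ctg%05d", seq_along(uniq)),
    g_start = IRanges::start(uniq) - 1L,
    g_end = IRanges::end(uniq),
    stringsAsFactors = FALSE)
  gseq <- as.character(genome[[1L]])
  residues <- substring(gseq, origins$g_start + 1L, origins$g_end)
  contigs <- Biostrings::DNAStringSet(stats::setNames(residues,
                                                      origins$contig_id))
  list(contigs = contigs, origins = origins)
}

#' Tile BAC-clone analogues across the genome
#'
#' Deterministic alternative to [extract_bacs()]: overlapping fixed-length
#' windows stepped across the genome, guaranteeing that every region (and
#' hence every scaffold shorter than `step`) is fully contained in at least
#' one BAC. Useful when the validation requires complete BAC coverage
#' rather than the random clone sampling of a real BAC set.
#'
#' @param genome One-record [Biostrings::DNAStringSet] or its length in bp.
#' @param bac_length Window length in bp.
#' @param step Distance between consecutive window starts in bp (must not
#'   exceed `bac_length`).
#' @return A list with `bacs` (`NULL`; only intervals are materialized) and
#'   `intervals` (data.frame `bac_id`, `g_start`, `g_end`).
#' @export
tile_bacs <- function(genome, bac_length = 80000, step = 40000) {
  L <- if (is.numeric(genome)) genome else Biostrings::width(genome)[1L]
  if (step > bac_length) abort("step must not exceed bac_length")
  starts <- seq(0, max(0, L - bac_length), by = step)
  if (utils::tail(starts, 1L) + bac_length < L)
    starts <- c(starts, L - bac_length)
  intervals <- data.frame(bac_id = sprintf("tile%03d", seq_along(starts)),
                          g_start = starts,
                          g_end = pmin(starts + bac_length, L),
                          stringsAsFactors = FALSE)
  list(bacs = NULL, intervals = intervals)
}

#' Extract BAC-clone analogues from the genome
#'
#' Random genome substrings standing in for independently assembled BAC
#' clones used as ground truth for scaffold validation.
#'
#' @param genome One-record [Biostrings::DNAStringSet].
#' @param n Number of BACs.
#' @param length_range Range `c(min, max)` of BAC lengths in bp.
#' @param seed Integer seed.
#' @return A list with `bacs` (named [Biostrings::DNAStringSet]) and
#'   `intervals` (data.frame `bac_id`, `g_start`, `g_end`).
#' @export
extract_bacs <- function(genome, n, length_range = c(30000, 60000), seed = 1L) {
  L <- Biostrings::width(genome)[1L]
  if (length_range[2L] > L) abort("BAC length range exceeds genome length")
  if (n == 0L)
    return(list(bacs = Biostrings::DNAStringSet(),
                intervals = data.frame(bac_id = character(0),
                                       g_start = numeric(0),
                                       g_end = numeric(0))))
  with_seed(seed, {
    len <- round(stats::runif(n, length_range[1L], length_range[2L]))
    start <- floor(stats::runif(n, 0, L - len))
    intervals <- data.frame(bac_id = sprintf("bac%03d", seq_len(n)),
                            g_start = start, g_end = start + len,
                            stringsAsFactors = FALSE)
    gseq <- as.character(genome[[1L]])
    bacs <- Biostrings::DNAStringSet(stats::setNames(
      substring(gseq, start + 1L, start + len), intervals$bac_id))
    list(bacs = bacs, intervals = intervals)
  })
}
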