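#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#' @importFrom IRanges IRanges reduce width start end
NULL

# ---------------------------------------------------------------------------
# All on-disk formats keep their native coordinate conventions (BLAST tabular
# and AGP are 1-based inclusive); everything in memory is 0-based half-open.
# Conversion happens here and only here.
# ---------------------------------------------------------------------------

#' Read a FASTA file into a DNAStringSet
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id (first whitespace
#'   token of each header).
#' @details Duplicate record ids and empty sequences are hard errors: both
#'   break the downstream bookkeeping that maps hits and read placements onto
#'   sequences by id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    abort("duplicate sequence id(s) in ", path, ": ",
          paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    abort("empty sequence(s) in ", path, ": ",
          paste(names(seqs)[Biostrings::width(seqs) == 0L], collapse = ", "))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    abort("sequences must carry unique names")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

hit_cols <- c("query_id", "target_id", "pct_identity", "aln_len", "mismatches",
              "gap_length", "q_start", "q_end", "t_start", "t_end",
              "t_strand", "e_value", "bit_score")

#' Read a 12-column BLAST-style tabular hit file
#'
#' Columns are the standard tabular order: query id, target id, percent
#' identity, alignment length (aa for protein-vs-nucleotide searches),
#' mismatches, gap openings, query start/end (1-based inclusive, amino
#' acids), target start/end (1-based inclusive, bp; start > end encodes a
#' minus-strand hit), e-value, bit score.
#'
#' @param path Path to the TSV.
#' @return A data.frame with one row per hit. Target coordinates are
#'   normalized to an ordered `[t_start, t_end)` 0-based half-open interval
#'   plus a `t_strand` flag; query coordinates stay 1-based inclusive residue
#'   positions (the natural unit for protein coverage arithmetic).
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) abort("hit table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(hit_cols)), hit_cols))
    num <- setdiff(hit_cols, c("query_id", "target_id", "t_strand"))
    df[num] <- lapply(df[num], as.numeric)
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 12L)
  if (length(short))
    abort("hit table row ", short[1L], " has ",
          lengths(fields)[short[1L]], " columns (12 required)")
  m <- t(vapply(fields, function(f) f[1:12], character(12L)))
  suppress_na <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad)) abort("non-numeric ", col, " at row ", bad[1L])
    v
  }
  ts <- suppress_na(m[, 9L], "target start")
  te <- suppress_na(m[, 10L], "target end")
  minus <- ts > te
  data.frame(
    query_id = m[, 1L], target_id = m[, 2L],
    pct_identity = suppress_na(m[, 3L], "percent identity"),
    aln_len = suppress_na(m[, 4L], "alignment length"),
    mismatches = suppress_na(m[, 5L], "mismatches"),
    gap_length = suppress_na(m[, 6L], "gap length"),
    q_start = suppress_na(m[, 7L], "query start"),
    q_end = suppress_na(m[, 8L], "query end"),
    t_start = ifelse(minus, te, ts) - 1,        # to 0-based half-open
    t_end = ifelse(minus, ts, te),
    t_strand = ifelse(minus, "-", "+"),
    e_value = suppress_na(m[, 11L], "e-value"),
    bit_score = suppress_na(m[, 12L], "bit score"),
    stringsAsFactors = FALSE)
}

#' Write hits back to 12-column BLAST-style TSV
#'
#' Inverse of [read_hits_tsv()]: restores 1-based inclusive coordinates and
#' re-encodes minus-strand hits as target start > end.
#'
#' @param hits Data.frame as returned by [read_hits_tsv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  stopifnot(all(hit_cols %in% names(hits)))
  ts1 <- hits$t_start + 1
  te1 <- hits$t_end
  minus <- hits$t_strand == "-"
  out <- data.frame(hits$query_id, hits$target_id,
                    hits$pct_identity, hits$aln_len, hits$mismatches,
                    hits$gap_length, hits$q_start, hits$q_end,
                    ifelse(minus, te1, ts1), ifelse(minus, ts1, te1),
                    hits$e_value, hits$bit_score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

pair_cols <- c("pair_id", "library_id",
               "target1", "start1", "end1", "strand1",
               "target2", "start2", "end2", "strand2")

#' Read mate-pair mapping records
#'
#' The pair-mapping table is a 10-column TSV: `pair_id`, `library_id`, then
#' for each of the two reads its target sequence id, 0-based start, exclusive
#' end and strand (`F`/`R`). Unmapped reads carry `*` in all four fields.
#'
#' @param path Path to the TSV (header line required).
#' @return Data.frame with the columns above plus logical `mapped1`/`mapped2`;
#'   coordinates of unmapped reads are `NA`.
#' @export
read_pair_mappings <- function(path) {
  if (!file.exists(path)) abort("pair mapping table not found: ", path)
  df <- read_tsv(path, col_classes = "character")
  missing <- setdiff(pair_cols, names(df))
  if (length(missing))
    abort("pair mapping table lacks column(s): ", paste(missing, collapse = ", "))
  parse_side <- function(t, s, e, strand, side) {
    mapped <- t != "*"
    bad <- which(mapped & !strand %in% c("F", "R"))
    if (length(bad))
      abort("malformed strand token '", strand[bad[1L]], "' at data row ",
            bad[1L], " (read ", side, ")")
    s_n <- suppressWarnings(as.numeric(ifelse(mapped, s, NA)))
    e_n <- suppressWarnings(as.numeric(ifelse(mapped, e, NA)))
    bad <- which(mapped & (is.na(s_n) | is.na(e_n) | s_n >= e_n))
    if (length(bad))
      abort("invalid coordinates at data row ", bad[1L], " (read ", side, ")")
    list(target = ifelse(mapped, t, NA_character_), start = s_n, end = e_n,
         strand = ifelse(mapped, strand, NA_character_), mapped = mapped)
  }
  r1 <- parse_side(df$target1, df$start1, df$end1, df$strand1, 1L)
  r2 <- parse_side(df$target2, df$start2, df$end2, df$strand2, 2L)
  data.frame(pair_id = df$pair_id, library_id = df$library_id,
             target1 = r1$target, start1 = r1$start, end1 = r1$end,
             strand1 = r1$strand, mapped1 = r1$mapped,
             target2 = r2$target, start2 = r2$start, end2 = r2$end,
             strand2 = r2$strand, mapped2 = r2$mapped,
             stringsAsFactors = FALSE)
}

#' Write mate-pair mapping records
#'
#' @param pairs Data.frame as returned by [read_pair_mappings()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_mappings <- function(pairs, path) {
  fmt_side <- function(t, s, e, strand, mapped) {
    list(t = ifelse(mapped, t, "*"),
         s = ifelse(mapped, format(s, scientific = FALSE, trim = TRUE), "*"),
         e = ifelse(mapped, format(e, scientific = FALSE, trim = TRUE), "*"),
         strand = ifelse(mapped, strand, "*"))
  }
  a <- fmt_side(pairs$target1, pairs$start1, pairs$end1, pairs$strand1, pairs$mapped1)
  b <- fmt_side(pairs$target2, pairs$start2, pairs$end2, pairs$strand2, pairs$mapped2)
  out <- data.frame(pair_id = pairs$pair_id, library_id = pairs$library_id,
                    target1 = a$t, start1 = a$s, end1 = a$e, strand1 = a$strand,
                    target2 = b$t, start2 = b$s, end2 = b$e, strand2 = b$strand)
  write_tsv(out, path)
}

#' Read scaffold composition from an AGP v2.0 file
#'
#' Only `W` (contig) and `N`/`U` (gap) component rows are expected. The
#' in-memory representation is one row per contig part: `scaffold_id`,
#' `contig_id`, `orientation` (`+`/`-`) and `gap_after` (bp of gap between
#' this part and the next within the scaffold; 0 for the last part).
#'
#' @param path AGP file path.
#' @param contig_ids Optional character vector of known contig ids; any AGP
#'   component id absent from it is a hard error.
#' @return Data.frame of scaffold parts in file order.
#' @export
read_agp <- function(path, contig_ids = NULL) {
  if (!file.exists(path)) abort("AGP file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L) abort("AGP row ", i, " has fewer than 8 columns")
    if (f[5L] == "W") {
      parts[[length(parts) + 1L]] <- data.frame(
        scaffold_id = f[1L], contig_id = f[6L],
        orientation = if (f[9L] %in% c("-", "minus")) "-" else "+",
        gap_after = 0, stringsAsFactors = FALSE)
    } else if (f[5L] %in% c("N", "U")) {
      if (length(parts) == 0L || parts[[length(parts)]]$scaffold_id != f[1L])
        abort("AGP row ", i, ": gap with no preceding contig part")
      parts[[length(parts)]]$gap_after <- as.numeric(f[6L])
    } else {
      abort("AGP row ", i, ": unsupported component type '", f[5L], "'")
    }
  }
  comp <- do.call(rbind, parts)
  if (is.null(comp)) abort("AGP file contains no component rows: ", path)
  if (!is.null(contig_ids)) {
    unknown <- setdiff(comp$contig_id, contig_ids)
    if (length(unknown))
      abort("AGP references unknown contig id(s): ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  }
  rownames(comp) <- NULL
  comp
}

#' Write scaffold composition as AGP v2.0
#'
#' @param composition Data.frame of parts as returned by [read_agp()].
#' @param contig_lengths Named numeric vector of contig lengths (bp), used to
#'   lay out object coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(composition, contig_lengths, path) {
  unknown <- setdiff(composition$contig_id, names(contig_lengths))
  if (length(unknown))
    abort("no length known for contig id(s): ",
          paste(utils::head(unknown, 5L), collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  for (sid in unique(composition$scaffold_id)) {
    rows <- composition[composition$scaffold_id == sid, , drop = FALSE]
    pos <- 0
    part <- 0L
    for (j in seq_len(nrow(rows))) {
      len <- contig_lengths[[rows$contig_id[j]]]
      part <- part + 1L
      writeLines(paste(sid, pos + 1, pos + len, part, "W", rows$contig_id[j],
                       1, len, rows$orientation[j], sep = "\t"), con)
      pos <- pos + len
      if (j < nrow(rows) && rows$gap_after[j] > 0) {
        part <- part + 1L
        writeLines(paste(sid, pos + 1, pos + rows$gap_after[j], part, "N",
                         rows$gap_after[j], "scaffold", "yes", "paired-ends",
                         sep = "\t"), con)
        pos <- pos + rows$gap_after[j]
      }
    }
  }
  invisible(path)
}

#' Read a reference gene-order table
#'
#' Four tab-separated columns with header: `query_id`, `chromosome`,
#' `order_index` (integer rank of the gene along its reference chromosome)
#' and `protein_length` (aa).
#'
#' @param path Path to the TSV.
#' @return Data.frame with those columns.
#' @export
read_gene_order <- function(path) {
  df <- read_tsv(path)
  need <- c("query_id", "chromosome", "order_index", "protein_length")
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort("gene order table lacks column(s): ", paste(missing, collapse = ", "))
  dup <- duplicated(df[c("chromosome", "order_index")])
  if (any(dup))
    abort("duplicate order_index within chromosome at row ", which(dup)[1L])
  if (any(df$protein_length < 1)) abort("protein_length must be >= 1")
  df
}

#' Write a reference gene-order table
#' @param gene_order Data.frame as returned by [read_gene_order()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_order <- function(gene_order, path) {
  write_tsv(gene_order[c("query_id", "chromosome", "order_index",
                         "protein_length")], path)
}
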