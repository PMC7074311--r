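#' Read gene features from a GFF3 annotation
#'
#' Minimal strict GFF3 reader for gene-level interval lookups: parses the
#' nine tab-separated columns, keeps rows whose type is `gene`, and reports
#' malformed lines by number. Coordinates follow GFF3: 1-based, closed.
#'
#' @param path Path to an (uncompressed) GFF3 file.
#' @return Data frame `seqid`, `start`, `end`, `strand`, `gene_id` (the
#'   `ID=` attribute, or `NA` when absent).
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  rows <- which(keep)
  if (!length(rows)) {
    return(data.frame(seqid = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad)) {
    stop("malformed GFF3 line ", rows[bad[1]], ": expected 9 tab-separated fields, found ",
         lengths(parts)[bad[1]])
  }
  tab <- do.call(rbind, parts)
  start <- suppressWarnings(as.numeric(tab[, 4]))
  end <- suppressWarnings(as.numeric(tab[, 5]))
  badpos <- which(is.na(start) | is.na(end) | start > end)
  if (length(badpos)) {
    stop("malformed GFF3 line ", rows[badpos[1]], ": invalid start/end coordinates")
  }
  is_gene <- tab[, 3] == "gene"
  ids <- rep(NA_character_, sum(is_gene))
  m <- regmatches(tab[is_gene, 9], regexec("(?:^|;)ID=([^;]+)", tab[is_gene, 9]))
  got <- lengths(m) == 2L
  ids[got] <- vapply(m[got], `[`, "", 2L)
  data.frame(seqid = tab[is_gene, 1], start = start[is_gene],
             end = end[is_gene], strand = tab[is_gene, 7],
             gene_id = ids, stringsAsFactors = FALSE)
}

#' Genes overlapping a physical support interval
#'
#' Returns the genes whose span intersects the closed, 1-based interval
#' `[bp_lo, bp_hi]` on the given chromosome — the gene-content lookup used
#' to turn a 1-LOD support interval into a candidate-gene list.
#'
#' @param genes Gene table from [read_gff3_genes()].
#' @param seqid Chromosome / sequence id to query.
#' @param bp_lo,bp_hi Interval bounds in bp (closed).
#' @return A list `genes` (subset of rows) and `count`.
#' @export
genes_in_interval <- function(genes, seqid, bp_lo, bp_hi) {
  stopifnot(bp_lo <= bp_hi)
  hit <- genes$seqid == as.character(seqid) &
    genes$start <= bp_hi & genes$end >= bp_lo
  list(genes = genes[hit, , drop = FALSE], count = sum(hit))
}
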