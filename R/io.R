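# File formats: validating CSV readers/writers for maps, genotypes,
# phenotypes and marker calls, plus JSON/YAML configuration. CSV is the
# native format (headered, UTF-8, dot decimal separator); the columns map
# one-to-one onto the JoinMap/MapQTL data model without reproducing those
# proprietary dialects.

.read_csv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.check_numeric_column <- function(df, col, path) {
  raw <- df[[col]]
  if (is.numeric(raw)) return(as.numeric(raw))
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & raw != "" & is.na(x))
  if (length(bad)) {
    hint <- if (grepl(",", raw[bad[1]], fixed = TRUE)) {
      " (comma decimal separator? use '.')"
    } else ""
    stop("non-numeric value in ", path, ", line ", bad[1] + 1L,
         ", column '", col, "': '", raw[bad[1]], "'", hint)
  }
  x
}

#' Read / write a genetic map CSV
#'
#' Columns `marker,chrom,cm,bp,parent`; the reader validates the map
#' invariants (unique names, strictly increasing cM and bp per chromosome).
#'
#' @param path CSV path.
#' @return A `genetic_map` data frame.
#' @export
read_map_csv <- function(path) {
  df <- .read_csv_checked(path)
  needed <- c("marker", "chrom", "cm", "bp", "parent")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("unknown schema in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df$cm <- .check_numeric_column(df, "cm", path)
  df$bp <- .check_numeric_column(df, "bp", path)
  genetic_map(df$marker, df$chrom, df$cm, df$bp, df$parent)
}

#' @rdname read_map_csv
#' @param map A `genetic_map`.
#' @export
write_map_csv <- function(map, path) {
  validate_genetic_map(map)
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a genotype CSV
#'
#' First column `id` (unique offspring ids), one column per marker with
#' values `a`, `b` or empty/NA.
#'
#' @param path CSV path.
#' @param parent Optional parent label to attach.
#' @param map Optional `genetic_map` to attach (enables position lookups).
#' @return A `genotype_matrix`.
#' @export
read_genotype_csv <- function(path, parent = NA_character_, map = NULL) {
  df <- .read_csv_checked(path)
  if (names(df)[1] != "id") stop("unknown schema in ", path, ": first column must be 'id'")
  dup <- which(duplicated(df$id))
  if (length(dup)) {
    stop("duplicated offspring id in ", path, ", line ", dup[1] + 1L,
         ": '", df$id[dup[1]], "'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == ""] <- NA_character_
  bad <- which(!is.na(m) & !(m %in% c("a", "b")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid genotype call in ", path, ", line ", bad[1, 1] + 1L,
         ", column '", colnames(m)[bad[1, 2]], "': '", m[bad[1, , drop = FALSE]], "'")
  }
  rownames(m) <- df$id
  attr(m, "parent") <- parent
  if (!is.null(map)) attr(m, "map") <- map
  class(m) <- c("genotype_matrix", class(m))
  m
}

#' @rdname read_genotype_csv
#' @param geno A `genotype_matrix`.
#' @export
write_genotype_csv <- function(geno, path) {
  df <- data.frame(id = rownames(geno), unclass(geno), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a phenotype CSV
#'
#' Long format `id,season,SEDW,SEDN,SEDA`; numeric columns are validated
#' cell-wise with file/line/column errors, and the SEDA = SEDW/SEDN
#' identity is checked row-wise where all three are present.
#'
#' @param path CSV path.
#' @return A phenotype data frame.
#' @export
read_phenotype_csv <- function(path) {
  df <- .read_csv_checked(path)
  needed <- c("id", "season", "SEDW", "SEDN", "SEDA")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("unknown schema in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("SEDW", "SEDN", "SEDA")) {
    df[[col]] <- .check_numeric_column(df, col, path)
  }
  df$season <- as.character(df$season)
  full <- stats::complete.cases(df[, c("SEDW", "SEDN", "SEDA")])
  off <- which(full & abs(df$SEDA - df$SEDW / df$SEDN) >= 1e-9)
  if (length(off)) {
    stop("SEDA != SEDW/SEDN in ", path, ", line ", off[1] + 1L)
  }
  df
}

#' @rdname read_phenotype_csv
#' @param pheno A phenotype data frame.
#' @export
write_phenotype_csv <- function(pheno, path) {
  utils::write.csv(pheno[, c("id", "season", "SEDW", "SEDN", "SEDA")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a marker-call CSV
#'
#' Long format `id,marker,call` (SSR allele sizes or SNP genotypes as
#' character calls).
#'
#' @param path CSV path.
#' @return A data frame `id`, `marker`, `call`.
#' @export
read_marker_calls_csv <- function(path) {
  df <- .read_csv_checked(path)
  needed <- c("id", "marker", "call")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("unknown schema in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- which(duplicated(df[, c("id", "marker")]))
  if (length(dup)) {
    stop("duplicated id/marker pair in ", path, ", line ", dup[1] + 1L)
  }
  df
}

#' Analysis configuration
#'
#' Validated settings bundle for a full run, echoed into output metadata.
#'
#' @param cutoff_g Seedless/seeded SEDW cutoff (g).
#' @param n_permutations Permutations for LOD thresholds.
#' @param alpha Type-I error rate.
#' @param step_cm Scan grid step (cM).
#' @param window_cm Cofactor exclusion window (cM).
#' @param seed Integer RNG seed.
#' @param traits Traits to analyse.
#' @param paths Optional named list of input paths.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(cutoff_g = 0.045, n_permutations = 1000,
                            alpha = 0.05, step_cm = 1, window_cm = 30,
                            seed = 1L, traits = c("SEDW", "SEDN", "SEDA"),
                            paths = list()) {
  stopifnot(cutoff_g > 0, n_permutations >= 100, alpha > 0, alpha <= 1,
            step_cm > 0, window_cm >= 0)
  structure(list(cutoff_g = cutoff_g, n_permutations = n_permutations,
                 alpha = alpha, step_cm = step_cm, window_cm = window_cm,
                 seed = as.integer(seed), traits = traits, paths = paths),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param path JSON or YAML file with configuration fields.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(analysis_config, cfg)
}

#' Write permutation thresholds as JSON
#'
#' @param thresholds Result of [permutation_thresholds()].
#' @param path Output path.
#' @param config Optional [analysis_config()] echoed into the metadata.
#' @export
write_thresholds_json <- function(thresholds, path, config = NULL) {
  payload <- list(thresholds = thresholds,
                  metadata = list(package_version = as.character(utils::packageVersion("seedqtl")),
                                  config = if (!is.null(config)) unclass(config)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
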