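#' Construct a genetic map
#'
#' A genetic map is a data frame with one row per marker and columns
#' `marker`, `chrom`, `cm`, `bp`, `parent`. Within each chromosome both the
#' cM and the bp positions must be strictly increasing and marker names must
#' be unique across the whole map.
#'
#' @param marker Character vector of unique marker names.
#' @param chrom Chromosome identifier per marker (coerced to character).
#' @param cm Map position in centiMorgan.
#' @param bp Physical position in base pairs.
#' @param parent Parent label for the map (e.g. "MA" or "CS").
#' @return A `genetic_map` data frame.
#' @export
genetic_map <- function(marker, chrom, cm, bp, parent) {
  map <- data.frame(
    marker = as.character(marker),
    chrom = as.character(chrom),
    cm = as.numeric(cm),
    bp = as.numeric(bp),
    parent = as.character(parent),
    stringsAsFactors = FALSE
  )
  validate_genetic_map(map)
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @rdname genetic_map
#' @param map A candidate map data frame.
#' @export
validate_genetic_map <- function(map) {
  needed <- c("marker", "chrom", "cm", "bp", "parent")
  missing_cols <- setdiff(needed, names(map))
  if (length(missing_cols)) {
    stop("map is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(map) == 0L) stop("map has no markers")
  if (anyDuplicated(map$marker)) {
    stop("duplicated marker names: ",
         paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  }
  for (chr in unique(map$chrom)) {
    sub <- map[map$chrom == chr, ]
    if (is.unsorted(sub$cm, strictly = TRUE)) {
      stop("cM positions not strictly increasing on chromosome ", chr)
    }
    if (is.unsorted(sub$bp, strictly = TRUE)) {
      stop("bp positions not strictly increasing on chromosome ", chr)
    }
  }
  invisible(map)
}

#' Parse chromosome and physical position from a SNP name
#'
#' SNP markers on the grapevine 20K chip are conventionally renamed to
#' `chr{C}_{bp}_1` after their position in the 12X.2 reference assembly,
#' e.g. `chr2_5144635_1` is chromosome 2 at 5,144,635 bp.
#'
#' @param name Character vector of marker names.
#' @return A data frame with columns `marker`, `chrom`, `bp`; `chrom`/`bp`
#'   are `NA` for names that do not follow the convention.
#' @export
parse_snp_name <- function(name) {
  stopifnot(is.character(name))
  m <- regmatches(name, regexec("^chr([0-9]+)_([0-9]+)_[0-9]+$", name))
  chrom <- vapply(m, function(x) if (length(x) == 3L) x[2] else NA_character_, "")
  bp <- vapply(m, function(x) if (length(x) == 3L) as.numeric(x[3]) else NA_real_, 0)
  data.frame(marker = name, chrom = chrom, bp = bp, stringsAsFactors = FALSE)
}

# Chromosome lengths (cM) used for the packaged default parental maps. The
# totals are 1575 cM for MA and 1430 cM for CS; lengths are even across the
# 19 grapevine chromosomes except where the emulated QTL architecture needs
# longer arms (CS chr7 and chr18 carry QTLs near 96-100 cM).
.default_chrom_lengths <- function(parent) {
  if (parent == "MA") {
    len <- c(rep(83, 17), 82, 82)  # 17*83 + 2*82 = 1575
  } else if (parent == "CS") {
    len <- rep(72, 19)
    len[c(7, 18)] <- 105
    short <- setdiff(seq_len(19), c(7, 18))
    len[short[1:4]] <- 71          # 13*72 + 4*71 + 2*105 = 1430
  } else {
    stop("unknown parent label: ", parent)
  }
  stats::setNames(len, as.character(seq_len(19)))
}

#' Default parental genetic maps
#'
#' Builds the packaged default maps for the two parents of the emulated
#' cross: Muscat of Alexandria (MA, 1575 cM) and Crimson Seedless (CS,
#' 1430 cM), 19 chromosomes each, markers every 1 cM (the density of the
#' real 20K-chip maps). Physical positions advance ~313 kb per cM, the
#' genome-wide average spacing, and marker names follow the
#' `chr{C}_{bp}_1` convention so physical coordinates can be recovered by
#' [parse_snp_name()].
#'
#' @param parent "MA" or "CS".
#' @param spacing_cm Marker spacing in cM (default 1).
#' @param kb_per_cm Physical-to-genetic scale in kb per cM (default 313).
#' @return A `genetic_map` data frame.
#' @export
default_parent_map <- function(parent = c("MA", "CS"), spacing_cm = 1,
                               kb_per_cm = 313) {
  parent <- match.arg(parent)
  lens <- .default_chrom_lengths(parent)
  pieces <- lapply(names(lens), function(chr) {
    cm <- seq(0, lens[[chr]], by = spacing_cm)
    bp <- round(1e5 + cm * kb_per_cm * 1e3)
    data.frame(
      marker = sprintf("chr%s_%d_1", chr, bp),
      chrom = chr, cm = cm, bp = bp, parent = parent,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, pieces)
  class(map) <- c("genetic_map", "data.frame")
  map
}
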