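# Shared data containers: genotype matrix, population map, trait table.

#' Construct a genotype matrix object
#'
#' The central substrate of all population-genetic computations: an
#' individuals x loci matrix of diploid alternate-allele dosages (0, 1, 2,
#' or `NA` for missing) plus per-locus metadata.
#'
#' @param dosage Integer matrix, individuals in rows, loci in columns; values
#'   in `{0, 1, 2, NA}`. Row names are taken as sample ids if `sample_ids` is
#'   not given.
#' @param locus_meta Data frame with one row per locus and columns `chrom`,
#'   `pos` (1-based), `id`, `ref`, `alt`. An optional logical column
#'   `multiallelic` flags records whose ALT held more than one allele.
#' @param sample_ids Character vector of individual labels, one per row.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, locus_meta, sample_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(sample_ids)) {
    stop_pstfst("sample ids are required (rownames or `sample_ids`)",
                "pstfst_invalid_input")
  }
  if (nrow(dosage) != length(sample_ids)) {
    stop_pstfst("dosage rows do not match sample ids", "pstfst_invalid_input")
  }
  if (ncol(dosage) != nrow(locus_meta)) {
    stop_pstfst("dosage columns do not match locus metadata",
                "pstfst_invalid_input")
  }
  needed <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(needed, names(locus_meta))
  if (length(missing_cols)) {
    stop_pstfst(paste0("locus_meta lacks columns: ",
                       paste(missing_cols, collapse = ", ")),
                "pstfst_invalid_input")
  }
  if (any(locus_meta$pos < 1)) {
    stop_pstfst("locus positions must be 1-based (>= 1)",
                "pstfst_invalid_input")
  }
  if (any(!is.na(dosage) & (dosage < 0L | dosage > 2L))) {
    stop_pstfst("dosages must be 0, 1, 2 or NA", "pstfst_invalid_input")
  }
  if (!"multiallelic" %in% names(locus_meta)) {
    locus_meta$multiallelic <- FALSE
  }
  same <- !is.na(locus_meta$ref) & !is.na(locus_meta$alt) &
    locus_meta$ref == locus_meta$alt
  if (any(same)) {
    stop_pstfst("ref and alt alleles must differ", "pstfst_invalid_input")
  }
  rownames(dosage) <- sample_ids
  colnames(dosage) <- locus_meta$id
  rownames(locus_meta) <- NULL
  structure(
    list(dosage = dosage, locus_meta = locus_meta,
         sample_ids = as.character(sample_ids)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf("<geno_matrix> %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage), 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

# subset a geno_matrix by locus index and/or individual index
subset_geno <- function(g, loci = NULL, individuals = NULL) {
  d <- g$dosage
  meta <- g$locus_meta
  if (!is.null(loci)) {
    d <- d[, loci, drop = FALSE]
    meta <- meta[loci, , drop = FALSE]
  }
  ids <- rownames(d)
  if (!is.null(individuals)) {
    keep <- if (is.character(individuals)) match(individuals, ids) else individuals
    d <- d[keep, , drop = FALSE]
    ids <- rownames(d)
  }
  geno_matrix(d, meta, ids)
}

#' Construct and validate a population map
#'
#' A three-level grouping shared by genotypes and traits: individuals belong
#' to populations, populations nest in regions, and regions belong to a range
#' (`"native"` or `"non-native"`). Nesting must be strict: a population maps
#' to exactly one region and a region to exactly one range.
#'
#' @param df Data frame with character columns `individual`, `population`,
#'   `region`, `range`.
#' @return A validated data frame of class `pop_map`.
#' @export
pop_map <- function(df) {
  needed <- c("individual", "population", "region", "range")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_pstfst(paste0("population map lacks columns: ",
                       paste(missing_cols, collapse = ", ")),
                "pstfst_invalid_input")
  }
  df <- as.data.frame(df)[needed]
  for (col in needed) df[[col]] <- as.character(df[[col]])
  dup <- duplicated(df$individual)
  if (any(dup)) {
    stop_pstfst(paste0("duplicated individuals in map: ",
                       paste(unique(df$individual[dup]), collapse = ", ")),
                "pstfst_map_error")
  }
  bad_pop <- tapply(df$region, df$population, function(r) length(unique(r)) > 1)
  if (any(bad_pop)) {
    stop_pstfst(paste0("populations assigned to more than one region: ",
                       paste(names(bad_pop)[bad_pop], collapse = ", ")),
                "pstfst_map_error")
  }
  bad_reg <- tapply(df$range, df$region, function(r) length(unique(r)) > 1)
  if (any(bad_reg)) {
    stop_pstfst(paste0("regions with mixed range labels: ",
                       paste(names(bad_reg)[bad_reg], collapse = ", ")),
                "pstfst_map_error")
  }
  rownames(df) <- NULL
  class(df) <- c("pop_map", "data.frame")
  df
}

# region (or population/range) label per individual, in the order of `ids`
map_level <- function(map, ids, level = c("region", "population", "range")) {
  level <- match.arg(level)
  idx <- match(ids, map$individual)
  if (anyNA(idx)) {
    stop_pstfst(paste0("individuals absent from the population map: ",
                       paste(ids[is.na(idx)][seq_len(min(5, sum(is.na(idx))))],
                             collapse = ", ")),
                "pstfst_map_error")
  }
  map[[level]][idx]
}

#' Construct and validate a trait table
#'
#' Long-format table of individual-level quantitative trait measurements.
#'
#' @param df Data frame with columns `individual`, `trait`, `value`.
#' @param map Optional [pop_map()]; when given, every individual must appear
#'   in it.
#' @return A validated data frame of class `trait_table`.
#' @export
trait_table <- function(df, map = NULL) {
  needed <- c("individual", "trait", "value")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_pstfst(paste0("trait table lacks columns: ",
                       paste(missing_cols, collapse = ", ")),
                "pstfst_invalid_input")
  }
  df <- as.data.frame(df)
  df$individual <- as.character(df$individual)
  df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value))) {
    stop_pstfst("trait values must be finite", "pstfst_invalid_input")
  }
  if (!is.null(map)) {
    absent <- setdiff(df$individual, map$individual)
    if (length(absent)) {
      stop_pstfst(paste0("trait individuals absent from the population map: ",
                         paste(utils::head(absent, 5), collapse = ", ")),
                  "pstfst_map_error")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("trait_table", "data.frame")
  df
}
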