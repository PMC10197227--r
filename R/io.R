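# Readers and writers for the package's three input formats: VCF genotypes,
# population map TSV, and long-format trait CSV.

#' Read a VCF file into a genotype matrix
#'
#' Parses the GT field of a VCFv4.x file (plain or bgzipped) into diploid
#' alternate-allele dosages. Phased separators (`|`) are treated as unphased;
#' any GT token containing `.` (including half-calls such as `./1`) is fully
#' missing. Records whose ALT column lists more than one allele are retained
#' but flagged `multiallelic` so the filter stage can remove them; allele
#' indices greater than 1 are treated as missing dosages.
#'
#' @param path Path to a VCF file.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) {
    stop_pstfst(paste0("VCF not found: ", path), "pstfst_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")   # loci x individuals, character
  if (is.null(gt)) {
    stop_pstfst("VCF has no GT genotype field", "pstfst_parse_error")
  }
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt) | nchar(ref) > 1 |
    (nchar(gsub(",", "", alt)) > (1 + nchar(gsub("[^,]", "", alt))))
  # dosage from GT tokens; table-driven for speed and strictness
  tok <- gsub("\\|", "/", as.vector(gt))
  dos <- rep(NA_integer_, length(tok))
  dos[tok %in% "0/0"] <- 0L
  dos[tok %in% c("0/1", "1/0")] <- 1L
  dos[tok %in% "1/1"] <- 2L
  dosage <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt))
  meta <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = fix[, "ID"],
    ref = ref,
    alt = alt,
    multiallelic = as.logical(multi),
    stringsAsFactors = FALSE
  )
  no_id <- is.na(meta$id) | meta$id == "."
  meta$id[no_id] <- paste0(meta$chrom[no_id], ":", meta$pos[no_id])
  geno_matrix(t(dosage), meta, colnames(gt))
}

# minimal VCFv4.2 writer (GT only); deterministic text output
write_vcf <- function(g, path) {
  d <- g$dosage
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  td <- t(d)
  gt[!is.na(td) & td == 0L] <- "0/0"
  gt[!is.na(td) & td == 1L] <- "0/1"
  gt[!is.na(td) & td == 2L] <- "1/1"
  meta <- g$locus_meta
  body <- paste(meta$chrom, meta$pos, meta$id, meta$ref, meta$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pstfst",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a population map TSV
#'
#' Expects a tab-separated file with header
#' `individual  population  region  range` and validates the nesting
#' (population within region within range) via [pop_map()].
#'
#' @param path Path to the TSV file.
#' @return A [pop_map()].
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) {
    stop_pstfst(paste0("population map not found: ", path), "pstfst_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  pop_map(df)
}

#' Read a long-format trait CSV
#'
#' Expects columns `individual,trait_name,value` (or `individual,trait,value`).
#'
#' @param path Path to the CSV file.
#' @param map Optional [pop_map()] used to validate individual ids.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, map = NULL) {
  if (!file.exists(path)) {
    stop_pstfst(paste0("trait table not found: ", path), "pstfst_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("trait_name" %in% names(df) && !"trait" %in% names(df)) {
    names(df)[names(df) == "trait_name"] <- "trait"
  }
  trait_table(df, map)
}

#' Write a simulated fixture set to disk
#'
#' Serializes a genotype matrix (VCF), population map (TSV), trait table
#' (CSV, long form with header `individual,trait_name,value`) and the
#' simulation truth record (JSON) into one directory, returning a manifest.
#' The files round-trip losslessly through [read_vcf()],
#' [read_population_map()] and [read_trait_table()].
#'
#' @param genotypes A [geno_matrix()].
#' @param map A [pop_map()] covering every genotyped individual.
#' @param traits A [trait_table()] (may have zero rows, in which case no CSV
#'   is written and a warning is raised).
#' @param truth Optional list of simulation truth values to store as JSON.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of written paths (the manifest).
#' @export
write_fixture_set <- function(genotypes, map, traits = NULL, truth = NULL,
                              out_dir) {
  absent <- setdiff(genotypes$sample_ids, map$individual)
  if (length(absent)) {
    stop_pstfst(paste0("genotyped individuals missing from map: ",
                       paste(utils::head(absent, 5), collapse = ", ")),
                "pstfst_integrity_error")
  }
  if (!is.null(traits) && nrow(traits) > 0) {
    absent_t <- setdiff(traits$individual, map$individual)
    if (length(absent_t)) {
      stop_pstfst(paste0("trait individuals missing from map: ",
                         paste(utils::head(absent_t, 5), collapse = ", ")),
                  "pstfst_integrity_error")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c()
  vcf_path <- file.path(out_dir, "genotypes.vcf")
  write_vcf(genotypes, vcf_path)
  manifest["vcf"] <- vcf_path

  map_path <- file.path(out_dir, "population_map.tsv")
  utils::write.table(as.data.frame(map), map_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest["map"] <- map_path

  if (!is.null(traits) && nrow(traits) > 0) {
    tr <- as.data.frame(traits)
    names(tr)[names(tr) == "trait"] <- "trait_name"
    traits_path <- file.path(out_dir, "traits.csv")
    utils::write.csv(tr, traits_path, row.names = FALSE, quote = FALSE)
    manifest["traits"] <- traits_path
  } else {
    warning("empty trait table: no traits.csv written")
  }
  if (!is.null(truth)) {
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest["truth"] <- truth_path
  }
  manifest
}
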