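# File formats: genotype tables and marker maps as TSV, killer-system
# configuration as JSON.

#' Genotype table
#'
#' A data frame with a `sample_id` column and one column of genotype codes
#' (`II`, `H`, `JJ`, or `NA`) per marker; optional `phenotype` and
#' `population` columns are carried through untouched.
#'
#' @param df A data frame to validate and classify.
#' @return The data frame with class `genotype_table`.
#' @export
genotype_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"sample_id" %in% names(df))
    stop("a genotype table needs a 'sample_id' column")
  markers <- setdiff(names(df), c("sample_id", "phenotype", "population"))
  if (!length(markers)) stop("a genotype table needs at least one marker column")
  if (!nrow(df)) stop("empty genotype table")
  for (m in markers) {
    bad <- !(df[[m]] %in% GENOTYPE_CODES | is.na(df[[m]]))
    if (any(bad))
      stop("unknown genotype code '", df[[m]][which(bad)[1]], "' in row ",
           which(bad)[1], ", column '", m, "'")
  }
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Markers of a genotype table
#' @param table A [genotype_table()].
#' @return Character vector of marker column names.
#' @export
markers <- function(table) {
  setdiff(names(table), c("sample_id", "phenotype", "population"))
}

#' Read / write a genotype table as TSV
#'
#' Tab-separated UTF-8 with a header row; missing genotypes written as the
#' literal string `NA`. `read_genotype_table()` validates codes and reports
#' the offending row and column on failure; the pair is a lossless
#' round-trip.
#'
#' @param path File path.
#' @param table A [genotype_table()].
#' @return `read_genotype_table()` returns a [genotype_table()];
#'   `write_genotype_table()` returns `path` invisibly.
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "NA",
                          check.names = FALSE, stringsAsFactors = FALSE)
  genotype_table(df)
}

#' @rdname read_genotype_table
#' @export
write_genotype_table <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a marker map as TSV
#'
#' Columns `marker`, `chrom`, `pos_bp`, optionally `cM`. Marker names must
#' be unique and positions positive integers.
#'
#' @param path File path.
#' @param map A data frame with the columns above.
#' @return `read_marker_map()` returns a data frame (a [genetic_map()] when
#'   a `cM` column is present).
#' @export
read_marker_map <- function(path) {
  m <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("marker", "chrom", "pos_bp")
  if (!all(need %in% names(m)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$marker)) stop("duplicated marker names in map")
  if (any(is.na(m$pos_bp)) || any(m$pos_bp <= 0) || any(m$pos_bp != round(m$pos_bp)))
    stop("pos_bp must be positive integers")
  m$pos_bp <- as.integer(m$pos_bp)
  if ("cM" %in% names(m))
    return(genetic_map(m$marker, m$chrom, m$cM, m$pos_bp))
  m
}

#' @rdname read_marker_map
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Load killer-system definitions from a JSON configuration file
#'
#' The file declares `loci` (name, chrom, pos_bp, role) and `systems`
#' (killer, partner, partner_mode, targeted_allele, survival_s, optional
#' collateral_c) referencing loci by name. A bundled example describing the
#' two-pathway activator/suppressor network ships as
#' `system.file("extdata", "efs_s24_ink_s35.json", package = "pollenkiller")`.
#'
#' @param path Path to the JSON file.
#' @param quiet Suppress the per-system derived-k message.
#' @return List of [killer_system()] objects, named by killer locus.
#' @examples
#' cfg <- system.file("extdata", "efs_s24_ink_s35.json", package = "pollenkiller")
#' load_systems_config(cfg, quiet = TRUE)
#' @export
load_systems_config <- function(path, quiet = FALSE) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$loci) || !length(cfg$loci)) stop("config has no 'loci'")
  if (is.null(cfg$systems) || !length(cfg$systems)) stop("config has no 'systems'")
  loci <- list()
  for (l in cfg$loci) {
    for (f in c("name", "chrom", "pos_bp", "role"))
      if (is.null(l[[f]])) stop("locus entry missing field '", f, "'")
    loci[[l$name]] <- locus(l$name, l$chrom, l$pos_bp, l$role)
  }
  systems <- list()
  for (s in cfg$systems) {
    for (f in c("killer", "partner", "partner_mode", "targeted_allele", "survival_s"))
      if (is.null(s[[f]])) stop("system entry missing field '", f, "'")
    if (is.null(loci[[s$killer]])) stop("system references unknown locus '", s$killer, "'")
    if (is.null(loci[[s$partner]])) stop("system references unknown locus '", s$partner, "'")
    ks <- killer_system(
      killer = loci[[s$killer]], partner = loci[[s$partner]],
      partner_mode = s$partner_mode, targeted_allele = s$targeted_allele,
      survival_s = s$survival_s,
      collateral_c = if (is.null(s$collateral_c)) 0 else s$collateral_c
    )
    if (!quiet)
      message(sprintf("system %s/%s: s = %.4f -> k = %.4f",
                      ks$killer$name, ks$partner$name, ks$survival_s, ks$k))
    systems[[ks$killer$name]] <- ks
  }
  systems
}
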