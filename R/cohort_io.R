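#' Read a participant phenotype table
#'
#' Reads the per-participant clinical record: study group (healthy control
#' `HC` or `IBS`), IBS bowel-habit subtype (`C`onstipation, `D`iarrhea,
#' `M`ixed, or `NONE` for controls), the induced visceral pain score (IVP,
#' Gastrointestinal Pain Pointer units on a 0--100 scale), and demographics.
#'
#' The file is tab-separated UTF-8 with header columns `participant_id`,
#' `group`, `subtype`, `ivp_score`, `sex`, `age`, `race`. Gzip-compressed
#' files are read transparently.
#'
#' @param path Path to a TSV (optionally `.gz`) phenotype file.
#' @return A tibble with one validated row per participant.
#' @examples
#' p <- read_phenotype_table(painlink_example("phenotype_cohort36.tsv"))
#' dplyr::count(p, group)
#' @export
read_phenotype_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("participant_id", "group", "subtype", "ivp_score", "sex", "age", "race")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("phenotype file is missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "painlink_format_error")
  }
  df <- df[required]
  if (nrow(df) == 0) {
    warn("phenotype file contains a header but no records.")
    return(tibble(participant_id = character(), group = character(),
                  subtype = character(), ivp_score = double(),
                  sex = character(), age = double(), race = character()))
  }
  df$ivp_score <- suppressWarnings(as.numeric(df$ivp_score))
  df$age <- suppressWarnings(as.numeric(df$age))
  bad_ivp <- which(is.na(df$ivp_score) | df$ivp_score < 0 | df$ivp_score > 100)
  if (length(bad_ivp) > 0) {
    abort(sprintf("ivp_score outside [0, 100] (or non-numeric) at row(s): %s",
                  paste(bad_ivp, collapse = ", ")),
          class = "painlink_validation_error")
  }
  if (anyDuplicated(df$participant_id)) {
    abort("duplicate participant_id in phenotype table.",
          class = "painlink_validation_error")
  }
  bad_group <- which(!df$group %in% c("HC", "IBS"))
  if (length(bad_group) > 0) {
    abort(sprintf("group must be HC or IBS; offending row(s): %s",
                  paste(bad_group, collapse = ", ")),
          class = "painlink_validation_error")
  }
  bad_sub <- which(!df$subtype %in% c("C", "D", "M", "NONE"))
  if (length(bad_sub) > 0) {
    abort(sprintf("subtype must be one of C, D, M, NONE; offending row(s): %s",
                  paste(bad_sub, collapse = ", ")),
          class = "painlink_validation_error")
  }
  mism <- which((df$group == "HC") != (df$subtype == "NONE"))
  if (length(mism) > 0) {
    abort(sprintf("subtype must be NONE exactly for HC participants; row(s): %s",
                  paste(mism, collapse = ", ")),
          class = "painlink_validation_error")
  }
  bad_age <- which(is.na(df$age) | df$age <= 0)
  if (length(bad_age) > 0) {
    abort(sprintf("age must be a positive number; offending row(s): %s",
                  paste(bad_age, collapse = ", ")),
          class = "painlink_validation_error")
  }
  as_tibble(df)
}

#' Write a phenotype table
#'
#' @param phenotypes Tibble as returned by [read_phenotype_table()].
#' @param path Output TSV path (`.gz` allowed).
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path, progress = FALSE)
  invisible(path)
}

# Shared feature-matrix reader: first column = feature id, remaining columns =
# per-sample numeric values. Errors carry the (row, column) of the first
# offending cell so malformed exports are locatable.
read_feature_matrix <- function(path, what) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2) {
    abort(sprintf("%s file needs a feature-id column plus at least one sample column.", what),
          class = "painlink_format_error")
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate feature id(s) in %s table: %s", what,
                  paste(head(dup, 5), collapse = ", ")),
          class = "painlink_validation_error")
  }
  vals <- as.matrix(df[-1])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | vals %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric cell in %s table at row %d, column '%s' (value '%s')",
                  what, bad[1, 1], colnames(vals)[bad[1, 2]], vals[bad[1, 1], bad[1, 2]]),
          class = "painlink_format_error")
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Read an OTU abundance matrix
#'
#' Reads an OTU-by-sample table of nonnegative hybridization-intensity-like
#' abundance values (rows = OTUs, columns = samples; first column holds OTU
#' ids). Negative values are rejected.
#'
#' @param path Path to a TSV (optionally `.gz`) abundance file.
#' @return A numeric matrix with OTU rownames and sample colnames.
#' @export
read_abundance_table <- function(path) {
  m <- read_feature_matrix(path, "abundance")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("negative abundance at row '%s', sample '%s'",
                  rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]),
          class = "painlink_validation_error")
  }
  m
}

#' Read a gene/probe expression matrix
#'
#' @param path Path to a TSV (optionally `.gz`) expression file.
#' @param stage Processing stage of the stored values; one of `"raw"`,
#'   `"global_normalized"`, `"log_scaled"`, `"gene_summarized"`.
#' @return A numeric matrix (features x samples) carrying a `stage` attribute.
#' @seealso [global_mean_normalize()], [log_scale_to_target()],
#'   [summarize_probes_to_genes()]
#' @export
read_expression_table <- function(path, stage = "raw") {
  stage <- match.arg(stage, expression_stages())
  m <- read_feature_matrix(path, "expression")
  attr(m, "stage") <- stage
  m
}

#' Read an OTU taxonomy table
#'
#' Columns: `otu_id`, `phylum`, `family`, `genus`, `species`. The sentinel
#' `"unclassified"` is allowed at any rank (and is common: many array OTUs are
#' undescribed below the family level).
#'
#' @param path Path to a TSV (optionally `.gz`) taxonomy file.
#' @return A tibble with one row per OTU.
#' @export
read_taxonomy_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("otu_id", "phylum", "family", "genus", "species")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("taxonomy file is missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "painlink_format_error")
  }
  df <- df[required]
  if (anyDuplicated(df$otu_id)) {
    abort("duplicate otu_id in taxonomy table.", class = "painlink_validation_error")
  }
  as_tibble(df)
}

#' Write a feature-by-sample matrix as TSV
#'
#' Values are written at full double precision so a write/read round trip
#' reproduces the matrix exactly.
#'
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @param path Output TSV path (`.gz` allowed).
#' @param id_column Name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path, id_column = "feature_id") {
  assert_feature_matrix(m, "m")
  df <- as_tibble(m, rownames = id_column)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a taxonomy table
#' @param taxonomy Tibble as returned by [read_taxonomy_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_table <- function(taxonomy, path) {
  readr::write_tsv(taxonomy, path, progress = FALSE)
  invisible(path)
}

#' Bundle the four cohort tables
#'
#' @param phenotype Phenotype tibble.
#' @param abundance OTU abundance matrix (OTUs x samples).
#' @param taxonomy Taxonomy tibble.
#' @param expression Expression matrix (features x samples).
#' @return A `cohort_bundle` list.
#' @export
cohort_bundle <- function(phenotype, abundance, taxonomy, expression) {
  assert_feature_matrix(abundance, "abundance")
  assert_feature_matrix(expression, "expression")
  structure(list(phenotype = phenotype, abundance = abundance,
                 taxonomy = taxonomy, expression = expression),
            class = "cohort_bundle")
}

#' Cross-validate a cohort bundle
#'
#' Computes the analysis sample set (the intersection of the phenotype
#' participant ids with the abundance and expression sample columns), lists
#' phenotyped participants missing from either omics table (these are dropped
#' from correlation stages but kept for phenotype-only statistics), and lists
#' OTUs without a taxonomy record.
#'
#' @param bundle A [cohort_bundle()].
#' @return A `bundle_validation` list with elements `analysis_samples`,
#'   `dropped_from_abundance`, `dropped_from_expression`,
#'   `unphenotyped_samples`, `otus_without_taxonomy`, and `counts`.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  pid <- bundle$phenotype$participant_id
  ab <- colnames(bundle$abundance)
  ex <- colnames(bundle$expression)
  analysis <- sort(intersect(pid, intersect(ab, ex)))
  if (length(analysis) == 0) {
    abort("no sample is shared by the phenotype, abundance, and expression tables.",
          class = "painlink_validation_error")
  }
  report <- list(
    analysis_samples = analysis,
    dropped_from_abundance = sort(setdiff(pid, ab)),
    dropped_from_expression = sort(setdiff(pid, ex)),
    unphenotyped_samples = sort(setdiff(union(ab, ex), pid)),
    otus_without_taxonomy = sort(setdiff(rownames(bundle$abundance),
                                         bundle$taxonomy$otu_id)),
    counts = list(n_phenotyped = length(pid),
                  n_analysis = length(analysis),
                  n_otus = nrow(bundle$abundance),
                  n_expression_features = nrow(bundle$expression))
  )
  structure(report, class = "bundle_validation")
}

#' @export
print.bundle_validation <- function(x, ...) {
  cat("Cohort bundle validation\n")
  cat(sprintf("  phenotyped participants: %d\n", x$counts$n_phenotyped))
  cat(sprintf("  analysis sample set:     %d\n", x$counts$n_analysis))
  cat(sprintf("  dropped (no abundance):  %d\n", length(x$dropped_from_abundance)))
  cat(sprintf("  dropped (no expression): %d\n", length(x$dropped_from_expression)))
  cat(sprintf("  OTUs without taxonomy:   %d\n", length(x$otus_without_taxonomy)))
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report A `bundle_validation` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Path to a packaged example file
#' @param file File name under the package's `extdata` directory; `NULL` lists
#'   the available files.
#' @return A file path (or a character vector of file names).
#' @export
painlink_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "painlink"))
  } else {
    system.file("extdata", file, package = "painlink", mustWork = TRUE)
  }
}
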