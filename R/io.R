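#' Read one site's cohort from a delimited text file
#'
#' Expects a comma- or tab-separated file with a header row: feature columns
#' plus one binary label column. The separator is taken from the file
#' extension (`.tsv`/`.txt` = tab, otherwise comma). Feature kinds are
#' inferred: a column whose values all lie in \{0, 1\} is binary, anything
#' else continuous. Row order is preserved.
#'
#' @param path file path.
#' @param label_column name of the 0/1 label column (default `"label"`).
#' @param site_id site label; defaults to the file name without extension.
#' @param impute `"none"` (default) rejects files with missing cells;
#'   `"mode-mean"` fills binary features with their mode and continuous
#'   features with their mean (missing labels are always an error).
#' @return a [site_cohort()].
#' @export
read_site_table <- function(path, label_column = "label", site_id = NULL,
                            impute = c("none", "mode-mean")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in ", path)
  }
  labels <- df[[label_column]]
  if (anyNA(labels)) stop("missing values in label column")
  if (!is.numeric(labels) || !all(labels %in% c(0, 1))) {
    stop("label column must contain only 0 and 1")
  }
  features <- df[, setdiff(names(df), label_column), drop = FALSE]
  if (anyNA(features)) {
    if (impute == "none") {
      stop("missing feature values in ", path,
           " (use impute = \"mode-mean\" to fill them)")
    }
    for (j in seq_along(features)) {
      col <- features[[j]]
      if (!anyNA(col)) next
      obs <- col[!is.na(col)]
      if (length(obs) == 0L) stop("feature column ", names(features)[j],
                                  " is entirely missing")
      fill <- if (all(obs %in% c(0, 1))) {
        as.numeric(names(which.max(table(obs))))
      } else {
        mean(obs)
      }
      col[is.na(col)] <- fill
      features[[j]] <- col
    }
  }
  site_id <- site_id %||% sub("\\.[^.]*$", "", basename(path))
  site_cohort(site_id, features, labels)
}

#' Write one site's cohort to a delimited text file
#'
#' The inverse of [read_site_table()]: features plus a `label` column, with a
#' header row and no row names. Comma-separated unless the path ends in
#' `.tsv`/`.txt`.
#'
#' @param cohort a [site_cohort()].
#' @param path output file path.
#' @param label_column name for the label column (default `"label"`).
#' @return `path`, invisibly.
#' @export
write_site_table <- function(cohort, path, label_column = "label") {
  stopifnot(inherits(cohort, "site_cohort"))
  if (label_column %in% names(cohort$features)) {
    stop("a feature is already named '", label_column, "'")
  }
  df <- cohort$features
  df[[label_column]] <- cohort$labels
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a federated cohort to a directory of site tables
#'
#' One delimited file per site plus a `manifest.json` recording the schema,
#' per-site class counts and (when known) the generator seed.
#'
#' @param cohort a [federated_cohort()].
#' @param dir output directory (created if absent).
#' @param seed optional integer recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_federated_cohort <- function(cohort, dir, seed = NULL) {
  stopifnot(inherits(cohort, "federated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (s in cohort$sites) {
    f <- file.path(dir, paste0(s$site_id, ".csv"))
    write_site_table(s, f)
    files <- c(files, basename(f))
  }
  counts <- cohort_class_counts(cohort)
  manifest <- list(
    schema = list(names = cohort$schema$names, kinds = cohort$schema$kinds),
    seed = seed,
    sites = lapply(counts, function(cc) {
      list(site_id = cc$site_id, file = paste0(cc$site_id, ".csv"),
           n = cc$n, positives = cc$positives, negatives = cc$negatives)
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
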