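#' Study-set containers and input/output
#'
#' A `study_set` is a data frame of diagnostic 2x2 tables, one trial per
#' row, with columns `study_id`, `article_id`, `year`, `country`,
#' `ethnicity_group`, `cancer_label`, `cancer_group`, `pancreatic`,
#' `sample_source`, `sample_group`, `tp`, `fn`, `fp`, `tn`, `sample_size`.
#' Only `study_id` and the four counts are mandatory on input; missing
#' metadata columns are defaulted. Counts follow the usual convention:
#' `tp`/`fn` partition the diseased arm, `fp`/`tn` the non-diseased arm.
#'
#' @name study_set
NULL

.META_DEFAULTS <- list(
  article_id = NA_character_, year = NA_integer_, country = "unknown",
  ethnicity_group = "unknown", cancer_label = "unknown",
  cancer_group = "unknown", pancreatic = NA, sample_source = "unknown",
  sample_group = "unknown", sample_size = NA_integer_
)
.COUNT_COLS <- c("tp", "fn", "fp", "tn")

#' Construct and validate a study set
#'
#' @param studies data frame with at least `study_id`, `tp`, `fn`, `fp`,
#'   `tn`. Extra columns are kept.
#' @param provenance free-text description of where the rows came from.
#' @return A `study_set` (data frame subclass) with defaulted metadata
#'   columns and a `provenance` attribute.
#' @export
study_set <- function(studies, provenance = "constructed in R") {
  stopifnot(is.data.frame(studies))
  df <- as.data.frame(studies, stringsAsFactors = FALSE)
  miss <- setdiff(c("study_id", .COUNT_COLS), names(df))
  if (length(miss) > 0L) {
    stop("study table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("study set must contain at least one trial", call. = FALSE)
  for (nm in names(.META_DEFAULTS)) {
    if (is.null(df[[nm]])) df[[nm]] <- .META_DEFAULTS[[nm]]
  }
  if (all(is.na(df$article_id))) df$article_id <- df$study_id
  for (cc in .COUNT_COLS) {
    x <- df[[cc]]
    if (is.character(x)) {
      xn <- suppressWarnings(as.numeric(x))
      if (anyNA(xn)) {
        bad <- df$study_id[is.na(xn)][1L]
        stop("non-numeric ", cc, " in row '", bad, "'", call. = FALSE)
      }
      x <- xn
    }
    if (anyNA(x)) stop("missing ", cc, " in row '", df$study_id[is.na(x)][1L], "'", call. = FALSE)
    if (any(x < 0)) stop("negative ", cc, " in row '", df$study_id[x < 0][1L], "'", call. = FALSE)
    if (any(x != round(x))) {
      stop("non-integer ", cc, " in row '", df$study_id[x != round(x)][1L], "'", call. = FALSE)
    }
    df[[cc]] <- as.integer(round(x))
  }
  dup <- df$study_id[duplicated(df$study_id)]
  if (length(dup) > 0L) {
    stop("duplicate study_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  n1 <- df$tp + df$fn
  n2 <- df$fp + df$tn
  if (any(n1 < 1L)) {
    stop("no diseased arm (tp + fn == 0) in row '", df$study_id[n1 < 1L][1L], "'", call. = FALSE)
  }
  if (any(n2 < 1L)) {
    stop("no non-diseased arm (fp + tn == 0) in row '", df$study_id[n2 < 1L][1L], "'", call. = FALSE)
  }
  ok <- is.na(df$sample_size) | (n1 + n2 == df$sample_size)
  if (!all(ok)) {
    stop("tp + fn + fp + tn != sample_size in row '", df$study_id[!ok][1L], "'", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("study_set", "data.frame"), provenance = provenance)
}

#' @export
print.study_set <- function(x, ...) {
  cat("Study set:", nrow(x), "trial(s) from",
      length(unique(x$article_id)), "article(s)\n")
  cat("Provenance:", attr(x, "provenance"), "\n")
  print(as.data.frame(x)[, intersect(
    c("study_id", "year", "cancer_label", "sample_group", .COUNT_COLS), names(x))], ...)
  invisible(x)
}

#' Subset a study set, keeping class and provenance
#' @param x a `study_set`
#' @param ... passed to the data frame method
#' @export
`[.study_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("study_id", .COUNT_COLS) %in% names(out)) &&
      nrow(out) > 0L) {
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- c("study_set", "data.frame")
  }
  out
}

#' Read a study table from a delimited text file
#'
#' The delimiter is auto-detected between comma and tab (comma canonical);
#' pass `dialect` to force one. The file must carry a header row naming at
#' least `study_id`, `tp`, `fn`, `fp`, `tn`.
#'
#' @param path path to a CSV/TSV file.
#' @param dialect `"auto"`, `"comma"` or `"tab"`.
#' @return a validated [study_set].
#' @export
read_studies <- function(path, dialect = c("auto", "comma", "tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE, encoding = "UTF-8")
    dialect <- if (lengths(regmatches(first, gregexpr("\t", first))) >
                   lengths(regmatches(first, gregexpr(",", first)))) "tab" else "comma"
  }
  sep <- if (dialect == "tab") "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = TRUE, fileEncoding = "UTF-8")
  study_set(df, provenance = path)
}

#' Load a packaged study set
#'
#' `"liu2021_mir21"` is the packaged 30-trial exosomal miR-21 set
#' (26 articles, 2008-2020); see
#' `system.file("extdata", "liu2021_mir21_README.md", package = "dtapool")`
#' for column provenance and the derived subgroup labels.
#'
#' @param name fixture identifier.
#' @return a [study_set].
#' @export
load_fixture <- function(name = "liu2021_mir21") {
  path <- system.file("extdata", paste0(name, ".csv"), package = "dtapool")
  if (!nzchar(path)) {
    known <- sub("\\.csv$", "",
                 dir(system.file("extdata", package = "dtapool"), pattern = "\\.csv$"))
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  out <- read_studies(path)
  attr(out, "provenance") <- paste0("fixture:", name)
  out
}

#' Write analysis results to disk
#'
#' JSON output is lossless (full float precision) and round-trips
#' bit-identically through [jsonlite::read_json()]; CSV is provided for
#' tabular results.
#'
#' @param results a data frame, list, or any of the package's result
#'   objects.
#' @param path output file path (parent directory must exist).
#' @param format `"json"` or `"csv"`.
#' @export
write_results <- function(results, path, format = c("json", "csv")) {
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("json", "csv")) {
    stop("format must be \"json\" or \"csv\"", call. = FALSE)
  }
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  if (format == "csv") {
    df <- as.data.frame(results)
    write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(.jsonable(results), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(path)
}

## strip attributes/classes that do not serialize meaningfully
.jsonable <- function(x) {
  if (is.matrix(x)) return(unclass(x))
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, .jsonable))
  }
  x
}
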