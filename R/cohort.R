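#' Cohort table for a two-arm randomized trial
#'
#' A `cohort_table` holds one row per subject: an opaque `subject_id`, a unique
#' positive `registration_order`, the randomized `arm` (`"treatment"` or
#' `"control"`), the binary 1-year `success` indicator (1 = no recurrence
#' within follow-up), the `event_time` in months on (0, horizon], the binary
#' `event_indicator` (1 = recurrence observed at `event_time`), and the
#' baseline covariates declared in `schema`. Success and the event indicator
#' encode the same endpoint, so `success == 1 - event_indicator` is enforced.
#'
#' @param data A data.frame with the mandatory columns above plus one column
#'   per schema feature. If `success` is absent it is derived as
#'   `1 - event_indicator`.
#' @param schema Named character vector mapping each covariate name to
#'   `"continuous"` or `"categorical"`.
#' @param horizon Follow-up horizon in months (default 12).
#' @return An object of class `cohort_table`: a list with elements `data`
#'   (rows ordered by `registration_order`) and `schema`.
#' @export
cohort_table <- function(data, schema, horizon = 12) {
  stopifnot(is.data.frame(data))
  if (length(schema) == 0 || is.null(names(schema)) || any(names(schema) == ""))
    stop("schema must be a named character vector", call. = FALSE)
  if (!all(schema %in% c("continuous", "categorical")))
    stop("schema values must be 'continuous' or 'categorical'", call. = FALSE)

  mandatory <- c("subject_id", "registration_order", "arm", "event_time",
                 "event_indicator")
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols) > 0)
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  missing_feat <- setdiff(names(schema), names(data))
  if (length(missing_feat) > 0)
    stop("schema error: declared feature(s) absent from data: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)

  data$subject_id <- as.character(data$subject_id)
  data$registration_order <- as.integer(data$registration_order)
  if (anyNA(data$registration_order) || any(data$registration_order <= 0))
    stop("validation error: registration_order must be positive integers",
         call. = FALSE)
  if (anyDuplicated(data$registration_order))
    stop("validation error: duplicate registration_order", call. = FALSE)

  if (!all(data$arm %in% c("treatment", "control")))
    stop("validation error: arm must be 'treatment' or 'control'",
         call. = FALSE)
  data$arm <- as.character(data$arm)

  if (!all(data$event_indicator %in% c(0, 1)))
    stop("validation error: event_indicator must be 0/1", call. = FALSE)
  data$event_indicator <- as.integer(data$event_indicator)

  if (any(is.na(data$event_time)) || any(data$event_time <= 0))
    stop("validation error: event_time must be positive", call. = FALSE)
  if (any(data$event_time > horizon))
    stop("validation error: event_time exceeds the follow-up horizon (",
         horizon, " months)", call. = FALSE)

  if (!"success" %in% names(data)) {
    data$success <- 1L - data$event_indicator
  } else {
    data$success <- as.integer(data$success)
    if (!all(data$success %in% c(0, 1)))
      stop("validation error: success must be 0/1", call. = FALSE)
    if (any(data$success != 1L - data$event_indicator))
      stop("validation error: success must equal 1 - event_indicator",
           call. = FALSE)
  }

  for (f in names(schema)) {
    if (schema[[f]] == "continuous") {
      data[[f]] <- as.numeric(data[[f]])
    } else {
      v <- as.character(data[[f]])
      v[!is.na(v) & v == ""] <- NA_character_
      data[[f]] <- v
    }
  }

  data <- data[order(data$registration_order),
               c(mandatory[1:3], "success", mandatory[4:5], names(schema))]
  rownames(data) <- NULL
  structure(list(data = data, schema = schema, horizon = horizon),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$data), "subjects,",
      length(x$schema), "covariates\n")
  cat("  arms:", sum(x$data$arm == "treatment"), "treatment /",
      sum(x$data$arm == "control"), "control\n")
  cat("  events:", sum(x$data$event_indicator), "within",
      x$horizon, "months\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `cohort_table`.
#' @return Integer count.
#' @export
n_subjects <- function(cohort) nrow(cohort$data)

#' Covariate columns of a cohort
#' @param cohort A `cohort_table`.
#' @return data.frame of the schema-declared covariates, in schema order.
#' @export
covariate_data <- function(cohort) cohort$data[names(cohort$schema)]

#' Read a cohort CSV with its JSON schema sidecar
#'
#' The file dialect is comma-separated UTF-8 with a mandatory header row;
#' empty cells denote missing values and are preserved as `NA`, never imputed
#' at load time. The schema may be given directly or read from
#' `<path>.schema.json` (written by [write_cohort()]).
#'
#' @param path Path to the cohort CSV.
#' @param schema Named character vector of feature types, or `NULL` to read
#'   the sidecar.
#' @return A [cohort_table()].
#' @export
load_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(schema)) {
    sidecar <- paste0(path, ".schema.json")
    if (!file.exists(sidecar))
      stop("no schema supplied and sidecar not found: ", sidecar,
           call. = FALSE)
    schema <- unlist(jsonlite::read_json(sidecar))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        check.names = FALSE, fileEncoding = "UTF-8")
  cohort_table(df, schema)
}

#' Write a cohort CSV plus schema sidecar and provenance record
#'
#' Missing values are written as empty cells so that load -> write -> load is
#' an identity on values and missingness pattern. A `<path>.schema.json`
#' sidecar declares feature types and a `<path>.provenance.json` records the
#' subject count and arm sizes.
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(cohort$data, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  jsonlite::write_json(as.list(cohort$schema), paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  prov <- list(n = n_subjects(cohort),
               n_treatment = sum(cohort$data$arm == "treatment"),
               n_control = sum(cohort$data$arm == "control"),
               features = length(cohort$schema))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Split a cohort by registration order
#'
#' Deterministic partition used for train/validation/test separation: the
#' first part takes the `sizes[1]` earliest-registered subjects, the second
#' the remainder. Randomization imbalance between arms within each part is
#' deliberate — the split ignores arm, exactly as an enrollment-order split
#' of a real trial would.
#'
#' @param cohort A `cohort_table`.
#' @param sizes Integer pair summing to the cohort size. Default
#'   `(ceiling(n/2), floor(n/2))`.
#' @return List of two `cohort_table`s, `first` and `second`.
#' @export
split_by_registration_order <- function(cohort, sizes = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- n_subjects(cohort)
  if (is.null(sizes)) sizes <- c(ceiling(n / 2), floor(n / 2))
  sizes <- as.integer(sizes)
  if (length(sizes) != 2 || any(sizes < 0) || sum(sizes) != n)
    stop("sizes must be two non-negative integers summing to the cohort size (",
         n, ")", call. = FALSE)
  first <- cohort$data[seq_len(sizes[1]), , drop = FALSE]
  second <- cohort$data[setdiff(seq_len(n), seq_len(sizes[1])), , drop = FALSE]
  list(first = cohort_table(first, cohort$schema, cohort$horizon),
       second = cohort_table(second, cohort$schema, cohort$horizon))
}
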