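#' Assemble a binary response-pattern dataset
#'
#' Validates and tags a subjects-by-trials table of binary causal-inference
#' successes so that downstream fitting functions know which columns are
#' trial indicators. One row per child; each trial column holds 1 when the
#' child made the intended causal inference on that trial and 0 otherwise.
#'
#' Children with a missing value on any trial column are excluded listwise,
#' mirroring the usual treatment of incomplete test-trial records.
#'
#' @param data A data frame with columns `subject_id`, `age_months`,
#'   optionally `age_group` (years, one of 2, 3, 4, 5), and one 0/1 column
#'   per test trial.
#' @param trials Character vector naming the trial columns. Defaults to every
#'   column other than `subject_id`, `age_months`, `age_group` and columns
#'   whose name starts with a dot (sidecar columns such as simulation truth
#'   labels).
#' @return A tibble of class `response_data` with the trial columns recorded
#'   in `attr(, "trials")`.
#' @examples
#' df <- tibble::tibble(
#'   subject_id = c("a", "b"), age_months = c(30, 65),
#'   trial1 = c(1, 0), trial2 = c(0, 1)
#' )
#' response_data(df)
#' @export
response_data <- function(data, trials = NULL) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (!all(c("subject_id", "age_months") %in% names(data))) {
    abort("`data` must have `subject_id` and `age_months` columns.")
  }
  reserved <- c("subject_id", "age_months", "age_group")
  if (is.null(trials)) {
    trials <- setdiff(names(data), reserved)
    trials <- trials[!startsWith(trials, ".")]
  }
  if (length(trials) < 1L) abort("At least one trial column is required.")
  missing_cols <- setdiff(trials, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Trial columns not found: ", paste(missing_cols, collapse = ", ")))
  }

  resp <- as.matrix(data[trials])
  incomplete <- rowSums(is.na(resp)) > 0L
  if (any(incomplete)) {
    inform(paste0(
      sum(incomplete), " subject(s) excluded listwise for missing trial responses."
    ))
    data <- data[!incomplete, , drop = FALSE]
    resp <- resp[!incomplete, , drop = FALSE]
  }
  if (nrow(data) < 1L) abort("No complete subjects remain.")
  if (!all(resp %in% c(0, 1))) {
    abort("Trial columns must contain only 0/1 values.")
  }
  if (anyNA(data$age_months) || any(data$age_months <= 0)) {
    abort("`age_months` must be strictly positive and non-missing.")
  }
  if ("age_group" %in% names(data)) {
    if (length(data$age_group) != nrow(data) ||
        !all(data$age_group %in% c(2, 3, 4, 5))) {
      abort("`age_group` must be one of 2, 3, 4, 5 (years) for every subject.")
    }
  }
  structure(data, trials = trials,
            class = c("response_data", class(tibble::tibble())))
}

#' @export
print.response_data <- function(x, ...) {
  cat("<response_data> ", nrow(x), " subjects x ", length(attr(x, "trials")),
      " trials (", paste(attr(x, "trials"), collapse = ", "), ")\n", sep = "")
  NextMethod()
}

#' Extract the binary response matrix of a response dataset
#'
#' @param data A [response_data] object.
#' @return An n-by-J numeric 0/1 matrix with trial names as columns.
#' @export
response_matrix <- function(data) {
  stopifnot(inherits(data, "response_data"))
  m <- as.matrix(as.data.frame(data)[attr(data, "trials")])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}

response_trials <- function(data) attr(data, "trials")

#' Read a response dataset from CSV
#'
#' Expects the header `subject_id,age_months,age_group,trial1,...` (the
#' `age_group` column is optional, trial columns are whatever remains).
#'
#' @param path Path to a UTF-8, comma-separated file.
#' @inheritParams response_data
#' @return A [response_data] tibble.
#' @export
read_response_csv <- function(path, trials = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  response_data(raw, trials = trials)
}

#' Write a response dataset to CSV
#'
#' Writes the standard `subject_id,age_months,age_group,trial...` table. When
#' the dataset was produced by [simulate_lcm_data()] and carries simulation
#' truth, a sidecar `<stem>.truth.csv` with the true class labels and a
#' `<stem>.config.json` echo of the generating configuration are written next
#' to it.
#'
#' @param data A [response_data] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(data, path) {
  stopifnot(inherits(data, "response_data"))
  keep <- intersect(c("subject_id", "age_months", "age_group",
                      response_trials(data)), names(data))
  readr::write_csv(as.data.frame(data)[keep], path)
  if (".true_class" %in% names(data)) {
    stem <- sub("\\.csv$", "", path)
    readr::write_csv(
      data.frame(subject_id = data$subject_id, true_class = data$.true_class),
      paste0(stem, ".truth.csv")
    )
    cfg <- attr(data, "generator_config")
    if (!is.null(cfg)) {
      jsonlite::write_json(unclass(cfg), paste0(stem, ".config.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  invisible(path)
}
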