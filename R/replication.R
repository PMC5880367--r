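#' Default trial scoring scheme
#'
#' Maps raw response codes to binary success on the five blicket-detector
#' test trials. Success means making the intended causal inference:
#' \itemize{
#'   \item screening-off: placing the causally efficacious object X alone;
#'   \item indirect screening-off A: placing object Z alone;
#'   \item indirect screening-off B: labeling object Y a blicket;
#'   \item backwards blocking: not labeling object Y a blicket;
#'   \item non-causal association: using a finger press.
#' }
#' All other scorable codes count as failure; `no_response` / `unscorable`
#' are unscorable and trigger listwise exclusion of the child.
#'
#' By default the two labeling trials score only the target object Y. With
#' `strict_b = TRUE` the indirect-screening-off-B trial additionally
#' requires that object X was not labeled a blicket (compound codes
#' `Y_blicket_X_blicket` / `Y_blicket_X_not_blicket`).
#'
#' @param strict_b Require a correct X label on the B trial (off by default).
#' @return A tibble with columns `trial`, `code`, `outcome` (one of
#'   `success`, `failure`, `unscorable`).
#' @export
scoring_scheme <- function(strict_b = FALSE) {
  rows <- list(
    screening_off = list(
      success = "X_alone",
      failure = c("Y_alone", "both", "other")
    ),
    indirect_screening_off_a = list(
      success = "Z_alone",
      failure = c("X_alone", "Y_alone", "XZ", "YZ", "XY", "XYZ", "other")
    ),
    indirect_screening_off_b = list(
      success = c("Y_blicket",
                  if (!strict_b) "Y_blicket_X_blicket",
                  "Y_blicket_X_not_blicket"),
      failure = c("Y_not_blicket",
                  if (strict_b) "Y_blicket_X_blicket",
                  "other")
    ),
    backwards_blocking = list(
      success = c("Y_not_blicket"),
      failure = c("Y_blicket", "other")
    ),
    non_causal_association = list(
      success = "finger_press",
      failure = c("associated_object", "non_associated_object",
                  "object_combination", "other")
    )
  )
  purrr::map_dfr(names(rows), function(tr) {
    sch <- rows[[tr]]
    dplyr::bind_rows(
      tibble::tibble(trial = tr, code = sch$success, outcome = "success"),
      tibble::tibble(trial = tr, code = sch$failure, outcome = "failure"),
      tibble::tibble(trial = tr, code = c("no_response", "unscorable"),
                     outcome = "unscorable")
    )
  })
}

#' Read a scoring scheme from YAML
#'
#' The file maps each trial to a code-to-outcome table, e.g.
#' `screening_off: {X_alone: success, both: failure, no_response: unscorable}`.
#'
#' @param path Path to a YAML file.
#' @return A scheme tibble as from [scoring_scheme()].
#' @export
read_scoring_scheme <- function(path) {
  spec <- yaml::read_yaml(path)
  out <- purrr::map_dfr(names(spec), function(tr) {
    codes <- spec[[tr]]
    tibble::tibble(trial = tr, code = names(codes),
                   outcome = unlist(codes, use.names = FALSE))
  })
  bad <- setdiff(unique(out$outcome), c("success", "failure", "unscorable"))
  if (length(bad) > 0L) {
    abort(paste0("Unknown outcome(s) in scheme: ", paste(bad, collapse = ", ")))
  }
  out
}

#' Score raw trial records into a binary response dataset
#'
#' Rescores raw trial-response codes as succeeding (1: the intended causal
#' inference was made) or not succeeding (0: any other scorable response).
#' Children with an unscorable code on any trial are flagged and excluded
#' listwise; unknown codes are an error naming the offending record.
#'
#' @param records Long tibble with columns `subject_id`, `trial`, `code`,
#'   and per-subject `age_months` (plus optional `age_group`) repeated on
#'   each record.
#' @param scheme A scheme tibble from [scoring_scheme()] or
#'   [read_scoring_scheme()].
#' @param trial_order Order of the trial columns in the output; defaults to
#'   the order of first appearance in `scheme`.
#' @return A [response_data] tibble with one 0/1 column per trial.
#' @export
score_responses <- function(records, scheme = scoring_scheme(),
                            trial_order = NULL) {
  stopifnot(all(c("subject_id", "trial", "code") %in% names(records)))
  records <- tibble::as_tibble(records)
  unknown_trial <- setdiff(unique(records$trial), unique(scheme$trial))
  if (length(unknown_trial) > 0L) {
    abort(paste0("Trial(s) not in scheme: ", paste(unknown_trial, collapse = ", ")))
  }
  scored <- dplyr::left_join(records, scheme, by = c("trial", "code"))
  if (anyNA(scored$outcome)) {
    bad <- scored[is.na(scored$outcome), ][1L, ]
    abort(paste0("Unknown code '", bad$code, "' for trial '", bad$trial,
                 "' (subject ", bad$subject_id, ")."))
  }
  scored <- dplyr::mutate(
    scored,
    success = dplyr::case_when(outcome == "success" ~ 1,
                               outcome == "failure" ~ 0,
                               TRUE ~ NA_real_)
  )
  if (is.null(trial_order)) trial_order <- unique(scheme$trial)
  trial_order <- intersect(trial_order, unique(records$trial))

  meta_cols <- intersect(c("age_months", "age_group"), names(records))
  wide <- tidyr::pivot_wider(
    scored[c("subject_id", meta_cols, "trial", "success")],
    names_from = "trial", values_from = "success"
  )
  flagged <- wide$subject_id[rowSums(is.na(wide[trial_order])) > 0L]
  if (length(flagged) > 0L) {
    inform(paste0("Excluding ", length(flagged),
                  " subject(s) with unscorable responses: ",
                  paste(flagged, collapse = ", ")))
  }
  response_data(wide, trials = trial_order)
}

#' Screen items for response variability
#'
#' Drops trials on which too few children succeed to carry information about
#' strategy differences (the screen is one-sided: near-ceiling items are
#' retained). The default threshold 0.05 excludes an item that only 2% of
#' children pass while keeping one that 97% pass.
#'
#' @param data A [response_data] tibble.
#' @param min_success_prop Items with overall success proportion strictly
#'   below this are dropped; must lie in `[0, 0.5)`.
#' @return A list with `data` (the screened [response_data]) and `report`
#'   (a tibble of per-item proportions and the keep decision).
#' @export
screen_item_variability <- function(data, min_success_prop = 0.05) {
  stopifnot(inherits(data, "response_data"),
            min_success_prop >= 0, min_success_prop < 0.5)
  Y <- response_matrix(data)
  prop <- colMeans(Y)
  report <- tibble::tibble(
    trial = colnames(Y), n = nrow(Y), successes = colSums(Y),
    success_prop = prop, kept = prop >= min_success_prop
  )
  kept <- report$trial[report$kept]
  if (length(kept) == 0L) abort("All items fall below the variability screen.")
  if (any(!report$kept)) {
    inform(paste0("Excluding low-variability trial(s): ",
                  paste(report$trial[!report$kept], collapse = ", ")))
  }
  list(data = response_data(tibble::as_tibble(data), trials = kept),
       report = report)
}

as_table_2x2 <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (is.matrix(table)) {
    stopifnot(dim(table) == c(2L, 2L))
  } else {
    stopifnot(length(table) == 4L)
    table <- matrix(table, 2L, 2L, byrow = TRUE)
  }
  if (any(table < 0) || any(table != round(table))) {
    abort("2x2 table entries must be nonnegative integers.")
  }
  storage.mode(table) <- "double"
  table
}

#' Pearson chi-square test for a 2x2 table
#'
#' The classical uncorrected chi-square, `n (ad - bc)^2 / (r1 r2 c1 c2)`,
#' with 1 degree of freedom. No continuity correction is applied.
#'
#' @param table A 2x2 matrix of counts, or a length-4 vector `c(a, b, c, d)`
#'   read row-wise (rows = groups, columns = succeed / not succeed).
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @examples
#' chisq_2x2(c(16, 7, 8, 8)) # 1.53
#' @export
chisq_2x2 <- function(table) {
  tab <- as_table_2x2(table)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Chi-square is undefined for a table with a zero margin.")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic), df = 1L,
                 p_value = unname(ht$p.value))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value from the hypergeometric distribution of the
#' top-left cell given fixed margins. Two two-sided conventions are
#' available: `"minlik"` (default; sum the probabilities of all tables no
#' more probable than the observed one, the common statistical-software
#' rule) and `"doubling"` (twice the smaller one-sided tail, capped at 1).
#' Degenerate margins leave a single possible table and give p = 1.
#'
#' @inheritParams chisq_2x2
#' @param convention Two-sided rule, `"minlik"` or `"doubling"`.
#' @return The two-sided p-value.
#' @examples
#' fisher_2x2(c(22, 1, 16, 0)) # 1
#' @export
fisher_2x2 <- function(table, convention = c("minlik", "doubling")) {
  convention <- match.arg(convention)
  tab <- as_table_2x2(table)
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  if (convention == "minlik") {
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- phyper(a, r1, r2, c1)
    upper <- phyper(a - 1, r1, r2, c1, lower.tail = FALSE)
    p <- 2 * min(lower, upper)
  }
  min(p, 1)
}

#' Strategy-by-age-group summary
#'
#' Cross-tabulates modal class assignments against age group and expresses
#' counts as percentages within each age group (each group's percentages sum
#' to 100). Empty age groups are absent from the output.
#'
#' @param labels Class labels (e.g. from [lcm_classify()]).
#' @param age_group Age group per subject (same length as `labels`).
#' @return A tibble with `age_group`, `class`, `n`, `percent`.
#' @export
class_by_age_summary <- function(labels, age_group) {
  stopifnot(length(labels) == length(age_group))
  tibble::tibble(age_group = age_group, class = labels) |>
    dplyr::count(.data$age_group, .data$class, name = "n") |>
    tidyr::complete(.data$age_group, class = sort(unique(labels)),
                    fill = list(n = 0L)) |>
    dplyr::group_by(.data$age_group) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
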