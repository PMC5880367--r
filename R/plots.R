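#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_histogram geom_vline labs scale_y_continuous facet_wrap
#'   theme_minimal .data
NULL

#' @export
ggplot2::autoplot

#' Plot the response-probability profiles of a fitted model
#'
#' One line per latent class: the probability of succeeding on each trial
#' given class membership — the profile plot that makes strategies readable.
#'
#' @param object An `lcm_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lcm_fit <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$term == "response_prob") |>
    dplyr::mutate(trial = factor(.data$trial, levels = object$trials),
                  class = factor(paste0("class ", .data$class)))
  ggplot(df, aes(x = .data$trial, y = .data$estimate,
                 group = .data$class, colour = .data$class)) +
    geom_line() +
    geom_point(size = 2) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = NULL, y = "P(success | class)", colour = NULL,
         title = "Class response-probability profiles") +
    theme_minimal()
}

#' Plot the bootstrap null distribution of the G-squared statistic
#'
#' @param object An `lcm_gof` object.
#' @param ... Unused.
#' @return A ggplot object: histogram of replicate G-squared values with the
#'   observed value marked.
#' @export
autoplot.lcm_gof <- function(object, ...) {
  ggplot(tibble::tibble(g2 = object$bootstrap_g2), aes(x = .data$g2)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey35") +
    geom_vline(xintercept = object$g2_observed, colour = "firebrick") +
    labs(x = expression(G^2), y = "bootstrap replicates",
         title = sprintf("Parametric bootstrap: p = %.3f (B = %d)",
                         object$p_value, object$n_bootstrap)) +
    theme_minimal()
}

#' Plot strategy percentages by age group
#'
#' @param summary A tibble from [class_by_age_summary()], or a
#'   `study_report` whose `class_by_age` element is used.
#' @return A ggplot object: grouped bars of within-group percentages.
#' @export
plot_class_by_age <- function(summary) {
  if (inherits(summary, "study_report")) summary <- summary$class_by_age
  if (is.null(summary)) abort("No age-group summary available.")
  df <- dplyr::mutate(summary,
                      class = factor(paste0("class ", .data$class)),
                      age_group = factor(.data$age_group))
  ggplot(df, aes(x = .data$age_group, y = .data$percent, fill = .data$class)) +
    geom_col(position = "dodge") +
    labs(x = "age group (years)", y = "% of children", fill = NULL,
         title = "Strategy use by age group") +
    theme_minimal()
}

#' Plot the model-comparison table of a study report
#'
#' @param object A `study_report` object.
#' @param ... Unused.
#' @return A ggplot object: BIC against the number of classes for the
#'   covariate-free fits, with covariate models overlaid.
#' @export
autoplot.study_report <- function(object, ...) {
  df <- dplyr::mutate(object$comparison,
                      model = paste0(.data$n_classes, " class",
                                     ifelse(.data$n_classes > 1, "es", ""),
                                     ifelse(.data$covariate == "none", "",
                                            paste0(" + age on ", .data$covariate))))
  ggplot(df, aes(x = stats::reorder(.data$model, .data$bic), y = .data$bic,
                 fill = .data$selected)) +
    geom_col() +
    labs(x = NULL, y = "BIC", fill = "selected") +
    theme_minimal() +
    ggplot2::coord_flip()
}
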