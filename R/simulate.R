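#' Configure the synthetic response-data generator
#'
#' Describes a generating latent class model over four age groups of
#' children: how many children per group, the group age distributions
#' (normal, truncated to each group's 12-month band), the class model
#' (either fixed proportions or a multinomial logit of class on age in
#' months), and per-class response probabilities with optional logit-scale
#' age slopes for accuracy-growth generation.
#'
#' @param n_per_group Four nonnegative integers: children aged 2, 3, 4, 5
#'   years.
#' @param age_means,age_sds Four means/SDs in months for the group age
#'   distributions.
#' @param class_probs Length-K probability vector of class proportions, or
#'   `NULL` when `membership_coef` is given.
#' @param membership_coef Optional list with `intercepts` and `slopes`
#'   (each length K-1, classes 2..K versus class 1) defining class
#'   membership as a multinomial logit in age (months).
#' @param response_probs K-by-J matrix of per-class success probabilities.
#' @param response_slopes Optional K-by-J logit-scale slopes on age in
#'   months; responses are then Bernoulli with probability
#'   `plogis(qlogis(response_probs) + response_slopes * age)`. Boundary
#'   response probabilities (exactly 0 or 1) cannot carry a nonzero slope.
#' @param trial_names Item names (columns of the generated table).
#' @param seed Default seed used when the simulation call gives none.
#' @return A `generator_config` object.
#' @seealso [lcm_preset()] for ready-made configurations.
#' @export
generator_config <- function(n_per_group = c(23, 23, 23, 21),
                             age_means = c(30.04, 40.87, 54.39, 67.33),
                             age_sds = c(3.16, 3.56, 2.98, 2.44),
                             class_probs = NULL,
                             membership_coef = NULL,
                             response_probs,
                             response_slopes = NULL,
                             trial_names = NULL,
                             seed = 1) {
  stopifnot(length(n_per_group) == 4, all(n_per_group >= 0),
            length(age_means) == 4, length(age_sds) == 4)
  if (any(age_sds < 0)) abort("Age standard deviations must be nonnegative.")
  if (sum(n_per_group) < 1) abort("At least one child is required.")
  response_probs <- as.matrix(response_probs)
  K <- nrow(response_probs)
  if (any(response_probs < 0 | response_probs > 1)) {
    abort("`response_probs` must lie in [0, 1].")
  }
  if (is.null(class_probs) == is.null(membership_coef)) {
    abort("Give exactly one of `class_probs` or `membership_coef`.")
  }
  if (!is.null(class_probs)) {
    stopifnot(length(class_probs) == K)
    if (abs(sum(class_probs) - 1) > 1e-12 || any(class_probs < 0)) {
      abort("`class_probs` must be a simplex vector (sum 1 within 1e-12).")
    }
  } else {
    stopifnot(length(membership_coef$intercepts) == K - 1,
              length(membership_coef$slopes) == K - 1)
  }
  if (!is.null(response_slopes)) {
    response_slopes <- as.matrix(response_slopes)
    stopifnot(dim(response_slopes) == dim(response_probs))
    at_boundary <- response_probs %in% c(0, 1)
    if (any(response_slopes[at_boundary] != 0)) {
      abort("Boundary response probabilities (0 or 1) cannot have nonzero age slopes: the logit is undefined.")
    }
  }
  if (is.null(trial_names)) {
    trial_names <- paste0("trial", seq_len(ncol(response_probs)))
  }
  structure(
    list(n_per_group = as.integer(n_per_group), age_means = age_means,
         age_sds = age_sds, class_probs = class_probs,
         membership_coef = membership_coef, response_probs = response_probs,
         response_slopes = response_slopes, trial_names = trial_names,
         seed = seed),
    class = "generator_config"
  )
}

#' Ready-made generator configurations
#'
#' Three presets covering the structures the analysis pipeline must
#' distinguish:
#' \describe{
#'   \item{`"study"`}{Three strategy classes with fixed proportions
#'     51/90, 27/90, 12/90 and the selected-model response probabilities
#'     (rows: 1/.67/.94/1, .48/.33/1/0, 0/0/1/1) over four trials; group
#'     sizes 23/23/23/21 with the study's group age means and SDs.}
#'   \item{`"age_logit"`}{The same response probabilities, but class
#'     membership follows a multinomial logit in age calibrated so the
#'     first-class share rises and the second-class share falls with age
#'     (modal class 2 among 2-year-olds, modal class 1 from age 3 up),
#'     with a small third class throughout.}
#'   \item{`"one_class"`}{A single class with interior response
#'     probabilities (0.7, 0.5, 0.9, 0.6) and no age effect: the null
#'     against which strategy variability is judged.}
#'   \item{`"accuracy_growth"`}{A single class whose success probabilities
#'     rise with age on the logit scale (slope 0.08 per month, probability
#'     0.5 at 48 months): variability from accuracy growth, not strategy
#'     mixture.}
#' }
#'
#' @param preset One of `"study"`, `"age_logit"`, `"one_class"`,
#'   `"accuracy_growth"`.
#' @param ... Overrides passed on to [generator_config()].
#' @return A `generator_config`.
#' @export
lcm_preset <- function(preset = c("study", "age_logit", "one_class",
                                  "accuracy_growth"), ...) {
  preset <- match.arg(preset)
  study_probs <- matrix(
    c(1, 0.67, 0.94, 1,
      0.48, 0.33, 1, 0,
      0, 0, 1, 1),
    nrow = 3, byrow = TRUE
  )
  args <- switch(
    preset,
    study = list(class_probs = c(51, 27, 12) / 90,
                 response_probs = study_probs),
    age_logit = list(
      membership_coef = list(intercepts = c(4.32, -2.2),
                             slopes = c(-0.12, 0)),
      response_probs = study_probs
    ),
    one_class = list(class_probs = 1,
                     response_probs = matrix(c(0.7, 0.5, 0.9, 0.6), 1)),
    accuracy_growth = {
      slope <- 0.08
      list(class_probs = 1,
           response_probs = matrix(rep(plogis(-slope * 48), 4), 1),
           response_slopes = matrix(rep(slope, 4), 1))
    }
  )
  defaults <- utils::modifyList(args, list(...))
  do.call(generator_config, defaults)
}

#' Draw ages for the four age groups
#'
#' Ages are drawn from per-group normal distributions truncated to each
#' group's 12-month band (24-36, 36-48, 48-60, 60-72 months), so group
#' labels stay consistent with ages. A zero SD makes every child in that
#' group exactly the group mean.
#'
#' @param config A [generator_config()].
#' @param seed Seed (defaults to the config's).
#' @return A tibble with `age_months` and `age_group` (2, 3, 4, 5 years).
#' @export
sample_ages <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  bands <- cbind(lower = c(24, 36, 48, 60), upper = c(36, 48, 60, 72))
  groups <- purrr::map_dfr(1:4, function(g) {
    n <- config$n_per_group[g]
    if (n == 0L) return(tibble::tibble(age_months = numeric(0), age_group = integer(0)))
    mu <- config$age_means[g]; sd <- config$age_sds[g]
    if (sd == 0) {
      age <- rep(mu, n)
    } else {
      lo <- pnorm(bands[g, "lower"], mu, sd)
      hi <- pnorm(bands[g, "upper"], mu, sd)
      age <- qnorm(runif(n, lo, hi), mu, sd)
    }
    tibble::tibble(age_months = age, age_group = g + 1L)
  })
  groups
}

#' Simulate a response dataset from a generator configuration
#'
#' Draws each child's age ([sample_ages()]), latent class (fixed proportions
#' or softmax of the age logit) and Bernoulli trial responses. The true class
#' is attached as a `.true_class` sidecar column that the fitting code never
#' sees (it is excluded from the trial columns); the generating configuration
#' travels along as an attribute.
#'
#' @param config A [generator_config()], e.g. from [lcm_preset()].
#' @param seed Seed (defaults to the config's); identical seeds give
#'   identical datasets.
#' @param n_per_group Optional override of the config's group sizes.
#' @return A [response_data] tibble with an extra `.true_class` column.
#' @examples
#' dat <- simulate_lcm_data(lcm_preset("study"), seed = 42)
#' table(dat$.true_class)
#' @export
simulate_lcm_data <- function(config, seed = config$seed, n_per_group = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(n_per_group)) {
    config <- utils::modifyList(config, list(n_per_group = as.integer(n_per_group)))
    class(config) <- "generator_config"
  }
  ages <- sample_ages(config, seed = seed)
  n <- nrow(ages)
  K <- nrow(config$response_probs)
  J <- ncol(config$response_probs)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed((as.numeric(seed) + 1) %% 2147483647)
  if (!is.null(config$class_probs)) {
    cls <- sample.int(K, n, replace = TRUE, prob = config$class_probs)
  } else {
    eta <- cbind(0, matrix(config$membership_coef$intercepts, n, K - 1L, byrow = TRUE) +
                   outer(ages$age_months, config$membership_coef$slopes))
    PI <- row_softmax(eta)
    cls <- vapply(seq_len(n), function(i) sample.int(K, 1L, prob = PI[i, ]),
                  integer(1))
  }

  Y <- matrix(0L, n, J)
  for (i in seq_len(n)) {
    p <- config$response_probs[cls[i], ]
    if (!is.null(config$response_slopes)) {
      s <- config$response_slopes[cls[i], ]
      p <- ifelse(p %in% c(0, 1), p, plogis(qlogis(p) + s * ages$age_months[i]))
    }
    Y[i, ] <- rbinom(J, 1, p)
  }
  colnames(Y) <- config$trial_names

  out <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = sprintf("child%03d", seq_len(n)),
      age_months = ages$age_months,
      age_group = ages$age_group
    ),
    tibble::as_tibble(Y),
    tibble::tibble(.true_class = cls)
  )
  out <- response_data(out, trials = config$trial_names)
  attr(out, "generator_config") <- config
  out
}
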