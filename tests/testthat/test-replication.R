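test_that("raw trial codes are scored into binary successes", {
  records <- tibble::tribble(
    ~subject_id, ~age_months, ~trial, ~code,
    "a", 30, "screening_off", "X_alone",
    "a", 30, "backwards_blocking", "Y_blicket",
    "b", 50, "screening_off", "both",
    "b", 50, "backwards_blocking", "Y_not_blicket",
    "c", 60, "screening_off", "no_response",
    "c", 60, "backwards_blocking", "Y_blicket"
  )
  expect_message(rd <- score_responses(records), "unscorable")
  expect_equal(nrow(rd), 2) # subject c excluded listwise
  Y <- response_matrix(rd)
  expect_equal(Y[, "screening_off"], c(1, 0), ignore_attr = TRUE)
  expect_equal(Y[, "backwards_blocking"], c(0, 1), ignore_attr = TRUE)

  bad <- dplyr::mutate(records[1, ], code = "made_up")
  expect_error(score_responses(bad), "made_up")
})

test_that("scoring schemes round-trip through YAML and support strict labeling", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "screening_off:",
    "  X_alone: success",
    "  both: failure",
    "  no_response: unscorable"
  ), path)
  sch <- read_scoring_scheme(path)
  expect_equal(sch$outcome, c("success", "failure", "unscorable"))
  writeLines(c("screening_off:", "  X_alone: win"), path)
  expect_error(read_scoring_scheme(path), "Unknown outcome")

  # strict mode flips the compound success where X was mislabeled
  default <- scoring_scheme()
  strict <- scoring_scheme(strict_b = TRUE)
  code <- "Y_blicket_X_blicket"
  get_outcome <- function(s) {
    s$outcome[s$trial == "indirect_screening_off_b" & s$code == code]
  }
  expect_equal(get_outcome(default), "success")
  expect_equal(get_outcome(strict), "failure")
})

test_that("the variability screen drops only low-success items", {
  set.seed(1)
  n <- 90
  Y <- cbind(
    rbinom(n, 1, 0.6), rbinom(n, 1, 0.5), rep(1, n),
    rbinom(n, 1, 0.5), rep(c(1, 0), c(2, n - 2)) # 2/90 successes
  )
  dat <- make_response_data(Y)
  expect_message(res <- screen_item_variability(dat), "trial5")
  expect_equal(attr(res$data, "trials"), paste0("trial", 1:4))
  expect_false(res$report$kept[5])
  expect_true(all(res$report$kept[1:4])) # near-ceiling item 3 is retained
  expect_equal(unname(res$report$success_prop[5]), 2 / 90)

  all_zero <- make_response_data(matrix(0, 10, 2))
  expect_error(screen_item_variability(all_zero), "All items")
})

test_that("Pearson chi-square reproduces the printed comparison statistics", {
  # published cross-study comparisons, uncorrected, df = 1
  expect_equal(round(chisq_2x2(c(16, 7, 8, 8))$statistic, 2), 1.53)
  expect_equal(round(chisq_2x2(c(22, 1, 10, 6))$statistic, 2), 7.04)
  expect_equal(round(chisq_2x2(c(22, 1, 14, 2))$statistic, 2), 0.88)
  expect_equal(round(chisq_2x2(c(22, 1, 16, 0))$statistic, 2), 0.71)
  expect_equal(round(chisq_2x2(c(22, 1, 15, 1))$statistic, 2), 0.07)
  # identical rows carry no association
  expect_equal(chisq_2x2(c(5, 5, 5, 5))$statistic, 0)
  # agrees with the closed form n(ad-bc)^2 / (r1 r2 c1 c2)
  expect_equal(chisq_2x2(c(13, 10, 18, 7))$statistic,
               48 * (13 * 7 - 10 * 18)^2 / (23 * 25 * 31 * 17),
               tolerance = 1e-12)
  expect_error(chisq_2x2(c(0, 0, 3, 4)), "zero margin")
})

test_that("Fisher's exact test matches brute-force enumeration", {
  # a zero-margin column leaves a single table: p = 1
  expect_equal(fisher_2x2(c(22, 1, 16, 0)), 1)
  expect_equal(fisher_2x2(c(0, 0, 0, 0)), 1)
  expect_equal(fisher_2x2(c(3, 0, 5, 0)), 1)
  # strong association, hand-enumerable margins 10/10, 10/10
  expect_equal(fisher_2x2(c(1, 9, 9, 1)), 202 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(round(fisher_2x2(c(1, 9, 9, 1)), 4), 0.0011)

  # exhaustive agreement with the enumeration oracle over small totals
  # (the full n <= 60 sweep lives with the calibration checks)
  mismatches <- 0L
  for (n in c(5, 9, 14)) {
    for (r1 in 0:n) {
      for (c1 in 0:n) {
        r2 <- n - r1
        support <- max(0, c1 - r2):min(r1, c1)
        for (a in support) {
          tab <- matrix(c(a, r1 - a, c1 - a, r2 - (c1 - a)), 2, byrow = TRUE)
          if (abs(fisher_2x2(tab) - fisher_bruteforce(tab)) > 1e-10) {
            mismatches <- mismatches + 1L
          }
        }
      }
    }
  }
  expect_equal(mismatches, 0L)

  # and with the standard implementation on a spread of tables
  for (tab in list(c(13, 10, 18, 7), c(22, 1, 10, 6), c(4, 19, 16, 7),
                   c(2, 8, 7, 3), c(9, 14, 12, 11))) {
    m <- matrix(tab, 2, byrow = TRUE)
    expect_equal(fisher_2x2(m),
                 stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }

  # the doubling convention is never smaller than half the min-lik p
  expect_gte(fisher_2x2(c(22, 1, 10, 6), convention = "doubling"),
             fisher_2x2(c(22, 1, 10, 6)) / 2)
})

test_that("class-by-age percentages are row-normalized", {
  labels <- c(1, 1, 2, 3, 1, 2)
  groups <- c(2, 2, 2, 3, 3, 3)
  tab <- class_by_age_summary(labels, groups)
  sums <- tapply(tab$percent, tab$age_group, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_equal(tab$percent[tab$age_group == 2 & tab$class == 1], 200 / 3)

  # degenerate: everyone in class 1
  tab1 <- class_by_age_summary(rep(1, 6), groups)
  expect_true(all(tab1$percent == 100))

  # labels independent of group approximate the marginal proportions
  set.seed(7)
  lab <- sample(1:3, 2000, replace = TRUE, prob = c(0.567, 0.3, 0.133))
  grp <- sample(2:5, 2000, replace = TRUE)
  tab2 <- class_by_age_summary(lab, grp)
  for (g in 2:5) {
    expect_true(all(abs(tab2$percent[tab2$age_group == g] -
                          c(56.7, 30.0, 13.3)) < 5))
  }
})
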