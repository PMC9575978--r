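test_that("respondent draws follow the population model", {
  prefs <- default_true_preferences()

  degenerate <- prefs
  degenerate$sds[] <- 0
  set.seed(1)
  r <- draw_respondent(degenerate, "low")
  expect_equal(r$beta, degenerate$means)
  expect_equal(r$amount_coef, 0.046)
  expect_equal(r$asc, 1.102)

  # income interactions shift the fixed coefficients only
  set.seed(1)
  rm_ <- draw_respondent(degenerate, "middle")
  expect_equal(rm_$amount_coef, 0.046 + 0.065)
  expect_equal(rm_$asc, 1.102 + 0.067)
  rh <- draw_respondent(degenerate, "high")
  expect_equal(rh$amount_coef, 0.046 + 0.007)

  # CLT check on one random coefficient: b = 0.331, w = 0.416
  set.seed(42)
  draws <- replicate(10000, draw_respondent(prefs, "low")$beta[["type_Cash"]])
  expect_lt(abs(mean(draws) - 0.331), 4 * 0.416 / sqrt(10000))
  expect_lt(abs(stats::sd(draws) - 0.416), 0.02)

  expect_error(true_preferences(c(a = 1), c(a = -0.1), 0.1, 0), "negative sd")
})

test_that("task utilities are the coded dot product plus the ASC", {
  catalog <- default_catalog()
  cs <- data.frame(set_id = 1, block = 1, position = c("A", "B"),
                   amount = c(500, 50), type = c("Cash", "Voucher"),
                   schedule = c("Consistent", "Escalating"),
                   sessions = c("1_week", "3_week"),
                   location = c("Healthcare", "Workplace"),
                   stringsAsFactors = FALSE)
  zero <- list(beta = stats::setNames(rep(0, 6), names(default_true_preferences()$means)),
               amount_coef = 0, asc = 1.102)
  expect_equal(task_utilities(zero, cs, catalog),
               c(A = 0, B = 0, optout = 1.102))

  # identical alternatives give equal utilities
  same <- cs; same[2, -(1:3)] <- same[1, -(1:3)]
  set.seed(3)
  coefs <- draw_respondent(default_true_preferences(), "middle")
  Vs <- task_utilities(coefs, same, catalog)
  expect_equal(Vs[["A"]], Vs[["B"]])

  # hand computation: effects coding +1 for estimated levels, -1 omitted
  b <- coefs$beta
  V_A <- coefs$amount_coef * 50 + b[["type_Cash"]] + b[["schedule_Consistent"]] +
    b[["sessions_1_week"]] + b[["location_Healthcare"]]
  V_B <- coefs$amount_coef * 5 - b[["type_Cash"]] - b[["schedule_Consistent"]] -
    (b[["sessions_1_fortnight"]] + b[["sessions_1_week"]] + b[["sessions_2_week"]]) -
    b[["location_Healthcare"]]
  V <- task_utilities(coefs, cs, catalog)
  expect_equal(V[["A"]], V_A)
  expect_equal(V[["B"]], V_B)
  expect_equal(V[["optout"]], coefs$asc)

  bad <- cs; bad$amount[1] <- 123
  expect_error(task_utilities(coefs, bad, catalog), "unknown level")
})

test_that("simulated choices follow the three-alternative logit", {
  catalog <- money_catalog()
  # V = (0, 0, 0): symmetric choice, and chi-square GOF against softmax
  cs <- money_set(0, 0)
  coefs <- money_coefs(0, 0)
  set.seed(7)
  n <- 30000
  picks <- character(n)
  for (i in seq_len(n)) {
    r <- simulate_task(coefs, cs, catalog)
    picks[i] <- if (r$enroll == "no") "optout" else r$preferred
  }
  freq <- table(factor(picks, c("A", "B", "optout"))) / n
  expect_true(all(abs(freq - 1 / 3) < 0.02))
  expect_gt(stats::chisq.test(table(factor(picks, c("A", "B", "optout"))))$p.value,
            0.01)

  # V = (1, 0, 0.5): empirical frequencies match the closed-form softmax
  cs2 <- money_set(10, 0)
  coefs2 <- money_coefs(1, 0.5)
  expect_equal(unname(task_utilities(coefs2, cs2, catalog)), c(1, 0, 0.5))
  p_true <- exp(c(1, 0, 0.5)) / sum(exp(c(1, 0, 0.5)))
  set.seed(11)
  n <- 50000
  picks <- character(n)
  for (i in seq_len(n)) {
    r <- simulate_task(coefs2, cs2, catalog)
    picks[i] <- if (r$enroll == "no") "optout" else r$preferred
  }
  freq <- table(factor(picks, c("A", "B", "optout"))) / n
  expect_lt(max(abs(freq - p_true)), 0.01)

  # a hugely negative ASC forces enrolment
  coefs3 <- money_coefs(1, -30)
  set.seed(13)
  enr <- replicate(200, simulate_task(coefs3, cs2, catalog)$enroll)
  expect_true(all(enr == "yes"))
  # when the opt-out is drawn the preferred program maximizes utility
  coefs4 <- money_coefs(1, 30)
  set.seed(14)
  r4 <- simulate_task(coefs4, cs2, catalog)
  expect_equal(r4$enroll, "no")
  expect_equal(r4$preferred, "A")
})

test_that("Gumbel-max and softmax sampling are distributionally equivalent", {
  catalog <- money_catalog()
  cs <- money_set(10, 0)
  coefs <- money_coefs(1, 0.5)
  n <- 100000
  draw_freq <- function(method, seed) {
    set.seed(seed)
    picks <- character(n)
    for (i in seq_len(n)) {
      r <- simulate_task(coefs, cs, catalog, method = method)
      picks[i] <- if (r$enroll == "no") "optout" else r$preferred
    }
    table(factor(picks, c("A", "B", "optout"))) / n
  }
  f_soft <- draw_freq("softmax", 21)
  f_gum <- draw_freq("gumbel", 22)
  expect_lt(max(abs(f_soft - f_gum)), 0.01)
  p_true <- exp(c(1, 0, 0.5)) / sum(exp(c(1, 0, 0.5)))
  expect_lt(max(abs(f_gum - p_true)), 0.01)
})

test_that("cohort simulation plants aberrant respondents exactly", {
  catalog <- default_catalog()
  prefs <- default_true_preferences()
  design <- generate_design(catalog, 30, 3, seed = 77, n_restarts = 1)
  cfg <- cohort_config(c(low = 20L, middle = 20L, high = 20L), design,
                       catalog, prefs,
                       planted = c(nontrader = 2L, dominance_failer = 3L,
                                   never_enroller = 4L), seed = 501L)
  data <- simulate_cohort(cfg)
  expect_equal(length(unique(data$respondent_id)), 60)
  expect_equal(length(detect_nontraders(data)), 2)
  expect_equal(length(apply_dominance_filter(data)), 3)
  expect_equal(length(detect_never_enrollers(data)), 4)

  # deterministic from the seed
  data2 <- simulate_cohort(cfg)
  expect_identical(data, data2)

  # nothing planted: cleaning removes nobody
  cfg0 <- cohort_config(c(low = 6L, middle = 6L, high = 6L), design,
                        catalog, prefs, seed = 502L)
  d0 <- simulate_cohort(cfg0)
  expect_equal(clean_study(d0)$report$n_final, 18)

  # income-by-block assignment balanced within one
  tab <- table(unique(data[c("respondent_id", "income_group", "block")])[-1])
  expect_lte(max(tab) - min(tab), 1)

  expect_error(cohort_config(c(low = 1L, middle = 1L, high = 1L), design,
                             catalog, prefs,
                             planted = c(nontrader = 4L, dominance_failer = 0L,
                                         never_enroller = 0L), seed = 1L),
               "exceed")
})

test_that("study data CSV round-trips", {
  catalog <- default_catalog()
  design <- generate_design(catalog, 15, 3, seed = 31, n_restarts = 1)
  cfg <- cohort_config(c(low = 3L, middle = 3L, high = 3L), design, catalog,
                       default_true_preferences(), seed = 32L)
  data <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(data, path)
  back <- read_study_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(data), ignore_attr = TRUE)
})
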