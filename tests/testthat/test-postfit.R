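test_that("WTA is the coefficient ratio on the pound scale", {
  fit <- fake_fit(c(amount = 0.046, asc = 1.102, type_Cash = 0.138,
                    location_Healthcare = 0))
  # beta = 3k alpha with unit 10 gives -10k
  expect_equal(wta_point(fit, "type_Cash"), -10 * 0.138 / 0.046)
  expect_equal(wta_point(fit, "location_Healthcare"), 0)
  # positive coefficient and positive alpha give a negative WTA
  expect_lt(wta_point(fit, "type_Cash"), 0)
  # the opt-out constant's ratio is the mean-program indifference amount
  expect_equal(wta_point(fit, "asc"), -10 * 1.102 / 0.046)

  fit0 <- fake_fit(c(amount = 0, asc = 1, type_Cash = 1))
  expect_error(wta_point(fit0, "type_Cash"), "zero")
  expect_error(wta_point(fit, "nope"), "unknown term")

  # income interactions shift the denominator
  fit2 <- fake_fit(c(amount = 0.04, amount_x_middle = 0.01, asc = 1,
                     type_Cash = 0.05))
  expect_equal(wta_point(fit2, "type_Cash", income = "middle"),
               -10 * 0.05 / 0.05)
})

test_that("Krinsky-Robb intervals match closed forms", {
  # degenerate covariance collapses the interval onto the point
  fit0 <- fake_fit(c(a = 2, b = 1))
  kr0 <- krinsky_robb(fit0, function(th) th[["a"]] - th[["b"]], n_draws = 500)
  expect_equal(kr0$low, 1)
  expect_equal(kr0$high, 1)
  expect_equal(kr0$point, 1)

  # linear quantity: percentile CI converges to the normal CI
  V <- matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  fit1 <- fake_fit(c(a = 2, b = 1), vcov = V)
  a_vec <- c(2, -1)
  kr1 <- krinsky_robb(fit1, function(th) 2 * th[["a"]] - th[["b"]],
                      n_draws = 100000, seed = 31)
  mu <- sum(a_vec * c(2, 1))
  sdq <- sqrt(drop(t(a_vec) %*% V %*% a_vec))
  lo <- mu - stats::qnorm(0.975) * sdq
  hi <- mu + stats::qnorm(0.975) * sdq
  width <- hi - lo
  expect_lt(abs(kr1$low - lo), 0.02 * width)
  expect_lt(abs(kr1$high - hi), 0.02 * width)

  # ratio quantity with small SEs agrees with the delta method
  Vs <- diag(c(1e-4, 1e-6))
  dimnames(Vs) <- list(c("num", "den"), c("num", "den"))
  fit2 <- fake_fit(c(num = 0.3, den = 0.05), vcov = Vs)
  ratio <- function(th) th[["num"]] / th[["den"]]
  kr2 <- krinsky_robb(fit2, ratio, n_draws = 100000, seed = 32)
  g <- c(1 / 0.05, -0.3 / 0.05^2)
  sd_delta <- sqrt(drop(t(g) %*% Vs %*% g))
  lo2 <- 6 - stats::qnorm(0.975) * sd_delta
  hi2 <- 6 + stats::qnorm(0.975) * sd_delta
  w2 <- hi2 - lo2
  expect_lt(abs(kr2$low - lo2), 0.05 * w2)
  expect_lt(abs(kr2$high - hi2), 0.05 * w2)

  fit_nocov <- fake_fit(c(a = 1)); fit_nocov$vcov <- NULL
  expect_error(krinsky_robb(fit_nocov, function(th) th[["a"]]), "covariance")
})

test_that("WTA table orders interval endpoints for presentation", {
  V <- diag(c(1e-4, 1e-4, 1e-4))
  nm <- c("amount", "asc", "type_Cash")
  dimnames(V) <- list(nm, nm)
  fit <- fake_fit(c(amount = 0.046, asc = 1.102, type_Cash = 0.331), vcov = V)
  tab <- wta_table(fit, terms = c("type_Cash", "asc"), n_draws = 2000, seed = 2)
  expect_equal(tab$term, c("type_Cash", "asc"))
  expect_true(all(tab$ci_low <= tab$ci_high))
  expect_true(all(abs(tab$ci_near) <= abs(tab$ci_far)))
  expect_equal(tab$wta[1], -10 * 0.331 / 0.046)
})

test_that("uptake predictions follow the binary logit", {
  catalog <- default_catalog()
  base <- list(type = "Cash", schedule = "Consistent", sessions = "1_week",
               location = "Healthcare")
  # V equal to the ASC: one half exactly
  fit <- fake_fit(c(amount = 0.1, asc = 0.5,
                    type_Cash = 0.1, schedule_Consistent = 0.1,
                    sessions_1_fortnight = 0, sessions_1_week = 0.1,
                    sessions_2_week = 0, location_Healthcare = 0.1))
  # V(prog) = 0.1*amount/10 + 0.4; at amount 1: 0.01 + 0.4 ... choose amount
  # so that V = asc: 0.1*a/10 + 0.4 = 0.5 -> a = 10
  pr <- c(base, amount = 10)
  up <- predict_uptake(fit, pr, catalog)
  expect_equal(up$probability, 0.5)

  # hugely negative ASC forces enrolment
  fit_neg <- fit; fit_neg$estimates[["asc"]] <- -30
  expect_gt(predict_uptake(fit_neg, pr, catalog)$probability, 0.999999)

  # with zero SDs the simulated path equals the closed form exactly
  expect_equal(predict_uptake(fit, pr, catalog, n_draws = 50)$probability,
               stats::plogis(0), tolerance = 1e-12)

  # means-only ignores fitted heterogeneity; the simulated path shrinks
  # extreme probabilities toward 1/2
  fit_h <- fit
  fit_h$sds <- c(type_Cash = 0.5)
  pr2 <- c(base, amount = 200)
  p_mean <- predict_uptake(fit_h, pr2, catalog, means_only = TRUE)$probability
  expect_equal(p_mean, stats::plogis(0.1 * 20 + 0.4 - 0.5))
  p_sim <- predict_uptake(fit_h, pr2, catalog, n_draws = 20000,
                          seed = 4)$probability
  expect_lt(p_sim, p_mean)
  expect_gt(p_sim, 0.5)

  # income group adjusts both the amount coefficient and the ASC
  fit_inc <- fake_fit(c(amount = 0.05, amount_x_middle = 0.05, asc = 0.4,
                        asc_x_middle = 0.2,
                        type_Cash = 0.1, schedule_Consistent = 0.1,
                        sessions_1_fortnight = 0, sessions_1_week = 0.1,
                        sessions_2_week = 0, location_Healthcare = 0.1))
  pr_mid <- c(base, amount = 20, income_group = "middle")
  expect_equal(predict_uptake(fit_inc, pr_mid, catalog)$probability,
               stats::plogis(0.1 * 2 + 0.4 - 0.6))
})

test_that("uptake curves are monotone, concave above one half", {
  catalog <- default_catalog()
  base <- list(type = "Cash", schedule = "Consistent", sessions = "1_week",
               location = "Healthcare")
  fit <- fake_fit(c(table2_truth()[c("amount", "asc", "type_Cash",
                                     "schedule_Consistent",
                                     "sessions_1_fortnight", "sessions_1_week",
                                     "sessions_2_week", "location_Healthcare")]))
  amounts <- seq(50, 1000, by = 50)
  curve <- uptake_curve(fit, base, amounts, catalog, means_only = TRUE)
  expect_true(all(diff(curve$uptake) > 0))
  above <- which(curve$uptake > 0.5)
  d2 <- diff(diff(curve$uptake[above]))
  expect_true(all(d2 <= 1e-12))

  single <- uptake_curve(fit, base, 500, catalog, means_only = TRUE)
  expect_equal(single$uptake,
               predict_uptake(fit, c(base, amount = 500), catalog,
                              means_only = TRUE)$probability)
  expect_error(uptake_curve(fit, base, numeric(0), catalog), "non-empty")
  expect_error(uptake_curve(fit, base, -5, catalog), "non-negative")
})

test_that("the indifference amount solves V = V_optout", {
  catalog <- default_catalog()
  fit <- fake_fit(c(amount = 0.046, asc = 1.102, type_Cash = 0.331,
                    schedule_Consistent = 0.067, sessions_1_fortnight = 0.221,
                    sessions_1_week = 0.273, sessions_2_week = 0.114,
                    location_Healthcare = 0.124))
  # mean program: attribute utilities vanish under effects coding
  expect_equal(indifference_amount(fit), 10 * 1.102 / 0.046)
  # at the solution the means-only uptake is exactly one half
  base <- list(type = "Cash", schedule = "Consistent", sessions = "1_week",
               location = "Healthcare")
  a_star <- indifference_amount(fit, base, catalog = catalog)
  v_attr <- 0.331 + 0.067 + 0.273 + 0.124
  expect_equal(a_star, 10 * (1.102 - v_attr) / 0.046)
  p <- stats::plogis(0.046 * a_star / 10 + v_attr - 1.102)
  expect_equal(p, 0.5, tolerance = 1e-9)

  # delta = 0 and zero attribute utilities give zero
  fit0 <- fake_fit(c(amount = 0.046, asc = 0, type_Cash = 0,
                     schedule_Consistent = 0, sessions_1_fortnight = 0,
                     sessions_1_week = 0, sessions_2_week = 0,
                     location_Healthcare = 0))
  expect_equal(indifference_amount(fit0), 0)

  # increasing the ASC strictly increases the indifference amount
  deltas <- c(0.5, 1, 1.5)
  vals <- vapply(deltas, function(d) {
    f <- fit; f$estimates[["asc"]] <- d
    indifference_amount(f)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))

  fit_neg <- fit; fit_neg$estimates[["amount"]] <- -0.01
  expect_error(indifference_amount(fit_neg), "positive")
})

test_that("WTA respects effects-coding linearity and unit consistency", {
  fit <- fake_fit(c(amount = 0.046, asc = 1.102, sessions_1_fortnight = 0.221,
                    sessions_1_week = 0.273, sessions_2_week = 0.114))
  # omitted-level WTA is minus the sum of the estimated levels' WTAs
  wtas <- vapply(c("sessions_1_fortnight", "sessions_1_week", "sessions_2_week"),
                 function(t) wta_point(fit, t), numeric(1))
  omitted_beta <- -sum(fit$estimates[c("sessions_1_fortnight",
                                       "sessions_1_week", "sessions_2_week")])
  expect_equal(10 * omitted_beta / (-0.046), -sum(wtas))

  # rescaling amount and its coefficient together leaves uptake unchanged
  catalog <- default_catalog()
  base <- list(type = "Cash", schedule = "Consistent", sessions = "1_week",
               location = "Healthcare", amount = 350)
  full <- fake_fit(c(table2_truth()[c("amount", "asc", "type_Cash",
                                      "schedule_Consistent",
                                      "sessions_1_fortnight",
                                      "sessions_1_week", "sessions_2_week",
                                      "location_Healthcare")]))
  p10 <- predict_uptake(full, base, catalog, unit = 10,
                        means_only = TRUE)$probability
  full2 <- full
  full2$estimates[["amount"]] <- full$estimates[["amount"]] * 2
  p20 <- predict_uptake(full2, base, catalog, unit = 20,
                        means_only = TRUE)$probability
  expect_equal(p10, p20, tolerance = 1e-12)
})
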