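test_that("Halton sequences are the radical inverses in prime bases", {
  H <- halton_sequence(3, 2)
  expect_equal(H[, 1], c(1 / 2, 1 / 4, 3 / 4))
  expect_equal(H[, 2], c(1 / 3, 2 / 3, 1 / 9))
  # skip discards leading points
  expect_equal(halton_sequence(2, 1, skip = 1)[, 1], c(1 / 4, 3 / 4))
  # strictly inside the unit interval
  H2 <- halton_sequence(500, 6, skip = 100)
  expect_true(all(H2 > 0 & H2 < 1))
  expect_error(halton_sequence(10, 26), "prime table")
  expect_error(halton_sequence(0, 1), "at least 1")
})

test_that("conditional logit log-likelihood matches closed forms", {
  # one task, three alternatives, equal utilities
  e1 <- encoded_from_v(list(c(0, 0, 0)), chosen = 1)
  expect_equal(mnl_loglik(c(x = 1), e1), log(1 / 3))

  # effective two-alternative task: V_chosen - V_other = ln 3 -> log(0.75)
  e2 <- data.frame(respondent_id = 1, task_id = 1, set_id = 1,
                   alt = c("A", "B"), chosen = c(1L, 0L),
                   x = c(log(3), 0))
  class(e2) <- c("encoded_data", "data.frame")
  expect_equal(mnl_loglik(c(x = 1), e2), log(0.75))

  # scaling: n identical symmetric tasks
  e3 <- encoded_from_v(rep(list(c(0, 0, 0)), 50), chosen = rep(2, 50))
  expect_equal(mnl_loglik(c(x = 5), e3), 50 * log(1 / 3))

  # brute-force enumeration oracle on random instances with 4 alternatives
  set.seed(19)
  for (rep in 1:5) {
    V <- round(stats::rnorm(4), 3)
    ch <- sample(4, 1)
    e4 <- data.frame(respondent_id = 1, task_id = 1, set_id = 1,
                     alt = letters[1:4], chosen = as.integer(seq_len(4) == ch),
                     x = V)
    class(e4) <- c("encoded_data", "data.frame")
    expect_equal(mnl_loglik(c(x = 1), e4), log(exp(V[ch]) / sum(exp(V))),
                 tolerance = 1e-12)
  }

  expect_error(mnl_loglik(c(x = Inf), e1), "non-finite")
})

test_that("zero-variance simulated likelihood equals the conditional logit", {
  sm <- small_encoded(n_per_income = 20L)
  enc <- sm$encoded
  spec <- default_model_spec(sm$catalog)
  terms <- c(spec$fixed_terms, spec$random_terms)
  set.seed(5)
  params <- stats::setNames(stats::rnorm(length(terms), 0, 0.3), terms)
  oracle <- mnl_loglik(params, enc)
  n_resp <- length(unique(enc$respondent_id))
  for (R in c(1L, 10L, 100L)) {
    draws <- make_draws(n_resp, length(spec$random_terms), R)
    p_full <- c(params, stats::setNames(rep(0, length(spec$random_terms)),
                                        paste0("sd_", spec$random_terms)))
    expect_equal(simulated_loglik(p_full, enc, draws, spec$random_terms),
                 oracle, tolerance = 1e-10)
  }
})

test_that("simulation agrees with Gauss-Hermite quadrature in one dimension", {
  # single respondent, single task; one random coefficient b +- w
  e <- encoded_from_v(list(c(1, 0, 0.4)), chosen = 1)
  b <- 0.8; w <- 0.5
  gh <- pracma::gaussHermite(80)
  p_of <- function(beta) {
    V <- beta * c(1, 0, 0.4)
    exp(V[1]) / sum(exp(V))
  }
  oracle <- log(sum(gh$w * vapply(gh$x, function(t)
    p_of(b + sqrt(2) * w * t), numeric(1))) / sqrt(pi))
  draws <- make_draws(1, 1, 5000L)
  sim <- simulated_loglik(c(x = b, sd_x = w), e, draws, "x")
  expect_equal(sim, oracle, tolerance = 1e-3)
})

test_that("simulated likelihood is symmetric in respondent order and SD sign", {
  sm <- small_encoded(n_per_income = 20L)
  enc <- sm$encoded
  spec <- default_model_spec(sm$catalog)
  terms <- c(spec$fixed_terms, spec$random_terms)
  set.seed(8)
  params <- c(stats::setNames(stats::rnorm(length(terms), 0, 0.3), terms),
              stats::setNames(stats::runif(length(spec$random_terms), 0.1, 0.5),
                              paste0("sd_", spec$random_terms)))
  n_resp <- length(unique(enc$respondent_id))
  draws <- make_draws(n_resp, length(spec$random_terms), 50L)
  ll <- simulated_loglik(params, enc, draws, spec$random_terms)

  # permuting whole respondents leaves the panel likelihood unchanged,
  # provided each respondent keeps their own draws
  ids <- unique(enc$respondent_id)
  set.seed(9)
  perm <- sample(ids)
  enc_perm <- do.call(rbind, lapply(perm, function(i) enc[enc$respondent_id == i, ]))
  class(enc_perm) <- c("encoded_data", "data.frame")
  draws_perm <- draws[, , match(perm, ids), drop = FALSE]
  expect_equal(simulated_loglik(params, enc_perm, draws_perm, spec$random_terms),
               ll, tolerance = 1e-10)

  # flipping the sign of an SD leaves the exact likelihood unchanged; with
  # finite quasi-random draws the identity holds up to simulation noise
  flipped <- params
  flipped["sd_type_Cash"] <- -flipped["sd_type_Cash"]
  expect_equal(simulated_loglik(flipped, enc, draws, spec$random_terms), ll,
               tolerance = 2e-3)
  # in the one-dimensional quadrature-checked setting the symmetry is exact
  # because the Gauss-Hermite nodes are symmetric about zero
  e1 <- encoded_from_v(list(c(1, 0, 0.4)), chosen = 1)
  d1 <- make_draws(1, 1, 64L)
  d1[, 1, 1] <- c(d1[1:32, 1, 1], -d1[1:32, 1, 1])  # antithetic pairs
  expect_equal(simulated_loglik(c(x = 0.8, sd_x = 0.5), e1, d1, "x"),
               simulated_loglik(c(x = 0.8, sd_x = -0.5), e1, d1, "x"),
               tolerance = 1e-12)
})

test_that("the estimator recovers a homogeneous population", {
  sm <- small_encoded(n_per_income = 167L, sds_zero = TRUE, seed = 811L)
  spec <- default_model_spec(sm$catalog, n_draws = 100L, seed = 3L)
  fit <- fit_mixed_logit(spec, sm$encoded)
  expect_true(fit$converged)
  truth <- table2_truth()
  z <- abs(fit$estimates[names(truth)] - truth) / fit$se_estimates[names(truth)]
  expect_true(all(z < 3))
  # fitted SDs sit at the w = 0 boundary; their folded MLEs scatter within
  # the boundary sampling spread, well below the true heterogeneity the
  # default preferences carry (0.29-0.55 for the well-identified terms)
  expect_true(all(fit$sds < 0.35))
  expect_lt(fit$sds[["type_Cash"]], 0.25)
  expect_lt(fit$sds[["location_Healthcare"]], 0.25)
  # reported SDs are non-negative by construction
  expect_true(all(fit$sds >= 0))

  # refitting with the same spec reproduces the estimates exactly
  fit2 <- fit_mixed_logit(spec, sm$encoded)
  expect_identical(coef(fit), coef(fit2))
})

test_that("fitting rejects unidentifiable models", {
  sm <- small_encoded(n_per_income = 20L)
  enc <- sm$encoded
  enc$dup <- enc$type_Cash
  spec <- model_spec(fixed_terms = c("amount", "asc", "dup"),
                     random_terms = c("type_Cash"), n_draws = 10L)
  expect_error(fit_mixed_logit(spec, enc), "linearly dependent")
  expect_error(model_spec(fixed_terms = "a", random_terms = "a"), "disjoint")
})

test_that("the effects table completes each attribute to zero sum", {
  fit <- fake_fit(estimates = c(
    amount = 0.046, asc = 1.102,
    type_Cash = 0.331, schedule_Consistent = 0.067,
    sessions_1_fortnight = 0.221, sessions_1_week = 0.273,
    sessions_2_week = 0.114, location_Healthcare = 0.124),
    sds = c(type_Cash = 0.416, schedule_Consistent = 0.120,
            sessions_1_fortnight = 0.393, sessions_1_week = 0.290,
            sessions_2_week = 0.022, location_Healthcare = 0.549))
  tab <- report_effects_table(fit, default_catalog())
  omitted <- tab[tab$omitted, ]
  expect_equal(omitted$estimate[omitted$attribute == "sessions"], -0.608)
  expect_equal(omitted$estimate[omitted$attribute == "type"], -0.331)
  for (a in c("type", "schedule", "sessions", "location"))
    expect_equal(sum(tab$estimate[tab$attribute == a]), 0)
  expect_true(all(is.na(omitted$se)))
})

test_that("significance stars follow the conventional thresholds", {
  expect_equal(incentdce:::p_stars(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", ""))
})
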