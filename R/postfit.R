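#' Marginal willingness to accept (WTA)
#'
#' The monetary equivalent (pounds over the whole program) of a unit change
#' in a coded attribute column: the attribute coefficient divided by the
#' negative of the amount coefficient, restored to the pound scale by the
#' rescale unit. A positive coefficient therefore yields a negative WTA
#' (less money is needed when the program carries the preferred level).
#'
#' @param fit a [fit_mixed_logit()] result.
#' @param term a model column name (`"asc"` gives the opt-out constant's
#'   ratio, the indifference amount of the mean program).
#' @param unit rescale unit in pounds used when encoding.
#' @param income income group whose amount coefficient is used (`"low"` is
#'   the reference, i.e. the main amount coefficient).
#' @return WTA in pounds (scalar).
#' @export
wta_point <- function(fit, term, unit = 10, income = "low") {
  beta <- if (term %in% names(fit$estimates)) fit$estimates[[term]] else
    stop("unknown term '", term, "'")
  alpha <- amount_coef_income(fit, income)
  if (alpha == 0) stop("amount coefficient is zero; WTA undefined")
  unit * beta / (-alpha)
}

amount_coef_income <- function(fit, income = c("low", "middle", "high")) {
  income <- match.arg(income)
  amt <- setdiff(names(fit$estimates),
                 c("asc", "amount_x_middle", "amount_x_high",
                   "asc_x_middle", "asc_x_high", names(fit$sds)))[1]
  a <- fit$estimates[[amt]]
  if (income == "middle") a <- a + (fit$estimates[["amount_x_middle"]] %||% 0)
  if (income == "high") a <- a + (fit$estimates[["amount_x_high"]] %||% 0)
  a
}

asc_income <- function(fit, income = c("low", "middle", "high")) {
  income <- match.arg(income)
  d <- fit$estimates[["asc"]]
  if (income == "middle") d <- d + (fit$estimates[["asc_x_middle"]] %||% 0)
  if (income == "high") d <- d + (fit$estimates[["asc_x_high"]] %||% 0)
  d
}

#' Krinsky-Robb simulation intervals
#'
#' Draws parameter vectors from the multivariate normal with mean at the
#' estimates and the fitted covariance, evaluates a derived quantity on each
#' draw, and returns percentile bounds.
#'
#' @param fit a [fit_mixed_logit()] result (or any list with `estimates`,
#'   `sds` and `vcov` over `c(means, sd_<term>)`).
#' @param quantity function of one named parameter vector (means and
#'   `sd_<term>` entries) returning a scalar.
#' @param n_draws number of parameter draws (default 10000).
#' @param seed seed for the draws.
#' @param level confidence level (default 0.95).
#' @return list with `low`, `high` (raw percentiles), `point` (quantity at
#'   the estimates) and `draws` (the simulated quantities, invisibly used by
#'   callers).
#' @export
krinsky_robb <- function(fit, quantity, n_draws = 10000L, seed = 1L,
                         level = 0.95) {
  if (is.null(fit$vcov)) stop("fit has no covariance matrix")
  mu <- fit$estimates
  if (length(fit$sds))
    mu <- c(mu, stats::setNames(fit$sds, paste0("sd_", names(fit$sds))))
  V <- fit$vcov
  if (!isTRUE(all.equal(dim(V), c(length(mu), length(mu)))))
    stop("covariance dimension does not match the parameter vector")
  # numerical Hessians can leave tiny negative eigenvalues; clip those and
  # refuse only substantively indefinite matrices
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  scale <- max(abs(eg$values), 1e-12)
  if (min(eg$values) < -1e-4 * scale)
    stop("covariance matrix is not positive semi-definite")
  V <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
  dimnames(V) <- list(names(mu), names(mu))
  old <- .Random.seed_save()
  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, mu = mu, Sigma = V)
  .Random.seed_restore(old)
  colnames(draws) <- names(mu)
  q <- apply(draws, 1L, function(row) quantity(row))
  alpha <- (1 - level) / 2
  b <- stats::quantile(q, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(low = b[1], high = b[2], point = quantity(mu), draws = q)
}

#' WTA table with Krinsky-Robb 95% intervals
#'
#' One row per coded attribute column plus the opt-out constant. Interval
#' endpoints are reported both as raw percentiles (`ci_low <= ci_high`) and
#' in presentation order (closer to zero first), which is how negative WTA
#' ranges are conventionally printed.
#'
#' @param fit a [fit_mixed_logit()] result.
#' @param terms columns to report (default: all random terms plus `"asc"`).
#' @param unit rescale unit in pounds.
#' @param n_draws,seed,level passed to [krinsky_robb()].
#' @return data frame with columns `term`, `wta`, `ci_low`, `ci_high`,
#'   `ci_near`, `ci_far`.
#' @export
wta_table <- function(fit, terms = NULL, unit = 10, n_draws = 10000L,
                      seed = 1L, level = 0.95) {
  if (is.null(terms)) terms <- c(names(fit$sds), "asc")
  amt <- setdiff(names(fit$estimates),
                 c("asc", "amount_x_middle", "amount_x_high",
                   "asc_x_middle", "asc_x_high", names(fit$sds)))[1]
  rows <- lapply(seq_along(terms), function(i) {
    term <- terms[i]
    kr <- krinsky_robb(fit, function(theta) unit * theta[[term]] / (-theta[[amt]]),
                       n_draws = n_draws, seed = seed + i, level = level)
    near_far <- if (abs(kr$low) <= abs(kr$high)) c(kr$low, kr$high) else c(kr$high, kr$low)
    data.frame(term = term, wta = kr$point, ci_low = kr$low, ci_high = kr$high,
               ci_near = near_far[1], ci_far = near_far[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  out
}

program_utility <- function(program, catalog, unit, estimates, amount = NULL) {
  amt <- continuous_attr(catalog)
  a <- amount %||% program[[amt]]
  v_attr <- 0
  for (at in catalog$attributes) {
    if (at$coding == "continuous") next
    x <- effects_code(catalog, at$name, as.character(program[[at$name]]))
    v_attr <- v_attr + sum(estimates[names(x)] * x)
  }
  list(amount = as.numeric(a), v_attr = v_attr)
}

#' Predicted program uptake
#'
#' The probability of enrolling in a given program rather than opting out:
#' the binary logit probability `exp(V)/(exp(V) + exp(V_optout))`, averaged
#' over simulated draws of the random coefficients (or evaluated at the
#' means with `means_only = TRUE`). The amount coefficient and the opt-out
#' ASC are adjusted for the program's income group.
#'
#' @param fit a [fit_mixed_logit()] result.
#' @param program named list: one level per categorical attribute, `amount`
#'   in pounds, optionally `income_group` (default `"low"`).
#' @param catalog a [dce_catalog()].
#' @param unit rescale unit in pounds.
#' @param n_draws random-coefficient draws (default 2000).
#' @param seed seed for the draws.
#' @param means_only evaluate at the population means (no integration).
#' @return list of class `"uptake_prediction"` with `program`,
#'   `probability`, `n_draws`, `seed`.
#' @export
predict_uptake <- function(fit, program, catalog, unit = 10, n_draws = 2000L,
                           seed = 1L, means_only = FALSE) {
  income <- program$income_group %||% "low"
  pu <- program_utility(program, catalog, unit, fit$estimates)
  alpha <- amount_coef_income(fit, income)
  delta <- asc_income(fit, income)
  v_amount <- alpha * pu$amount / unit
  if (means_only || length(fit$sds) == 0L || all(fit$sds == 0)) {
    prob <- stats::plogis(v_amount + pu$v_attr - delta)
  } else {
    old <- .Random.seed_save()
    set.seed(seed)
    Zd <- matrix(stats::rnorm(n_draws * length(fit$sds)), n_draws,
                 dimnames = list(NULL, names(fit$sds)))
    .Random.seed_restore(old)
    # per-draw attribute utility: mean part fixed, add sd * z per random term
    x_prog <- numeric(length(fit$sds))
    names(x_prog) <- names(fit$sds)
    for (at in catalog$attributes) {
      if (at$coding == "continuous") next
      x <- effects_code(catalog, at$name, as.character(program[[at$name]]))
      keep <- intersect(names(x), names(x_prog))
      x_prog[keep] <- x[keep]
    }
    dev <- drop(Zd %*% (fit$sds * x_prog))
    prob <- mean(stats::plogis(v_amount + pu$v_attr + dev - delta))
  }
  structure(list(program = program, probability = prob,
                 n_draws = if (means_only) 0L else n_draws, seed = seed,
                 means_only = means_only),
            class = "uptake_prediction")
}

#' Predicted uptake across incentive amounts
#'
#' Applies [predict_uptake()] to each amount with a shared seed, yielding a
#' grid suitable for plotting the uptake curve and for export.
#'
#' @param fit,catalog,unit,n_draws,seed,means_only as in [predict_uptake()].
#' @param base_program named list of categorical levels (and optionally
#'   `income_group`); its `amount` entry is ignored.
#' @param amounts vector of amounts in pounds (non-empty, non-negative).
#' @return data frame with columns `amount` and `uptake`.
#' @export
uptake_curve <- function(fit, base_program, amounts, catalog, unit = 10,
                         n_draws = 2000L, seed = 1L, means_only = FALSE) {
  if (length(amounts) == 0L) stop("amounts must be non-empty")
  if (any(amounts < 0)) stop("amounts must be non-negative")
  up <- vapply(amounts, function(a) {
    pr <- base_program; pr$amount <- a
    predict_uptake(fit, pr, catalog, unit = unit, n_draws = n_draws,
                   seed = seed, means_only = means_only)$probability
  }, numeric(1))
  data.frame(amount = amounts, uptake = up)
}

#' Enrolment-indifference amount
#'
#' The amount at which, at the mean coefficients, the utility of the given
#' program equals the utility of opting out:
#' `amount = unit * (delta_income - V_attributes) / alpha_income`. At this
#' amount the means-only enrolment probability is exactly one half. With no
#' `base_program` the "mean program" is used: under effects coding its
#' attribute utility is zero, so the indifference amount reduces to the
#' ASC-to-amount coefficient ratio.
#'
#' @param fit a [fit_mixed_logit()] result.
#' @param base_program optional named list of categorical levels (and
#'   `income_group`).
#' @param unit rescale unit in pounds.
#' @param catalog a [dce_catalog()]; required when `base_program` is given.
#' @return amount in pounds (scalar).
#' @export
indifference_amount <- function(fit, base_program = NULL, unit = 10,
                                catalog = NULL) {
  income <- if (!is.null(base_program)) base_program$income_group %||% "low" else "low"
  alpha <- amount_coef_income(fit, income)
  if (alpha <= 0) stop("amount coefficient must be positive for a finite indifference amount")
  delta <- asc_income(fit, income)
  v_attr <- 0
  if (!is.null(base_program)) {
    if (is.null(catalog)) stop("catalog required with a base_program")
    v_attr <- program_utility(base_program, catalog, unit, fit$estimates)$v_attr
  }
  unit * (delta - v_attr) / alpha
}
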