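#' Halton quasi-random sequences
#'
#' Radical-inverse (van der Corput) sequences in the first `dim` prime bases,
#' with the first `skip` points of each dimension discarded. All values lie
#' strictly in (0, 1).
#'
#' @param n number of points.
#' @param dim number of dimensions (at most 25).
#' @param skip number of initial points to discard (burn-in).
#' @return an `n` by `dim` matrix.
#' @examples
#' halton_sequence(3, 2)  # base 2: 1/2 1/4 3/4; base 3: 1/3 2/3 1/9
#' @export
halton_sequence <- function(n, dim, skip = 0L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47,
              53, 59, 61, 67, 71, 73, 79, 83, 89, 97)
  if (dim > length(primes)) stop("dim exceeds the prime table (max 25)")
  if (n < 1L) stop("n must be at least 1")
  radical_inverse <- function(idx, base) {
    out <- numeric(length(idx))
    f <- 1 / base
    i <- idx
    while (any(i > 0)) {
      out <- out + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    out
  }
  idx <- seq_len(n) + skip
  vapply(seq_len(dim), function(d) radical_inverse(idx, primes[d]),
         numeric(n))
}

#' Normal draws for maximum simulated likelihood
#'
#' Builds the respondent-by-draw array of standard-normal deviates used by
#' [simulated_loglik()] and [fit_mixed_logit()]: Halton points in one prime
#' base per random term, transformed by the normal quantile function, with
#' consecutive blocks of `R` points per respondent.
#'
#' @param n_resp number of respondents (panels).
#' @param n_random number of random coefficients.
#' @param R draws per respondent.
#' @param type `"halton"` (default) or `"pseudo"` (seeded `rnorm`).
#' @param skip Halton burn-in.
#' @param seed seed for `type = "pseudo"` (recorded either way).
#' @return array of dimension `c(R, n_random, n_resp)` with attributes
#'   `type`, `R`, `skip`, `seed`.
#' @export
make_draws <- function(n_resp, n_random, R, type = c("halton", "pseudo"),
                       skip = 100L, seed = 1L) {
  type <- match.arg(type)
  if (R < 1L) stop("R must be at least 1")
  Z <- if (n_random == 0L) {
    array(0, dim = c(R, 0L, n_resp))
  } else if (type == "halton") {
    H <- halton_sequence(n_resp * R, n_random, skip = skip)
    Q <- stats::qnorm(H)
    array(aperm(array(Q, dim = c(R, n_resp, n_random)), c(1, 3, 2)),
          dim = c(R, n_random, n_resp))
  } else {
    old <- .Random.seed_save()
    set.seed(seed)
    out <- array(stats::rnorm(R * n_random * n_resp),
                 dim = c(R, n_random, n_resp))
    .Random.seed_restore(old)
    out
  }
  attr(Z, "type") <- type; attr(Z, "R") <- R
  attr(Z, "skip") <- skip; attr(Z, "seed") <- seed
  Z
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# internal: index structures from an encoded dataset (3 rows per task,
# tasks grouped by respondent); validates the layout
encoded_index <- function(data) {
  if (nrow(data) %% 3L != 0L) stop("encoded data must have 3 rows per task")
  ord <- order(match(data$respondent_id, unique(data$respondent_id)),
               data$task_id, match(data$alt, c("A", "B", "optout")))
  data <- data[ord, , drop = FALSE]
  n_tasks <- nrow(data) / 3L
  alt_idx <- rep(1:3, n_tasks)
  chosen_mat <- matrix(data$chosen, nrow = 3L)
  if (!all(colSums(chosen_mat) == 1L))
    stop("each task must have exactly one chosen alternative")
  chosen <- max.col(t(chosen_mat)) - 1L
  task_resp <- data$respondent_id[seq(1L, nrow(data), by = 3L)]
  resp_ids <- unique(task_resp)
  n_per_resp <- as.integer(table(factor(task_resp, levels = resp_ids)))
  resp_task_start <- c(0L, cumsum(n_per_resp))
  list(data = data, n_tasks = n_tasks, chosen = as.integer(chosen),
       resp_ids = resp_ids, resp_task_start = as.integer(resp_task_start))
}

model_matrix_encoded <- function(data, terms) {
  miss <- setdiff(terms, names(data))
  if (length(miss)) stop("encoded data missing columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(data)[, terms, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite values in model columns")
  X
}

#' Conditional (multinomial) logit log-likelihood
#'
#' The closed-form panel-free logit log-likelihood
#' `sum_t log(exp(V_chosen)/sum_j exp(V_j))`, computed with max-subtraction.
#' Serves as the independent oracle for the simulated likelihood in the
#' degenerate (zero standard deviation) case.
#'
#' @param params named coefficient vector over model columns.
#' @param data an `encoded_data` data frame (any number of alternatives per
#'   task; tasks identified by `respondent_id` and `task_id`, exactly one
#'   `chosen = 1` row each).
#' @return the log-likelihood (scalar).
#' @export
mnl_loglik <- function(params, data) {
  X <- model_matrix_encoded(data, names(params))
  V <- drop(X %*% params)
  if (any(!is.finite(V))) stop("non-finite utilities")
  task <- interaction(data$respondent_id, data$task_id, drop = TRUE)
  groups <- split(seq_along(V), task)
  sum(vapply(groups, function(g) {
    c <- g[data$chosen[g] == 1L]
    if (length(c) != 1L) stop("each task must have exactly one chosen alternative")
    vmax <- max(V[g])
    V[c] - vmax - log(sum(exp(V[g] - vmax)))
  }, numeric(1)))
}

# fast internal path: data already validated/sorted to 3 rows per task
mnl_ll3 <- function(params, X, chosen, n_tasks) {
  V <- matrix(drop(X %*% params), nrow = 3L)
  vmax <- apply(V, 2L, max)
  lse <- vmax + log(colSums(exp(sweep(V, 2L, vmax))))
  sum(V[cbind(chosen + 1L, seq_len(n_tasks))] - lse)
}

mnl_gr3 <- function(params, X, chosen, n_tasks) {
  V <- matrix(drop(X %*% params), nrow = 3L)
  vmax <- apply(V, 2L, max)
  E <- exp(sweep(V, 2L, vmax))
  P <- sweep(E, 2L, colSums(E), "/")
  y <- matrix(0, 3L, n_tasks)
  y[cbind(chosen + 1L, seq_len(n_tasks))] <- 1
  drop(crossprod(X, as.vector(y - P)))
}

fit_mnl <- function(X, chosen, n_tasks, terms, maxit = 300L) {
  start <- stats::setNames(numeric(length(terms)), terms)
  opt <- stats::optim(start,
                      function(p) -mnl_ll3(p, X, chosen, n_tasks),
                      function(p) -mnl_gr3(p, X, chosen, n_tasks),
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  stats::setNames(opt$par, terms)
}

#' Panel-simulated mixed logit log-likelihood
#'
#' `sum_i log[(1/R) sum_r prod_t P_it(beta_ir)]` with
#' `beta_irk = b_k + w_k * z_irk`, task products accumulated in log space
#' and draws shared across a respondent's tasks (panel structure).
#'
#' @param params named vector: means for every model column, then one
#'   `sd_<term>` entry per random term.
#' @param data an `encoded_data` data frame.
#' @param draws a [make_draws()] array with one column per random term (in
#'   the order of the `sd_` entries) and one slice per respondent.
#' @param random_terms character vector of random-coefficient columns.
#' @return the simulated log-likelihood (scalar).
#' @export
simulated_loglik <- function(params, data, draws, random_terms) {
  terms <- setdiff(names(params), paste0("sd_", random_terms))
  idx <- encoded_index(data)
  X <- model_matrix_encoded(idx$data, terms)
  theta <- c(params[terms], params[paste0("sd_", random_terms)])
  rand_cols <- match(random_terms, terms) - 1L
  if (anyNA(rand_cols)) stop("random terms must be among the model columns")
  if (dim(draws)[3] != length(idx$resp_ids))
    stop("draws must have one slice per respondent")
  msl_loglik_cpp(as.numeric(theta), t(X), idx$chosen, idx$resp_task_start,
                 draws, as.integer(rand_cols), FALSE)$loglik
}

#' Mixed logit model specification
#'
#' @param fixed_terms model columns entering with fixed coefficients (the
#'   amount, the opt-out ASC and the income interactions).
#' @param random_terms model columns with normally distributed individual
#'   coefficients (the effects-coded attribute columns).
#' @param n_draws simulation draws per respondent (default 500).
#' @param draw_type `"halton"` (default) or `"pseudo"`.
#' @param halton_skip Halton burn-in (default 100).
#' @param panel share draws across a respondent's tasks (default `TRUE`;
#'   `FALSE` treats every task as its own panel).
#' @param seed recorded seed (drives `"pseudo"` draws).
#' @param maxit,gtol optimizer settings: BFGS iteration cap and the gradient
#'   max-norm below which the fit is declared converged.
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(fixed_terms, random_terms, n_draws = 500L,
                       draw_type = c("halton", "pseudo"), halton_skip = 100L,
                       panel = TRUE, seed = 1L, maxit = 500L, gtol = 1e-2) {
  draw_type <- match.arg(draw_type)
  if (length(intersect(fixed_terms, random_terms)))
    stop("fixed and random term sets must be disjoint")
  if (n_draws < 1L) stop("n_draws must be at least 1")
  structure(list(fixed_terms = fixed_terms, random_terms = random_terms,
                 n_draws = as.integer(n_draws), draw_type = draw_type,
                 halton_skip = as.integer(halton_skip), panel = panel,
                 seed = as.integer(seed), maxit = as.integer(maxit),
                 gtol = gtol), class = "model_spec")
}

#' @param catalog a [dce_catalog()]; random terms are its effects-coded
#'   columns, fixed terms the amount, ASC and income interactions.
#' @param ... passed to [model_spec()].
#' @rdname model_spec
#' @export
default_model_spec <- function(catalog, ...) {
  amt <- continuous_attr(catalog)
  model_spec(
    fixed_terms = c(amt, "asc", "amount_x_middle", "amount_x_high",
                    "asc_x_middle", "asc_x_high"),
    random_terms = setdiff(coded_columns(catalog), amt), ...)
}

# central-difference Hessian of an analytic gradient function
num_hessian <- function(grad_fn, theta) {
  p <- length(theta)
  H <- matrix(0, p, p)
  h <- 1e-4 * pmax(abs(theta), 0.01)
  for (j in seq_len(p)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    H[, j] <- (grad_fn(tp) - grad_fn(tm)) / (2 * h[j])
  }
  (H + t(H)) / 2
}

#' Fit a panel mixed logit by maximum simulated likelihood
#'
#' Maximizes the simulated log-likelihood by BFGS with the analytic
#' gradient, warm-started from the conditional-logit estimates (random-term
#' standard deviations initialized at 0.1). Standard deviations are
#' identified only up to sign and are reported as absolute values. Standard
#' errors come from the inverse numerical Hessian at the optimum; a robust
#' (sandwich) variant is not implemented.
#'
#' @param spec a [model_spec()].
#' @param data an `encoded_data` data frame.
#' @return object of class `"mixlogit_fit"`: `estimates` (named means, fixed
#'   and random), `sds` (named, non-negative), `se_estimates`, `se_sds`,
#'   `vcov` (over `c(means, sds)` free parameters), `loglik`, `n_obs`,
#'   `n_respondents`, `converged`, `gradient_norm`, `draws_used`, `spec`.
#' @export
fit_mixed_logit <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  terms <- c(spec$fixed_terms, spec$random_terms)
  idx <- encoded_index(data)
  X <- model_matrix_encoded(idx$data, terms)
  # identifiability screen: model columns must not be collinear
  if (qr(X)$rank < ncol(X))
    stop("model columns are linearly dependent; model not identifiable")
  Kr <- length(spec$random_terms)
  rand_cols <- match(spec$random_terms, terms) - 1L

  if (spec$panel) {
    resp_task_start <- idx$resp_task_start
    n_panels <- length(idx$resp_ids)
  } else {
    n_panels <- idx$n_tasks
    resp_task_start <- 0:idx$n_tasks
  }
  Z <- make_draws(n_panels, Kr, spec$n_draws, type = spec$draw_type,
                  skip = spec$halton_skip, seed = spec$seed)

  Xt <- t(X)
  mnl_start <- fit_mnl(X, idx$chosen, idx$n_tasks, terms)
  theta0 <- c(mnl_start, stats::setNames(rep(0.1, Kr),
                                         paste0("sd_", spec$random_terms)))

  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    key <- paste(format(theta, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- msl_loglik_cpp(theta, Xt, idx$chosen,
                                  as.integer(resp_task_start), Z,
                                  as.integer(rand_cols), TRUE)
      cache$key <- key
    }
    cache$val
  }
  fn <- function(theta) -evaluate(theta)$loglik
  gr <- function(theta) -evaluate(theta)$gradient
  opt <- stats::optim(theta0, fn, gr, method = "BFGS",
                      control = list(maxit = spec$maxit, reltol = 1e-10))
  theta_hat <- opt$par
  K <- length(terms)
  # |w| identifiability: report the non-negative representative
  if (Kr > 0L) theta_hat[K + seq_len(Kr)] <- abs(theta_hat[K + seq_len(Kr)])
  final <- msl_loglik_cpp(theta_hat, Xt, idx$chosen,
                          as.integer(resp_task_start), Z,
                          as.integer(rand_cols), TRUE)
  gnorm <- max(abs(final$gradient))

  grad_only <- function(theta) -msl_loglik_cpp(theta, Xt, idx$chosen,
                                               as.integer(resp_task_start), Z,
                                               as.integer(rand_cols), TRUE)$gradient
  H <- num_hessian(grad_only, theta_hat)
  vcov <- tryCatch(solve(H), error = function(e) NULL)
  se_flagged <- FALSE
  if (is.null(vcov) || any(diag(vcov) < 0)) {
    vcov <- MASS::ginv(H)
    se_flagged <- TRUE
  }
  par_names <- c(terms, paste0("sd_", spec$random_terms))
  dimnames(vcov) <- list(par_names, par_names)
  se <- sqrt(pmax(diag(vcov), 0))

  structure(list(
    estimates = stats::setNames(theta_hat[seq_len(K)], terms),
    sds = stats::setNames(theta_hat[K + seq_len(Kr)], spec$random_terms),
    se_estimates = stats::setNames(se[seq_len(K)], terms),
    se_sds = stats::setNames(se[K + seq_len(Kr)], spec$random_terms),
    vcov = vcov,
    loglik = final$loglik,
    n_obs = idx$n_tasks,
    n_respondents = length(idx$resp_ids),
    converged = opt$convergence == 0L && gnorm < spec$gtol * max(1, abs(final$loglik)),
    gradient_norm = gnorm,
    se_flagged = se_flagged,
    draws_used = list(type = spec$draw_type, R = spec$n_draws,
                      skip = spec$halton_skip, seed = spec$seed),
    spec = spec), class = "mixlogit_fit")
}

#' @export
print.mixlogit_fit <- function(x, ...) {
  cat("Panel mixed logit (maximum simulated likelihood)\n")
  cat("  respondents:", x$n_respondents, "  tasks:", x$n_obs,
      "  draws:", x$draws_used$R, paste0("(", x$draws_used$type, ")"), "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " converged:", x$converged, "\n\n")
  est <- data.frame(Estimate = round(x$estimates, 3),
                    SE = round(x$se_estimates, 3))
  est$SD <- NA_real_; est$SD_SE <- NA_real_
  est[names(x$sds), "SD"] <- round(x$sds, 3)
  est[names(x$sds), "SD_SE"] <- round(x$se_sds, 3)
  print(est)
  invisible(x)
}

#' @export
logLik.mixlogit_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates) + length(object$sds),
            class = "logLik")
}

#' @export
coef.mixlogit_fit <- function(object, ...) c(object$estimates,
                                             stats::setNames(object$sds,
                                                             paste0("sd_", names(object$sds))))

#' @export
vcov.mixlogit_fit <- function(object, ...) object$vcov

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Effects table with omitted-level estimates
#'
#' Presents the fitted means attribute by attribute. The omitted level's
#' estimate is the negative sum of the estimated levels of the same
#' attribute (zero-sum property of effects coding) and carries no standard
#' error. Stars mark two-sided normal tests at .05/.01/.001.
#'
#' @param fit a [fit_mixed_logit()] result.
#' @param catalog a [dce_catalog()].
#' @return data frame of class `"effects_table"` with columns `attribute`,
#'   `level`, `term`, `estimate`, `se`, `p`, `stars`, `sd`, `sd_se`,
#'   `sd_stars`, `omitted`.
#' @export
report_effects_table <- function(fit, catalog) {
  rows <- list()
  add_row <- function(attribute, level, term, estimate, se, sd = NA_real_,
                      sd_se = NA_real_, omitted = FALSE) {
    p <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(estimate / se))
    sd_p <- if (is.na(sd_se) || sd_se == 0) NA_real_ else 2 * stats::pnorm(-abs(sd / sd_se))
    rows[[length(rows) + 1L]] <<- data.frame(
      attribute = attribute, level = level, term = term,
      estimate = estimate, se = se, p = p,
      stars = if (is.na(p)) "" else p_stars(p),
      sd = sd, sd_se = sd_se,
      sd_stars = if (is.na(sd_p)) "" else p_stars(sd_p),
      omitted = omitted, stringsAsFactors = FALSE)
  }
  for (a in catalog$attributes) {
    if (a$coding == "continuous") {
      term <- a$name
      add_row(a$name, "(continuous)", term, fit$estimates[[term]],
              fit$se_estimates[[term]])
      next
    }
    lv <- setdiff(a$levels, a$omitted_level)
    terms <- paste0(a$name, "_", sanitize_label(lv))
    miss <- setdiff(terms, names(fit$estimates))
    if (length(miss)) stop("fit does not cover coded columns: ",
                           paste(miss, collapse = ", "))
    for (j in seq_along(lv)) {
      add_row(a$name, lv[j], terms[j], fit$estimates[[terms[j]]],
              fit$se_estimates[[terms[j]]],
              sd = if (terms[j] %in% names(fit$sds)) fit$sds[[terms[j]]] else NA_real_,
              sd_se = if (terms[j] %in% names(fit$se_sds)) fit$se_sds[[terms[j]]] else NA_real_)
    }
    add_row(a$name, a$omitted_level, NA_character_,
            -sum(fit$estimates[terms]), NA_real_, omitted = TRUE)
  }
  for (term in intersect(c("asc", "amount_x_middle", "amount_x_high",
                           "asc_x_middle", "asc_x_high"),
                         names(fit$estimates))) {
    add_row("(constants)", term, term, fit$estimates[[term]],
            fit$se_estimates[[term]])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("effects_table", "data.frame")
  out
}

#' @export
print.effects_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = digits, format = "f"))
  cat(sprintf("%-12s %-14s %16s %14s\n", "Attribute", "Level",
              "Estimate (SE)", "SD (SE)"))
  for (i in seq_len(nrow(df))) {
    est <- paste0(fmt(df$estimate[i]),
                  if (!is.na(df$se[i])) paste0(" (", fmt(df$se[i]), ")", df$stars[i]) else "")
    sd <- if (!is.na(df$sd[i]))
      paste0(fmt(df$sd[i]), " (", fmt(df$sd_se[i]), ")", df$sd_stars[i]) else ""
    cat(sprintf("%-12s %-14s %16s %14s\n", df$attribute[i], df$level[i], est, sd))
  }
  invisible(x)
}
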