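#' Population preference parameters for cohort simulation
#'
#' Houses the data-generating parameters of the panel random utility model:
#' population means and standard deviations of the normally distributed
#' individual coefficients on the effects-coded attributes, a fixed amount
#' coefficient (per rescaled-pound unit) with income-group interactions, and
#' a fixed opt-out alternative-specific constant (ASC) with income-group
#' interactions. Low income is the reference group and carries no
#' interaction terms.
#'
#' @param means named numeric vector over the coded categorical columns.
#' @param sds named non-negative numeric vector over the same columns.
#' @param amount_coef amount coefficient per rescale unit (fixed, no SD).
#' @param asc_optout opt-out constant (fixed, no SD).
#' @param amount_by_income named vector with elements `middle` and `high`.
#' @param asc_by_income named vector with elements `middle` and `high`.
#' @return an object of class `"true_preferences"`.
#' @export
true_preferences <- function(means, sds, amount_coef, asc_optout,
                             amount_by_income = c(middle = 0, high = 0),
                             asc_by_income = c(middle = 0, high = 0)) {
  if (!identical(sort(names(means)), sort(names(sds))))
    stop("means and sds must cover the same coded columns")
  if (any(sds < 0)) stop("negative sd")
  stopifnot(all(c("middle", "high") %in% names(amount_by_income)),
            all(c("middle", "high") %in% names(asc_by_income)))
  structure(list(means = means, sds = sds[names(means)],
                 amount_coef = amount_coef, asc_optout = asc_optout,
                 amount_by_income = amount_by_income,
                 asc_by_income = asc_by_income),
            class = "true_preferences")
}

#' Published-magnitude default preferences
#'
#' Means and SDs for the coded columns of [default_catalog()], an amount
#' coefficient of 0.046 per 10-pound unit, an opt-out ASC of 1.102 and the
#' income interactions, so that simulated cohorts carry the magnitudes the
#' estimation stage is expected to recover.
#'
#' @return a [true_preferences()] object.
#' @export
default_true_preferences <- function() {
  true_preferences(
    means = c(type_Cash = 0.331, schedule_Consistent = 0.067,
              sessions_1_fortnight = 0.221, sessions_1_week = 0.273,
              sessions_2_week = 0.114, location_Healthcare = 0.124),
    sds = c(type_Cash = 0.416, schedule_Consistent = 0.120,
            sessions_1_fortnight = 0.393, sessions_1_week = 0.290,
            sessions_2_week = 0.022, location_Healthcare = 0.549),
    amount_coef = 0.046, asc_optout = 1.102,
    amount_by_income = c(middle = 0.065, high = 0.007),
    asc_by_income = c(middle = 0.067, high = 0.363))
}

#' Draw one respondent's coefficient vector
#'
#' Random columns are drawn independently `beta_k ~ Normal(mean_k, sd_k^2)`;
#' the amount coefficient and opt-out ASC are fixed at the population value
#' plus the applicable income interaction (middle/high; low is the
#' reference). Uses the current RNG stream.
#'
#' @param prefs a [true_preferences()].
#' @param income one of `"low"`, `"middle"`, `"high"`.
#' @return list of class `"individual_coefs"` with elements `beta` (named
#'   vector), `amount_coef`, `asc`, `income_group`.
#' @export
draw_respondent <- function(prefs, income = c("low", "middle", "high")) {
  income <- match.arg(income)
  beta <- prefs$means + prefs$sds * stats::rnorm(length(prefs$means))
  names(beta) <- names(prefs$means)
  add_amt <- if (income == "low") 0 else prefs$amount_by_income[[income]]
  add_asc <- if (income == "low") 0 else prefs$asc_by_income[[income]]
  structure(list(beta = beta,
                 amount_coef = prefs$amount_coef + add_amt,
                 asc = prefs$asc_optout + add_asc,
                 income_group = income),
            class = "individual_coefs")
}

#' Deterministic utilities of one choice set for one respondent
#'
#' `V_alt = alpha_i * amount/unit + sum_k beta_ik x_alt,k` for the two
#' program alternatives and `V_optout = asc_i` (the ASC plus any income
#' interaction, already folded into the individual coefficients).
#'
#' @param coefs an [draw_respondent()] result (or a hand-built list with the
#'   same fields).
#' @param choice_set a two-row design data frame (positions A and B).
#' @param catalog a [dce_catalog()].
#' @param unit rescale unit in pounds.
#' @return named numeric vector `c(A = , B = , optout = )`.
#' @export
task_utilities <- function(coefs, choice_set, catalog, unit = 10) {
  amt <- continuous_attr(catalog)
  util_of <- function(pos) {
    row <- choice_set[choice_set$position == pos, , drop = FALSE]
    if (nrow(row) != 1L) stop("choice set must have one row per position")
    v <- 0
    for (a in catalog$attributes) {
      if (a$coding == "continuous") {
        amount <- as.numeric(row[[a$name]])
        if (!amount %in% a$levels)
          stop("unknown level '", amount, "' of attribute '", a$name, "'")
        v <- v + coefs$amount_coef * amount / unit
      } else {
        x <- effects_code(catalog, a$name, as.character(row[[a$name]]))
        v <- v + sum(coefs$beta[names(x)] * x)
      }
    }
    v
  }
  c(A = util_of("A"), B = util_of("B"), optout = coefs$asc)
}

#' Simulate one two-stage task response
#'
#' Draws one of the three alternatives (program A, program B, opt-out) with
#' logit probabilities `exp(V_j)/sum exp(V)`. When the opt-out is drawn, the
#' reported preferred program is the larger-utility program (tie goes to A)
#' and `enroll = "no"`; otherwise the drawn program is preferred and
#' `enroll = "yes"`. `method = "gumbel"` instead adds independent standard
#' Gumbel noise to each utility and takes the argmax, which induces the same
#' choice distribution.
#'
#' @param coefs individual coefficients.
#' @param choice_set,catalog,unit as in [task_utilities()].
#' @param method `"softmax"` (default) or `"gumbel"`.
#' @return list with `preferred` ("A"/"B") and `enroll` ("yes"/"no").
#' @export
simulate_task <- function(coefs, choice_set, catalog, unit = 10,
                          method = c("softmax", "gumbel")) {
  method <- match.arg(method)
  V <- task_utilities(coefs, choice_set, catalog, unit)
  draw <- if (method == "softmax") {
    p <- exp(V - max(V)); p <- p / sum(p)
    sample(3L, 1L, prob = p)
  } else {
    which.max(V - log(-log(stats::runif(3L))))
  }
  if (draw == 3L) {
    list(preferred = if (V[["B"]] > V[["A"]]) "B" else "A", enroll = "no")
  } else {
    list(preferred = c("A", "B")[draw], enroll = "yes")
  }
}

#' Cohort configuration
#'
#' @param n_per_income named integer vector `c(low=, middle=, high=)`.
#' @param design a blocked [dce_design] (tasks per respondent = block size).
#' @param catalog a [dce_catalog()].
#' @param prefs a [true_preferences()].
#' @param planted named counts `c(nontrader=, dominance_failer=,
#'   never_enroller=)` of aberrant respondents to plant (disjoint types).
#' @param seed integer seed; mandatory for reproducible cohorts.
#' @param unit rescale unit in pounds.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_income, design, catalog, prefs,
                          planted = c(nontrader = 0L, dominance_failer = 0L,
                                      never_enroller = 0L),
                          seed, unit = 10) {
  stopifnot(all(c("low", "middle", "high") %in% names(n_per_income)))
  for (nm in c("nontrader", "dominance_failer", "never_enroller"))
    if (is.na(planted[nm])) planted[nm] <- 0L
  if (sum(planted) > sum(n_per_income))
    stop("planted counts exceed the total number of respondents")
  structure(list(n_per_income = n_per_income, design = design,
                 catalog = catalog, prefs = prefs,
                 planted = planted[c("nontrader", "dominance_failer",
                                     "never_enroller")],
                 seed = seed, unit = unit),
            class = "cohort_config")
}

#' Simulate a full study cohort
#'
#' Respondents are stratified by income group and assigned to blocks in
#' rotation within each group, so per income-by-block counts differ by at
#' most one. Each respondent answers every set of their block plus the
#' dominance-check set. Behaviour types: `nontrader` reports the same
#' position on every set; `dominance_failer` fails the dominance check but
#' otherwise responds from the model; `never_enroller` reports
#' `enroll = "no"` everywhere (preferred program still utility-maximizing);
#' all others respond from the model with a passing dominance check.
#' A respondent who would trip a cleaning rule by chance rather than by
#' plan receives a minimal deterministic repair (one preference flipped on
#' the most utility-balanced task, or one enrolment granted on the most
#' favourable task) so that planted counts are exact without conditioning
#' the joint response distribution. Fully reproducible from the config
#' seed.
#'
#' @param config a [cohort_config()].
#' @return a `study_data` data frame: one row per respondent-by-set with
#'   columns `respondent_id`, `income_group`, `block`, `behavior_type`,
#'   `set_id`, `preferred`, `enroll`, `dominance_response`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  design <- config$design
  catalog <- config$catalog
  unit <- config$unit
  dom_set <- build_dominance_set(catalog, dominant_position = "A")
  blocks <- sort(unique(design$block))
  sets_by_block <- lapply(blocks, function(b)
    sort(unique(design$set_id[design$block == b])))
  names(sets_by_block) <- as.character(blocks)

  incomes <- rep(c("low", "middle", "high"),
                 times = config$n_per_income[c("low", "middle", "high")])
  n <- length(incomes)
  block_of <- integer(n)
  for (g in c("low", "middle", "high")) {
    idx <- which(incomes == g)
    block_of[idx] <- blocks[((seq_along(idx) - 1L) %% length(blocks)) + 1L]
  }
  behavior <- rep("model", n)
  n_planted <- sum(config$planted)
  if (n_planted > 0L) {
    # spread planted types over evenly spaced respondent ids so each income
    # group and block receives some of each type
    slots <- unique(round(seq(1L, n, length.out = n_planted)))
    k <- 1L
    while (length(slots) < n_planted) { # guard against rounding collisions
      if (!(k %in% slots)) slots <- c(slots, k)
      k <- k + 1L
    }
    slots <- sort(slots[seq_len(n_planted)])
    behavior[slots] <- rep(c("nontrader", "dominance_failer", "never_enroller"),
                           times = config$planted)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sets <- sets_by_block[[as.character(block_of[i])]]
    n_tasks <- length(sets)
    coefs <- draw_respondent(config$prefs, incomes[i])
    preferred <- character(n_tasks); enroll <- character(n_tasks)
    V <- matrix(0, n_tasks, 3L)
    for (t in seq_along(sets)) {
      cs <- design[design$set_id == sets[t], , drop = FALSE]
      V[t, ] <- task_utilities(coefs, cs, catalog, unit)
      r <- simulate_task(coefs, cs, catalog, unit)
      preferred[t] <- r$preferred; enroll[t] <- r$enroll
    }
    if (behavior[i] == "nontrader") preferred[] <- "A"
    if (behavior[i] == "never_enroller") enroll[] <- "no"
    # Exact planted counts require that no other respondent trips a
    # cleaning rule by chance. Rather than resampling whole response
    # vectors (which conditions the joint distribution and induces
    # spurious preference heterogeneity), apply a minimal local repair:
    # flip the single most utility-balanced preference, or grant the
    # single most enrolment-favourable "yes".
    if (behavior[i] != "nontrader" && n_tasks > 1L &&
        length(unique(preferred)) == 1L) {
      t_flip <- which.min(abs(V[, 1L] - V[, 2L]))
      preferred[t_flip] <- if (preferred[t_flip] == "A") "B" else "A"
    }
    if (behavior[i] != "never_enroller" && all(enroll == "no")) {
      enroll[which.max(pmax(V[, 1L], V[, 2L]) - V[, 3L])] <- "yes"
    }
    rows[[i]] <- data.frame(
      respondent_id = i, income_group = incomes[i], block = block_of[i],
      behavior_type = behavior[i], set_id = sets,
      preferred = preferred, enroll = enroll,
      dominance_response = if (behavior[i] == "dominance_failer") "fail" else "pass",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("study_data", "data.frame")
  attr(out, "dominance_set") <- dom_set
  out
}

#' Read or write study data as CSV
#'
#' Columns: `respondent_id`, `income_group`, `block`, `behavior_type`
#' (synthetic bookkeeping only, ignored by the analysis), `set_id`,
#' `preferred`, `enroll`, `dominance_response`.
#'
#' @param data a `study_data` data frame.
#' @param path CSV path.
#' @export
write_study_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "income_group", "block", "set_id", "preferred",
            "enroll", "dominance_response")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("study data missing columns: ", paste(miss, collapse = ", "))
  class(df) <- c("study_data", "data.frame")
  df
}
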