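# Shared builders for small, fully hand-checkable inputs.

# one effects-coded binary attribute
binary_catalog <- function() {
  dce_catalog(list(
    attribute_spec("t", c("lo", "hi"), omitted_level = "lo",
                   preference_direction = c("lo", "hi"))))
}

# two effects-coded binary attributes
two_binary_catalog <- function() {
  dce_catalog(list(
    attribute_spec("x", c("x0", "x1"), omitted_level = "x0"),
    attribute_spec("y", c("y0", "y1"), omitted_level = "y0")))
}

# single continuous attribute: utilities are amount_coef * amount / unit,
# handy for exact softmax arithmetic
money_catalog <- function(levels = c(0, 5, 10)) {
  dce_catalog(list(attribute_spec("amount", levels, coding = "continuous",
                                  preference_direction = "increasing")))
}

money_set <- function(a_amt, b_amt, set_id = 1L) {
  data.frame(set_id = set_id, block = 1L, position = c("A", "B"),
             amount = c(a_amt, b_amt), stringsAsFactors = FALSE)
}

money_coefs <- function(amount_coef, asc) {
  structure(list(beta = stats::setNames(numeric(0), character(0)),
                 amount_coef = amount_coef, asc = asc, income_group = "low"),
            class = "individual_coefs")
}

# hand-built study_data rows: one respondent's responses
respondent_rows <- function(id, preferred, enroll, dominance = "pass",
                            income = "low", block = 1L) {
  n <- length(preferred)
  data.frame(respondent_id = id, income_group = income, block = block,
             behavior_type = "model", set_id = seq_len(n),
             preferred = preferred, enroll = rep_len(enroll, n),
             dominance_response = dominance, stringsAsFactors = FALSE)
}

as_study <- function(...) {
  df <- do.call(rbind, list(...))
  class(df) <- c("study_data", "data.frame")
  df
}

# minimal encoded_data: one column "x", utilities V = x * params[["x"]];
# vlist gives per-task utility triples (A, B, optout), chosen in 1..3
encoded_from_v <- function(vlist, chosen) {
  n <- length(vlist)
  df <- data.frame(
    respondent_id = rep(seq_len(n), each = 3L),
    task_id = rep(seq_len(n), each = 3L),
    set_id = rep(seq_len(n), each = 3L),
    alt = rep(c("A", "B", "optout"), n),
    chosen = as.integer(unlist(lapply(seq_len(n), function(i)
      seq_len(3L) == chosen[i]))),
    x = unlist(vlist), stringsAsFactors = FALSE)
  class(df) <- c("encoded_data", "data.frame")
  attr(df, "n_obs") <- n
  df
}

# a small simulated-and-encoded dataset for estimator tests; cached per
# session so several test blocks can share it
small_encoded <- local({
  cache <- new.env(parent = emptyenv())
  function(n_per_income = 60L, sds_zero = FALSE, seed = 301L) {
    key <- paste(n_per_income, sds_zero, seed)
    if (is.null(cache[[key]])) {
      catalog <- default_catalog()
      prefs <- default_true_preferences()
      if (sds_zero) prefs$sds[] <- 0
      design <- generate_design(catalog, 30, 3, seed = seed, n_restarts = 2)
      cfg <- cohort_config(
        c(low = n_per_income, middle = n_per_income, high = n_per_income),
        design, catalog, prefs, seed = seed + 1L)
      data <- simulate_cohort(cfg)
      enc <- to_long_format(clean_study(data)$data, design, catalog)
      cache[[key]] <- list(encoded = enc, design = design, catalog = catalog,
                           prefs = prefs)
    }
    cache[[key]]
  }
})

# a fitted-model stand-in with hand-set parameters for post-estimation tests
fake_fit <- function(estimates, sds = numeric(0), vcov = NULL) {
  nm <- c(names(estimates),
          if (length(sds)) paste0("sd_", names(sds)))
  if (is.null(vcov)) {
    vcov <- diag(0, length(nm))
    dimnames(vcov) <- list(nm, nm)
  }
  structure(list(estimates = estimates, sds = sds,
                 se_estimates = stats::setNames(sqrt(diag(vcov))[seq_along(estimates)],
                                                names(estimates)),
                 se_sds = stats::setNames(rep(NA_real_, length(sds)), names(sds)),
                 vcov = vcov, loglik = NA_real_, converged = TRUE),
            class = "mixlogit_fit")
}

table2_truth <- function() {
  c(amount = 0.046, asc = 1.102, amount_x_middle = 0.065,
    amount_x_high = 0.007, asc_x_middle = 0.067, asc_x_high = 0.363,
    type_Cash = 0.331, schedule_Consistent = 0.067,
    sessions_1_fortnight = 0.221, sessions_1_week = 0.273,
    sessions_2_week = 0.114, location_Healthcare = 0.124)
}
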