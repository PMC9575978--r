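#' Exclusion cascade and descriptive enrolment statistics
#'
#' Respondents are removed in a fixed order, each rule applied to the
#' survivors of the previous one, and each removal attributed to the first
#' rule that caught it: (1) nontraders — constant preferred position across
#' all tasks (always A or always B); (2) dominance-check failures; (3)
#' universal opt-outs — `enroll = "no"` on every task.
#'
#' @name exclusion_cascade
NULL

split_ids <- function(data) split(seq_len(nrow(data)), data$respondent_id)

#' @param data a `study_data` data frame.
#' @return `detect_nontraders()` and `detect_never_enrollers()` return the
#'   flagged respondent ids.
#' @rdname exclusion_cascade
#' @export
detect_nontraders <- function(data) {
  by_id <- split(data$preferred, data$respondent_id)
  ids <- names(by_id)[vapply(by_id, function(p) length(unique(p)) == 1L,
                             logical(1))]
  methods_cast_id(ids, data)
}

#' @rdname exclusion_cascade
#' @export
detect_never_enrollers <- function(data) {
  by_id <- split(data$enroll, data$respondent_id)
  ids <- names(by_id)[vapply(by_id, function(e) all(e == "no"), logical(1))]
  methods_cast_id(ids, data)
}

#' @rdname exclusion_cascade
#' @export
apply_dominance_filter <- function(data) {
  if (!"dominance_response" %in% names(data) || anyNA(data$dominance_response))
    stop("dominance_response must be recorded for every respondent")
  by_id <- split(data$dominance_response, data$respondent_id)
  ids <- names(by_id)[vapply(by_id, function(d) any(d == "fail"), logical(1))]
  methods_cast_id(ids, data)
}

methods_cast_id <- function(ids, data) {
  if (is.numeric(data$respondent_id)) as.numeric(ids) else ids
}

#' Apply the full exclusion cascade
#'
#' @param data a `study_data` data frame.
#' @param order character vector giving the cascade order (default
#'   nontraders, then dominance failures, then never-enrollers); exposed for
#'   sensitivity analyses only.
#' @return list with `data` (the cleaned `study_data`) and `report` (class
#'   `"cleaning_report"`): input/removed/final counts and the removed ids
#'   per rule, each respondent attributed to the first rule removing them.
#' @export
clean_study <- function(data, order = c("nontrader", "dominance", "never_enroller")) {
  stopifnot(setequal(order, c("nontrader", "dominance", "never_enroller")))
  n_input <- length(unique(data$respondent_id))
  removed <- list(nontrader = NULL, dominance = NULL, never_enroller = NULL)
  surv <- data
  for (rule in order) {
    ids <- switch(rule,
                  nontrader = detect_nontraders(surv),
                  dominance = apply_dominance_filter(surv),
                  never_enroller = detect_never_enrollers(surv))
    removed[[rule]] <- ids
    surv <- surv[!surv$respondent_id %in% ids, , drop = FALSE]
  }
  class(surv) <- c("study_data", "data.frame")
  report <- structure(list(
    n_input = n_input,
    n_nontraders_removed = length(removed$nontrader),
    n_dominance_removed = length(removed$dominance),
    n_never_enrollers_removed = length(removed$never_enroller),
    n_final = length(unique(surv$respondent_id)),
    removed_ids = removed,
    order = order), class = "cleaning_report")
  list(data = surv, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Exclusion cascade (", paste(x$order, collapse = " -> "), ")\n", sep = "")
  cat("  input respondents:     ", x$n_input, "\n")
  cat("  nontraders removed:    ", x$n_nontraders_removed, "\n")
  cat("  dominance failures:    ", x$n_dominance_removed, "\n")
  cat("  never-enrollers:       ", x$n_never_enrollers_removed, "\n")
  cat("  final evaluable sample:", x$n_final, "\n")
  invisible(x)
}

round_half_up <- function(x, digits) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Descriptive enrolment statistics
#'
#' Computed on the sample retained after the nontrader and dominance
#' exclusions but before the never-enroller exclusion, so universal
#' opt-outs contribute to the denominator. Percentages are rounded half-up
#' to two decimals for display.
#'
#' @param data `study_data` after nontrader and dominance exclusions.
#' @return list of class `"enrollment_stats"`: counts and percentages of
#'   all-enroll and never-enroll respondents and the overall fraction of
#'   "would enroll" responses.
#' @export
describe_enrollment <- function(data) {
  by_id <- split(data$enroll, data$respondent_id)
  denom <- length(by_id)
  n_always <- sum(vapply(by_id, function(e) all(e == "yes"), logical(1)))
  n_never <- sum(vapply(by_id, function(e) all(e == "no"), logical(1)))
  structure(list(
    n_always_enroll = n_always,
    pct_always_enroll = round_half_up(100 * n_always / denom, 2),
    n_never_enroll = n_never,
    pct_never_enroll = round_half_up(100 * n_never / denom, 2),
    pct_enroll_responses = round_half_up(100 * mean(data$enroll == "yes"), 2),
    denominator_n = denom), class = "enrollment_stats")
}

#' @export
print.enrollment_stats <- function(x, ...) {
  cat(sprintf("Willing to enroll in all programs: %.2f%% (n = %d)\n",
              x$pct_always_enroll, x$n_always_enroll))
  cat(sprintf("Would not enroll in any program:   %.2f%% (n = %d)\n",
              x$pct_never_enroll, x$n_never_enroll))
  cat(sprintf("'Would enroll' responses overall:  %.2f%% (of %d respondents)\n",
              x$pct_enroll_responses, x$denominator_n))
  invisible(x)
}

estimation_columns <- function(catalog) {
  c(continuous_attr(catalog),
    setdiff(coded_columns(catalog), continuous_attr(catalog)),
    "asc", "amount_x_middle", "amount_x_high", "asc_x_middle", "asc_x_high")
}

#' Encode cleaned study data into the three-alternative long format
#'
#' Each respondent-task becomes three rows (program A, program B, opt-out).
#' Program rows carry the rescaled amount, the effects-coded attribute
#' columns and amount-by-income interaction columns; the opt-out row carries
#' `asc = 1` and ASC-by-income interaction columns, with every attribute
#' column zero (so program utilities are expressed relative to the attribute
#' mean under effects coding). The chosen alternative is the opt-out when
#' `enroll = "no"`, else the preferred program.
#'
#' @param data cleaned `study_data`.
#' @param design the blocked design the respondents answered.
#' @param catalog a [dce_catalog()].
#' @param unit rescale unit in pounds.
#' @return an `encoded_data` data frame with columns `respondent_id`,
#'   `task_id`, `set_id`, `alt`, `chosen` and the model columns; attribute
#'   `n_obs` gives the respondent-task count (rows = 3 * n_obs).
#' @export
to_long_format <- function(data, design, catalog, unit = 10) {
  if (nrow(data) == 0L) stop("no respondents to encode")
  unknown <- setdiff(unique(data$set_id), unique(design$set_id))
  if (length(unknown))
    stop("responses reference unknown set ids: ", paste(unknown, collapse = ", "))
  amt <- continuous_attr(catalog)
  cat_cols <- setdiff(coded_columns(catalog), amt)

  # coded rows for every set in the design, positions A and B
  sets <- sort(unique(design$set_id))
  coded_by_set <- lapply(sets, function(s) {
    cs <- design[design$set_id == s, , drop = FALSE]
    lapply(c(A = "A", B = "B"), function(pos) {
      row <- cs[cs$position == pos, , drop = FALSE]
      code_profile(as.list(row[1, attr_names(catalog)]), catalog,
                   unit = unit, center_amount = FALSE)
    })
  })
  names(coded_by_set) <- as.character(sets)

  n_obs <- nrow(data)
  cols <- estimation_columns(catalog)
  X <- matrix(0, nrow = 3L * n_obs, ncol = length(cols),
              dimnames = list(NULL, cols))
  alt <- rep(c("A", "B", "optout"), n_obs)
  chosen <- integer(3L * n_obs)
  is_mid <- data$income_group == "middle"
  is_high <- data$income_group == "high"
  for (i in seq_len(n_obs)) {
    base <- 3L * (i - 1L)
    coded <- coded_by_set[[as.character(data$set_id[i])]]
    for (j in 1:2) {
      v <- coded[[j]]
      X[base + j, names(v)] <- v
      X[base + j, "amount_x_middle"] <- v[[amt]] * is_mid[i]
      X[base + j, "amount_x_high"] <- v[[amt]] * is_high[i]
    }
    X[base + 3L, "asc"] <- 1
    X[base + 3L, "asc_x_middle"] <- as.numeric(is_mid[i])
    X[base + 3L, "asc_x_high"] <- as.numeric(is_high[i])
    chosen[base + if (data$enroll[i] == "no") 3L else match(data$preferred[i], c("A", "B"))] <- 1L
  }
  out <- data.frame(respondent_id = rep(data$respondent_id, each = 3L),
                    task_id = rep(seq_len(n_obs), each = 3L),
                    set_id = rep(data$set_id, each = 3L),
                    alt = alt, chosen = chosen, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X))
  class(out) <- c("encoded_data", "data.frame")
  attr(out, "n_obs") <- n_obs
  attr(out, "unit") <- unit
  out
}

#' @export
print.encoded_data <- function(x, ...) {
  cat("Encoded choice data:", attr(x, "n_obs"), "respondent-tasks,",
      nrow(x), "alternative rows,",
      length(unique(x$respondent_id)), "respondents\n")
  utils::str(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Read or write encoded data as CSV
#'
#' @param data an `encoded_data` data frame.
#' @param path CSV path.
#' @export
write_encoded_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_encoded_csv
#' @export
read_encoded_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("encoded_data", "data.frame")
  attr(df, "n_obs") <- nrow(df) / 3L
  df
}
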