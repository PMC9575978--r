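#' Attribute catalogs for paired choice designs
#'
#' An attribute catalog lists the attributes of the hypothetical programs and
#' the levels each may take. Exactly one attribute may be continuous (the
#' incentive amount, in pounds); all others are categorical and effects coded
#' against a declared omitted level. An optional `preference_direction`
#' (ordering of levels from worst to best, or `"increasing"`/`"decreasing"`
#' for the continuous attribute) is used only to construct dominance-check
#' sets and to reject dominated pairs during design search.
#'
#' @param name attribute name (unique within a catalog).
#' @param levels ordered vector of level labels; numeric and strictly
#'   increasing for a continuous attribute.
#' @param coding `"effects"` (categorical, default) or `"continuous"`.
#' @param omitted_level reference level for effects coding (categorical
#'   attributes only; defaults to the first level).
#' @param preference_direction optional: for categorical attributes a
#'   permutation of `levels` ordered worst to best; for continuous
#'   attributes `"increasing"` or `"decreasing"`.
#' @return `attribute_spec()` returns an object of class `"attribute_spec"`;
#'   `dce_catalog()` an object of class `"dce_catalog"`.
#' @examples
#' cat5 <- default_catalog()
#' coded_columns(cat5)
#' @export
attribute_spec <- function(name, levels, coding = c("effects", "continuous"),
                           omitted_level = NULL, preference_direction = NULL) {
  coding <- match.arg(coding)
  if (length(levels) < 2L) stop("attribute '", name, "' needs at least 2 levels")
  if (coding == "continuous") {
    levels <- as.numeric(levels)
    if (anyNA(levels) || any(diff(levels) <= 0))
      stop("continuous levels must be numeric and strictly increasing")
    if (!is.null(preference_direction) &&
        !preference_direction %in% c("increasing", "decreasing"))
      stop("continuous preference_direction must be 'increasing' or 'decreasing'")
  } else {
    levels <- as.character(levels)
    if (anyDuplicated(levels)) stop("duplicate levels in attribute '", name, "'")
    if (is.null(omitted_level)) omitted_level <- levels[1L]
    if (!omitted_level %in% levels)
      stop("omitted_level '", omitted_level, "' is not a level of '", name, "'")
    if (!is.null(preference_direction) &&
        !setequal(preference_direction, levels))
      stop("preference_direction must be a permutation of the levels of '", name, "'")
  }
  structure(list(name = name, levels = levels, coding = coding,
                 omitted_level = if (coding == "effects") omitted_level else NULL,
                 preference_direction = preference_direction),
            class = "attribute_spec")
}

#' @param attributes list of [attribute_spec()] objects.
#' @rdname attribute_spec
#' @export
dce_catalog <- function(attributes) {
  if (length(attributes) == 0L) stop("catalog has no attributes")
  stopifnot(all(vapply(attributes, inherits, logical(1), "attribute_spec")))
  nm <- vapply(attributes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("attribute names must be unique")
  if (sum(vapply(attributes, function(a) a$coding == "continuous", logical(1))) > 1L)
    stop("at most one continuous attribute is permitted")
  names(attributes) <- nm
  structure(list(attributes = attributes), class = "dce_catalog")
}

#' @export
print.dce_catalog <- function(x, ...) {
  cat("Choice attribute catalog (", length(x$attributes), " attributes)\n", sep = "")
  for (a in x$attributes) {
    cat("  ", a$name, " [", a$coding, "]: ",
        paste(a$levels, collapse = "; "), sep = "")
    if (!is.null(a$omitted_level)) cat("  (omitted: ", a$omitted_level, ")", sep = "")
    cat("\n")
  }
  invisible(x)
}

attr_names <- function(catalog) names(catalog$attributes)

continuous_attr <- function(catalog) {
  for (a in catalog$attributes) if (a$coding == "continuous") return(a$name)
  NULL
}

sanitize_label <- function(x) {
  x <- gsub("[^A-Za-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Coded design columns of a catalog
#'
#' Effects coding gives each L-level categorical attribute L-1 columns named
#' `<attribute>_<level>` for the non-omitted levels; the continuous attribute
#' contributes a single column carrying its own name.
#'
#' @param catalog a [dce_catalog()].
#' @return character vector of coded column names, in catalog order.
#' @export
coded_columns <- function(catalog) {
  unlist(lapply(catalog$attributes, function(a) {
    if (a$coding == "continuous") return(a$name)
    lv <- setdiff(a$levels, a$omitted_level)
    paste0(a$name, "_", sanitize_label(lv))
  }), use.names = FALSE)
}

#' Effects-code one level of a categorical attribute
#'
#' Non-omitted level k maps to +1 in its own column and 0 elsewhere; the
#' omitted level maps to -1 in every column, so each column sums to zero over
#' a balanced enumeration of levels and the omitted level's implied estimate
#' is the negative sum of the others.
#'
#' @param catalog a [dce_catalog()].
#' @param attribute name of a categorical attribute.
#' @param level a level label of that attribute.
#' @return named numeric vector of length L-1.
#' @examples
#' effects_code(default_catalog(), "type", "Cash")
#' @export
effects_code <- function(catalog, attribute, level) {
  a <- catalog$attributes[[attribute]]
  if (is.null(a)) stop("unknown attribute '", attribute, "'")
  if (a$coding != "effects") stop("'", attribute, "' is not effects coded")
  lv <- setdiff(a$levels, a$omitted_level)
  out <- stats::setNames(numeric(length(lv)), paste0(a$name, "_", sanitize_label(lv)))
  if (identical(as.character(level), a$omitted_level)) {
    out[] <- -1
  } else if (as.character(level) %in% lv) {
    out[paste0(a$name, "_", sanitize_label(as.character(level)))] <- 1
  } else {
    stop("unknown level '", level, "' of attribute '", attribute, "'")
  }
  out
}

#' Rescale an incentive amount
#'
#' The incentive amount enters the model as a continuous variable divided by
#' a rescale unit (default 10 pounds) so coefficients are of interpretable
#' magnitude; the rescaling has no effect on the substantive relationships.
#'
#' @param amount_gbp amount(s) in pounds, non-negative.
#' @param unit positive rescale unit in pounds.
#' @return `amount_gbp / unit`.
#' @export
rescale_amount <- function(amount_gbp, unit = 10) {
  if (unit <= 0) stop("rescale unit must be positive")
  if (any(amount_gbp < 0)) stop("negative amount")
  amount_gbp / unit
}

#' Code a profile into the design-column basis
#'
#' @param profile named list or vector mapping attribute name to level.
#' @param catalog a [dce_catalog()].
#' @param unit rescale unit in pounds for the continuous attribute.
#' @param center_amount if `TRUE`, center the continuous attribute at the
#'   mean of its catalog levels (used inside the null-prior D-error).
#' @return named numeric vector over [coded_columns()].
#' @export
code_profile <- function(profile, catalog, unit = 10, center_amount = FALSE) {
  out <- numeric(0)
  for (a in catalog$attributes) {
    lev <- profile[[a$name]]
    if (is.null(lev) || is.na(lev)) stop("profile missing attribute '", a$name, "'")
    if (a$coding == "continuous") {
      lev <- as.numeric(lev)
      if (!lev %in% a$levels) stop("unknown level '", lev, "' of attribute '", a$name, "'")
      ctr <- if (center_amount) mean(a$levels) else 0
      v <- stats::setNames((lev - ctr) / unit, a$name)
    } else {
      v <- effects_code(catalog, a$name, as.character(lev))
    }
    out <- c(out, v)
  }
  out
}

#' Enumerate the full factorial of profiles
#'
#' @param catalog a [dce_catalog()].
#' @return data frame with one row per profile and one column per attribute,
#'   in deterministic lexicographic order by catalog order (the last
#'   attribute varies fastest).
#' @export
enumerate_profiles <- function(catalog) {
  if (length(catalog$attributes) == 0L) stop("catalog has no attributes")
  lv <- lapply(catalog$attributes, `[[`, "levels")
  grid <- expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(lv)), drop = FALSE]
  names(grid) <- attr_names(catalog)
  rownames(grid) <- NULL
  grid
}

#' The five-attribute incentive-program catalog
#'
#' Incentive amount (7 levels, 50 to 1000 pounds, continuous), incentive type
#' (voucher/cash), reward schedule (escalating with reset/consistent),
#' session frequency (one per fortnight up to three per week) and program
#' location (workplace/healthcare centre). Preference directions (worst to
#' best) follow the direction of the estimated preferences and are used only
#' for dominance construction; they are an analyst assertion, not data.
#'
#' @return a [dce_catalog()].
#' @export
default_catalog <- function() {
  dce_catalog(list(
    attribute_spec("amount", c(50, 100, 200, 350, 500, 750, 1000),
                   coding = "continuous", preference_direction = "increasing"),
    attribute_spec("type", c("Voucher", "Cash"), omitted_level = "Voucher",
                   preference_direction = c("Voucher", "Cash")),
    attribute_spec("schedule", c("Escalating", "Consistent"),
                   omitted_level = "Escalating",
                   preference_direction = c("Escalating", "Consistent")),
    attribute_spec("sessions", c("1_fortnight", "1_week", "2_week", "3_week"),
                   omitted_level = "3_week",
                   preference_direction = c("3_week", "2_week", "1_fortnight", "1_week")),
    attribute_spec("location", c("Workplace", "Healthcare"),
                   omitted_level = "Workplace",
                   preference_direction = c("Workplace", "Healthcare"))
  ))
}

#' Read or write a catalog as YAML or JSON
#'
#' The file holds a top-level `attributes` list with fields `name`, `levels`,
#' `coding`, `omitted_level` and `preference_direction`.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return a [dce_catalog()].
#' @export
read_catalog <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  dce_catalog(lapply(raw$attributes, function(a) {
    attribute_spec(a$name, unlist(a$levels),
                   coding = a$coding %||% "effects",
                   omitted_level = a$omitted_level,
                   preference_direction = if (!is.null(a$preference_direction))
                     unlist(a$preference_direction))
  }))
}

#' @param catalog a [dce_catalog()] to write.
#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  raw <- list(attributes = lapply(catalog$attributes, function(a) {
    out <- list(name = a$name, levels = a$levels, coding = a$coding)
    if (!is.null(a$omitted_level)) out$omitted_level <- a$omitted_level
    if (!is.null(a$preference_direction))
      out$preference_direction <- a$preference_direction
    out
  }))
  names(raw$attributes) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
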