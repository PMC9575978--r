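#' Utility-neutral paired choice designs
#'
#' A blocked design is a data frame with one row per alternative: columns
#' `set_id`, `block`, `position` ("A"/"B") and one column per catalog
#' attribute (level labels verbatim; amounts numeric in pounds). The
#' null-prior (utility-neutral) D-error of a set of paired alternatives is
#' `det(M^-1)^(1/p)` where `p` is the number of coded columns and
#' `M = (1/4) * sum_s z_s z_s'` with `z_s = coded(A) - coded(B)`: the
#' multinomial-logit information matrix for paired sets evaluated at zero
#' coefficients, under which every pair has choice probabilities (1/2, 1/2).
#'
#' @name dce_design
NULL

new_design <- function(df, catalog) {
  df <- as.data.frame(df)
  need <- c("set_id", "block", "position", attr_names(catalog))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design is missing columns: ", paste(miss, collapse = ", "))
  df <- df[order(df$set_id, df$position), need]
  rownames(df) <- NULL
  class(df) <- c("dce_design", "data.frame")
  df
}

design_profiles <- function(design, catalog, position) {
  design[design$position == position, attr_names(catalog), drop = FALSE]
}

coded_matrix <- function(profiles, catalog, unit = 10, center_amount = FALSE) {
  do.call(rbind, lapply(seq_len(nrow(profiles)), function(i)
    code_profile(as.list(profiles[i, , drop = FALSE]), catalog,
                 unit = unit, center_amount = center_amount)))
}

design_z <- function(design, catalog, unit = 10) {
  A <- coded_matrix(design_profiles(design, catalog, "A"), catalog, unit, TRUE)
  B <- coded_matrix(design_profiles(design, catalog, "B"), catalog, unit, TRUE)
  Z <- A - B
  colnames(Z) <- coded_columns(catalog)
  Z
}

d_error_from_z <- function(Z) {
  p <- ncol(Z)
  M <- crossprod(Z) / 4
  if (qr(M)$rank < p) return(Inf)
  ld <- determinant(M, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  exp(-as.numeric(ld$modulus) / p)
}

#' Null-prior D-error of a paired design
#'
#' @param design a design data frame (see [dce_design]); the `block` column
#'   may be absent.
#' @param catalog a [dce_catalog()].
#' @param unit rescale unit (pounds) for the continuous attribute, which is
#'   centered at the mean of its levels inside the information matrix.
#' @return positive real, or `Inf` when the information matrix is singular.
#' @export
d_error_null <- function(design, catalog, unit = 10) {
  if (!"block" %in% names(design)) design$block <- 1L
  d_error_from_z(design_z(new_design(design, catalog), catalog, unit))
}

## -- dominance ---------------------------------------------------------------

direction_rank <- function(a, level) {
  if (a$coding == "continuous") {
    v <- as.numeric(level)
    if (identical(a$preference_direction, "decreasing")) -v else v
  } else {
    match(as.character(level), a$preference_direction)
  }
}

has_all_directions <- function(catalog) {
  all(!vapply(catalog$attributes, function(a) is.null(a$preference_direction),
              logical(1)))
}

# TRUE when x dominates y: at least as good everywhere, strictly better
# everywhere (strict=TRUE) or somewhere (strict=FALSE)
dominates <- function(x, y, catalog, strict = TRUE) {
  d <- vapply(catalog$attributes, function(a) {
    direction_rank(a, x[[a$name]]) - direction_rank(a, y[[a$name]])
  }, numeric(1))
  if (strict) all(d > 0) else all(d >= 0) && any(d > 0)
}

set_is_valid <- function(pa, pb, catalog, reject_dominated, strict) {
  if (identical(unname(unlist(pa)), unname(unlist(pb)))) return(FALSE)
  if (reject_dominated && has_all_directions(catalog)) {
    if (dominates(pa, pb, catalog, strict) || dominates(pb, pa, catalog, strict))
      return(FALSE)
  }
  TRUE
}

#' Construct the dominance-check choice set
#'
#' One additional set in which the dominant alternative is strictly better on
#' every attribute under the supplied preference directions; respondents who
#' do not select it fail the rationality screen. Directions must be asserted
#' for every attribute.
#'
#' @param catalog a [dce_catalog()] with `preference_direction` on every
#'   attribute.
#' @param dominant_position `"A"` or `"B"`.
#' @param set_id set identifier for the returned rows.
#' @return a two-row design data frame (positions A and B, block `NA`).
#' @export
build_dominance_set <- function(catalog, dominant_position = "A", set_id = 0L) {
  if (!has_all_directions(catalog))
    stop("preference_direction must be supplied for every attribute")
  best <- lapply(catalog$attributes, function(a) {
    r <- vapply(a$levels, function(l) direction_rank(a, l), numeric(1))
    a$levels[which.max(r)]
  })
  worst <- lapply(catalog$attributes, function(a) {
    r <- vapply(a$levels, function(l) direction_rank(a, l), numeric(1))
    a$levels[which.min(r)]
  })
  rows <- if (dominant_position == "A") list(best, worst) else list(worst, best)
  df <- data.frame(set_id = set_id, block = NA_integer_, position = c("A", "B"),
                   stringsAsFactors = FALSE)
  for (nm in attr_names(catalog))
    df[[nm]] <- c(rows[[1]][[nm]], rows[[2]][[nm]])
  df
}

## -- search ------------------------------------------------------------------

# per-attribute coding matrices (level index -> coded row), amount centered
attr_codings <- function(catalog, unit) {
  lapply(catalog$attributes, function(a) {
    if (a$coding == "continuous") {
      matrix((a$levels - mean(a$levels)) / unit, ncol = 1)
    } else {
      m <- matrix(0, length(a$levels), length(a$levels) - 1L)
      for (i in seq_along(a$levels))
        m[i, ] <- effects_code(catalog, a$name, a$levels[i])
      m
    }
  })
}

code_from_idx <- function(idx, codings) {
  unlist(lapply(seq_along(codings), function(a) codings[[a]][idx[a], ]),
         use.names = FALSE)
}

idx_valid <- function(ia, ib, catalog, ranks, reject_dominated, strict) {
  if (all(ia == ib)) return(FALSE)
  if (reject_dominated && !is.null(ranks)) {
    d <- vapply(seq_along(ia), function(a) ranks[[a]][ia[a]] - ranks[[a]][ib[a]],
                numeric(1))
    if (strict) {
      if (all(d > 0) || all(d < 0)) return(FALSE)
    } else {
      if ((all(d >= 0) && any(d > 0)) || (all(d <= 0) && any(d < 0))) return(FALSE)
    }
  }
  TRUE
}

#' Generate a blocked utility-neutral design by coordinate exchange
#'
#' Minimizes the null-prior D-error from random starting designs by cycling
#' over sets, alternatives and attributes and accepting any level exchange
#' that lowers the D-error, with multiple restarts. Candidate sets whose
#' alternatives are identical, or where one alternative strictly dominates
#' the other under the catalog's preference directions, are rejected. Sets
#' are then partitioned into equal blocks by a greedy assignment that
#' balances per-block level counts (ties broken by set order).
#'
#' @param catalog a [dce_catalog()].
#' @param n_sets number of paired sets; must be divisible by `n_blocks` and
#'   at least the number of coded columns.
#' @param n_blocks number of blocks.
#' @param seed integer seed for the random starts.
#' @param n_restarts number of random restarts (default 20).
#' @param max_passes maximum exchange passes per restart.
#' @param unit rescale unit for the continuous attribute.
#' @param reject_dominated reject dominated pairs (requires directions on all
#'   attributes to take effect).
#' @param strict_dominance if `TRUE` (default) only strict dominance on every
#'   attribute triggers rejection; if `FALSE`, weak dominance does too.
#' @param balance_spread level-balance constraint: the search starts from a
#'   level-balanced random design and rejects exchanges that would push any
#'   attribute's level-count spread (max minus min count over all
#'   alternatives) above this cap (default 2). Without it, D-optimality
#'   allocates a linearly coded continuous attribute only to its extreme
#'   levels.
#' @param max_overlap diagnostic threshold: warn (and flag) when any
#'   attribute's overlap rate exceeds it.
#' @return a [dce_design] data frame with attributes `diagnostics` (a
#'   [diagnose()] result), `d_error_start` (D-error of the winning restart's
#'   random start) and `flagged` (`TRUE` when diagnostics failed the
#'   thresholds).
#' @export
generate_design <- function(catalog, n_sets, n_blocks, seed = NULL,
                            n_restarts = 20L, max_passes = 25L, unit = 10,
                            reject_dominated = TRUE, strict_dominance = TRUE,
                            balance_spread = 2L, max_overlap = 0.5) {
  if (n_sets %% n_blocks != 0L)
    stop("n_sets must be divisible by n_blocks (equal blocks)")
  codings <- attr_codings(catalog, unit)
  p <- sum(vapply(codings, ncol, integer(1)))
  if (n_sets < p)
    stop("n_sets must be at least the number of coded columns (", p, ")")
  if (!is.null(seed)) set.seed(seed)
  nlev <- vapply(catalog$attributes, function(a) length(a$levels), integer(1))
  na <- length(nlev)
  ranks <- if (has_all_directions(catalog)) {
    lapply(catalog$attributes, function(a)
      vapply(a$levels, function(l) direction_rank(a, l), numeric(1)))
  } else NULL

  set_ok <- function(IA, IB, s)
    idx_valid(IA[s, ], IB[s, ], catalog, ranks, reject_dominated,
              strict_dominance)

  # level-balanced random start: per attribute, a shuffled near-equal
  # allocation of levels over the 2*n_sets alternative slots; invalid sets
  # (identical or dominated pairs) are repaired by balance-preserving swaps
  # of B-side values between sets
  random_start <- function() {
    for (outer_try in seq_len(50L)) {
      IA <- matrix(0L, n_sets, na); IB <- matrix(0L, n_sets, na)
      for (a in seq_len(na)) {
        total <- 2L * n_sets
        base <- total %/% nlev[a]
        cnt <- rep(base, nlev[a])
        extra <- total - base * nlev[a]
        if (extra > 0L) {
          add <- sample.int(nlev[a], extra)
          cnt[add] <- cnt[add] + 1L
        }
        slots <- sample(rep.int(seq_len(nlev[a]), cnt))
        IA[, a] <- slots[seq(1L, total, by = 2L)]
        IB[, a] <- slots[seq(2L, total, by = 2L)]
      }
      for (rep_try in seq_len(500L)) {
        bad <- which(!vapply(seq_len(n_sets), function(s) set_ok(IA, IB, s),
                             logical(1)))
        if (!length(bad)) return(list(IA = IA, IB = IB))
        s <- bad[1L]
        a <- sample.int(na, 1L)
        t <- sample(setdiff(seq_len(n_sets), s), 1L)
        tmp <- IB[s, a]; IB[s, a] <- IB[t, a]; IB[t, a] <- tmp
        if (!set_ok(IA, IB, t) && !set_ok(IA, IB, s)) {  # revert useless swaps
          tmp <- IB[s, a]; IB[s, a] <- IB[t, a]; IB[t, a] <- tmp
        }
      }
    }
    stop("could not construct a valid balanced starting design")
  }

  level_counts_of <- function(IA, IB) {
    lapply(seq_len(na), function(a)
      tabulate(c(IA[, a], IB[, a]), nbins = nlev[a]))
  }

  z_of <- function(IA, IB) {
    t(vapply(seq_len(n_sets), function(s)
      code_from_idx(IA[s, ], codings) - code_from_idx(IB[s, ], codings),
      numeric(p)))
  }

  best <- NULL
  for (rs in seq_len(n_restarts)) {
    st <- random_start()
    IA <- st$IA; IB <- st$IB
    counts <- level_counts_of(IA, IB)
    Z <- z_of(IA, IB)
    d_start <- d_error_from_z(Z)
    d_cur <- d_start
    for (pass in seq_len(max_passes)) {
      improved <- FALSE
      for (s in seq_len(n_sets)) {
        for (side in 1:2) {
          for (a in seq_len(na)) {
            cur_lev <- if (side == 1L) IA[s, a] else IB[s, a]
            best_lev <- cur_lev; best_d <- d_cur
            for (l in seq_len(nlev[a])) {
              if (l == cur_lev) next
              cnt <- counts[[a]]
              cnt[cur_lev] <- cnt[cur_lev] - 1L; cnt[l] <- cnt[l] + 1L
              if (max(cnt) - min(cnt) > balance_spread) next
              ia <- IA[s, ]; ib <- IB[s, ]
              if (side == 1L) ia[a] <- l else ib[a] <- l
              if (!idx_valid(ia, ib, catalog, ranks, reject_dominated,
                             strict_dominance)) next
              Zs <- code_from_idx(ia, codings) - code_from_idx(ib, codings)
              Z2 <- Z; Z2[s, ] <- Zs
              d_new <- d_error_from_z(Z2)
              if (d_new < best_d - 1e-12) { best_d <- d_new; best_lev <- l }
            }
            if (best_lev != cur_lev) {
              if (side == 1L) IA[s, a] <- best_lev else IB[s, a] <- best_lev
              counts[[a]][cur_lev] <- counts[[a]][cur_lev] - 1L
              counts[[a]][best_lev] <- counts[[a]][best_lev] + 1L
              Z[s, ] <- code_from_idx(IA[s, ], codings) -
                code_from_idx(IB[s, ], codings)
              d_cur <- best_d
              improved <- TRUE
            }
          }
        }
      }
      if (!improved) break
    }
    if (is.null(best) || d_cur < best$d) {
      best <- list(IA = IA, IB = IB, d = d_cur, d_start = d_start)
    }
  }

  lev_of <- function(I) {
    out <- vector("list", na)
    for (a in seq_len(na)) out[[a]] <- catalog$attributes[[a]]$levels[I[, a]]
    out
  }
  la <- lev_of(best$IA); lb <- lev_of(best$IB)
  df <- data.frame(set_id = rep(seq_len(n_sets), each = 2L),
                   block = NA_integer_,
                   position = rep(c("A", "B"), n_sets),
                   stringsAsFactors = FALSE)
  for (a in seq_len(na)) {
    nm <- attr_names(catalog)[a]
    col <- vector(if (catalog$attributes[[a]]$coding == "continuous")
      "numeric" else "character", 2L * n_sets)
    col[seq(1L, 2L * n_sets, by = 2L)] <- la[[a]]
    col[seq(2L, 2L * n_sets, by = 2L)] <- lb[[a]]
    df[[nm]] <- col
  }
  df$block <- rep(assign_blocks(df, catalog, n_blocks), each = 2L)
  df <- balance_positions(df, catalog)
  design <- new_design(df, catalog)
  diag <- diagnose(design, catalog, unit = unit)
  flagged <- any(diag$overlap_rate > max_overlap)
  if (flagged)
    warning("design exceeds the overlap threshold on at least one attribute")
  attr(design, "diagnostics") <- diag
  attr(design, "d_error_start") <- best$d_start
  attr(design, "flagged") <- flagged
  design
}

# Alternate which position carries the (direction-score) better alternative
# within each block. The null-prior D-error is invariant under swapping A
# and B, but without this a block can end up with the generally preferable
# alternative at the same position in most of its sets, which makes
# "always chose position A" a likely response pattern rather than the
# aberrant one the nontrader screen is meant to catch. Falls back to a
# seeded coin flip per set when directions are not asserted.
balance_positions <- function(df, catalog, seed = NULL) {
  score <- function(row) {
    s <- 0
    for (a in catalog$attributes) {
      if (is.null(a$preference_direction)) return(NA_real_)
      r <- direction_rank(a, row[[a$name]])
      rng <- vapply(a$levels, function(l) direction_rank(a, l), numeric(1))
      s <- s + (r - min(rng)) / max(max(rng) - min(rng), 1e-9)
    }
    s
  }
  out <- df
  for (b in unique(df$block)) {
    sets <- sort(unique(df$set_id[df$block == b]))
    for (k in seq_along(sets)) {
      rows <- which(df$set_id == sets[k])
      ra <- df[rows[df$position[rows] == "A"], , drop = FALSE]
      rb <- df[rows[df$position[rows] == "B"], , drop = FALSE]
      sa <- score(ra[1, ]); sb <- score(rb[1, ])
      better_at_A <- if (is.na(sa) || is.na(sb) || sa == sb)
        stats::runif(1) < 0.5 else sa > sb
      want_A <- (k %% 2L) == 1L   # odd sets: better alternative at A
      if (better_at_A != want_A) {
        ia <- rows[df$position[rows] == "A"]
        ib <- rows[df$position[rows] == "B"]
        nm <- attr_names(catalog)
        tmp <- out[ia, nm]
        out[ia, nm] <- out[ib, nm]
        out[ib, nm] <- tmp
      }
    }
  }
  out
}

# greedy per-block level balance; processes sets in set_id order, scores a
# placement by the sum of squared per-level counts after placement
assign_blocks <- function(df, catalog, n_blocks) {
  n_sets <- length(unique(df$set_id))
  per_block <- n_sets / n_blocks
  counts <- lapply(catalog$attributes, function(a)
    matrix(0, n_blocks, length(a$levels),
           dimnames = list(NULL, as.character(a$levels))))
  sizes <- integer(n_blocks)
  block_of <- integer(n_sets)
  sets <- sort(unique(df$set_id))
  for (i in seq_along(sets)) {
    rows <- df[df$set_id == sets[i], ]
    open <- which(sizes < per_block)
    score <- vapply(open, function(b) {
      s <- 0
      for (a in seq_along(catalog$attributes)) {
        nm <- attr_names(catalog)[a]
        cnt <- counts[[a]][b, ]
        for (lv in as.character(rows[[nm]])) cnt[lv] <- cnt[lv] + 1
        s <- s + sum(cnt^2)
      }
      s
    }, numeric(1))
    b <- open[which.min(score)]
    for (a in seq_along(catalog$attributes)) {
      nm <- attr_names(catalog)[a]
      for (lv in as.character(rows[[nm]]))
        counts[[a]][b, lv] <- counts[[a]][b, lv] + 1
    }
    sizes[b] <- sizes[b] + 1L
    block_of[i] <- b
  }
  block_of
}

#' Design diagnostics: level balance, overlap, orthogonality, D-error
#'
#' @param design a design data frame.
#' @param catalog a [dce_catalog()].
#' @param unit rescale unit for the continuous attribute.
#' @return a list of class `"dce_diagnostics"`: `level_counts` (per
#'   attribute, counts over all alternatives), `overlap_rate` (per attribute,
#'   fraction of sets with the same level in both alternatives),
#'   `max_abs_column_correlation` over the coded columns, and `d_error`.
#' @export
diagnose <- function(design, catalog, unit = 10) {
  if (!"block" %in% names(design)) design$block <- 1L
  design <- new_design(design, catalog)
  n_sets <- length(unique(design$set_id))
  A <- design_profiles(design, catalog, "A")
  B <- design_profiles(design, catalog, "B")
  level_counts <- lapply(catalog$attributes, function(a) {
    lv <- as.character(a$levels)
    tab <- table(factor(c(as.character(A[[a$name]]), as.character(B[[a$name]])),
                        levels = lv))
    stats::setNames(as.integer(tab), lv)
  })
  overlap <- vapply(catalog$attributes, function(a)
    mean(as.character(A[[a$name]]) == as.character(B[[a$name]])), numeric(1))
  X <- rbind(coded_matrix(A, catalog, unit, TRUE),
             coded_matrix(B, catalog, unit, TRUE))
  keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
  max_cor <- if (sum(keep) >= 2L) {
    C <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(C) <- 0
    max(C)
  } else 0
  structure(list(level_counts = level_counts,
                 overlap_rate = overlap,
                 max_abs_column_correlation = max_cor,
                 d_error = d_error_from_z(design_z(design, catalog, unit))),
            class = "dce_diagnostics")
}

#' @export
print.dce_diagnostics <- function(x, ...) {
  cat("Design diagnostics\n")
  cat("  D-error (null prior):", format(x$d_error, digits = 6), "\n")
  cat("  max |column correlation|:",
      format(x$max_abs_column_correlation, digits = 4), "\n")
  cat("  overlap rate per attribute:\n")
  for (nm in names(x$overlap_rate))
    cat("    ", nm, ": ", sprintf("%.3f", x$overlap_rate[[nm]]), "\n", sep = "")
  cat("  level counts:\n")
  for (nm in names(x$level_counts))
    cat("    ", nm, ": ",
        paste(names(x$level_counts[[nm]]), x$level_counts[[nm]],
              sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read or write a design CSV
#'
#' One row per alternative with columns `set_id`, `block`, `position` and the
#' attribute levels verbatim (amounts as numbers in pounds).
#'
#' @param design a design data frame.
#' @param path CSV file path.
#' @param catalog a [dce_catalog()] used to validate on read.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, catalog) {
  new_design(utils::read.csv(path, stringsAsFactors = FALSE), catalog)
}
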