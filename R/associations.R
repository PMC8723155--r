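#' Two-group tests at a cluster split
#'
#' The three built-in association tests compare the left and the right
#' subcluster of one branching point. Values are passed as vectors named by
#' sample ID; missing values are dropped per side.
#'
#' `fisher_exact()` tests a categorical outcome via the exact conditional
#' test on the levels-by-side contingency table (two-sided; for 2x2 tables
#' the statistic is the conditional odds-ratio estimate). Levels absent
#' after missing-value removal are dropped; for large tables where the exact
#' network algorithm is infeasible a Monte-Carlo p-value with a fixed,
#' reported seed is used.
#'
#' `t_test()` tests a continuous outcome with Welch's unequal-variance
#' two-sample t-test by default (`pooled = TRUE` gives the pooled-variance
#' test).
#'
#' `logrank_test()` tests a survival outcome with the standard two-group
#' log-rank test; the statistic is the chi-squared value
#' (O_left - E_left)^2 / V accumulated over pooled event times, with p from
#' a 1-df chi-squared distribution.
#'
#' @param members_left,members_right character vectors of sample IDs.
#' @param column values named by sample ID. For `logrank_test()`, a data
#'   frame with `time` and `event` columns and sample IDs as row names.
#' @param pooled use the pooled-variance t-test instead of Welch's.
#' @param mc_seed seed for the Monte-Carlo fallback of large Fisher tables.
#' @return a list with `statistic`, `p`, `n_left`, `n_right`, `test`,
#'   per-side `summary_left`/`summary_right` strings, and `status`
#'   (`"ok"` or `"skipped"` with a `reason`).
#' @name split_tests
NULL

test_skip <- function(test, reason, n_left = NA_integer_, n_right = NA_integer_,
                      summary_left = NA_character_, summary_right = NA_character_) {
  list(statistic = NA_real_, p = NA_real_, n_left = n_left, n_right = n_right,
       test = test, summary_left = summary_left, summary_right = summary_right,
       status = "skipped", reason = reason)
}

#' @rdname split_tests
#' @export
fisher_exact <- function(members_left, members_right, column, mc_seed = 20210916) {
  x_l <- column[members_left]
  x_r <- column[members_right]
  x_l <- x_l[!is.na(x_l)]
  x_r <- x_r[!is.na(x_r)]
  sum_str <- function(x) {
    tt <- table(x)
    paste(paste0(names(tt), ":", as.integer(tt)), collapse = ",")
  }
  sl <- sum_str(x_l); sr <- sum_str(x_r)
  if (length(x_l) < 1L || length(x_r) < 1L) {
    return(test_skip("fisher", "no non-missing values on one side",
                     length(x_l), length(x_r), sl, sr))
  }
  levels_all <- sort(unique(c(x_l, x_r)))
  if (length(levels_all) < 2L) {
    return(test_skip("fisher", "fewer than 2 levels after NA removal",
                     length(x_l), length(x_r), sl, sr))
  }
  tab <- rbind(table(factor(x_l, levels = levels_all)),
               table(factor(x_r, levels = levels_all)))
  ft <- tryCatch(stats::fisher.test(tab), error = function(e) NULL)
  test_name <- "fisher"
  if (is.null(ft)) {
    # exact network algorithm infeasible for this table: Monte-Carlo fallback
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(mc_seed)
    ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e5)
    test_name <- paste0("fisher_mc(seed=", mc_seed, ")")
  }
  stat <- if (all(dim(tab) == 2L)) unname(ft$estimate) else NA_real_
  list(statistic = stat, p = ft$p.value,
       n_left = length(x_l), n_right = length(x_r), test = test_name,
       summary_left = sl, summary_right = sr, status = "ok", reason = NA_character_)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' @rdname split_tests
#' @export
t_test <- function(members_left, members_right, column, pooled = FALSE) {
  x_l <- column[members_left]
  x_r <- column[members_right]
  x_l <- x_l[!is.na(x_l)]
  x_r <- x_r[!is.na(x_r)]
  sum_str <- function(x) {
    sprintf("%.3g±%.3g", mean(x), stats::sd(x))
  }
  test_name <- if (pooled) "t_pooled" else "t_welch"
  if (length(x_l) < 2L || length(x_r) < 2L) {
    return(test_skip(test_name, "fewer than 2 non-missing values on one side",
                     length(x_l), length(x_r)))
  }
  sl <- sum_str(x_l); sr <- sum_str(x_r)
  tt <- tryCatch(stats::t.test(x_l, x_r, var.equal = pooled),
                 error = function(e) NULL)
  if (is.null(tt)) {
    return(test_skip(test_name, "constant data (statistic undefined)",
                     length(x_l), length(x_r), sl, sr))
  }
  list(statistic = unname(tt$statistic), p = tt$p.value,
       n_left = length(x_l), n_right = length(x_r), test = test_name,
       summary_left = sl, summary_right = sr, status = "ok", reason = NA_character_)
}

#' @rdname split_tests
#' @export
logrank_test <- function(members_left, members_right, column) {
  stopifnot(is.data.frame(column), all(c("time", "event") %in% names(column)))
  ids <- rownames(column)
  take <- function(members) {
    s <- column[ids %in% members, , drop = FALSE]
    s[stats::complete.cases(s), , drop = FALSE]
  }
  d_l <- take(members_left)
  d_r <- take(members_right)
  sum_str <- function(d) sprintf("%d events/%d", sum(d$event), nrow(d))
  if (nrow(d_l) == 0L || nrow(d_r) == 0L) {
    return(test_skip("logrank", "one side empty after NA removal",
                     nrow(d_l), nrow(d_r)))
  }
  sl <- sum_str(d_l); sr <- sum_str(d_r)
  if (sum(d_l$event) + sum(d_r$event) == 0) {
    return(test_skip("logrank", "no events in pooled data",
                     nrow(d_l), nrow(d_r), sl, sr))
  }
  grp <- factor(c(rep("left", nrow(d_l)), rep("right", nrow(d_r))))
  time <- c(d_l$time, d_r$time)
  event <- c(d_l$event, d_r$event)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- unname(sd$chisq)
  list(statistic = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n_left = nrow(d_l), n_right = nrow(d_r), test = "logrank",
       summary_left = sl, summary_right = sr, status = "ok", reason = NA_character_)
}

#' Run association tests for every valid cluster pair and outcome
#'
#' Dispatches the type-appropriate test (Fisher's exact, Welch's t,
#' log-rank, or a user-supplied custom function) at every valid split
#' against every outcome, and Bonferroni-adjusts the raw p-values by the
#' number of valid cluster pairs. Because the dendrogram partitions the
#' samples into cascaded, non-overlapping groups, the tests across splits
#' are independent, so this factor controls the family-wise error rate
#' per outcome.
#'
#' @param pairs an `sg_splits` tibble with validity flags from
#'   [enumerate_valid_pairs()].
#' @param outcomes an [outcome_table()].
#' @param custom_tests optional named list mapping an outcome name to a
#'   function `f(members_left, members_right, column)` returning a list (or
#'   numeric vector) with elements `statistic` and `p`; the outcome's
#'   built-in dispatch is replaced.
#' @param across_outcomes if `TRUE`, the correction factor additionally
#'   multiplies by the number of outcomes. Off by default: the adjustment
#'   factor is the number of valid cluster pairs only.
#' @param pooled passed to [t_test()].
#' @return a tibble of class `sg_associations` with one row per
#'   (valid pair x outcome): `cid_left`, `cid_right`, `outcome`, `test`,
#'   `statistic`, `p_raw`, `p_adj`, `n_left`, `n_right`, `summary_left`,
#'   `summary_right`, `status`, `reason`. The number of valid pairs is kept
#'   in `attr(, "m")`.
#' @export
run_associations <- function(pairs, outcomes, custom_tests = NULL,
                             across_outcomes = FALSE, pooled = FALSE) {
  stopifnot(inherits(pairs, "sg_splits"), inherits(outcomes, "outcome_table"))
  if (is.null(pairs$is_valid)) {
    stop("run enumerate_valid_pairs() before run_associations()", call. = FALSE)
  }
  valid <- pairs[pairs$is_valid, , drop = FALSE]
  m <- nrow(valid)
  empty <- tibble::tibble(
    cid_left = numeric(), cid_right = numeric(), outcome = character(),
    test = character(), statistic = numeric(), p_raw = numeric(),
    p_adj = numeric(), n_left = integer(), n_right = integer(),
    summary_left = character(), summary_right = character(),
    status = character(), reason = character())
  if (m == 0L) {
    warning("no valid cluster pairs: no tests run", call. = FALSE)
    res <- empty
    attr(res, "m") <- 0L
    class(res) <- c("sg_associations", class(res))
    return(res)
  }
  rows <- list()
  for (i in seq_len(m)) {
    ml <- valid$members_left[[i]]
    mr <- valid$members_right[[i]]
    for (nm in names(outcomes$columns)) {
      col <- outcomes$columns[[nm]]
      type <- outcomes$types[[nm]]
      named <- function(v) stats::setNames(v, outcomes$sample_ids)
      r <- if (!is.null(custom_tests) && nm %in% names(custom_tests)) {
        run_custom_test(custom_tests[[nm]], ml, mr, col, outcomes$sample_ids, nm)
      } else if (nm %in% names(outcomes$untestable)) {
        test_skip(type, outcomes$untestable[[nm]])
      } else if (type == "categorical") {
        fisher_exact(ml, mr, named(col))
      } else if (type == "continuous") {
        t_test(ml, mr, named(col), pooled = pooled)
      } else if (type == "survival") {
        sv <- col
        rownames(sv) <- outcomes$sample_ids
        logrank_test(ml, mr, sv)
      } else {
        test_skip(type, "no test for declared type")
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cid_left = valid$cid_left[i], cid_right = valid$cid_right[i],
        outcome = nm, test = r$test, statistic = r$statistic, p_raw = r$p,
        p_adj = NA_real_, n_left = as.integer(r$n_left),
        n_right = as.integer(r$n_right),
        summary_left = r$summary_left, summary_right = r$summary_right,
        status = r$status, reason = r$reason %||% NA_character_)
    }
  }
  res <- dplyr::bind_rows(rows)
  factor_m <- if (across_outcomes) m * length(outcomes$columns) else m
  res <- bonferroni_adjust(res, factor_m)
  attr(res, "m") <- m
  attr(res, "correction_factor") <- factor_m
  class(res) <- c("sg_associations", class(res))
  res
}

run_custom_test <- function(fn, ml, mr, col, sample_ids, outcome_name) {
  if (is.data.frame(col)) rownames(col) <- sample_ids else names(col) <- sample_ids
  out <- fn(ml, mr, col)
  stat <- unname(out[["statistic"]])
  p <- unname(out[["p"]])
  if (is.null(p) || !is.numeric(p) || is.na(p) || p < 0 || p > 1) {
    stop("custom test for outcome '", outcome_name,
         "' returned a p-value outside [0, 1]", call. = FALSE)
  }
  list(statistic = if (is.null(stat)) NA_real_ else stat, p = p,
       n_left = length(ml), n_right = length(mr), test = "custom",
       summary_left = NA_character_, summary_right = NA_character_,
       status = "ok", reason = NA_character_)
}

#' Bonferroni adjustment over the valid cluster pairs
#'
#' Multiplies each raw p-value by the correction factor `m` (the number of
#' valid cluster pairs, fixed before testing and not reduced by per-outcome
#' missingness) and caps at 1.
#'
#' @param results a results tibble with a `p_raw` column.
#' @param m positive integer correction factor.
#' @return `results` with `p_adj = min(1, p_raw * m)`.
#' @export
bonferroni_adjust <- function(results, m) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 1)
  results$p_adj <- pmin(1, results$p_raw * m)
  results
}

#' @export
print.sg_associations <- function(x, ...) {
  cat("Association results:", nrow(x), "tests over", attr(x, "m"),
      "valid cluster pairs (Bonferroni factor",
      attr(x, "correction_factor") %||% attr(x, "m"), ")\n")
  NextMethod()
}

#' Write association results to a TSV file
#'
#' @param results an `sg_associations` tibble.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(as.data.frame(results), path)
  invisible(path)
}
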