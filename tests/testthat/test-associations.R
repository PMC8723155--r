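test_that("outcome types are inferred from the column class", {
  expect_equal(infer_outcome_type(c("F", "M", "F")), "categorical")
  expect_equal(infer_outcome_type(c(TRUE, FALSE)), "categorical")
  expect_equal(infer_outcome_type(rnorm(20) + 25), "continuous")
  # low-cardinality numeric codes are categorical unless declared otherwise
  expect_equal(infer_outcome_type(rep(c(0, 1, 2), 10)), "categorical")
  expect_error(infer_outcome_type(c(NA, NA)), "missing")

  df <- data.frame(sex = c("F", "M", "F", "M", "F", "M"),
                   bmi = c(21.5, 30.2, 24.4, 28, 26.1, 23.3),
                   grade = c(1, 2, 1, 2, 2, 1), t = c(5, 3, 8, 1, 2, 6),
                   e = c(1, 0, 1, 1, 0, 1), row.names = paste0("s", 1:6))
  ot <- outcome_table(df, survival = list(os = c("t", "e")),
                      types = c(grade = "continuous"))
  expect_equal(unname(ot$types[c("os", "sex", "bmi", "grade")]),
               c("survival", "categorical", "continuous", "continuous"))
  # single-level categorical flagged untestable, not an error
  df2 <- data.frame(x = rep("A", 6), row.names = paste0("s", 1:6))
  expect_match(outcome_table(df2)$untestable[["x"]], "levels")
})

test_that("Fisher test reproduces exact enumeration on known tables", {
  mk <- function(l, r) {
    col <- setNames(c(rep(c("A", "B"), l), rep(c("A", "B"), r)), NULL)
    # build from explicit counts: l = c(nA, nB) on the left, r on the right
    left <- c(rep("A", l[1]), rep("B", l[2]))
    right <- c(rep("A", r[1]), rep("B", r[2]))
    ids_l <- paste0("l", seq_along(left))
    ids_r <- paste0("r", seq_along(right))
    list(ml = ids_l, mr = ids_r,
         col = setNames(c(left, right), c(ids_l, ids_r)))
  }
  flat <- mk(c(1, 1), c(1, 1))
  expect_equal(fisher_exact(flat$ml, flat$mr, flat$col)$p, 1)

  diag2 <- mk(c(2, 0), c(0, 2))
  expect_equal(fisher_exact(diag2$ml, diag2$mr, diag2$col)$p, 1 / 3)

  diag5 <- mk(c(5, 0), c(0, 5))
  expect_equal(fisher_exact(diag5$ml, diag5$mr, diag5$col)$p, 2 / 252)
})

test_that("Fisher p matches the hypergeometric oracle on random 2x2 tables", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    tab <- matrix(rmultinom(1, n, runif(4, 0.1, 1)), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    left <- rep(c("A", "B"), tab[, 1])
    right <- rep(c("A", "B"), tab[, 2])
    ids <- paste0("s", seq_len(n))
    col <- setNames(c(left, right), ids)
    ml <- ids[seq_along(left)]
    mr <- ids[-seq_along(left)]
    res <- fisher_exact(ml, mr, col)
    expect_equal(res$p, oracle_fisher_2x2(t(tab)), tolerance = 1e-10)
  }
})

test_that("Fisher skips degenerate tables and drops empty levels", {
  col <- setNames(c("A", "A", "A", "A"), paste0("s", 1:4))
  r <- fisher_exact(c("s1", "s2"), c("s3", "s4"), col)
  expect_equal(r$status, "skipped")
  expect_match(r$reason, "levels")

  col2 <- setNames(c("A", "B", NA, NA), paste0("s", 1:4))
  r2 <- fisher_exact(c("s1", "s2"), c("s3", "s4"), col2)
  expect_equal(r2$status, "skipped")
  expect_match(r2$reason, "non-missing")
})

test_that("Welch t-test matches the closed form", {
  ids <- paste0("s", 1:6)
  col <- setNames(c(1, 2, 3, 4, 5, 6), ids)
  r <- t_test(ids[1:3], ids[4:6], col)
  expect_equal(r$statistic, -sqrt(27 / 2), tolerance = 1e-6) # -3.674
  expect_equal(r$p, 2 * pt(-sqrt(27 / 2), df = 4), tolerance = 1e-10)
  expect_equal(r$p, 0.0214, tolerance = 1e-2)

  set.seed(21)
  for (i in 1:50) {
    nl <- sample(2:15, 1); nr <- sample(2:15, 1)
    x <- rnorm(nl); y <- rnorm(nr, 0.5)
    ids <- paste0("s", seq_len(nl + nr))
    col <- setNames(c(x, y), ids)
    r <- t_test(ids[seq_len(nl)], ids[nl + seq_len(nr)], col)
    o <- oracle_welch(x, y)
    expect_equal(r$statistic, o$t, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  }
})

test_that("t-test degenerate and symmetry cases behave", {
  ids <- paste0("s", 1:8)
  col <- setNames(c(1, 2, 3, 4, 1, 2, 3, 4), ids)
  r <- t_test(ids[1:4], ids[5:8], col)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  const <- setNames(rep(5, 8), ids)
  expect_equal(t_test(ids[1:4], ids[5:8], const)$status, "skipped")
  expect_equal(t_test(ids[1], ids[2:8], col)$status, "skipped")

  # shifting one group moves t monotonically
  stats <- sapply(c(0, 1, 2), function(shift) {
    t_test(ids[1:4], ids[5:8], col + c(rep(0, 4), rep(shift, 4)))$statistic
  })
  expect_true(all(diff(stats) < 0))
})

test_that("log-rank test matches the O/E/V oracle", {
  sv <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
                   row.names = paste0("s", 1:4))
  r <- logrank_test(c("s1", "s2"), c("s3", "s4"), sv)
  expect_equal(r$statistic, 49 / 17, tolerance = 1e-8)
  expect_equal(r$p, pchisq(49 / 17, 1, lower.tail = FALSE), tolerance = 1e-8)

  set.seed(31)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    nl <- sample(2:(n - 2), 1)
    time <- round(rexp(n, 0.2), 2) + 0.01
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) next
    ids <- paste0("s", seq_len(n))
    sv <- data.frame(time = time, event = event, row.names = ids)
    r <- logrank_test(ids[seq_len(nl)], ids[(nl + 1):n], sv)
    o <- oracle_logrank(time, event, rep(c("L", "R"), c(nl, n - nl)))
    expect_equal(r$statistic, o$chisq, tolerance = 1e-6)
    expect_equal(r$p, o$p, tolerance = 1e-6)
  }
})

test_that("log-rank handles censoring-dominated and degenerate inputs", {
  ids <- paste0("s", 1:8)
  sv <- data.frame(time = rep(c(1, 2, 3, 4), 2), event = rep(1, 8),
                   row.names = ids)
  r <- logrank_test(ids[1:4], ids[5:8], sv)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)

  # censoring all right-side subjects early shrinks the later risk sets
  sv2 <- data.frame(time = c(5, 6, 7, 8, 6, 6, 6, 6),
                    event = c(1, 1, 1, 1, 0, 0, 0, 0), row.names = ids)
  r2 <- logrank_test(ids[1:4], ids[5:8], sv2)
  o2 <- oracle_logrank(sv2$time, sv2$event, rep(c("L", "R"), each = 4))
  expect_equal(r2$statistic, o2$chisq, tolerance = 1e-8)

  none <- data.frame(time = 1:8, event = rep(0, 8), row.names = ids)
  expect_equal(logrank_test(ids[1:4], ids[5:8], none)$status, "skipped")
  sv$time[1:4] <- NA
  expect_equal(logrank_test(ids[1:4], ids[5:8], sv)$status, "skipped")
})

test_that("run_associations emits one row per valid pair and outcome", {
  sim <- small_planted(seed = 5)
  hc <- build_tree(sim$data)
  pairs <- enumerate_valid_pairs(assign_cluster_ids(hc), min_size = 0.1)
  res <- run_associations(pairs, sim$outcome_table)
  m <- attr(pairs, "m")
  expect_equal(nrow(res), m * 3)
  expect_equal(attr(res, "m"), m)
  combos <- paste(res$cid_left, res$outcome)
  expect_false(anyDuplicated(combos) > 0)
  expect_true(all(res$status %in% c("ok", "skipped")))
  ok <- res[res$status == "ok", ]
  expect_true(all(ok$p_raw >= 0 & ok$p_raw <= 1))
  expect_true(all(ok$p_adj >= ok$p_raw))
})

test_that("Bonferroni adjustment multiplies by the valid-pair count, capped", {
  res <- tibble::tibble(p_raw = c(0.01, 0.5, 0.2))
  expect_equal(bonferroni_adjust(res, 5)$p_adj, c(0.05, 1, 1))
  expect_equal(bonferroni_adjust(res, 3)$p_adj, c(0.03, 1, 0.6))
  expect_equal(bonferroni_adjust(res, 1)$p_adj, res$p_raw)

  # factor is the number of valid pairs, not pairs x outcomes
  sim <- small_planted(seed = 6)
  hc <- build_tree(sim$data)
  pairs <- enumerate_valid_pairs(assign_cluster_ids(hc), min_size = 0.1)
  res2 <- run_associations(pairs, sim$outcome_table)
  m <- attr(pairs, "m")
  ok <- res2[res2$status == "ok", ]
  expect_equal(ok$p_adj, pmin(1, ok$p_raw * m))
  # optional across-outcome factor
  res3 <- run_associations(pairs, sim$outcome_table, across_outcomes = TRUE)
  ok3 <- res3[res3$status == "ok", ]
  expect_equal(ok3$p_adj, pmin(1, ok3$p_raw * m * 3))
})

test_that("missingness is isolated to the affected pair and outcome", {
  sim <- small_planted(seed = 8)
  hc <- build_tree(sim$data)
  pairs <- enumerate_valid_pairs(assign_cluster_ids(hc), min_size = 0.1)
  res0 <- run_associations(pairs, sim$outcome_table)
  ot <- sim$outcome_table
  # blank one outcome for the left members of the top split
  top_left <- pairs$members_left[[1]]
  ot$columns$bmi[match(top_left, ot$sample_ids)] <- NA
  res <- run_associations(pairs, ot)
  top_bmi <- res[res$cid_left == 2 & res$outcome == "bmi", ]
  expect_equal(top_bmi$status, "skipped")
  expect_match(top_bmi$reason, "non-missing|fewer")
  # other outcomes are untouched everywhere
  expect_equal(res[res$outcome != "bmi", ], res0[res0$outcome != "bmi", ])
  # bmi stays testable at splits disjoint from the blanked samples
  valid <- pairs[pairs$is_valid, ]
  untouched <- valid$cid_left[vapply(seq_len(nrow(valid)), function(i) {
    !any(c(valid$members_left[[i]], valid$members_right[[i]]) %in% top_left)
  }, logical(1))]
  if (length(untouched) > 0) {
    expect_true(all(res$status[res$outcome == "bmi" &
                                 res$cid_left %in% untouched] == "ok"))
  }
})

test_that("custom test functions are dispatched and validated", {
  sim <- small_planted(seed = 9)
  hc <- build_tree(sim$data)
  pairs <- enumerate_valid_pairs(assign_cluster_ids(hc), min_size = 0.1)
  custom <- list(bmi = function(ml, mr, col) {
    w <- wilcox.test(col[ml], col[mr])
    list(statistic = unname(w$statistic), p = w$p.value)
  })
  res <- run_associations(pairs, sim$outcome_table, custom_tests = custom)
  bmi <- res[res$outcome == "bmi", ]
  expect_true(all(bmi$test == "custom"))
  expect_true(all(bmi$p_raw >= 0 & bmi$p_raw <= 1))

  bad <- list(bmi = function(ml, mr, col) list(statistic = 1, p = 2))
  expect_error(run_associations(pairs, sim$outcome_table, custom_tests = bad),
               "bmi.*outside")
})

test_that("no valid pairs yields an empty result with a warning", {
  hc <- random_tree(6, seed = 1)
  splits <- assign_cluster_ids(hc)
  expect_warning(vp <- enumerate_valid_pairs(splits, min_size = 5), "no valid")
  df <- data.frame(y = rnorm(6), row.names = hc$labels)
  ot <- outcome_table(df)
  expect_warning(res <- run_associations(vp, ot), "no tests run")
  expect_equal(nrow(res), 0L)
})

test_that("the planted outcome wins the top split in most simulations", {
  hits <- 0L
  n_sim <- 30
  for (seed in seq_len(n_sim)) {
    des <- planted_design(
      n_samples = 80, n_features = 40,
      partitions = list(list(parent = 1, fraction = 0.5,
                             features = 1:10, delta_x = 2)),
      outcomes = list(planted = list(type = "continuous", group = 1,
                                     effect = 1.5),
                      noise = list(type = "continuous", group = 1,
                                   effect = 0)),
      seed = seed)
    sim <- generate_planted(des)
    hc <- build_tree(sim$data)
    pairs <- enumerate_valid_pairs(assign_cluster_ids(hc))
    res <- run_associations(pairs, outcome_table(sim$outcomes))
    best <- res[which.min(res$p_raw), ]
    if (best$outcome == "planted" && best$cid_left == 2) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_sim)
})
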