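# Independent brute-force oracles. These recompute expected values from
# first principles and deliberately share no code with the package.

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the same margins whose
# probability does not exceed that of the observed table
oracle_fisher_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == 2L))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_all <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(a_all, function(a) {
    exp(lchoose(r1, a) + lchoose(n - r1, c1 - a) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[a_all == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# closed-form Welch two-sample t-test
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# two-group log-rank chi-squared by explicit O/E/V accumulation over the
# pooled distinct event times
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  g1 <- sort(unique(group))[1L]
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d_tot * n1 / n_tot
    if (n_tot > 1) {
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  chisq <- (o1 - e1)^2 / v
  list(o1 = o1, e1 = e1, v = v, chisq = chisq,
       p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# brute-force valid-pair count: walk the merge table recursively and count
# splits where both children reach min_size
oracle_valid_pair_count <- function(hc, min_size) {
  n <- length(hc$order)
  size_of <- function(child) {
    if (child < 0) 1L
    else sum(vapply(hc$merge[child, ], size_of, integer(1)))
  }
  count <- 0L
  for (i in seq_len(n - 1L)) {
    s <- vapply(hc$merge[i, ], size_of, integer(1))
    if (min(s) >= min_size) count <- count + 1L
  }
  count
}

random_tree <- function(n, seed = NULL, linkage = "complete") {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(paste0("s", seq_len(n)), NULL))
  hclust(dist(x), method = linkage)
}

# small cohort with one planted two-group structure, for viz/pipeline tests
small_planted <- function(seed = 42, n = 60) {
  des <- planted_design(
    n_samples = n, n_features = 30,
    partitions = list(list(parent = 1, fraction = 0.5,
                           features = 1:10, delta_x = 2)),
    outcomes = list(
      bmi = list(type = "continuous", group = 1, effect = 1.5),
      sex = list(type = "categorical", group = 1, effect = 1.2),
      os = list(type = "survival", group = 1, effect = 0.8)),
    seed = seed)
  sim <- generate_planted(des)
  sim$outcome_table <- outcome_table(sim$outcomes, survival = sim$survival)
  sim
}
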