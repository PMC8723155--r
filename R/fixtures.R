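#' Specify a planted-subgroup simulation design
#'
#' Describes a synthetic cohort with nested binary group structure planted
#' into an omics matrix and into clinical outcomes, so the whole
#' cluster-then-test pipeline can be benchmarked against known ground
#' truth. Group labels reuse the heap-style cluster numbering: the full
#' cohort is group 1 and splitting group g yields groups 2g and 2g+1.
#'
#' @param n_samples,n_features cohort and feature-space size.
#' @param partitions list of nested binary partitions, each a list with
#'   `parent` (the group label to split; the first partition splits group 1,
#'   later ones must split a group created earlier, so partitions nest),
#'   `fraction` (share of the parent assigned to the first child, default
#'   0.5), `features` (indices of the affected feature subset) and
#'   `delta_x` (mean shift, in noise-SD units, added to the second child on
#'   those features; effect sizes must be >= 0).
#' @param outcomes named list of planted outcome effects, each a list with
#'   `type` in `c("continuous", "categorical", "survival")`, `group` (the
#'   partition parent whose children the effect separates, default 1) and
#'   `effect`: a continuous mean shift in SD units, a categorical log-odds
#'   shift of the second level, or a survival log hazard ratio.
#' @param censoring expected fraction of censored survival observations,
#'   achieved with independent uniform censoring over a fixed observation
#'   window (default 0.2).
#' @param baseline_hazard exponential event rate in the reference group.
#' @param seed integer seed fixing all randomness of [generate_planted()].
#' @return a list of class `planted_design`.
#' @export
planted_design <- function(n_samples = 200, n_features = 100,
                           partitions = list(list(parent = 1, fraction = 0.5,
                                                  features = 1:20, delta_x = 2)),
                           outcomes = list(y = list(type = "continuous",
                                                    group = 1, effect = 1.5)),
                           censoring = 0.2, baseline_hazard = 0.1,
                           seed = 1L) {
  stopifnot(n_samples >= 4, n_features >= 1)
  known_groups <- 1
  for (p in partitions) {
    p$fraction <- p$fraction %||% 0.5
    p$parent <- p$parent %||% 1
    if (!p$parent %in% known_groups) {
      stop("partition parent ", p$parent, " does not exist yet: partitions ",
           "must nest", call. = FALSE)
    }
    if (length(p$features) == 0L) {
      stop("a partition plants an effect on an empty feature subset", call. = FALSE)
    }
    if (any(p$features < 1 | p$features > n_features)) {
      stop("partition feature indices out of range", call. = FALSE)
    }
    if (p$delta_x < 0) stop("effect sizes must be >= 0", call. = FALSE)
    known_groups <- c(setdiff(known_groups, p$parent), 2 * p$parent, 2 * p$parent + 1)
  }
  for (nm in names(outcomes)) {
    o <- outcomes[[nm]]
    if (!o$type %in% c("continuous", "categorical", "survival")) {
      stop("unknown outcome type for '", nm, "'", call. = FALSE)
    }
  }
  structure(list(n_samples = n_samples, n_features = n_features,
                 partitions = partitions, outcomes = outcomes,
                 censoring = censoring, baseline_hazard = baseline_hazard,
                 seed = seed),
            class = "planted_design")
}

#' Generate a synthetic cohort from a planted design
#'
#' Data are group means plus unit Gaussian noise: every sample starts at 0
#' on every feature, and each partition adds its `delta_x` to the second
#' child's mean on the designated feature subset. Continuous outcomes are
#' standard normal plus the planted shift; categorical outcomes are
#' two-level draws with the planted log-odds shift from a balanced
#' baseline; survival times are exponential with the planted hazard ratio
#' and independent uniform censoring calibrated to the design's expected
#' censoring fraction. All randomness is fixed by the design seed.
#'
#' @param design a [planted_design()].
#' @return a list with `data` (samples x features numeric matrix, sample IDs
#'   `s1..sn`), `outcomes` (data frame, one row per sample; survival
#'   outcomes expand to `<name>_time` and `<name>_event` columns),
#'   `survival` (the declaration list ready for [outcome_table()]) and
#'   `truth` (tibble with the finest planted group of every sample plus the
#'   two-child membership of each partition).
#' @export
generate_planted <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  n <- design$n_samples
  p <- design$n_features
  ids <- paste0("s", seq_len(n))

  group <- rep(1, n)                       # finest group label per sample
  side_of <- list()                        # parent group -> second-child indicator
  for (part in design$partitions) {
    parent <- part$parent %||% 1
    frac <- part$fraction %||% 0.5
    members <- which(group == parent)
    n1 <- round(frac * length(members))
    first <- members[seq_len(n1)]
    second <- setdiff(members, first)
    group[first] <- 2 * parent
    group[second] <- 2 * parent + 1
    ind <- rep(NA, n)
    ind[first] <- 0
    ind[second] <- 1
    side_of[[as.character(parent)]] <- ind
  }

  mu <- matrix(0, n, p)
  for (part in design$partitions) {
    ind <- side_of[[as.character(part$parent %||% 1)]]
    shifted <- which(ind == 1)
    mu[shifted, part$features] <- mu[shifted, part$features] + part$delta_x
  }
  data <- mu + matrix(stats::rnorm(n * p), n, p)
  dimnames(data) <- list(ids, paste0("f", seq_len(p)))

  out_df <- data.frame(row.names = ids)
  survival_decl <- list()
  for (nm in names(design$outcomes)) {
    o <- design$outcomes[[nm]]
    g <- o$group %||% 1
    ind <- side_of[[as.character(g)]]
    if (is.null(ind)) {
      stop("outcome '", nm, "' references group ", g,
           " which no partition splits", call. = FALSE)
    }
    ind[is.na(ind)] <- 0   # samples outside the partitioned group: baseline
    if (o$type == "continuous") {
      out_df[[nm]] <- stats::rnorm(n) + o$effect * ind
    } else if (o$type == "categorical") {
      pr <- stats::plogis(0 + o$effect * ind)
      out_df[[nm]] <- ifelse(stats::rbinom(n, 1, pr) == 1, "B", "A")
    } else {
      rate <- design$baseline_hazard * exp(o$effect * ind)
      t_event <- stats::rexp(n, rate = rate)
      # window W with (1 - exp(-hW)) / (hW) = censoring fraction at baseline
      w <- censor_window(design$censoring) / design$baseline_hazard
      t_cens <- stats::runif(n, 0, w)
      out_df[[paste0(nm, "_time")]] <- pmin(t_event, t_cens)
      out_df[[paste0(nm, "_event")]] <- as.numeric(t_event <= t_cens)
      survival_decl[[nm]] <- c(paste0(nm, "_time"), paste0(nm, "_event"))
    }
  }

  truth <- tibble::tibble(sample_id = ids, group = group)
  for (g in names(side_of)) {
    truth[[paste0("split_", g)]] <- side_of[[g]]
  }

  list(data = data, outcomes = out_df, survival = survival_decl, truth = truth)
}

# solve (1 - exp(-x)) / x = frac for x (dimensionless window length)
censor_window <- function(frac) {
  stopifnot(frac > 0, frac < 1)
  stats::uniroot(function(x) (1 - exp(-x)) / x - frac,
                 lower = 1e-8, upper = 1e6, tol = 1e-10)$root
}
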