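#' Default pipeline configuration
#'
#' @return a named list of the pipeline defaults: Euclidean distance, Ward
#'   linkage, minimum subcluster size of 5% of the sample size, plot
#'   threshold at adjusted p <= 0.05.
#' @export
default_config <- function() {
  list(
    data = NULL,            # paths to data blocks (character vector)
    distance_files = NULL,  # paths to precomputed distance blocks
    outcomes = NULL,        # path to the outcomes table
    survival = list(),      # survival declarations: name = c(time, event)
    types = NULL,           # explicit outcome type declarations
    metric = "euclidean",
    linkage = "ward",
    min_size = 0.05,        # fraction of n (ceiling) or absolute count
    p_threshold = 0.05,
    seed = 1L,
    out_dir = NULL,
    figures = TRUE
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Unset keys fall back to [default_config()]; unknown keys are an error.
#'
#' @param path YAML file.
#' @return a config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  merged <- utils::modifyList(base, cfg)
  if (length(merged$survival) > 0L) {
    merged$survival <- lapply(merged$survival, unlist)
  }
  merged
}

#' Run the full subgroup-identification pipeline
#'
#' Executes cluster -> enumerate valid pairs -> test -> adjust -> export:
#' reads (or accepts in-memory) data and outcomes, builds the tree (fusing
#' multiple distance blocks when more than one input block is given), flags
#' valid cluster pairs, runs all association tests with Bonferroni
#' correction, and writes the results table, merge table, Newick tree,
#' machine-readable summary and (optionally) figures to `out_dir`.
#'
#' @param config a list as produced by [default_config()] /
#'   [read_config()]. In-memory objects may be supplied instead of paths:
#'   `config$data` may be a numeric matrix (or list of matrices),
#'   `config$distance_files` a list of matrices, and `config$outcomes` an
#'   [outcome_table()].
#' @return a list with `tree`, `pairs`, `results`, `summary` and (when
#'   `out_dir` is set) `files`. The summary records n, the number of valid
#'   pairs m, the resolved minimum size, and the significant-association
#'   count at `p_threshold`.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- utils::modifyList(default_config(), config)
  validate_config(config)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- inputs ---------------------------------------------------------
  data_blocks <- stage("read data", load_blocks(config$data, read_omics_matrix))
  dist_blocks <- stage("read distances",
                       load_blocks(config$distance_files, read_distance_matrix))
  outcomes <- stage("read outcomes", {
    if (inherits(config$outcomes, "outcome_table")) config$outcomes
    else if (is.character(config$outcomes)) {
      read_outcomes(config$outcomes, survival = config$survival,
                    types = config$types)
    } else if (is.data.frame(config$outcomes)) {
      outcome_table(config$outcomes, survival = config$survival,
                    types = config$types)
    } else stop("no outcomes given")
  })

  # --- clustering -----------------------------------------------------
  tree <- stage("clustering", {
    dists <- c(lapply(data_blocks, function(x) {
      as.matrix(stats::dist(x, method = config$metric))
    }), dist_blocks)
    if (length(dists) == 0L) stop("no data or distance inputs given")
    if (length(dists) == 1L && length(data_blocks) == 1L) {
      build_tree(data_blocks[[1L]], distance = config$metric,
                 linkage = config$linkage)
    } else if (length(dists) == 1L) {
      build_tree(distance = dists[[1L]], linkage = config$linkage)
    } else {
      fused <- fuse_distances(dists)
      build_tree(distance = fused, linkage = config$linkage)
    }
  })

  # --- enumerate + test ----------------------------------------------
  outcomes <- stage("align outcomes", align_outcomes(outcomes, tree))
  pairs <- stage("enumerate valid pairs", {
    enumerate_valid_pairs(assign_cluster_ids(tree), min_size = config$min_size)
  })
  results <- stage("association tests", run_associations(pairs, outcomes))

  skipped <- results[results$status == "skipped", , drop = FALSE]
  if (nrow(skipped) > 0L) {
    message(nrow(skipped), " test(s) skipped: ",
            paste(unique(stats::na.omit(skipped$reason)), collapse = "; "))
  }

  n_sig <- sum(results$status == "ok" &
                 results$p_adj <= config$p_threshold, na.rm = TRUE)
  summary <- list(
    n = attr(pairs, "n_samples"),
    m_valid_pairs = attr(pairs, "m"),
    min_size_fraction = if (config$min_size < 1) config$min_size else NULL,
    min_size_used = attr(pairs, "min_size_used"),
    p_threshold = config$p_threshold,
    n_tests = nrow(results),
    n_skipped = nrow(skipped),
    n_significant = n_sig,
    seed = config$seed,
    metric = config$metric,
    linkage = config$linkage
  )

  files <- NULL
  if (!is.null(config$out_dir)) {
    files <- stage("export", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      f <- list(
        results = file.path(config$out_dir, "results.tsv"),
        merge_table = file.path(config$out_dir, "merge_table.tsv"),
        newick = file.path(config$out_dir, "tree.nwk"),
        summary = file.path(config$out_dir, "summary.json"))
      write_results(results, f$results)
      write_merge_table(tree, f$merge_table)
      write_newick(tree, f$newick)
      jsonlite::write_json(summary, f$summary, auto_unbox = TRUE, digits = NA)
      if (isTRUE(config$figures)) {
        f$tree_plot <- file.path(config$out_dir, "tree.pdf")
        gg <- plot_tree(tree, results, p_threshold = config$p_threshold)
        ggplot2::ggsave(f$tree_plot, gg, width = 9, height = 5)
      }
      f
    })
  }

  list(tree = tree, pairs = pairs, outcomes = outcomes, results = results,
       summary = summary, files = files)
}

load_blocks <- function(x, reader) {
  if (is.null(x)) return(list())
  if (is.matrix(x)) return(list(x))
  if (is.list(x) && !is.data.frame(x)) return(x)
  if (is.data.frame(x)) return(list(as.matrix(x)))
  if (is.character(x)) return(lapply(x, reader))
  stop("unsupported input block specification", call. = FALSE)
}

validate_config <- function(config) {
  if (config$min_size < 1 && config$min_size >= 0.5) {
    stop("fractional min_size must be below 0.5", call. = FALSE)
  }
  if (config$min_size <= 0) stop("min_size must be positive", call. = FALSE)
  if (config$p_threshold <= 0 || config$p_threshold > 1) {
    stop("p_threshold must be in (0, 1]", call. = FALSE)
  }
  invisible(config)
}
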