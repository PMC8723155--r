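#' Read a samples-by-features omics matrix from CSV/TSV
#'
#' The first column holds the sample IDs and the header row the feature
#' IDs. The delimiter is chosen from the file extension (`.tsv`/`.txt` are
#' tab-separated, anything else comma-separated).
#'
#' @param path file path.
#' @return a numeric matrix with sample IDs as row names.
#' @export
read_omics_matrix <- function(path) {
  tab <- read_delim_auto(path)
  if (ncol(tab) < 2L) stop("matrix file needs a sample-ID column plus at ",
                           "least one feature column", call. = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  feats <- tab[, -1L, drop = FALSE]
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    if (!is.numeric(col)) {
      suppress <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(suppress) & !is.na(col) & col != "NA")[1L]
      if (!is.na(bad)) {
        stop("non-numeric value '", col[bad], "' at row ", bad, " (sample '",
             ids[bad], "'), column '", names(feats)[j], "'", call. = FALSE)
      }
      feats[[j]] <- suppress
    }
  }
  m <- as.matrix(feats)
  rownames(m) <- ids
  m
}

#' Read a clinical outcomes table from CSV/TSV
#'
#' @param path file path; the first column holds the sample IDs.
#' @param survival,types,max_levels passed to [outcome_table()].
#' @return an [outcome_table()].
#' @export
read_outcomes <- function(path, survival = list(), types = NULL,
                          max_levels = 5) {
  tab <- read_delim_auto(path)
  ids <- as.character(tab[[1L]])
  df <- as.data.frame(tab[, -1L, drop = FALSE])
  outcome_table(df, sample_ids = ids, survival = survival, types = types,
                max_levels = max_levels)
}

#' Read a square sample-by-sample distance matrix from CSV/TSV
#'
#' @param path file; first column and header carry matching sample IDs.
#' @return a validated symmetric matrix with zero diagonal.
#' @export
read_distance_matrix <- function(path) {
  tab <- read_delim_auto(path)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  if (!setequal(ids, colnames(m))) {
    stop("row and column sample IDs differ in ", path, call. = FALSE)
  }
  m <- m[, ids, drop = FALSE]
  validate_distance(m)
}

#' Write a matrix with sample-ID row names to CSV
#'
#' @param m matrix with row names.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_omics_matrix <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "sample_id")
  if (grepl("\\.(tsv|txt)$", path)) readr::write_tsv(df, path)
  else readr::write_csv(df, path)
  invisible(path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(tab) == 0L) stop("no data rows in ", path, call. = FALSE)
  tab
}

#' Align an outcome table to the samples of a clustering tree
#'
#' Samples present in the outcomes but absent from the tree are dropped
#' with a warning; tree samples without outcome rows are kept with all
#' outcome values missing, so every leaf is represented.
#'
#' @param outcomes an [outcome_table()].
#' @param tree an [stats::hclust] object with sample labels.
#' @return a re-aligned [outcome_table()] with `sample_ids` equal to the
#'   tree labels.
#' @export
align_outcomes <- function(outcomes, tree) {
  stopifnot(inherits(outcomes, "outcome_table"), inherits(tree, "hclust"))
  leaf_ids <- tree$labels %||% as.character(seq_along(tree$order))
  extra <- setdiff(outcomes$sample_ids, leaf_ids)
  if (length(extra) > 0L) {
    warning(length(extra), " outcome sample(s) not present in the tree were ",
            "ignored: ", paste(utils::head(extra, 5), collapse = ", "),
            call. = FALSE)
  }
  idx <- match(leaf_ids, outcomes$sample_ids)
  columns <- lapply(outcomes$columns, function(col) {
    if (is.data.frame(col)) col[idx, , drop = FALSE] else col[idx]
  })
  structure(list(sample_ids = leaf_ids, columns = columns,
                 types = outcomes$types, untestable = outcomes$untestable),
            class = "outcome_table")
}
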