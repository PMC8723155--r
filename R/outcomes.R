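#' Assemble a clinical outcomes table with typed columns
#'
#' Each clinical outcome is typed as categorical, continuous or survival;
#' the type decides which two-group test is run at every valid cluster pair
#' (Fisher's exact test, Welch's t-test or the log-rank test). Types are
#' inferred from the data but an explicit declaration always wins.
#'
#' Inference rules: logical, character and factor columns are categorical;
#' numeric columns with at most `max_levels` distinct observed values are
#' treated as categorical codes (override by declaring them continuous);
#' all other numeric columns are continuous. Survival outcomes cannot be
#' inferred and must be declared as (time, event) column pairs.
#'
#' @param df data frame of per-sample clinical variables.
#' @param sample_ids sample identifiers aligned to `df` rows; defaults to
#'   `rownames(df)` (or a `sample_id` column if present, which is then
#'   removed from the variables).
#' @param survival named list declaring survival outcomes, each entry a
#'   character pair `c(time_column, event_column)`; the event column must be
#'   0/1 (or logical). The two source columns are absorbed into one outcome.
#' @param types optional named character vector of explicit declarations,
#'   values in `c("categorical", "continuous")`.
#' @param max_levels numeric columns with `<= max_levels` distinct values
#'   are inferred categorical (default 5).
#' @return an object of class `outcome_table`: a list with `sample_ids`,
#'   `columns` (named list of per-outcome value vectors; survival outcomes
#'   are data frames with `time` and `event`), `types` (named character),
#'   and `untestable` (named character of skip reasons, e.g. single-level
#'   categorical columns).
#' @export
outcome_table <- function(df, sample_ids = NULL, survival = list(),
                          types = NULL, max_levels = 5) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(sample_ids)) {
    if ("sample_id" %in% names(df)) {
      sample_ids <- as.character(df$sample_id)
      df$sample_id <- NULL
    } else if (!is.null(rownames(df)) &&
               !identical(rownames(df), as.character(seq_len(nrow(df))))) {
      sample_ids <- rownames(df)
    } else {
      stop("sample identifiers are required (rownames, a sample_id column, ",
           "or the `sample_ids` argument)", call. = FALSE)
    }
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(df)) {
    stop("`sample_ids` length does not match the number of rows", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs", call. = FALSE)

  columns <- list()
  col_types <- character()
  untestable <- character()
  # remember where each outcome first appears so the declared column order
  # is preserved (a survival outcome sits at its time column's position)
  position <- stats::setNames(seq_along(df), names(df))
  col_pos <- numeric()

  for (nm in names(survival)) {
    pair <- survival[[nm]]
    if (length(pair) != 2L || !all(pair %in% names(df))) {
      stop("survival outcome '", nm, "' must name two existing columns ",
           "(time, event)", call. = FALSE)
    }
    time <- as.numeric(df[[pair[1L]]])
    event <- df[[pair[2L]]]
    if (is.logical(event)) event <- as.numeric(event)
    event <- as.numeric(event)
    ok <- !is.na(event)
    if (!all(event[ok] %in% c(0, 1))) {
      stop("event column '", pair[2L], "' must be 0/1", call. = FALSE)
    }
    if (any(time < 0, na.rm = TRUE)) {
      stop("survival times in '", pair[1L], "' must be non-negative", call. = FALSE)
    }
    columns[[nm]] <- data.frame(time = time, event = event)
    col_types[nm] <- "survival"
    col_pos[nm] <- position[[pair[1L]]]
    df[pair] <- NULL
  }

  for (nm in names(df)) {
    col <- df[[nm]]
    if (all(is.na(col))) {
      stop("outcome column '", nm, "' is entirely missing", call. = FALSE)
    }
    type <- if (!is.null(types) && nm %in% names(types)) {
      declared <- types[[nm]]
      if (!declared %in% c("categorical", "continuous")) {
        stop("declared type for '", nm, "' must be categorical or continuous",
             call. = FALSE)
      }
      declared
    } else {
      infer_outcome_type(col, max_levels = max_levels)
    }
    if (type == "categorical") {
      col <- as.character(col)
      lev <- unique(col[!is.na(col)])
      if (length(lev) < 2L) {
        untestable[nm] <- "fewer than 2 observed levels"
      }
    } else {
      col <- as.numeric(col)
    }
    columns[[nm]] <- col
    col_types[nm] <- type
    col_pos[nm] <- position[[nm]]
  }

  ord <- order(col_pos)
  columns <- columns[ord]
  col_types <- col_types[ord]

  structure(list(sample_ids = sample_ids, columns = columns,
                 types = col_types, untestable = untestable),
            class = "outcome_table")
}

#' Infer the statistical type of a single outcome column
#'
#' @param column a vector of per-sample values.
#' @param max_levels numeric columns with at most this many distinct
#'   observed values are classed categorical.
#' @return `"categorical"` or `"continuous"`. Survival outcomes are declared
#'   explicitly in [outcome_table()], never inferred.
#' @export
infer_outcome_type <- function(column, max_levels = 5) {
  if (length(column) == 0L) stop("empty outcome column", call. = FALSE)
  if (all(is.na(column))) stop("outcome column is entirely missing", call. = FALSE)
  if (is.logical(column) || is.character(column) || is.factor(column)) {
    return("categorical")
  }
  if (is.numeric(column)) {
    k <- length(unique(column[!is.na(column)]))
    return(if (k <= max_levels) "categorical" else "continuous")
  }
  stop("unsupported column class: ", paste(class(column), collapse = "/"),
       call. = FALSE)
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("Outcome table:", length(x$sample_ids), "samples,",
      length(x$columns), "outcomes\n")
  for (nm in names(x$columns)) {
    note <- if (nm %in% names(x$untestable)) {
      paste0(" [untestable: ", x$untestable[[nm]], "]")
    } else ""
    cat("  ", nm, ": ", x$types[[nm]], note, "\n", sep = "")
  }
  invisible(x)
}
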