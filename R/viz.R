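# dendrogram node coordinates: leaf x = position in plot order,
# cluster x = midpoint of its children, y = merge height
dendro_coords <- function(tree) {
  n <- length(tree$order)
  leaf_x <- integer(n)
  leaf_x[tree$order] <- seq_len(n)
  m <- n - 1L
  node_x <- numeric(m)
  node_y <- tree$height
  segs <- vector("list", m)
  child_xy <- function(child) {
    if (child < 0) c(leaf_x[-child], 0) else c(node_x[child], node_y[child])
  }
  for (i in seq_len(m)) {
    a <- child_xy(tree$merge[i, 1L])
    b <- child_xy(tree$merge[i, 2L])
    node_x[i] <- (a[1L] + b[1L]) / 2
    segs[[i]] <- tibble::tibble(
      x = c(a[1L], a[1L], b[1L]), xend = c(a[1L], b[1L], b[1L]),
      y = c(a[2L], node_y[i], node_y[i]), yend = c(node_y[i], node_y[i], b[2L]))
  }
  list(segments = dplyr::bind_rows(segs), node_x = node_x, node_y = node_y,
       leaf_x = leaf_x)
}

# x/y position of every split, keyed by cluster-pair IDs
split_positions <- function(tree, splits = NULL) {
  if (is.null(splits)) splits <- assign_cluster_ids(tree)
  coords <- dendro_coords(tree)
  tibble::tibble(
    cid_left = splits$cid_left, cid_right = splits$cid_right,
    is_valid = splits$is_valid %||% rep(NA, nrow(splits)),
    x = coords$node_x[splits$merge_index],
    y = coords$node_y[splits$merge_index])
}

#' Plot the annotated clustering tree
#'
#' Draws the dendrogram top-down with a white circle at every branching
#' point and labels each statistically significant association (status ok,
#' adjusted p at or below the threshold) at its split, with the outcome
#' name and adjusted p-value.
#'
#' @param tree an [stats::hclust] object.
#' @param results an `sg_associations` tibble computed on the same tree, or
#'   `NULL` for a bare tree.
#' @param p_threshold associations with `p_adj <= p_threshold` are
#'   annotated (default 0.05).
#' @param label_size annotation text size.
#' @return a ggplot object; `attr(, "annotations")` holds the annotation
#'   table (one row per drawn label) and `attr(, "splits_xy")` the split
#'   coordinates, so layouts can be checked programmatically.
#' @export
plot_tree <- function(tree, results = NULL, p_threshold = 0.05,
                      label_size = 2.6) {
  stopifnot(inherits(tree, "hclust"))
  coords <- dendro_coords(tree)
  pos <- suppressWarnings(split_positions(tree))
  ann <- annotation_table(pos, results, p_threshold)
  if (!is.null(results) && nrow(results) == 0L) {
    warning("empty results: tree drawn without annotations", call. = FALSE)
  }
  g <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = coords$segments,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend),
      linewidth = 0.3) +
    ggplot2::geom_point(
      data = pos, ggplot2::aes(x = .data$x, y = .data$y),
      shape = 21, fill = "white", colour = "black", size = 2) +
    ggplot2::scale_y_continuous(name = "height") +
    ggplot2::scale_x_continuous(name = NULL, breaks = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
  if (nrow(ann) > 0L) {
    g <- g + ggplot2::geom_label(
      data = ann,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = label_size, vjust = -0.2, label.size = 0.1, alpha = 0.85)
  }
  attr(g, "annotations") <- ann
  attr(g, "splits_xy") <- pos
  g
}

annotation_table <- function(pos, results, p_threshold) {
  empty <- tibble::tibble(cid_left = numeric(), cid_right = numeric(),
                          outcome = character(), p_adj = numeric(),
                          x = numeric(), y = numeric(), label = character())
  if (is.null(results) || nrow(results) == 0L) return(empty)
  sig <- results[results$status == "ok" & !is.na(results$p_adj) &
                   results$p_adj <= p_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) return(empty)
  sig <- dplyr::left_join(
    sig[, c("cid_left", "cid_right", "outcome", "p_adj")],
    pos[, c("cid_left", "cid_right", "x", "y")],
    by = c("cid_left", "cid_right"))
  sig <- sig[stats::complete.cases(sig[, c("x", "y")]), , drop = FALSE]
  # stack multiple labels at the same split
  sig <- dplyr::arrange(sig, .data$cid_left, .data$p_adj)
  sig$label <- sprintf("%s\np=%.2g", sig$outcome, sig$p_adj)
  sig
}

#' Overview figure: annotated tree, outcome tracks and data heatmap
#'
#' Stacks three vertically aligned panels over a shared sample axis in
#' dendrogram leaf order: the annotated tree on top; one track per clinical
#' outcome (a value-ordered colour map for continuous outcomes, colour
#' bands for categorical levels, and observation-time shading with event
#' markers for survival outcomes), each with red circles at the splits
#' where that outcome is significant; and the data matrix behind the
#' clustering as a heatmap with samples in leaf order (features scaled to
#' z-scores).
#'
#' @param tree an [stats::hclust].
#' @param results an `sg_associations` tibble from [run_associations()].
#' @param outcomes the [outcome_table()] used for testing.
#' @param data the samples-by-features matrix behind the clustering.
#' @param p_threshold significance threshold for markers (default 0.05).
#' @return a patchwork object; `attr(, "layout")` records the shared leaf
#'   order, the number of tracks and the significance-marker table.
#' @export
plot_overview <- function(tree, results, outcomes, data,
                          p_threshold = 0.05) {
  stopifnot(inherits(tree, "hclust"), inherits(outcomes, "outcome_table"))
  data <- as.matrix(data)
  leaf_ids <- tree$labels %||% as.character(seq_along(tree$order))
  if (!setequal(rownames(data), leaf_ids)) {
    stop("data sample IDs do not match the tree leaves", call. = FALSE)
  }
  leaf_order <- leaf_ids[tree$order]
  n <- length(leaf_order)
  outcomes <- align_outcomes(outcomes, tree)
  ord <- match(leaf_order, outcomes$sample_ids)

  pos <- suppressWarnings(split_positions(tree))
  sig <- annotation_table(pos, results, p_threshold)

  bare_theme <- ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank(),
                   axis.title.y = ggplot2::element_text(angle = 0, vjust = 0.5,
                                                        size = 8),
                   legend.position = "none")

  tracks <- list()
  for (nm in names(outcomes$columns)) {
    col <- outcomes$columns[[nm]]
    type <- outcomes$types[[nm]]
    if (type == "survival") {
      d <- tibble::tibble(x = seq_len(n), value = col$time[ord],
                          event = col$event[ord])
      tk <- ggplot2::ggplot(d) +
        ggplot2::geom_tile(ggplot2::aes(x = .data$x, y = 1,
                                        fill = .data$value)) +
        ggplot2::geom_point(
          data = d[!is.na(d$event) & d$event == 1, , drop = FALSE],
          ggplot2::aes(x = .data$x, y = 1), shape = 4, size = 0.8) +
        ggplot2::scale_fill_viridis_c(na.value = "grey90")
    } else if (type == "categorical") {
      d <- tibble::tibble(x = seq_len(n), value = factor(col[ord]))
      tk <- ggplot2::ggplot(d) +
        ggplot2::geom_tile(ggplot2::aes(x = .data$x, y = 1,
                                        fill = .data$value)) +
        ggplot2::scale_fill_brewer(palette = "Set2", na.value = "grey90")
    } else {
      v <- col[ord]
      d <- tibble::tibble(x = seq_len(n), value = v)
      tk <- ggplot2::ggplot(d) +
        ggplot2::geom_tile(ggplot2::aes(x = .data$x, y = 1,
                                        fill = .data$value)) +
        ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                      limits = range(v, na.rm = TRUE))
    }
    sig_nm <- sig[sig$outcome == nm, , drop = FALSE]
    if (nrow(sig_nm) > 0L) {
      tk <- tk + ggplot2::geom_point(
        data = sig_nm, ggplot2::aes(x = .data$x, y = 1),
        shape = 21, fill = "red", colour = "darkred", size = 1.6)
    }
    tk <- tk + ggplot2::labs(y = nm, x = NULL) +
      ggplot2::scale_x_continuous(limits = c(0.5, n + 0.5), expand = c(0, 0)) +
      bare_theme +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
    tracks[[nm]] <- tk
  }

  z <- scale(data[leaf_order, , drop = FALSE])
  hm <- tibble::as_tibble(z, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "feature", values_to = "z") |>
    dplyr::mutate(x = match(.data$sample, leaf_order))
  heat <- ggplot2::ggplot(hm) +
    ggplot2::geom_tile(ggplot2::aes(x = .data$x, y = .data$feature,
                                    fill = .data$z)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey90") +
    ggplot2::scale_x_continuous(limits = c(0.5, n + 0.5), expand = c(0, 0)) +
    ggplot2::labs(x = "samples (leaf order)", y = NULL) +
    bare_theme +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())

  tp <- plot_tree(tree, results, p_threshold = p_threshold)
  suppressMessages(
    tp <- tp + ggplot2::scale_x_continuous(limits = c(0.5, n + 0.5),
                                           expand = c(0, 0)))

  panels <- c(list(tree = tp), tracks, list(heatmap = heat))
  heights <- c(4, rep(0.5, length(tracks)), 4)
  fig <- patchwork::wrap_plots(panels, ncol = 1, heights = heights)
  attr(fig, "layout") <- list(
    leaf_order = leaf_order,
    n_tracks = length(tracks),
    track_names = names(tracks),
    markers = sig)
  fig
}

#' Detail plot for one cluster-pair association
#'
#' Continuous outcomes get side-by-side boxplots, categorical outcomes
#' stacked proportion bars, and survival outcomes Kaplan-Meier curves, each
#' labelled with the two cluster IDs and the adjusted p-value.
#'
#' @param pairs an `sg_splits` tibble with validity flags.
#' @param outcomes an [outcome_table()].
#' @param outcome name of the outcome to plot.
#' @param cid_left cluster ID of the left subcluster identifying the split
#'   (default 2, the top split).
#' @param results optional `sg_associations` tibble; if given, the
#'   adjusted p-value is taken from it, otherwise the test is run ad hoc
#'   and the raw p is shown.
#' @return a ggplot object.
#' @export
plot_association <- function(pairs, outcomes, outcome, cid_left = 2,
                             results = NULL) {
  stopifnot(inherits(pairs, "sg_splits"), inherits(outcomes, "outcome_table"))
  row <- pairs[pairs$cid_left == cid_left, , drop = FALSE]
  if (nrow(row) != 1L) stop("no split with cid_left = ", cid_left, call. = FALSE)
  if (!is.null(row$is_valid) && !isTRUE(row$is_valid)) {
    stop("split ", cid_left, " vs ", cid_left + 1, " is not a valid pair",
         call. = FALSE)
  }
  if (!outcome %in% names(outcomes$columns)) {
    stop("unknown outcome '", outcome, "'", call. = FALSE)
  }
  ml <- row$members_left[[1L]]
  mr <- row$members_right[[1L]]
  col <- outcomes$columns[[outcome]]
  type <- outcomes$types[[outcome]]
  cids <- c(row$cid_left, row$cid_right)

  p_label <- if (!is.null(results)) {
    hit <- results[results$cid_left == cids[1L] & results$outcome == outcome, ]
    if (nrow(hit) == 1L && hit$status == "ok") {
      sprintf("adjusted p = %.3g", hit$p_adj)
    } else if (nrow(hit) == 1L) {
      stop("association was skipped: ", hit$reason, call. = FALSE)
    } else NA_character_
  } else NA_character_

  if (type == "survival") {
    sv <- col
    rownames(sv) <- outcomes$sample_ids
    test <- logrank_test(ml, mr, sv)
    if (test$status == "skipped") stop("association not testable: ",
                                       test$reason, call. = FALSE)
    if (is.na(p_label)) p_label <- sprintf("raw p = %.3g", test$p)
    grp <- factor(rep(paste("cluster", cids), c(length(ml), length(mr))),
                  levels = paste("cluster", cids))
    idx <- match(c(ml, mr), outcomes$sample_ids)
    fit <- survival::survfit(
      survival::Surv(col$time[idx], col$event[idx]) ~ grp)
    km <- km_steps(fit, levels(grp))
    g <- ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                          colour = .data$cluster)) +
      ggplot2::geom_step() +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "time", y = "survival probability")
  } else {
    named <- stats::setNames(col, outcomes$sample_ids)
    test <- if (type == "categorical") fisher_exact(ml, mr, named)
            else t_test(ml, mr, named)
    if (test$status == "skipped") stop("association not testable: ",
                                       test$reason, call. = FALSE)
    if (is.na(p_label)) p_label <- sprintf("raw p = %.3g", test$p)
    d <- tibble::tibble(
      cluster = factor(rep(paste("cluster", cids), c(length(ml), length(mr))),
                       levels = paste("cluster", cids)),
      value = c(named[ml], named[mr]))
    d <- d[!is.na(d$value), , drop = FALSE]
    g <- if (type == "categorical") {
      ggplot2::ggplot(d, ggplot2::aes(x = .data$cluster,
                                      fill = factor(.data$value))) +
        ggplot2::geom_bar(position = "fill") +
        ggplot2::labs(y = "proportion", fill = outcome)
    } else {
      ggplot2::ggplot(d, ggplot2::aes(x = .data$cluster, y = .data$value)) +
        ggplot2::geom_boxplot(width = 0.5, fill = "grey85") +
        ggplot2::labs(y = outcome)
    }
  }
  g + ggplot2::ggtitle(
    sprintf("clusters %d vs %d: %s", cids[1L], cids[2L], outcome),
    subtitle = p_label) +
    ggplot2::theme_minimal()
}

# survfit -> step-function table, anchored at (0, 1) per group
km_steps <- function(fit, group_levels) {
  strata <- if (is.null(fit$strata)) {
    rep(group_levels[1L], length(fit$time))
  } else {
    rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  }
  d <- tibble::tibble(time = fit$time, surv = fit$surv, cluster = strata)
  anchors <- tibble::tibble(time = 0, surv = 1, cluster = group_levels)
  dplyr::arrange(dplyr::bind_rows(anchors, d), .data$cluster, .data$time)
}
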