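#' Hierarchical clustering of samples
#'
#' Builds the sample dendrogram that the subgroup search walks. Either a
#' samples-by-features numeric matrix is clustered with a named distance
#' metric, or a precomputed sample-by-sample distance (e.g. a fused
#' multi-omics distance from [fuse_distances()], or any externally computed
#' matrix) is clustered directly.
#'
#' @param data numeric matrix or data frame, samples in rows. Row names are
#'   the sample identifiers. May be `NULL` when `distance` is precomputed.
#' @param distance either a metric name understood by [stats::dist()]
#'   (`"euclidean"`, `"maximum"`, `"manhattan"`, `"canberra"`, `"binary"`,
#'   `"minkowski"`), or a precomputed square distance matrix / `dist` object.
#' @param linkage agglomeration rule: `"ward"` (an alias for `"ward.D2"`),
#'   `"ward.D"`, `"ward.D2"`, `"single"`, `"complete"`, `"average"`,
#'   `"mcquitty"`, `"centroid"` or `"median"`.
#' @return an [stats::hclust] object with sample labels.
#' @details Merge heights of the monotone linkages (ward/average/complete/
#'   single and variants) are non-decreasing; centroid and median linkage can
#'   produce inversions, which trigger a warning, not an error. Clustering is
#'   deterministic for a fixed input; distance ties are resolved by the
#'   agglomeration routine's fixed scan order (lowest involved sample index
#'   first).
#' @examples
#' x <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("s", 1:10), NULL))
#' hc <- build_tree(x, distance = "euclidean", linkage = "ward")
#' @export
build_tree <- function(data = NULL, distance = "euclidean", linkage = "ward") {
  linkage <- match_linkage(linkage)
  if (is.character(distance)) {
    metrics <- c("euclidean", "maximum", "manhattan", "canberra", "binary",
                 "minkowski")
    if (length(distance) != 1L || !distance %in% metrics) {
      stop("unknown distance metric '", paste(distance, collapse = ","),
           "'; supported: ", paste(metrics, collapse = ", "), call. = FALSE)
    }
    if (is.null(data)) stop("`data` is required when `distance` is a metric name", call. = FALSE)
    data <- as.matrix(data)
    if (nrow(data) < 2L) stop("at least 2 samples are required", call. = FALSE)
    if (is.null(rownames(data))) rownames(data) <- as.character(seq_len(nrow(data)))
    if (anyDuplicated(rownames(data))) stop("duplicate sample IDs in `data`", call. = FALSE)
    d <- stats::dist(data, method = distance)
    check_finite_dist(d, rownames(data))
  } else {
    d <- validate_distance(distance, allow_unnamed = TRUE)
    if (nrow(d) < 2L) stop("at least 2 samples are required", call. = FALSE)
    d <- stats::as.dist(d)
  }
  hc <- stats::hclust(d, method = linkage)
  check_monotone_heights(hc)
  hc
}

match_linkage <- function(linkage) {
  supported <- c("ward", "ward.D", "ward.D2", "single", "complete",
                 "average", "mcquitty", "centroid", "median")
  if (length(linkage) != 1L || !linkage %in% supported) {
    stop("unknown linkage '", paste(linkage, collapse = ","),
         "'; supported: ", paste(supported, collapse = ", "), call. = FALSE)
  }
  if (linkage == "ward") "ward.D2" else linkage
}

check_finite_dist <- function(d, ids) {
  if (all(is.finite(d))) return(invisible(TRUE))
  n <- attr(d, "Size")
  bad <- which(!is.finite(d))[1L]
  # recover (i, j) from the linearized lower-triangle index
  i <- 1L
  off <- bad
  while (off > n - i) {
    off <- off - (n - i)
    i <- i + 1L
  }
  j <- i + off
  stop("non-finite distance between samples '", ids[i], "' and '", ids[j], "'",
       call. = FALSE)
}

check_monotone_heights <- function(hc) {
  if (is.unsorted(hc$height)) {
    warning("merge heights are not monotone (linkage inversion); ",
            "the dendrogram contains inversions", call. = FALSE)
  }
  invisible(hc)
}

#' Assemble a clustering tree from an externally computed merge table
#'
#' Accepts generic agglomerative-clustering output as (child_a, child_b,
#' height) rows, so trees computed by any external tool or on any distance
#' (including similarity-network-fusion-style matrices) can be analyzed.
#' Children follow the usual merge-table encoding: a negative value -i is
#' leaf i, a positive value j is the cluster created by merge j.
#'
#' @param child_a,child_b integer vectors of length n-1.
#' @param heights non-negative merge heights, length n-1.
#' @param labels sample identifiers, length n (leaf order).
#' @return an [stats::hclust] object.
#' @export
tree_from_merges <- function(child_a, child_b, heights, labels) {
  n <- length(labels)
  m <- n - 1L
  if (length(child_a) != m || length(child_b) != m || length(heights) != m) {
    stop("expected ", m, " merges for ", n, " leaves", call. = FALSE)
  }
  if (any(heights < 0)) stop("merge heights must be non-negative", call. = FALSE)
  merge <- cbind(as.integer(child_a), as.integer(child_b))
  refs <- as.vector(merge)
  leaves <- -refs[refs < 0]
  nodes <- refs[refs > 0]
  if (!setequal(leaves, seq_len(n)) || anyDuplicated(leaves)) {
    stop("every leaf 1..n must be referenced exactly once as a child", call. = FALSE)
  }
  if (m > 1L && (!setequal(nodes, seq_len(m - 1L)) || anyDuplicated(nodes))) {
    stop("every non-final merge must be referenced exactly once as a child", call. = FALSE)
  }
  hc <- structure(
    list(merge = merge, height = as.numeric(heights),
         order = merge_order(merge, n), labels = as.character(labels),
         method = "external", call = match.call(),
         dist.method = "external"),
    class = "hclust")
  check_monotone_heights(hc)
  hc
}

# left-to-right leaf traversal of a merge table (plot order)
merge_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(n - 1L)
}

# leaf-index membership of every merge-created cluster
cluster_members <- function(hc) {
  m <- nrow(hc$merge)
  members <- vector("list", m)
  for (i in seq_len(m)) {
    get <- function(child) if (child < 0) -child else members[[child]]
    members[[i]] <- c(get(hc$merge[i, 1L]), get(hc$merge[i, 2L]))
  }
  members
}

#' Enumerate the splits of a clustering tree with heap-style cluster IDs
#'
#' Each of the n-1 internal nodes of the dendrogram is a branching point
#' that splits a parent cluster into a left and a right subcluster. Splits
#' are ranked by decreasing merge height (the top-down reading of the tree);
#' the whole cohort is cluster 1 and the rank-k split labels its children
#' 2k and 2k+1, so the top split always yields clusters 2 versus 3 and the
#' second-highest split clusters 4 versus 5. The side containing the
#' leftmost leaf in dendrogram order is "left".
#'
#' @param tree an [stats::hclust] object (from [build_tree()],
#'   [tree_from_merges()] or `hclust()` directly).
#' @return a tibble of class `sg_splits` with one row per split:
#'   `split_rank`, `parent_cid`, `cid_left`, `cid_right`, `height`,
#'   `n_left`, `n_right`, and list-columns `members_left`, `members_right`
#'   holding sample IDs. Validity flags are unset until
#'   [enumerate_valid_pairs()] is applied.
#' @details Height ties are broken by splitting the later-created (higher)
#'   cluster first, which keeps parents ahead of their children; remaining
#'   ties fall to the lower minimum leaf-order index. With non-monotone
#'   linkages a child can sit above its parent; its `parent_cid` is then
#'   `NA` and a warning is raised.
#' @export
assign_cluster_ids <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  m <- n - 1L
  labels <- tree$labels %||% as.character(seq_len(n))
  members <- cluster_members(tree)
  leaf_pos <- integer(n)           # position of each leaf in dendrogram order
  leaf_pos[tree$order] <- seq_len(n)

  min_pos <- vapply(members, function(ix) min(leaf_pos[ix]), integer(1))
  rank_order <- order(-tree$height, -seq_len(m), min_pos)

  cid_of_merge <- rep(NA_real_, m)
  cid_of_merge[m] <- 1
  out <- vector("list", m)
  inversion <- FALSE
  for (k in seq_len(m)) {
    j <- rank_order[k]
    a <- tree$merge[j, 1L]
    b <- tree$merge[j, 2L]
    mem <- function(child) if (child < 0) -child else members[[child]]
    mem_a <- mem(a); mem_b <- mem(b)
    if (min(leaf_pos[mem_a]) <= min(leaf_pos[mem_b])) {
      left <- a; right <- b; mem_l <- mem_a; mem_r <- mem_b
    } else {
      left <- b; right <- a; mem_l <- mem_b; mem_r <- mem_a
    }
    parent <- cid_of_merge[j]
    if (is.na(parent)) inversion <- TRUE
    cid_l <- 2 * k
    cid_r <- 2 * k + 1
    if (left > 0) cid_of_merge[left] <- cid_l
    if (right > 0) cid_of_merge[right] <- cid_r
    out[[k]] <- tibble::tibble(
      split_rank = k, parent_cid = parent,
      cid_left = cid_l, cid_right = cid_r,
      height = tree$height[j], merge_index = j,
      n_left = length(mem_l), n_right = length(mem_r),
      members_left = list(labels[sort(mem_l)]),
      members_right = list(labels[sort(mem_r)]))
  }
  if (inversion) {
    warning("tree contains linkage inversions; parent cluster IDs could not ",
            "be resolved for some splits (NA)", call. = FALSE)
  }
  splits <- dplyr::bind_rows(out)
  attr(splits, "n_samples") <- n
  class(splits) <- c("sg_splits", class(splits))
  splits
}

#' Flag valid cluster pairs by minimum subcluster size
#'
#' To avoid low-powered tests in small clusters, only branch points where
#' both the left and the right subcluster are at or above a minimum size are
#' tested. The default threshold is 5% of the sample size, rounded up.
#'
#' @param splits an `sg_splits` tibble from [assign_cluster_ids()].
#' @param min_size minimum subcluster size, either an absolute count
#'   (>= 1) or a fraction of the sample size in (0, 1), converted as
#'   `ceiling(fraction * n)`. Default `0.05`.
#' @return `splits` with a logical `is_valid` column; the number of valid
#'   pairs is in `attr(, "m")` and the resolved count in
#'   `attr(, "min_size_used")`.
#' @export
enumerate_valid_pairs <- function(splits, min_size = 0.05) {
  stopifnot(inherits(splits, "sg_splits"))
  n <- attr(splits, "n_samples")
  min_size <- resolve_min_size(min_size, n)
  if (min_size > floor(n / 2)) {
    warning("min_size = ", min_size, " exceeds floor(n/2) = ", floor(n / 2),
            ": no valid pairs possible", call. = FALSE)
  }
  splits$is_valid <- pmin(splits$n_left, splits$n_right) >= min_size
  attr(splits, "m") <- sum(splits$is_valid)
  attr(splits, "min_size_used") <- min_size
  splits
}

resolve_min_size <- function(min_size, n) {
  if (!is.numeric(min_size) || length(min_size) != 1L || min_size <= 0) {
    stop("`min_size` must be a single positive number", call. = FALSE)
  }
  if (min_size < 1) as.integer(ceiling(min_size * n)) else {
    if (min_size != floor(min_size)) {
      stop("absolute `min_size` must be a whole number", call. = FALSE)
    }
    as.integer(min_size)
  }
}

#' @export
print.sg_splits <- function(x, ...) {
  n <- attr(x, "n_samples")
  cat("Cluster splits over", n, "samples:", nrow(x), "branch points\n")
  if (!is.null(attr(x, "m"))) {
    cat("Valid pairs (min size", attr(x, "min_size_used"), "):",
        attr(x, "m"), "\n")
  }
  NextMethod()
}

#' Export a clustering tree
#'
#' `write_newick()` writes the dendrogram as a Newick string with branch
#' lengths equal to height differences; `write_merge_table()` writes a
#' 4-column TSV (child_a, child_b, height, size) in merge-table encoding,
#' readable back with [read_merge_table()].
#'
#' @param tree an [stats::hclust] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  # as.phylo halves hclust heights; rescale so branch lengths are height
  # differences and root-to-tip depth equals the root merge height
  phy$edge.length <- phy$edge.length * 2
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
write_merge_table <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  sizes <- lengths(cluster_members(tree))
  tab <- tibble::tibble(child_a = tree$merge[, 1L], child_b = tree$merge[, 2L],
                        height = tree$height, size = sizes)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read a merge table written by [write_merge_table()]
#'
#' @param path TSV with columns child_a, child_b, height (size is ignored).
#' @param leaf_ids sample identifiers in leaf order.
#' @return an [stats::hclust] object.
#' @export
read_merge_table <- function(path, leaf_ids) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("child_a", "child_b", "height")
  if (!all(need %in% names(tab))) {
    stop("merge table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tree_from_merges(tab$child_a, tab$child_b, tab$height, leaf_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
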