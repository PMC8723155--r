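#' Fuse per-block sample distance matrices for joint clustering
#'
#' Combines distance matrices computed on different omics blocks over the
#' same samples into one matrix by normalizing each block by its maximum
#' and summing:
#'
#' \deqn{D = D_1/\max(D_1) + D_2/\max(D_2) + \cdots + D_l/\max(D_l)}
#'
#' Each normalized block contributes a matrix whose maximum is exactly 1,
#' so no single block dominates by scale; the result is invariant to
#' positive rescaling of any block and to block input order. The maximum is
#' taken over off-diagonal entries (the diagonal is 0 by contract).
#'
#' @param blocks a list of square distance matrices (or `dist` objects),
#'   all over the same sample set. Matrices must be symmetric with zero
#'   diagonal and carry sample IDs as dimnames; blocks are aligned by ID.
#' @param allow_unnamed if `TRUE`, blocks without dimnames are accepted and
#'   aligned by position (all blocks must then be unnamed and conformable).
#' @return a square matrix of class `fused_dist` with attributes
#'   `block_names` and `block_max` (the per-block normalization constants).
#' @examples
#' d1 <- as.matrix(dist(matrix(rnorm(20), 10)))
#' d2 <- as.matrix(dist(matrix(rnorm(30), 10)))
#' dimnames(d1) <- dimnames(d2) <- list(letters[1:10], letters[1:10])
#' fd <- fuse_distances(list(block1 = d1, block2 = d2))
#' @export
fuse_distances <- function(blocks, allow_unnamed = FALSE) {
  if (!is.list(blocks) || length(blocks) < 1L) {
    stop("`blocks` must be a non-empty list of distance matrices", call. = FALSE)
  }
  block_names <- names(blocks) %||% paste0("block", seq_along(blocks))
  block_names[block_names == ""] <- paste0("block", which(block_names == ""))
  mats <- lapply(blocks, validate_distance, allow_unnamed = allow_unnamed)

  ids <- rownames(mats[[1L]])
  if (is.null(ids)) {
    sizes <- vapply(mats, nrow, integer(1))
    if (length(unique(sizes)) != 1L) {
      stop("unnamed blocks must all have the same dimension", call. = FALSE)
    }
  } else {
    for (k in seq_along(mats)[-1L]) {
      other <- rownames(mats[[k]])
      if (is.null(other)) stop("block '", block_names[k], "' has no sample IDs",
                               call. = FALSE)
      if (!setequal(ids, other)) {
        miss <- setdiff(ids, other)
        extra <- setdiff(other, ids)
        stop("sample sets differ between blocks: missing {",
             paste(utils::head(miss, 5), collapse = ", "), "}, extra {",
             paste(utils::head(extra, 5), collapse = ", "), "}", call. = FALSE)
      }
      mats[[k]] <- mats[[k]][ids, ids]
    }
  }

  block_max <- vapply(mats, function(m) {
    mx <- max(m[row(m) != col(m)])
    if (mx <= 0) stop("a block is all-zero: its maximum cannot normalize",
                      call. = FALSE)
    mx
  }, numeric(1))

  fused <- Reduce(`+`, Map(function(m, mx) m / mx, mats, block_max))
  fused <- (fused + t(fused)) / 2   # enforce exact symmetry
  diag(fused) <- 0
  structure(fused, block_names = block_names,
            block_max = stats::setNames(block_max, block_names),
            class = c("fused_dist", "matrix", "array"))
}

# shared distance-matrix validation (also used by build_tree)
validate_distance <- function(d, allow_unnamed = FALSE, tol = 1e-8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(d)) && !allow_unnamed) {
    stop("distance matrix has no sample IDs; pass allow_unnamed = TRUE to ",
         "align by position", call. = FALSE)
  }
  if (!is.null(rownames(d)) && !is.null(colnames(d)) &&
      !identical(rownames(d), colnames(d))) {
    stop("distance matrix row and column IDs differ", call. = FALSE)
  }
  if (!all(is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1L, ]
    ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
    stop("non-finite distance between samples '", ids[bad[1L]], "' and '",
         ids[bad[2L]], "'", call. = FALSE)
  }
  if (max(abs(d - t(d))) > tol) stop("distance matrix is not symmetric",
                                     call. = FALSE)
  if (any(abs(diag(d)) > tol)) stop("distance matrix diagonal must be zero",
                                    call. = FALSE)
  if (any(d < -tol)) stop("distances must be non-negative", call. = FALSE)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}
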