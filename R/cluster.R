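#' Squared Euclidean distance matrix
#'
#' `d(i, j) = sum_f (x_if - x_jf)^2`, the dissimilarity under which
#' Ward's criterion has its variance interpretation.
#'
#' @param x numeric matrix or data frame, items in rows, features in
#'   columns; row names become item ids.
#' @return symmetric matrix with zero diagonal, class `dist_sq`.
#' @export
#' @examples
#' dist_squared_euclidean(rbind(a = c(0, 0), b = c(3, 4)))["a", "b"] # 25
dist_squared_euclidean <- function(x) {
  m <- as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 items")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing feature value: item ",
         rownames(m)[bad[1]] %||% bad[1], ", feature ",
         colnames(m)[bad[2]] %||% bad[2])
  }
  d <- as.matrix(stats::dist(m, method = "euclidean"))^2
  structure(d, class = c("dist_sq", "matrix", "array"))
}

#' Ward agglomerative clustering
#'
#' Bottom-up agglomeration under Ward's minimum-variance criterion via
#' the Lance-Williams recurrence
#' `d(k, ij) = [(n_i + n_k) d(k,i) + (n_j + n_k) d(k,j) - n_k d(i,j)] /
#' (n_i + n_j + n_k)`,
#' applied to a squared Euclidean distance matrix. Merge heights are the
#' Lance-Williams distances (twice the within-cluster sum-of-squares
#' increment); under squared Euclidean input they are non-decreasing (no
#' inversions). Ties are broken deterministically by merging the
#' candidate pair with the lexicographically smallest pair of smallest
#' leaf indices.
#'
#' @param d symmetric distance matrix (ideally from
#'   [dist_squared_euclidean()]); a `dist` object is accepted.
#' @param labels optional item labels (default from `d`'s dimnames).
#' @return object of class `merge_tree`: list with `merge` (n-1 x 2,
#'   hclust coding: negative = leaf, positive = earlier merge), `height`,
#'   `labels`, `sizes` (cluster size after each merge).
#' @export
ward_cluster <- function(d, labels = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(as.matrix(d))
  n <- nrow(d)
  if (n < 2) stop("need at least 2 items")
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0) || any(d < 0)) {
    stop("d must be a symmetric non-negative matrix with zero diagonal")
  }
  labels <- labels %||% rownames(d) %||% as.character(seq_len(n))

  active <- seq_len(n)        # active cluster slots (column indices in d)
  size <- rep(1L, n)
  minleaf <- seq_len(n)       # smallest original leaf index per cluster
  code <- -seq_len(n)         # hclust merge coding per slot
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  sizes <- integer(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (a in seq_along(active)[-length(active)]) {
      for (b in seq((a + 1L), length(active))) {
        i <- active[a]; j <- active[b]
        key <- c(d[i, j], min(minleaf[i], minleaf[j]),
                 max(minleaf[i], minleaf[j]))
        if (is.null(best) || lex_less(key, best$key)) {
          best <- list(key = key, a = a, b = b)
        }
      }
    }
    i <- active[best$a]; j <- active[best$b]
    # order the pair so the smaller leaf-index cluster comes first
    if (minleaf[j] < minleaf[i]) { tmp <- i; i <- j; j <- tmp }
    h <- d[i, j]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- h
    ni <- size[i]; nj <- size[j]
    sizes[step] <- ni + nj

    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      d[i, k] <- d[k, i] <-
        ((ni + nk) * d[k, i] + (nj + nk) * d[k, j] - nk * h) /
          (ni + nj + nk)
    }
    size[i] <- ni + nj
    minleaf[i] <- min(minleaf[i], minleaf[j])
    code[i] <- step
    active <- setdiff(active, j)
  }

  structure(list(merge = merge, height = height, labels = labels,
                 sizes = sizes),
            class = "merge_tree")
}

lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("<merge_tree> ", length(x$labels), " leaves, ",
      length(x$height), " merges; height range [",
      signif(min(x$height), 4), ", ", signif(max(x$height), 4), "]\n",
      sep = "")
  invisible(x)
}

#' @rdname ward_cluster
#' @param x a `merge_tree`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.merge_tree <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$height),
    cluster_a = x$merge[, 1], cluster_b = x$merge[, 2],
    height = x$height, size = x$sizes
  )
}

#' @rdname ward_cluster
#' @param object a `merge_tree`.
#' @exportS3Method generics::glance
glance.merge_tree <- function(object, ...) {
  tibble::tibble(
    n_leaves = length(object$labels),
    n_merges = length(object$height),
    max_height = max(object$height),
    monotone = !is.unsorted(object$height)
  )
}

member_leaves <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    members[[s]] <- unlist(lapply(tree$merge[s, ], function(cl) {
      if (cl < 0) -cl else members[[cl]]
    }))
  }
  members
}

#' Cophenetic distances of a merge tree
#'
#' The cophenetic distance of two items is the merge height at which they
#' first join the same cluster.
#'
#' @param tree a [ward_cluster()] `merge_tree`.
#' @return symmetric matrix of cophenetic distances.
#' @export
cophenetic_distances <- function(tree) {
  n <- length(tree$labels)
  cm <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  members <- member_leaves(tree)
  for (s in seq_len(n - 1L)) {
    parts <- lapply(tree$merge[s, ], function(cl) {
      if (cl < 0) -cl else members[[cl]]
    })
    cm[parts[[1]], parts[[2]]] <- tree$height[s]
    cm[parts[[2]], parts[[1]]] <- tree$height[s]
  }
  cm
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the n(n-1)/2 original distances and the
#' cophenetic distances of the dendrogram — the standard measure of how
#' faithfully the tree preserves the distance structure.
#'
#' @param d the original distance matrix the tree was built from.
#' @param tree a `merge_tree` over the same items.
#' @return coefficient in `[-1, 1]`, or `NA` (with a message) when either
#'   distance vector is constant.
#' @export
cophenetic_correlation <- function(d, tree) {
  d <- unclass(as.matrix(d))
  n <- nrow(d)
  if (n != length(tree$labels)) stop("tree and d have different items")
  lower <- lower.tri(d)
  orig <- d[lower]
  coph <- cophenetic_distances(tree)[lower]
  if (sd(orig) == 0 || sd(coph) == 0) {
    message("constant distance vector: cophenetic correlation undefined")
    return(NA_real_)
  }
  cor(orig, coph)
}

#' Cut a merge tree
#'
#' Clusters are the connected components of the merges applied strictly
#' below `height` (so height 0 gives all singletons), or the partition
#' after the first `n - k` merges when `k` is given.
#'
#' @param tree a `merge_tree`.
#' @param height cut height (>= 0).
#' @param k desired number of clusters (alternative to `height`).
#' @return tibble `item`, `cluster` (clusters numbered by first
#'   appearance in leaf order).
#' @export
cut_tree <- function(tree, height = NULL, k = NULL) {
  n <- length(tree$labels)
  if (is.null(height) == is.null(k)) {
    stop("supply exactly one of height or k")
  }
  steps <- if (!is.null(height)) {
    stopifnot(height >= 0)
    which(tree$height < height)
  } else {
    stopifnot(k >= 1, k <= n)
    seq_len(n - k)
  }
  assign <- seq_len(n)
  members <- member_leaves(tree)
  for (s in steps) {
    leaves <- members[[s]]
    assign[leaves] <- min(assign[leaves])
  }
  cluster <- match(assign, unique(assign))
  tibble::tibble(item = tree$labels, cluster = cluster)
}

#' Convert a merge tree to an hclust object
#'
#' @param x a `merge_tree`.
#' @param ... unused.
#' @return a [stats::hclust] object (enables `plot()`,
#'   [stats::cophenetic()], [ape::as.phylo()], ...).
#' @export
as.hclust.merge_tree <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = leaf_order(x),
         labels = x$labels, method = "ward",
         dist.method = "squared euclidean",
         call = match.call()),
    class = "hclust"
  )
}

# leaf ordering without branch crossings: expand merges recursively
leaf_order <- function(tree) {
  expand <- function(cl) {
    if (cl < 0) return(-cl)
    c(expand(tree$merge[cl, 1]), expand(tree$merge[cl, 2]))
  }
  expand(nrow(tree$merge))
}

#' Serialize a merge tree as Newick
#'
#' @param tree a `merge_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  phy <- ape::as.phylo(as.hclust.merge_tree(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Split-half stability of a clustering
#'
#' Randomization scheme: each item receives a random number, items are
#' sorted by it and split into two halves; each half is re-clustered
#' (squared Euclidean + Ward) and cut into `k` clusters, and the
#' agreement of each half's partition with the full-data partition
#' (restricted to the half's items) is measured as pairwise
#' co-membership agreement (Rand index). Deterministic under `seed`.
#'
#' @param x items x features matrix (or data frame with rownames).
#' @param n_splits number of random splits (>= 1).
#' @param seed integer seed (mandatory; recorded on the result).
#' @param k number of clusters compared (default 2).
#' @return tibble `split`, `half`, `n_items`, `agreement`, with
#'   attributes `mean_agreement`, `seed`, `k`.
#' @export
split_half_stability <- function(x, n_splits, seed, k = 2) {
  m <- as.matrix(x)
  if (nrow(m) < 4) stop("need at least 4 items")
  if (n_splits < 1) stop("n_splits must be >= 1")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
  rownames(m) <- labels

  full <- cut_tree(ward_cluster(dist_squared_euclidean(m)), k = k)
  full_assign <- setNames(full$cluster, full$item)

  res <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_splits), function(s) {
      r <- runif(nrow(m))
      ord <- order(r)
      n_half <- floor(nrow(m) / 2)
      halves <- list(ord[seq_len(n_half)], ord[-seq_len(n_half)])
      purrr::map_dfr(1:2, function(h) {
        idx <- halves[[h]]
        sub <- m[idx, , drop = FALSE]
        part <- cut_tree(ward_cluster(dist_squared_euclidean(sub)),
                         k = min(k, nrow(sub)))
        agree <- rand_index(part$cluster,
                            unname(full_assign[part$item]))
        tibble::tibble(split = s, half = h, n_items = length(idx),
                       agreement = agree)
      })
    })
  })
  attr(res, "mean_agreement") <- mean(res$agreement)
  attr(res, "seed") <- seed
  attr(res, "k") <- k
  res
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two partitions agree (placed together
#' in both, or apart in both).
#'
#' @param a,b integer/character cluster assignments over the same items.
#' @return agreement in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}

#' @rdname ward_cluster
#' @exportS3Method ggplot2::autoplot
autoplot.merge_tree <- function(object, ...) {
  hc <- as.hclust.merge_tree(object)
  dend <- stats::as.dendrogram(hc)
  seg <- dendrogram_segments(dend)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_along(hc$order),
                                labels = hc$labels[hc$order]) +
    ggplot2::labs(x = NULL, y = "Merge height (Lance-Williams distance)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

dendrogram_segments <- function(dend) {
  segs <- list()
  walk <- function(node) {
    if (is.leaf(node)) {
      return(list(x = attr(node, "x") %||% 0, h = 0))
    }
    kids <- lapply(seq_along(node), function(i) walk(node[[i]]))
    h <- attr(node, "height")
    xs <- vapply(kids, `[[`, numeric(1), "x")
    hs <- vapply(kids, `[[`, numeric(1), "h")
    for (i in seq_along(kids)) {
      segs[[length(segs) + 1]] <<- tibble::tibble(
        x = xs[i], y = hs[i], xend = xs[i], yend = h)
    }
    segs[[length(segs) + 1]] <<- tibble::tibble(
      x = min(xs), y = h, xend = max(xs), yend = h)
    list(x = mean(range(xs)), h = h)
  }
  # assign leaf x positions in plotting order first
  x_counter <- 0
  dend <- stats::dendrapply(dend, function(node) {
    if (is.leaf(node)) {
      x_counter <<- x_counter + 1
      attr(node, "x") <- x_counter
    }
    node
  })
  walk(dend)
  dplyr::bind_rows(segs)
}
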