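# Small in-code fixtures and independent oracles shared across tests.

# A 3-brand, 4-analyte panel with one censored cell (Ag in B2).
tiny_panel <- function(policy = "zero") {
  p <- conc_panel(
    brand = rep(c("B1", "B2", "B3"), each = 4),
    analyte = rep(c("Cu", "As", "Pb", "Ag"), 3),
    level = c(
      10, 1.0, 0.2, 0.05,
      4200, 0.5, 0.1, 0,
      3, 9.7, 1.1, 0.04
    ),
    censored = c(rep(FALSE, 7), TRUE, rep(FALSE, 4)),
    mdl = rep(c(0.5, 0.1, 0.05, 0.02), 3)
  )
  apply_nondetect_policy(p, policy)
}

# Interpolation oracle for the p(n-1)+1 quantile convention (type 7),
# written independently of stats::quantile.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Exhaustive greedy Ward oracle working from raw coordinates: at every
# step evaluate, for every pair of clusters, the Lance-Williams merge
# distance 2 * |A||B|/(|A|+|B|) * ||mean_A - mean_B||^2 and merge the
# minimum (ties: smallest pair of smallest leaf indices).
ward_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_along(clusters)[-length(clusters)]) {
      for (b in seq(a + 1, length(clusters))) {
        A <- clusters[[a]]; B <- clusters[[b]]
        mA <- colMeans(x[A, , drop = FALSE])
        mB <- colMeans(x[B, , drop = FALSE])
        cost <- 2 * length(A) * length(B) / (length(A) + length(B)) *
          sum((mA - mB)^2)
        key <- c(cost, min(min(A), min(B)), max(min(A), min(B)))
        if (is.null(best) ||
              isTRUE(key[1] < best$key[1]) ||
              (key[1] == best$key[1] &&
                 (key[2] < best$key[2] ||
                    (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(key = key, a = a, b = b)
        }
      }
    }
    merged <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    clusters <- clusters[-c(best$a, best$b)]
    clusters[[length(clusters) + 1]] <- merged
    heights <- c(heights, best$key[1])
    parts <- lapply(clusters, sort)
    partitions[[length(partitions) + 1]] <-
      parts[order(vapply(parts, min, numeric(1)))]
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition for comparison up to cluster relabelling.
canonical_partition <- function(assign) {
  unname(split(seq_along(assign), assign)[order(
    vapply(split(seq_along(assign), assign), min, numeric(1))
  )])
}

# Partition of a merge_tree after each merge step, as sorted index sets.
tree_partitions <- function(tree) {
  n <- length(tree$labels)
  lapply(seq_len(n - 1), function(s) {
    cl <- cut_tree(tree, k = n - s)$cluster
    parts <- split(seq_len(n), cl)
    unname(parts[order(vapply(parts, min, numeric(1)))])
  })
}
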