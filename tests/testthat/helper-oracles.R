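# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct formulas,
# hand-rolled BFS.

# Step-up FDR by direct enumeration: try every candidate rank from the top.
brute_force_stepup <- function(p, q, c_V = 1) {
  V <- length(p)
  if (V == 0L) return(logical(0))
  ps <- sort(p)
  cutoff <- NA_real_
  for (i in V:1) {
    if (ps[i] <= (i / V) * q / c_V) { cutoff <- ps[i]; break }
  }
  if (is.na(cutoff)) rep(FALSE, V) else p <= cutoff
}

# All-pairs shortest paths by breadth-first search on a binary adjacency.
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] > 0))))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# Graph metrics straight from the definitions, using bfs_distances().
oracle_graph_metrics <- function(A) {
  n <- nrow(A)
  n_edges <- sum(A) / 2
  D <- bfs_distances(A)
  off <- D[upper.tri(D)]
  list(average_degree = 2 * n_edges / n,
       density = 2 * n_edges / (n * (n - 1)),
       average_path_length = if (n_edges == 0) NA_real_
                             else mean(off[is.finite(off)]),
       n_disconnected_pairs = 2 * sum(is.infinite(off)))
}

# Pearson correlation from the product-moment definition.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Explicit 8-corner trilinear interpolation at a single point (0-based).
oracle_trilinear <- function(vol, p) {
  i <- floor(p[1]); j <- floor(p[2]); k <- floor(p[3])
  fx <- p[1] - i; fy <- p[2] - j; fz <- p[3] - k
  v <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
         (if (dk) fz else 1 - fz)
    v <- v + w * vol[i + di + 1, j + dj + 1, k + dk + 1]
  }
  v
}

# OLS coefficients by solving the normal equations directly.
oracle_ols_residuals <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# Kruskal-Wallis H from the rank-sum definition with tie correction.
oracle_kruskal_h <- function(values_by_group) {
  x <- unlist(values_by_group, use.names = FALSE)
  n <- length(x)
  r <- rank(x)
  start <- 0
  H <- 0
  for (g in values_by_group) {
    ri <- r[(start + 1):(start + length(g))]
    H <- H + length(g) * (mean(ri) - (n + 1) / 2)^2
    start <- start + length(g)
  }
  H <- 12 / (n * (n + 1)) * H
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# A clean two-block group-Z matrix: strong within-block, weak across.
block_z_matrix <- function(sizes = c(4, 4), within = 5, between = 0.2) {
  n <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  Z <- matrix(between, n, n)
  for (b in seq_along(sizes)) Z[grp == b, grp == b] <- within
  diag(Z) <- NA
  rownames(Z) <- colnames(Z) <- as.character(seq_len(n))
  Z
}

# Small fixtures reused across files.
# Downscaled acquisition keeping the study's window proportions (baseline
# noise in the percent-change denominator stays realistically small).
tiny_config <- function(...) {
  sim_config(shape = c(10L, 10L, 3L), n_regions = 4L, n_acquisitions = 60L,
             baseline = c(0L, 25L), stimulation = c(40L, 60L), ...)
}

tiny_atlas <- function(config = tiny_config()) make_toy_atlas(config)
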