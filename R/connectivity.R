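#' Average voxel time series within atlas regions
#'
#' Per region, the unweighted mean over its voxels at each timepoint,
#' computed from residual (cleaned) images. Regions with no voxels are kept
#' as all-`NA` rows and flagged.
#'
#' @param bold a [bold_series()] of residuals.
#' @param atlas an [atlas()] on the same grid.
#' @return a `region_ts` matrix (regions x time) with attributes
#'   `region_ids`, `tr_seconds` and `missing_regions`.
#' @export
average_regions <- function(bold, atlas) {
  if (!identical(dim(bold$data)[1:3], atlas$grid$shape))
    stop("series and atlas are on different grids")
  tab <- atlas$region_table
  d <- dim(bold$data)
  mat <- matrix(bold$data, prod(d[1:3]), d[4])
  lab <- as.vector(atlas$labels)
  use <- as.vector(bold$mask) & lab > 0L
  sums <- rowsum(mat[use, , drop = FALSE], lab[use])
  counts <- as.vector(table(lab[use])[rownames(sums)])
  means <- sums / counts
  out <- matrix(NA_real_, nrow(tab), d[4])
  rownames(out) <- tab$region_id
  hit <- match(rownames(sums), as.character(tab$region_id))
  out[hit, ] <- means
  missing <- tab$region_id[is.na(out[, 1])]
  structure(out, region_ids = tab$region_id, tr_seconds = bold$tr_seconds,
            missing_regions = missing, class = "region_ts")
}

#' Region-to-region Pearson correlation matrix with Fisher z transform
#'
#' Pearson correlation across all region pairs (N regions give
#' `N (N - 1) / 2` unique pairs; the full 169-region atlas gives 14,196),
#' with unit diagonal, plus the elementwise Fisher z transform. Regions
#' with zero temporal variance (or missing series) are flagged and their
#' rows/columns set `NA` so downstream graphs exclude them.
#'
#' @param ts a `region_ts` matrix (regions x time), >= 3 timepoints.
#' @return object of class `connectivity_matrix`: `r`, `z`, `n_timepoints`,
#'   `n_pairs`, `flagged` (region ids excluded).
#' @export
pearson_matrix <- function(ts) {
  m <- unclass(ts)
  if (ncol(m) < 3L) stop("need at least 3 timepoints")
  sds <- apply(m, 1L, stats::sd)
  bad <- is.na(sds) | sds == 0
  r <- matrix(NA_real_, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  if (any(!bad)) {
    r[!bad, !bad] <- stats::cor(t(m[!bad, , drop = FALSE]))
  }
  diag(r)[!bad] <- 1
  ids <- attr(ts, "region_ids") %||% rownames(m)
  z <- fisher_z(r)
  diag(z) <- NA_real_                   # self-correlation carries no edge
  structure(list(r = r, z = z, n_timepoints = ncol(m),
                 n_pairs = sum(!bad) * (sum(!bad) - 1L) / 2L,
                 region_ids = ids, flagged = ids[bad]),
            class = "connectivity_matrix")
}

#' Fisher z transform of correlation coefficients
#'
#' `z = 0.5 * log((1 + r) / (1 - r)) = atanh(r)`, the variance-stabilising
#' map that improves the normality of sample correlations. Values at
#' exactly +/-1 are clipped to +/-(1 - 1e-7) (flagged via the `"clipped"`
#' attribute) so the transform stays finite.
#'
#' @param r numeric vector/matrix of correlations with `|r| <= 1`.
#' @return transformed values, same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  clip <- abs(r) >= 1 & !is.na(r)
  r[clip] <- sign(r[clip]) * (1 - 1e-7)
  out <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  if (any(clip)) attr(out, "clipped") <- which(clip)
  out
}

#' One-group Z matrix across subjects
#'
#' Per edge, a one-sample t-test of the subjects' Fisher-z values against
#' zero, converted to a standard-normal Z. The default conversion is
#' two-sided sign-preserving quantile matching:
#' `Z = sign(t) * qnorm(1 - p_two / 2)` with `p_two` from the t
#' distribution on n - 1 df; `method = "raw_t"` keeps the t value. Edges
#' with zero between-subject variance give infinite statistics and are
#' capped at `z_cap` and flagged.
#'
#' @param z_matrices list of per-subject symmetric Fisher-z matrices
#'   (>= 2, matching dimensions).
#' @param method `"quantile"` (default) or `"raw_t"`.
#' @param z_cap cap for infinite/overflowing Z values (default 8).
#' @return object of class `group_z_matrix`: `Z`, `n_subjects`, `method`,
#'   `capped` (index matrix of capped edges).
#' @export
group_z <- function(z_matrices, method = c("quantile", "raw_t"), z_cap = 8) {
  method <- match.arg(method)
  ns <- length(z_matrices)
  if (ns < 2L) stop("need at least 2 subjects")
  dims <- lapply(z_matrices, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("subject matrices must share dimensions")
  arr <- simplify2array(z_matrices)
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd)
  t_ <- m / (s / sqrt(ns))
  t_[!is.na(m) & m == 0 & !is.na(s) & s == 0] <- 0  # all-zero edge: no evidence
  if (method == "quantile") {
    p_two <- 2 * stats::pt(-abs(t_), df = ns - 1)
    Z <- sign(t_) * stats::qnorm(1 - p_two / 2)
  } else {
    Z <- t_
  }
  capped <- which(!is.na(Z) & abs(Z) > z_cap, arr.ind = TRUE)
  Z[!is.na(Z) & Z > z_cap] <- z_cap
  Z[!is.na(Z) & Z < -z_cap] <- -z_cap
  zero_var <- which(!is.na(s) & s == 0 & !is.na(m) & m != 0, arr.ind = TRUE)
  Z[zero_var] <- z_cap * sign(m[zero_var])
  diag(Z) <- NA_real_
  dimnames(Z) <- dimnames(z_matrices[[1]])
  structure(list(Z = Z, n_subjects = ns, method = method, z_cap = z_cap,
                 capped = rbind(capped, zero_var),
                 mean_z = m),
            class = "group_z_matrix")
}

#' Threshold a group Z matrix into a binary adjacency
#'
#' Keeps edges with `|Z| >= cutoff` (default 2.3, the conventional screen
#' against spurious or weak connections), zero diagonal, symmetric. `NA`
#' entries (flagged regions) never become edges.
#'
#' @param m a `group_z_matrix` or plain symmetric matrix.
#' @param cutoff nonnegative threshold.
#' @return binary adjacency matrix (0/1, symmetric, zero diagonal).
#' @export
threshold_z <- function(m, cutoff = 2.3) {
  if (cutoff < 0) stop("'cutoff' must be >= 0")
  Z <- if (inherits(m, "group_z_matrix")) m$Z else as.matrix(m)
  A <- (abs(Z) >= cutoff) * 1
  A[is.na(A)] <- 0
  diag(A) <- 0
  A[] <- pmax(A, t(A))                  # enforce symmetry
  A
}

#' Cluster regions by connectivity profile (mutual k-nearest neighbours)
#'
#' Each region's profile is its row of the group Z matrix. Profiles of
#' regions i and j are compared by correlation distance `1 - cor` over the
#' columns excluding i and j themselves (the self-entries carry no
#' information about similarity); each region keeps its k nearest
#' neighbours — ties at the k-th distance are all kept, so the result has
#' no order dependence — an undirected edge is drawn where the relation is
#' mutual, and the connected components of that mutual-kNN graph are the
#' clusters: how regions group into resting-state networks. Identical
#' profiles have distance 0 and always end up together.
#'
#' @param m a `group_z_matrix` or plain symmetric matrix.
#' @param k neighbours per region, `1 <= k < N`.
#' @return integer vector of cluster ids named by region.
#' @export
knn_cluster <- function(m, k = 5) {
  Z <- if (inherits(m, "group_z_matrix")) m$Z else as.matrix(m)
  diag(Z) <- 0
  keep <- which(rowSums(is.na(Z)) < ncol(Z))
  Zk <- Z[keep, keep, drop = FALSE]
  Zk[is.na(Zk)] <- 0
  n <- nrow(Zk)
  if (k < 1 || k >= n) stop(sprintf("'k' must be in [1, %d)", n))
  dist_ <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cols <- setdiff(seq_len(n), c(i, j))
      a <- Zk[i, cols]; b <- Zk[j, cols]
      d <- if (length(cols) < 2L || max(abs(a - b)) < 1e-12) {
        0
      } else {
        cc <- suppressWarnings(stats::cor(a, b))
        if (is.na(cc)) 2 else 1 - cc    # a constant vs varying profile
      }
      dist_[i, j] <- dist_[j, i] <- d
    }
  }
  diag(dist_) <- Inf
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    kth <- sort(dist_[i, ])[k]
    adj[i, dist_[i, ] <= kth + 1e-12] <- TRUE
  }
  mutual <- adj & t(adj)
  g <- igraph::graph_from_adjacency_matrix(mutual * 1, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- rep(NA_integer_, nrow(Z))
  out[keep] <- as.integer(comp)
  names(out) <- rownames(Z)
  out
}

#' Write a connectivity or group Z matrix as delimited text
#'
#' Region ids form the header row and first column.
#'
#' @param m matrix to write.
#' @param path output file.
#' @export
write_matrix <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Export a thresholded adjacency as an edge list
#'
#' One row per undirected suprathreshold edge: source, target, weight
#' (the |Z| of the group matrix), the format common graph tools ingest.
#'
#' @param A binary adjacency from [threshold_z()].
#' @param weights symmetric weight matrix (e.g. `abs(groupz$Z)`); defaults
#'   to the adjacency itself.
#' @return data.frame with columns `source`, `target`, `weight`.
#' @export
adjacency_edge_list <- function(A, weights = NULL) {
  if (is.null(weights)) weights <- A
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  ids <- rownames(A) %||% as.character(seq_len(nrow(A)))
  data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
             weight = weights[idx], stringsAsFactors = FALSE)
}
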