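#' BOLD percent-change map against the control window
#'
#' Per voxel, the percent change of each acquisition relative to that
#' voxel's mean over the pre-injection control window:
#' `pc(v, t) = 100 * (S(v, t) - B(v)) / B(v)`. Voxels outside the brain
#' mask, or whose baseline mean is not positive, are excluded (set `NA`)
#' and counted in the attached QC report.
#'
#' @param bold a [bold_series()].
#' @param windows a [window_spec()].
#' @return object of class `percent_change_map`: `pc` (4D array, percent
#'   units), `baseline_mean` (3D), `mask` (3D logical: voxels with a valid
#'   percent-change series), `windows`, and `qc` (counts of excluded
#'   voxels).
#' @export
percent_change <- function(bold, windows) {
  stopifnot(inherits(bold, "bold_series"), inherits(windows, "window_spec"))
  window_spec(windows$baseline, windows$stimulation, bold$n_acquisitions)
  d <- dim(bold$data)
  nvox <- prod(d[1:3])
  mat <- matrix(bold$data, nvox, d[4])
  B <- rowMeans(mat[, window_index(windows$baseline), drop = FALSE])
  valid <- as.vector(bold$mask) & is.finite(B) & B > 0
  pc <- matrix(NA_real_, nvox, d[4])
  pc[valid, ] <- 100 * (mat[valid, , drop = FALSE] / B[valid] - 1)
  structure(list(
    pc = array(pc, dim = d),
    baseline_mean = array(B, dim = d[1:3]),
    mask = array(valid, dim = d[1:3]),
    windows = windows,
    qc = list(n_nonpositive_baseline = sum(bold$mask & !(is.finite(B) & B > 0)),
              n_outside_mask = sum(!bold$mask))),
    class = "percent_change_map")
}

#' Apply the minimum signal-change floor
#'
#' A voxel enters statistical testing only if its percent change exceeds
#' the floor in magnitude at least once during the post-injection period
#' (every scan from the end of the control window onward). The default
#' floor of 1% is a conservative screen against spontaneous fluctuations;
#' it is a preprocessing step, not a significance claim. The boundary is
#' inclusive: a voxel peaking at exactly the floor is kept.
#'
#' @param pc a `percent_change_map` from [percent_change()].
#' @param floor_percent floor magnitude in percent (>= 0; 0 keeps all
#'   valid voxels).
#' @return logical 3D array of included voxels.
#' @export
apply_signal_floor <- function(pc, floor_percent = 1.0) {
  if (!is.finite(floor_percent) || floor_percent < 0)
    stop("'floor_percent' must be >= 0")
  d <- dim(pc$pc)
  post <- seq.int(pc$windows$baseline[2] + 1L, d[4])  # post-injection scans
  mat <- matrix(pc$pc, prod(d[1:3]), d[4])[, post, drop = FALSE]
  peak <- apply(abs(mat), 1L, max)
  array(as.vector(pc$mask) & !is.na(peak) & peak >= floor_percent,
        dim = d[1:3])
}

#' Voxelwise one-sample t-test of stimulation-window percent change
#'
#' For every included voxel, a two-tailed one-sample t-test of the
#' stimulation-window percent-change values against zero change:
#' `t = mean / (sd / sqrt(n))`, `df = n - 1`. Zero-variance voxels are
#' assigned p = 0 (nonzero mean) or p = 1 (all-zero) and flagged in QC.
#'
#' @param pc a `percent_change_map`.
#' @param included logical 3D array from [apply_signal_floor()].
#' @return object of class `voxel_tests`: 3D arrays `t`, `p`, `mean_pc`
#'   (stimulation-window mean percent change), logical `included`, `df`,
#'   and `qc`. The `significant` and `sign` layers are filled in by
#'   [voa_significance()].
#' @export
voxel_ttest <- function(pc, included) {
  stim <- window_index(pc$windows$stimulation)
  n <- length(stim)
  if (n < 3L) stop("stimulation window must contain at least 3 scans")
  d <- dim(pc$pc)
  mat <- matrix(pc$pc, prod(d[1:3]), d[4])[, stim, drop = FALSE]
  inc <- as.vector(included)
  m <- rowMeans(mat)
  sd_ <- sqrt(rowSums((mat - m)^2) / (n - 1))
  tval <- rep(NA_real_, length(m))
  pval <- rep(NA_real_, length(m))
  ok <- inc & sd_ > 0
  tval[ok] <- m[ok] / (sd_[ok] / sqrt(n))
  pval[ok] <- 2 * stats::pt(-abs(tval[ok]), df = n - 1)
  degen <- inc & sd_ == 0
  pval[degen] <- ifelse(m[degen] != 0, 0, 1)
  tval[degen] <- ifelse(m[degen] != 0, Inf * sign(m[degen]), 0)
  structure(list(
    t = array(tval, dim = d[1:3]), p = array(pval, dim = d[1:3]),
    mean_pc = array(ifelse(inc, m, NA_real_), dim = d[1:3]),
    included = included, df = n - 1L,
    qc = list(n_zero_variance = sum(degen))),
    class = "voxel_tests")
}

#' Welch two-sample alternative: baseline vs stimulation window
#'
#' Optional variant of the voxelwise test: Welch's unequal-variance
#' two-sample t between the baseline-window and stimulation-window
#' percent-change values of each included voxel.
#'
#' @inheritParams voxel_ttest
#' @return a `voxel_tests` object (fractional Welch `df` stored per map as
#'   the median over voxels).
#' @export
voxel_ttest_welch <- function(pc, included) {
  base <- window_index(pc$windows$baseline)
  stim <- window_index(pc$windows$stimulation)
  d <- dim(pc$pc)
  mat <- matrix(pc$pc, prod(d[1:3]), d[4])
  xb <- mat[, base, drop = FALSE]; xs <- mat[, stim, drop = FALSE]
  nb <- length(base); ns <- length(stim)
  mb <- rowMeans(xb); ms <- rowMeans(xs)
  vb <- rowSums((xb - mb)^2) / (nb - 1); vs <- rowSums((xs - ms)^2) / (ns - 1)
  se2 <- vb / nb + vs / ns
  inc <- as.vector(included)
  ok <- inc & se2 > 0
  tval <- rep(NA_real_, length(mb)); pval <- rep(NA_real_, length(mb))
  df <- se2^2 / ((vb / nb)^2 / (nb - 1) + (vs / ns)^2 / (ns - 1))
  tval[ok] <- (ms[ok] - mb[ok]) / sqrt(se2[ok])
  pval[ok] <- 2 * stats::pt(-abs(tval[ok]), df = df[ok])
  degen <- inc & se2 == 0
  pval[degen] <- ifelse(ms[degen] != mb[degen], 0, 1)
  tval[degen] <- ifelse(ms[degen] != mb[degen],
                        Inf * sign(ms - mb)[degen], 0)
  structure(list(
    t = array(tval, dim = d[1:3]), p = array(pval, dim = d[1:3]),
    mean_pc = array(ifelse(inc, ms, NA_real_), dim = d[1:3]),
    included = included, df = stats::median(df[ok]),
    qc = list(n_zero_variance = sum(degen))),
    class = "voxel_tests")
}

#' Benjamini-Hochberg step-up false-discovery-rate filter
#'
#' Sorts the V p-values ascending and finds the largest rank i with
#' `P(i) <= (i / V) * q / c(V)`; all p-values at or below that cutoff pass
#' (step-up rule, so tied p-values share the highest qualifying rank).
#' With `c_V = 1` this is the classical Benjamini-Hochberg procedure for
#' independent or positively dependent tests; `c_V = sum(1/i)` gives the
#' conservative arbitrary-dependence variant. The universe V is the set of
#' p-values handed in — for the voxel pipeline, the floor-included voxels
#' of one subject's brain mask, since filtering precedes testing.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q target false-discovery rate, in `(0, 1)`.
#' @param c_V the constant c(V) (default 1).
#' @return object of class `fdr_filter`: `V`, `q`, `c_V`, `cutoff_rank`
#'   (0 when nothing passes), `p_cutoff` (largest passing p, `NA` if none),
#'   `pass` (logical, input order), and `reported_fdr` (the BH-adjusted p
#'   at the cutoff rank — the "FDR was p = x" style summary; `NA` if none
#'   pass).
#' @export
fdr_filter <- function(p_values, q = 0.05, c_V = 1) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (!is.finite(q) || q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  V <- length(p)
  if (V == 0L)
    return(structure(list(V = 0L, q = q, c_V = c_V, cutoff_rank = 0L,
                          p_cutoff = NA_real_, pass = logical(0),
                          reported_fdr = NA_real_),
                     class = "fdr_filter"))
  ord <- order(p)                       # stable: ties keep input order
  ps <- p[ord]
  thresh <- (seq_len(V) / V) * q / c_V
  below <- which(ps <= thresh)
  cutoff_rank <- if (length(below)) max(below) else 0L
  p_cutoff <- if (cutoff_rank > 0L) ps[cutoff_rank] else NA_real_
  pass <- if (cutoff_rank > 0L) p <= p_cutoff else rep(FALSE, V)
  reported <- if (cutoff_rank > 0L) {
    adj <- rev(cummin(rev(pmin(ps * V * c_V / seq_len(V), 1))))
    adj[cutoff_rank]
  } else NA_real_
  structure(list(V = V, q = q, c_V = c_V, cutoff_rank = as.integer(cutoff_rank),
                 p_cutoff = p_cutoff, pass = pass, reported_fdr = reported),
            class = "fdr_filter")
}

#' Apply the FDR filter to a voxelwise test map
#'
#' Runs [fdr_filter()] over the included voxels of a [voxel_ttest()] result
#' and fills in the `significant` and `sign` layers (`+1`, `-1`, or `0`,
#' following the sign of the stimulation-window mean change).
#'
#' @param tests a `voxel_tests` object.
#' @param q target FDR.
#' @param c_V the constant c(V).
#' @return the `voxel_tests` object with `significant` (logical 3D),
#'   `sign` (integer 3D) and `fdr` (the `fdr_filter` result) added.
#' @export
voa_significance <- function(tests, q = 0.05, c_V = 1) {
  inc <- which(tests$included)
  f <- fdr_filter(tests$p[inc], q = q, c_V = c_V)
  sig <- array(FALSE, dim = dim(tests$p))
  sig[inc[f$pass]] <- TRUE
  sgn <- array(0L, dim = dim(tests$p))
  sgn[sig] <- ifelse(tests$mean_pc[sig] > 0, 1L, -1L)
  tests$significant <- sig
  tests$sign <- sgn
  tests$fdr <- f
  tests
}

#' Count per-region volumes of activation
#'
#' For every atlas region: the number of significant voxels with positive
#' stimulation-window mean change (positive VoA), the analogous negative
#' count, and both normalised by the region's voxel count. Regions with no
#' voxels in the label volume get `NA` fractions.
#'
#' @param tests a `voxel_tests` object that has passed through
#'   [voa_significance()].
#' @param atlas an [atlas()] on the same grid.
#' @return data.frame of class `region_activation_table` with columns
#'   `region_id`, `name`, `macro_region`, `positive_voa`, `negative_voa`,
#'   `region_n_voxels`, `positive_fraction`, `negative_fraction`.
#' @export
count_voa <- function(tests, atlas) {
  if (is.null(tests$significant))
    stop("run voa_significance() before count_voa()")
  if (!identical(dim(tests$p), atlas$grid$shape))
    stop("tests and atlas are on different grids")
  tab <- atlas$region_table
  lab <- as.vector(atlas$labels)
  sig <- as.vector(tests$significant)
  sgn <- as.vector(tests$sign)
  nb <- max(tab$region_id)
  pos <- tabulate(lab[sig & sgn > 0L], nbins = nb)[tab$region_id]
  neg <- tabulate(lab[sig & sgn < 0L], nbins = nb)[tab$region_id]
  out <- data.frame(region_id = tab$region_id, name = tab$name,
                    macro_region = tab$macro_region,
                    positive_voa = as.integer(pos),
                    negative_voa = as.integer(neg),
                    region_n_voxels = tab$n_voxels,
                    stringsAsFactors = FALSE)
  out$positive_fraction <- ifelse(out$region_n_voxels > 0,
                                  out$positive_voa / out$region_n_voxels, NA)
  out$negative_fraction <- ifelse(out$region_n_voxels > 0,
                                  out$negative_voa / out$region_n_voxels, NA)
  class(out) <- c("region_activation_table", "data.frame")
  out
}

#' Group composite map via inverse transforms and trilinear sampling
#'
#' For each voxel of the target (atlas-space) grid, each subject's
#' contribution is pulled from its own map by applying the inverse of the
#' subject-to-atlas transform and sampling trilinearly; the composite value
#' is the mean over subjects that land in bounds. Voxels where every
#' subject is out of bounds are `NA` and counted in the QC attribute.
#'
#' @param subject_maps list of 3D arrays (e.g. stimulation-window mean
#'   percent-change maps), one per subject.
#' @param transforms list of [affine_transform()]s (subject to atlas), one
#'   per subject.
#' @param target_grid the composite [volume_grid()].
#' @param subject_grids optional list of each subject's [volume_grid()];
#'   defaults to unit-voxel grids over each map's dimensions.
#' @return 3D array on `target_grid` with attributes `n_contributing`
#'   (3D integer) and `qc` (count of all-out-of-bounds voxels).
#' @export
composite_map <- function(subject_maps, transforms, target_grid,
                          subject_grids = NULL) {
  ns <- length(subject_maps)
  if (ns < 1L) stop("need at least one subject map")
  if (length(transforms) != ns) stop("one transform per subject map required")
  if (is.null(subject_grids))
    subject_grids <- lapply(subject_maps, function(m) volume_grid(dim(m)))
  shape <- target_grid$shape
  vox <- as.matrix(expand.grid(x = 0:(shape[1] - 1L), y = 0:(shape[2] - 1L),
                               z = 0:(shape[3] - 1L)))
  world <- voxel_to_world(target_grid, vox)
  acc <- numeric(nrow(vox))
  cnt <- integer(nrow(vox))
  for (j in seq_len(ns)) {
    inv <- affine_inverse(transforms[[j]])
    subj_world <- apply_affine(inv, world)
    subj_vox <- world_to_voxel(subject_grids[[j]], subj_world)
    val <- trilinear_sample(subject_maps[[j]], subj_vox)
    inb <- !attr(val, "oob") & !is.na(val)
    acc[inb] <- acc[inb] + val[inb]
    cnt <- cnt + inb
  }
  out <- ifelse(cnt > 0L, acc / cnt, NA_real_)
  out <- array(out, dim = shape)
  attr(out, "n_contributing") <- array(cnt, dim = shape)
  attr(out, "qc") <- list(n_uncovered = sum(cnt == 0L))
  out
}

#' Stimulation-window mean percent-change map for one subject
#'
#' @param pc a `percent_change_map`.
#' @return 3D array of window-mean percent change (`NA` outside the valid
#'   mask).
#' @export
window_mean_map <- function(pc) {
  stim <- window_index(pc$windows$stimulation)
  d <- dim(pc$pc)
  m <- rowMeans(matrix(pc$pc, prod(d[1:3]), d[4])[, stim, drop = FALSE])
  array(ifelse(as.vector(pc$mask), m, NA_real_), dim = d[1:3])
}

#' Group-mean region time course with standard errors
#'
#' For a set of regions (e.g. the somatosensory areas pooled), averages
#' each subject's percent change over the union of the regions' voxels at
#' every acquisition, then reports the across-subject mean and standard
#' error per acquisition — the group time-course trace with its 1%-floor
#' context.
#'
#' @param pc_maps list of `percent_change_map`s, one per subject (>= 2).
#' @param atlas shared [atlas()].
#' @param region_ids nonempty set of region ids to pool.
#' @return data.frame with columns `acquisition` (0-based), `time_seconds`,
#'   `mean`, `se`.
#' @param tr_seconds repetition time used for the time axis.
#' @export
region_timecourse <- function(pc_maps, atlas, region_ids, tr_seconds = 6) {
  if (!length(region_ids)) stop("region_ids must be nonempty")
  if (length(pc_maps) < 2L) stop("need at least 2 subjects for a standard error")
  sel <- as.vector(atlas$labels %in% region_ids)
  if (!any(sel)) stop("no atlas voxels carry the requested region ids")
  traces <- vapply(pc_maps, function(pc) {
    d <- dim(pc$pc)
    mat <- matrix(pc$pc, prod(d[1:3]), d[4])
    colMeans(mat[sel & as.vector(pc$mask), , drop = FALSE])
  }, numeric(dim(pc_maps[[1]]$pc)[4]))
  n <- ncol(traces)
  data.frame(acquisition = seq_len(nrow(traces)) - 1L,
             time_seconds = (seq_len(nrow(traces)) - 1L) * tr_seconds,
             mean = rowMeans(traces),
             se = apply(traces, 1L, stats::sd) / sqrt(n))
}
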