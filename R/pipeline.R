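#' Resolved analysis configuration
#'
#' One place for every analysis constant, with the standard defaults:
#' control window scans 0-50 and stimulation window scans 200-240
#' (half-open, 0-based), 1% signal floor, voxel FDR q = 0.05 with
#' c(V) = 1, group-Z edge threshold |Z| = 2.3, band-pass 0.01-0.1 Hz,
#' smoothing FWHM 0.8 mm, k = 5 mutual nearest neighbours.
#'
#' @param baseline,stimulation half-open scan windows.
#' @param floor_percent signal floor in percent.
#' @param q voxel/region FDR target.
#' @param c_V FDR constant c(V).
#' @param z_cutoff group-Z edge threshold.
#' @param bandpass_hz band edges `c(low, high)` in Hz.
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param knn_k neighbours for profile clustering.
#' @param seed integer seed for any stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(baseline = c(0, 50), stimulation = c(200, 240),
                            floor_percent = 1.0, q = 0.05, c_V = 1,
                            z_cutoff = 2.3, bandpass_hz = c(0.01, 0.1),
                            fwhm_mm = 0.8, knn_k = 5, seed = 1L) {
  windows <- window_spec(baseline, stimulation)
  if (floor_percent < 0) stop("floor_percent must be >= 0")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (z_cutoff < 0) stop("z_cutoff must be >= 0")
  structure(list(windows = windows, floor_percent = floor_percent, q = q,
                 c_V = c_V, z_cutoff = z_cutoff, bandpass_hz = bandpass_hz,
                 fwhm_mm = fwhm_mm, knn_k = knn_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Evoked-response analysis of one subject
#'
#' The per-subject chain: percent change against the control window, the
#' signal floor, the voxelwise one-sample t map, the Benjamini-Hochberg
#' filter over the included voxels, and the per-region VoA counts.
#'
#' @param bold a [bold_series()].
#' @param atlas an [atlas()] on the same grid.
#' @param config a [pipeline_config()].
#' @return list of class `voa_result`: `tests` (with significance layers),
#'   `voa` (region activation table), `pc_map` (window-mean percent-change
#'   3D map), `included` and the `percent_change_map` QC.
#' @export
run_voa_subject <- function(bold, atlas, config = pipeline_config()) {
  windows <- window_spec(config$windows$baseline, config$windows$stimulation,
                         bold$n_acquisitions)
  pc <- percent_change(bold, windows)
  included <- apply_signal_floor(pc, config$floor_percent)
  tests <- voxel_ttest(pc, included)
  tests <- voa_significance(tests, q = config$q, c_V = config$c_V)
  structure(list(tests = tests, voa = count_voa(tests, atlas),
                 pc_map = window_mean_map(pc), included = included,
                 qc = pc$qc),
            class = "voa_result")
}

#' Group evoked-response analysis
#'
#' Runs [run_voa_subject()] for every subject, assembles the per-region
#' per-group VoA summary, ranks regions by the Kruskal-Wallis dose test
#' (positive and negative VoA separately) with the across-region FDR
#' filter, and builds one composite percent-change map per dose group.
#'
#' @param bolds named list of [bold_series()], names = subject ids.
#' @param design a [study_design()] covering those subjects.
#' @param atlas shared [atlas()].
#' @param config a [pipeline_config()].
#' @param transforms optional named list of [affine_transform()]s
#'   (subject to atlas); identity if omitted.
#' @return list of class `voa_group_result`: `subjects` (per-subject
#'   results), `positive` / `negative` (ranked Kruskal-Wallis tables from
#'   [rank_and_flag()]), `composites` (per-dose 3D maps).
#' @export
run_voa_group <- function(bolds, design, atlas, config = pipeline_config(),
                          transforms = NULL) {
  ids <- design$subject_id
  if (!all(ids %in% names(bolds)))
    stop(sprintf("missing BOLD series for subject(s): %s",
                 paste(setdiff(ids, names(bolds)), collapse = ", ")))
  subjects <- lapply(stats::setNames(ids, ids),
                     function(s) run_voa_subject(bolds[[s]], atlas, config))
  doses <- sort(unique(design$dose_mg_per_kg))
  rank_one <- function(column) {
    rows <- lapply(seq_len(nrow(atlas$region_table)), function(i) {
      rid <- atlas$region_table$region_id[i]
      by_group <- lapply(stats::setNames(doses, format(doses, trim = TRUE)),
                         function(d) {
        subs <- ids[design$dose_mg_per_kg == d]
        vapply(subs, function(s) subjects[[s]]$voa[[column]][i], numeric(1))
      })
      kruskal_dose_test(by_group, region_id = rid,
                        name = atlas$region_table$name[i])
    })
    rank_and_flag(do.call(rbind, rows), q = config$q, c_V = config$c_V)
  }
  composites <- lapply(stats::setNames(doses, format(doses, trim = TRUE)),
                       function(d) {
    subs <- ids[design$dose_mg_per_kg == d]
    maps <- lapply(subs, function(s) {
      m <- subjects[[s]]$pc_map
      m[is.na(m)] <- 0
      m
    })
    tf <- if (is.null(transforms)) {
      rep(list(affine_transform(diag(4))), length(subs))
    } else transforms[subs]
    composite_map(maps, tf, atlas$grid)
  })
  structure(list(subjects = subjects, positive = rank_one("positive_voa"),
                 negative = rank_one("negative_voa"),
                 composites = composites, design = design),
            class = "voa_group_result")
}

#' Resting-state connectivity for one subject
#'
#' Cleans each region's series (band-pass, detrend, optional nuisance
#' regression) and computes the Pearson/Fisher-z connectivity matrix.
#'
#' @param ts a `region_ts` (regions x time), e.g. from
#'   [simulate_resting_state()] or [average_regions()].
#' @param config a [pipeline_config()].
#' @param nuisance optional [nuisance_set()].
#' @param tr_seconds sampling interval; defaults to the `region_ts`
#'   attribute.
#' @return a `connectivity_matrix`.
#' @export
run_rsfc_subject <- function(ts, config = pipeline_config(), nuisance = NULL,
                             tr_seconds = attr(ts, "tr_seconds") %||% 1) {
  cleaned <- t(apply(unclass(ts), 1L, clean_series, tr_seconds = tr_seconds,
                     nuisance = nuisance, low_hz = config$bandpass_hz[1],
                     high_hz = config$bandpass_hz[2]))
  rownames(cleaned) <- rownames(ts)
  attr(cleaned, "region_ids") <- attr(ts, "region_ids")
  pearson_matrix(cleaned)
}

#' Group resting-state network analysis
#'
#' One-group Z matrix across subjects' Fisher-z matrices, the |Z| >= cutoff
#' adjacency, the brain graph weighted by |Z| on suprathreshold edges, its
#' global metrics, per-macro-region degree distributions, and the
#' mutual-kNN profile clustering.
#'
#' @param conn_list list of `connectivity_matrix` objects (>= 2 subjects).
#' @param atlas shared [atlas()].
#' @param config a [pipeline_config()].
#' @return list of class `rsfc_group_result`: `group_z`, `adjacency`,
#'   `graph`, `metrics`, `degrees`, `macro_degrees`, `clusters`.
#' @export
run_rsfc_group <- function(conn_list, atlas, config = pipeline_config()) {
  gz <- group_z(lapply(conn_list, `[[`, "z"))
  A <- threshold_z(gz, cutoff = config$z_cutoff)
  rownames(A) <- colnames(A) <- as.character(atlas$region_table$region_id)
  g <- brain_graph(A, weights = abs(gz$Z))
  structure(list(group_z = gz, adjacency = A, graph = g,
                 metrics = global_metrics(g),
                 degrees = degree_centrality(g),
                 macro_degrees = macro_region_degrees(g, atlas$region_table),
                 clusters = knn_cluster(gz, k = min(config$knn_k,
                                                    nrow(A) - 1L))),
            class = "rsfc_group_result")
}
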