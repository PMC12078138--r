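#' Configuration for the synthetic phMRI study generator
#'
#' Bundles every tunable of the synthetic test bed. The defaults mirror the
#' acquisition this package models: 250 acquisitions at TR 6 s (25 min),
#' a 50-scan (5 min) pre-injection control window, a stimulation window over
#' scans 200-240, spontaneous voxel fluctuations on the order of +/-1%
#' (noise SD 0.5% with AR(1) temporal correlation), and a monotone
#' dose-response staircase across the four dose groups (vehicle, 0.03, 0.3,
#' 3.0 mg/kg) in both response amplitude and responsive extent. Resting-state
#' runs are 200 timepoints at TR 1 s with planted community structure
#' (within-community Pearson r 0.6) and a planted hub region.
#'
#' @param seed integer seed; all randomness in a generated object flows from
#'   it (one RNG stream per session).
#' @param shape grid shape in voxels.
#' @param n_regions number of atlas regions (<= 169).
#' @param n_macro_regions number of macro-region groups (<= 11).
#' @param tr_seconds,n_acquisitions acquisition timing of the phMRI run.
#' @param baseline,stimulation half-open 0-based scan windows.
#' @param noise_sd_percent SD of spontaneous percent-signal fluctuations.
#' @param drift_percent_per_scan linear drift slope (percent per scan).
#' @param ar1_coefficient lag-1 autocorrelation of the temporal noise, in
#'   `[0, 1)`.
#' @param dose_amplitudes named numeric map dose (mg/kg, as character) to
#'   plateau percent-change amplitude.
#' @param dose_extent named numeric map dose to the fraction of each
#'   region's voxels that respond, in `[0, 1]`.
#' @param spike_probability per-scan probability of a global motion spike.
#' @param spike_amplitude_percent magnitude of a spike frame (percent).
#' @param n_subjects_per_group subjects per dose group in a generated study.
#' @param sex_amplitude_ratio female/male multiplier on response amplitude
#'   (1 = no planted sex effect).
#' @param rs_n_timepoints,rs_tr_seconds resting-state run length and TR.
#' @param rs_target_r within-community Pearson correlation, in `(-1, 1)`.
#' @param rs_n_communities number of planted communities (>= 2).
#' @param rs_hub_r target Pearson correlation between the hub region and
#'   each of its partners.
#' @param rs_partner_weight variance share each partner devotes to its
#'   hub-pair factor (bounds the attainable `rs_hub_r`).
#' @param rs_n_partners number of hub partners (default 4).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       shape = c(32L, 32L, 8L),
                       n_regions = 12L,
                       n_macro_regions = 11L,
                       tr_seconds = 6,
                       n_acquisitions = 250L,
                       baseline = c(0L, 50L),
                       stimulation = c(200L, 240L),
                       noise_sd_percent = 0.5,
                       drift_percent_per_scan = 0,
                       ar1_coefficient = 0.3,
                       dose_amplitudes = c("0" = 0, "0.03" = 1, "0.3" = 2, "3" = 3),
                       dose_extent = c("0" = 0, "0.03" = 0.3, "0.3" = 0.5, "3" = 0.8),
                       spike_probability = 0,
                       spike_amplitude_percent = 3,
                       n_subjects_per_group = 6L,
                       sex_amplitude_ratio = 1,
                       rs_n_timepoints = 200L,
                       rs_tr_seconds = 1,
                       rs_target_r = 0.6,
                       rs_n_communities = 4L,
                       rs_hub_r = 0.4,
                       rs_partner_weight = 0.7,
                       rs_n_partners = 4L) {
  cfg <- list(seed = as.integer(seed), shape = as.integer(shape),
              n_regions = as.integer(n_regions),
              n_macro_regions = as.integer(n_macro_regions),
              tr_seconds = tr_seconds, n_acquisitions = as.integer(n_acquisitions),
              baseline = as.integer(baseline), stimulation = as.integer(stimulation),
              noise_sd_percent = noise_sd_percent,
              drift_percent_per_scan = drift_percent_per_scan,
              ar1_coefficient = ar1_coefficient,
              dose_amplitudes = dose_amplitudes, dose_extent = dose_extent,
              spike_probability = spike_probability,
              spike_amplitude_percent = spike_amplitude_percent,
              n_subjects_per_group = as.integer(n_subjects_per_group),
              sex_amplitude_ratio = sex_amplitude_ratio,
              rs_n_timepoints = as.integer(rs_n_timepoints),
              rs_tr_seconds = rs_tr_seconds, rs_target_r = rs_target_r,
              rs_n_communities = as.integer(rs_n_communities),
              rs_hub_r = rs_hub_r,
              rs_partner_weight = rs_partner_weight,
              rs_n_partners = as.integer(rs_n_partners))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  window_spec(cfg$baseline, cfg$stimulation, cfg$n_acquisitions)
  if (cfg$n_regions < 2L || cfg$n_regions > 169L)
    stop("n_regions must be between 2 and 169")
  if (cfg$n_macro_regions < 1L || cfg$n_macro_regions > 11L)
    stop("n_macro_regions must be between 1 and 11")
  if (cfg$ar1_coefficient < 0 || cfg$ar1_coefficient >= 1)
    stop("ar1_coefficient must be in [0, 1)")
  if (any(!is.finite(cfg$dose_amplitudes))) stop("dose amplitudes must be finite")
  if (any(cfg$dose_extent < 0 | cfg$dose_extent > 1))
    stop("dose extents must lie in [0, 1]")
  if (!identical(names(cfg$dose_amplitudes), names(cfg$dose_extent)))
    stop("dose_amplitudes and dose_extent must share the same dose keys")
  if (cfg$spike_probability < 0 || cfg$spike_probability > 1)
    stop("spike_probability must be in [0, 1]")
  if (abs(cfg$rs_target_r) >= 1)
    stop("rs_target_r must lie strictly inside (-1, 1)")
  if (abs(cfg$rs_hub_r) >= 1)
    stop("rs_hub_r must lie strictly inside (-1, 1)")
  if (cfg$rs_n_partners > 0L &&
      cfg$rs_n_partners * cfg$rs_hub_r^2 / cfg$rs_partner_weight > 1)
    stop("hub variance budget exceeded: reduce rs_hub_r or rs_n_partners")
  invisible(cfg)
}

# the 11 macro-region group names used for regional summaries
macro_region_names <- function() {
  c("Prefrontal ctx", "Somatosensory ctx", "Olfactory system", "Basal ganglia",
    "Thalamus", "Hippocampus", "Amygdala", "Hypothalamus", "Midbrain",
    "Brainstem", "Cerebellum")
}

#' Build a toy labelled atlas
#'
#' Tiles the interior of the grid (one background voxel of border on the x
#' and y faces) with `n_regions` contiguous rectangular blocks, each a
#' region, and assigns regions to macro-region groups round-robin. A stand-in
#' for a full segmented rodent atlas: the label/table contract is identical,
#' only the geometry is simplified.
#'
#' @param config a [sim_config()].
#' @return an [atlas()] whose region table has `n_regions` rows.
#' @export
make_toy_atlas <- function(config = sim_config()) {
  shape <- config$shape
  nr <- config$n_regions
  nx <- ceiling(sqrt(nr))
  ny <- ceiling(nr / nx)
  ix <- shape[1] - 2L  # interior extent after the 1-voxel border
  iy <- shape[2] - 2L
  if (ix < nx || iy < ny || shape[3] < 1L)
    stop(sprintf("grid too small for %d regions: need at least %d x %d x 1 (got %s)",
                 nr, nx + 2L, ny + 2L, paste(shape, collapse = "x")))
  labels <- array(0L, dim = shape)
  xb <- floor(seq(0L, ix, length.out = nx + 1L))
  yb <- floor(seq(0L, iy, length.out = ny + 1L))
  id <- 0L
  for (jy in seq_len(ny)) {
    for (jx in seq_len(nx)) {
      if (id >= nr) break
      id <- id + 1L
      labels[(1L + xb[jx] + 1L):(1L + xb[jx + 1L]),
             (1L + yb[jy] + 1L):(1L + yb[jy + 1L]), ] <- id
    }
  }
  groups <- macro_region_names()[seq_len(config$n_macro_regions)]
  tab <- data.frame(
    region_id = seq_len(nr),
    name = sprintf("Region %02d", seq_len(nr)),
    macro_region = groups[((seq_len(nr) - 1L) %% length(groups)) + 1L],
    stringsAsFactors = FALSE)
  atlas(labels, tab, grid = volume_grid(shape))
}

# AR(1) noise matrix (rows = series) with stationary SD `sd`
ar1_noise <- function(n_series, n_time, sd, rho) {
  e <- matrix(stats::rnorm(n_series * n_time), n_series, n_time)
  if (rho > 0) {
    innov_sd <- sqrt(1 - rho^2)
    e[, 1] <- e[, 1]
    for (t in 2:n_time) e[, t] <- rho * e[, t - 1] + innov_sd * e[, t]
  }
  e * sd
}

# ramp response profile: 0 through the control window, linear rise from
# `onset` to 1 at `plateau`, then sustained
ramp_profile <- function(n_time, onset, plateau) {
  t <- seq_len(n_time) - 1L
  pmin(pmax((t - onset) / max(plateau - onset, 1L), 0), 1)
}

#' Simulate one phMRI scanning session with planted dose-scaled activation
#'
#' Every masked voxel fluctuates around a baseline of 100 scanner units with
#' AR(1) noise of the configured SD (percent), optional linear drift and
#' optional global spike frames. In each region, a `dose_extent` fraction of
#' voxels is responsive: their signal ramps from the first post-injection
#' scan to the configured plateau amplitude by the start of the stimulation
#' window and stays elevated — an immediate rise to a sustained plateau, the
#' shape of the evoked somatosensory response this bed emulates. The planted
#' truth (per-region amplitude and exact responsive voxel set) is returned
#' alongside the series for parameter-recovery testing.
#'
#' @param atlas an [atlas()], typically from [make_toy_atlas()].
#' @param dose dose in mg/kg; must be a key of `config$dose_amplitudes`.
#' @param config a [sim_config()].
#' @param seed RNG seed for this session (default `config$seed`).
#' @param amplitude_scale extra multiplier on the planted amplitude (used
#'   for planted sex effects).
#' @return list of class `phmri_session`: `bold` (a [bold_series()]) and
#'   `truth` (amplitudes, responsive voxel indices, dose, windows).
#' @export
simulate_phmri_session <- function(atlas, dose, config = sim_config(),
                                   seed = config$seed, amplitude_scale = 1) {
  validate_sim_config(config)
  key <- format(dose, scientific = FALSE, trim = TRUE)
  if (!key %in% names(config$dose_amplitudes))
    stop(sprintf("dose %s has no configured amplitude (keys: %s)", key,
                 paste(names(config$dose_amplitudes), collapse = ", ")))
  set.seed(as.integer(seed))
  shape <- atlas$grid$shape
  n_time <- config$n_acquisitions
  mask <- atlas$labels > 0L
  vox <- which(mask)
  nvox <- length(vox)

  pc <- ar1_noise(nvox, n_time, config$noise_sd_percent, config$ar1_coefficient)
  if (config$drift_percent_per_scan != 0)
    pc <- pc + rep(config$drift_percent_per_scan * (seq_len(n_time) - 1L),
                   each = nvox)
  if (config$spike_probability > 0) {
    spikes <- which(stats::runif(n_time) < config$spike_probability)
    for (s in spikes)
      pc[, s] <- pc[, s] + sample(c(-1, 1), 1L) * config$spike_amplitude_percent
  } else spikes <- integer(0)

  amplitude <- config$dose_amplitudes[[key]] * amplitude_scale
  extent <- config$dose_extent[[key]]
  onset <- config$baseline[2]          # first post-injection scan (0-based)
  plateau <- config$stimulation[1]
  profile <- ramp_profile(n_time, onset, plateau)

  ids <- atlas$region_table$region_id
  responsive <- stats::setNames(vector("list", length(ids)), ids)
  truth_amp <- stats::setNames(rep(0, length(ids)), ids)
  if (amplitude != 0 && extent > 0) {
    lab_vox <- atlas$labels[vox]
    for (r in ids) {
      rv <- which(lab_vox == r)
      k <- round(extent * length(rv))
      if (k > 0L) {
        sel <- sort(sample(rv, k))
        pc[sel, ] <- pc[sel, ] + amplitude * rep(profile, each = k)
        responsive[[as.character(r)]] <- vox[sel]
        truth_amp[as.character(r)] <- amplitude
      }
    }
  }

  data <- array(100, dim = c(shape, n_time))
  idx <- rep(vox, n_time) +
    rep((seq_len(n_time) - 1L) * prod(shape), each = nvox)
  data[idx] <- 100 * (1 + pc / 100)

  bold <- bold_series(data, atlas$grid, tr_seconds = config$tr_seconds,
                      mask = mask)
  truth <- list(dose = dose, amplitude_percent = truth_amp,
                extent = extent, responsive_voxels = responsive,
                spike_scans = spikes, onset_scan = onset,
                windows = window_spec(config$baseline, config$stimulation,
                                      n_time))
  structure(list(bold = bold, truth = truth), class = "phmri_session")
}

#' Simulate a resting-state run with planted community and hub structure
#'
#' Generates one region-by-time matrix of standardised BOLD fluctuations.
#' The last region is a designated hub standing outside the communities
#' (the deep-nuclei pattern: few local neighbours, many long-range
#' partners); the remaining regions are split into `rs_n_communities`
#' consecutive blocks whose members share a latent signal with mixing
#' weight `rs_target_r`, so the expected within-community Pearson
#' correlation equals `rs_target_r`. The hub shares a private factor with
#' each of `rs_n_partners` partner regions, giving each hub-partner pair an
#' expected correlation of `rs_hub_r` without correlating the partners with
#' one another. The truth sidecar records community assignments (`NA` for
#' the hub) and the planted hub edge set.
#'
#' @inheritParams simulate_phmri_session
#' @return list of class `rs_session`: `ts` (a `region_ts`: regions x time
#'   matrix with `region_ids` and `tr_seconds` attributes) and `truth`
#'   (community per region, hub region, hub partner set).
#' @export
simulate_resting_state <- function(atlas, config = sim_config(),
                                   seed = config$seed) {
  validate_sim_config(config)
  nr <- nrow(atlas$region_table)
  if (nr < 4L) stop("resting-state simulation needs at least 4 regions")
  n_time <- config$rs_n_timepoints
  w <- config$rs_target_r
  if (w < 0) stop("rs_target_r must be nonnegative for the planted design")
  hub <- nr
  ncom <- min(config$rs_n_communities, nr - 1L)
  community <- rep(seq_len(ncom), each = ceiling((nr - 1L) / ncom))[seq_len(nr - 1L)]
  community <- c(community, NA_integer_)  # hub belongs to no community
  # the planted structure is a property of the condition, shared by every
  # subject: draw it from the config seed, then switch to the session seed
  # for this subject's noise
  set.seed(config$seed)
  partners <- sort(sample(seq_len(nr - 1L),
                          min(config$rs_n_partners, nr - 1L)))
  set.seed(as.integer(seed))

  latent <- matrix(stats::rnorm(ncom * n_time), ncom, n_time)
  eps <- matrix(stats::rnorm(nr * n_time), nr, n_time)
  pair <- matrix(stats::rnorm(max(length(partners), 1L) * n_time),
                 max(length(partners), 1L), n_time)

  h <- config$rs_partner_weight         # partner share on its hub factor
  g <- if (length(partners)) config$rs_hub_r^2 / h else 0
  cw <- rep(w, nr)                      # community variance share
  cw[partners] <- min(w, 1 - h - 0.05)  # partners keep a noise floor
  cw[hub] <- 0
  hw <- rep(0, nr)
  hw[partners] <- h

  ts <- matrix(0, nr, n_time)
  for (i in seq_len(nr)) {
    s <- if (is.na(community[i])) 0 else sqrt(cw[i]) * latent[community[i], ]
    if (i %in% partners)
      s <- s + sqrt(hw[i]) * pair[match(i, partners), ]
    if (i == hub && length(partners))
      s <- s + sqrt(g) * colSums(pair[seq_along(partners), , drop = FALSE])
    hub_share <- if (i == hub) g * length(partners) else 0
    noise_var <- 1 - (if (is.na(community[i])) 0 else cw[i]) - hw[i] - hub_share
    ts[i, ] <- s + sqrt(max(noise_var, 0)) * eps[i, ]
  }
  rownames(ts) <- atlas$region_table$region_id
  structure(list(
    ts = structure(ts, region_ids = atlas$region_table$region_id,
                   tr_seconds = config$rs_tr_seconds, class = "region_ts"),
    truth = list(community = stats::setNames(community,
                                             atlas$region_table$region_id),
                 hub_region = atlas$region_table$region_id[hub],
                 hub_partners = atlas$region_table$region_id[partners])),
    class = "rs_session")
}

#' Expand region time series to a voxelwise BOLD series
#'
#' Broadcasts each region's series to its atlas voxels plus independent
#' voxel-level noise, producing a [bold_series()] whose region averages
#' recover the input series. Used to exercise the voxel-to-region averaging
#' path on resting-state data.
#'
#' @param ts a `region_ts` from [simulate_resting_state()].
#' @param voxel_noise_sd SD of the added independent voxel noise.
#' @inheritParams simulate_phmri_session
#' @export
region_series_to_bold <- function(atlas, ts, voxel_noise_sd = 0.2,
                                  seed = 1L) {
  set.seed(as.integer(seed))
  n_time <- ncol(ts)
  shape <- atlas$grid$shape
  mask <- atlas$labels > 0L
  vox <- which(mask)
  lab_vox <- atlas$labels[vox]
  row_of <- match(lab_vox, attr(ts, "region_ids"))
  m <- ts[row_of, , drop = FALSE] +
    matrix(stats::rnorm(length(vox) * n_time, sd = voxel_noise_sd),
           length(vox), n_time)
  data <- array(0, dim = c(shape, n_time))
  idx <- rep(vox, n_time) +
    rep((seq_len(n_time) - 1L) * prod(shape), each = length(vox))
  data[idx] <- m
  bold_series(data, atlas$grid,
              tr_seconds = attr(ts, "tr_seconds") %||% 1, mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate and write a complete synthetic study to disk
#'
#' Builds the toy atlas, a balanced study design (`n_subjects_per_group`
#' per dose, split male/female), one phMRI session per subject (written as
#' NIfTI-1 with a JSON planted-truth sidecar and a JSON identity transform)
#' and one resting-state region-series table per subject, then writes the
#' design table and a manifest.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, the manifest data.frame (one row per written file).
#' @export
simulate_study <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atl <- make_toy_atlas(config)
  write_atlas(atl, file.path(out_dir, "atlas_labels.nii.gz"),
              file.path(out_dir, "atlas_regions.tsv"))
  doses <- as.numeric(names(config$dose_amplitudes))
  n <- config$n_subjects_per_group
  design <- study_design(
    subject_id = sprintf("sub-%02d", seq_len(n * length(doses))),
    dose_mg_per_kg = rep(doses, each = n),
    sex = rep(rep(c("male", "female"), length.out = n), length(doses)))
  write_design(design, file.path(out_dir, "design.tsv"))
  files <- list()
  for (i in seq_len(nrow(design))) {
    sid <- design$subject_id[i]
    scale <- if (design$sex[i] == "female") config$sex_amplitude_ratio else 1
    ses <- simulate_phmri_session(atl, design$dose_mg_per_kg[i], config,
                                  seed = config$seed + i,
                                  amplitude_scale = scale)
    bold_path <- file.path(out_dir, paste0(sid, "_bold.nii.gz"))
    write_bold(ses$bold, bold_path)
    truth <- ses$truth
    truth$responsive_voxels <- lapply(truth$responsive_voxels, as.integer)
    truth$windows <- NULL
    jsonlite::write_json(truth, file.path(out_dir, paste0(sid, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
    write_transform(affine_transform(diag(4)),
                    file.path(out_dir, paste0(sid, "_transform.json")))
    rs <- simulate_resting_state(atl, config, seed = config$seed + 10000L + i)
    utils::write.table(rs$ts, file.path(out_dir, paste0(sid, "_rs.tsv")),
                       sep = "\t", col.names = FALSE, quote = FALSE)
    files[[sid]] <- data.frame(subject_id = sid, bold = basename(bold_path),
                               stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, files)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
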