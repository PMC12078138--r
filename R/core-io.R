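#' Define a 3D sampling grid
#'
#' A `volume_grid` records the voxel lattice shared by a BOLD series, its
#' brain mask and the atlas: the number of voxels per axis, the physical
#' voxel size in mm, and the world-space position of the first voxel centre.
#' Continuous coordinates place voxel centres at integer indices and indexing
#' is 0-based, so voxel (i, j, k) sits at `origin + c(i, j, k) * voxel_size`
#' in world (mm) space.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0). Recycled from length 1.
#' @param origin numeric vector of length 3, world position (mm) of voxel
#'   (0, 0, 0). Defaults to the world origin.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three positive integers")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive lengths (mm)")
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(origin))) stop("'origin' must be finite (mm)")
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Convert between world (mm) and continuous voxel coordinates
#'
#' @param grid a [volume_grid()].
#' @param points numeric matrix (n x 3) or vector of length 3.
#' @return matrix (n x 3) of coordinates in the other frame.
#' @keywords internal
world_to_voxel <- function(grid, points) {
  p <- as_point_matrix(points)
  sweep(sweep(p, 2L, grid$origin, "-"), 2L, grid$voxel_size, "/")
}

#' @rdname world_to_voxel
#' @keywords internal
voxel_to_world <- function(grid, points) {
  p <- as_point_matrix(points)
  sweep(sweep(p, 2L, grid$voxel_size, "*"), 2L, grid$origin, "+")
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("points must have 3 columns (x, y, z)")
  p
}

#' Construct a BOLD time series object
#'
#' Bundles a subject's 4D acquisition with its grid, repetition time and
#' brain mask. One scanning session in the study design this package models
#' is 250 acquisitions at TR 6 s (25 min).
#'
#' @param data 4D numeric array (x, y, z, t) in arbitrary scanner units.
#' @param grid a [volume_grid()] matching `dim(data)[1:3]`.
#' @param tr_seconds positive repetition time in seconds.
#' @param mask logical 3D array marking brain voxels; defaults to all `TRUE`.
#' @return object of class `bold_series` with fields `data`, `grid`,
#'   `tr_seconds`, `n_acquisitions`, `mask`.
#' @export
bold_series <- function(data, grid, tr_seconds, mask = NULL) {
  if (length(dim(data)) != 4L) stop("'data' must be a 4D array (x, y, z, t)")
  if (!inherits(grid, "volume_grid")) stop("'grid' must be a volume_grid")
  if (!identical(dim(data)[1:3], grid$shape))
    stop("data spatial dimensions do not match the grid shape")
  tr_seconds <- as.numeric(tr_seconds)
  if (!is.finite(tr_seconds) || tr_seconds <= 0) stop("'tr_seconds' must be > 0")
  if (is.null(mask)) {
    mask <- array(TRUE, dim = grid$shape)
  } else {
    if (!identical(dim(mask), grid$shape)) stop("mask shape does not match grid")
    mask <- array(as.logical(mask), dim = grid$shape)
  }
  inmask <- data[array(mask, dim = dim(data))]
  if (any(!is.finite(inmask)))
    stop("non-finite voxel values inside the brain mask")
  structure(list(data = data, grid = grid, tr_seconds = tr_seconds,
                 n_acquisitions = dim(data)[4L], mask = mask),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %s voxels x %d acquisitions, TR %.3g s (%.3g min total), %d masked voxels\n",
              paste(x$grid$shape, collapse = "x"), x$n_acquisitions,
              x$tr_seconds, x$n_acquisitions * x$tr_seconds / 60,
              sum(x$mask)))
  invisible(x)
}

#' Analysis windows over the acquisition axis
#'
#' Scan intervals are half-open, 0-based: `c(0, 50)` means scans 0..49, the
#' 5-minute pre-injection control window at TR 6 s. The default stimulation
#' window `c(200, 240)` covers scans 200..239 late in the post-injection
#' period.
#'
#' @param baseline integer vector `c(start, stop)`, half-open control window.
#' @param stimulation integer vector `c(start, stop)`, half-open test window.
#' @param n_acquisitions optional series length used to validate bounds.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(baseline = c(0, 50), stimulation = c(200, 240),
                        n_acquisitions = NULL) {
  chk <- function(w, nm) {
    w <- as.integer(w)
    if (length(w) != 2L || any(is.na(w)) || w[1] < 0L || w[2] <= w[1])
      stop(sprintf("'%s' must be a non-empty half-open interval c(start, stop)", nm))
    w
  }
  baseline <- chk(baseline, "baseline")
  stimulation <- chk(stimulation, "stimulation")
  if (baseline[2] > stimulation[1])
    stop("baseline window must end at or before the stimulation window starts")
  if (!is.null(n_acquisitions) && stimulation[2] > n_acquisitions)
    stop(sprintf("stimulation window ends at %d but the series has %d acquisitions",
                 stimulation[2], as.integer(n_acquisitions)))
  structure(list(baseline = baseline, stimulation = stimulation),
            class = "window_spec")
}

# 1-based R index vector for a half-open 0-based scan interval
window_index <- function(interval) seq.int(interval[1] + 1L, interval[2])

#' Read and write 4D BOLD series as NIfTI-1
#'
#' `read_bold()` loads a 4D NIfTI-1 image; grid geometry and TR are taken
#' from the header (`pixdim`). `write_bold()` writes the series back so that
#' it round-trips through `read_bold()`. An optional companion mask file
#' (3D, nonzero = brain) restricts the analysis; otherwise all voxels are in
#' the mask.
#'
#' @param path NIfTI-1 file name (`.nii` or `.nii.gz`).
#' @param mask_path optional NIfTI-1 file with a 3D brain mask.
#' @return `read_bold()` returns a [bold_series()]; `write_bold()` returns
#'   `path` invisibly.
#' @export
read_bold <- function(path, mask_path = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected 4D image in %s, got %dD (axes %s)",
                 path, length(d), paste(d, collapse = "x")))
  pd <- RNifti::pixdim(img)
  grid <- volume_grid(d[1:3], voxel_size = pd[1:3])
  tr <- if (length(pd) >= 4L && is.finite(pd[4]) && pd[4] > 0) pd[4] else 1
  arr <- array(as.numeric(img), dim = d)
  if (any(!is.finite(arr)))
    stop(sprintf("non-finite voxel values in %s", path))
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    if (length(dim(m)) != 3L)
      stop(sprintf("expected 3D mask in %s", mask_path))
    mask <- array(as.numeric(m) != 0, dim = dim(m))
  }
  bold_series(arr, grid, tr_seconds = tr, mask = mask)
}

#' @rdname read_bold
#' @param bold a [bold_series()] to write.
#' @export
write_bold <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(bold$grid$voxel_size, bold$tr_seconds)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read and write 3D volumes (masks, label volumes, statistical maps)
#'
#' Integer label volumes are stored with an integer datatype so labels
#' round-trip exactly; real-valued maps are stored as float.
#'
#' @param path NIfTI-1 file name.
#' @param vol 3D array to write.
#' @param voxel_size voxel edge lengths in mm.
#' @param integer_labels write with an integer datatype (exact round-trip).
#' @return `read_volume()` returns a 3D array with a `voxel_size` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("expected 3D image in %s, got %dD", path, length(dim(img))))
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)[1:3]
  out
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, voxel_size = c(1, 1, 1),
                         integer_labels = FALSE) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path,
                     datatype = if (integer_labels) "int32" else "float")
  invisible(path)
}

#' Construct an atlas from a label volume and region table
#'
#' The atlas assigns every brain voxel an integer region label (0 =
#' background). The study-scale atlas this emulates has 169 segmented areas
#' grouped into 11 macro-regions; `region_table` carries that grouping. The
#' table's `n_voxels` column is validated against (or filled from) the label
#' volume.
#'
#' @param labels 3D integer array of region labels, 0 = background.
#' @param region_table data.frame with columns `region_id`, `name`,
#'   `macro_region` and optionally `n_voxels`.
#' @param grid a [volume_grid()]; defaults to unit voxels over `dim(labels)`.
#' @return object of class `atlas`.
#' @export
atlas <- function(labels, region_table, grid = NULL) {
  labels <- array(as.integer(labels), dim = dim(labels))
  if (length(dim(labels)) != 3L) stop("'labels' must be a 3D array")
  if (is.null(grid)) grid <- volume_grid(dim(labels))
  if (!identical(dim(labels), grid$shape)) stop("labels do not match grid shape")
  req <- c("region_id", "name", "macro_region")
  if (!all(req %in% names(region_table)))
    stop("region_table needs columns region_id, name, macro_region")
  region_table <- as.data.frame(region_table, stringsAsFactors = FALSE)
  region_table$region_id <- as.integer(region_table$region_id)
  if (anyDuplicated(region_table$region_id)) stop("region ids must be unique")
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(present, region_table$region_id)
  if (length(missing))
    stop(sprintf("labels present in the volume but absent from region_table: %s",
                 paste(missing, collapse = ", ")))
  counts <- tabulate(labels[labels > 0L], nbins = max(region_table$region_id))
  n_vox <- counts[region_table$region_id]
  n_vox[is.na(n_vox)] <- 0L
  if (!is.null(region_table$n_voxels)) {
    if (!all(region_table$n_voxels == n_vox))
      stop("region_table n_voxels disagrees with the label volume")
  }
  region_table$n_voxels <- as.integer(n_vox)
  structure(list(labels = labels, region_table = region_table, grid = grid),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("<atlas> %s voxels, %d regions in %d macro-regions, %d labelled voxels\n",
              paste(x$grid$shape, collapse = "x"), nrow(x$region_table),
              length(unique(x$region_table$macro_region)),
              sum(x$region_table$n_voxels)))
  invisible(x)
}

#' Read/write an atlas as a NIfTI label volume plus a region table
#'
#' The region table is UTF-8 tab-separated text with a header row
#' (`region_id`, `name`, `macro_region`, `n_voxels`). Label volumes
#' round-trip exactly (integer datatype); resampling of label volumes, if
#' ever needed, should be nearest-neighbour — labels are categorical.
#'
#' @param label_path NIfTI-1 file with the 3D integer labels.
#' @param table_path tab-separated region table.
#' @param x an [atlas()] to write.
#' @return `read_atlas()` returns an [atlas()].
#' @export
read_atlas <- function(label_path, table_path) {
  vol <- read_volume(label_path)
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  atlas(round(vol), tab,
        grid = volume_grid(dim(vol), voxel_size = attr(vol, "voxel_size")))
}

#' @rdname read_atlas
#' @export
write_atlas <- function(x, label_path, table_path) {
  write_volume(x$labels, label_path, voxel_size = x$grid$voxel_size,
               integer_labels = TRUE)
  utils::write.table(x$region_table, table_path, sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(x)
}

#' Affine subject-to-atlas transforms
#'
#' Each subject's spatial normalisation is summarised as a single 4x4
#' homogeneous matrix mapping subject world coordinates (mm) into atlas
#' space; composite-map construction applies the inverse to pull subject
#' values into the common space. Transforms are stored as JSON: 16 numbers,
#' row-major.
#'
#' @param matrix 4x4 numeric matrix, last row `(0, 0, 0, 1)`, invertible.
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(matrix) {
  m <- base::matrix(as.numeric(matrix), 4L, 4L)
  if (any(!is.finite(m))) stop("affine matrix must be finite")
  if (!isTRUE(all.equal(m[4, ], c(0, 0, 0, 1), tolerance = 1e-12)))
    stop("last row of an affine matrix must be (0, 0, 0, 1)")
  if (!is.finite(kappa(m, exact = TRUE)) || abs(det(m)) < 1e-12)
    stop("affine matrix must be invertible")
  structure(list(matrix = m), class = "affine_transform")
}

#' @rdname affine_transform
#' @param t an `affine_transform`.
#' @export
affine_inverse <- function(t) affine_transform(solve(t$matrix))

#' Apply an affine transform to points
#'
#' Homogeneous matrix-vector product with the trailing coordinate dropped.
#' Translation, rotation and scaling — the components the registration
#' pipeline composes — are all expressible this way.
#'
#' @param t an [affine_transform()].
#' @param points length-3 vector or n x 3 matrix of mm coordinates.
#' @return coordinates in the target frame, same shape as the input.
#' @export
apply_affine <- function(t, points) {
  vec <- is.null(dim(points))
  p <- as_point_matrix(points)
  if (any(!is.finite(p))) stop("points must be finite")
  out <- cbind(p, 1) %*% t(t$matrix)
  out <- out[, 1:3, drop = FALSE]
  if (vec && nrow(out) == 1L) drop(out) else out
}

#' Read/write affine transforms as JSON
#'
#' @param path JSON file holding 16 numbers, row-major.
#' @export
read_transform <- function(path) {
  v <- as.numeric(unlist(jsonlite::fromJSON(path)))
  if (length(v) != 16L) stop(sprintf("expected 16 numbers in %s", path))
  affine_transform(matrix(v, 4L, 4L, byrow = TRUE))
}

#' @rdname read_transform
#' @param t an [affine_transform()] to write.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(as.numeric(t(t$matrix)), path, digits = NA)
  invisible(path)
}

#' Sample a volume at continuous voxel coordinates by trilinear interpolation
#'
#' The value at a fractional coordinate is the weighted average of its eight
#' neighbouring voxels, the weight of each corner being the product of the
#' per-axis complementary fractional distances. Coordinates are 0-based with
#' voxel centres at integers. Points outside `[0, dim - 1]` on any axis take
#' `fill` and are flagged in the `"oob"` attribute — composite averaging
#' must know which contributions to drop rather than averaging in garbage.
#'
#' @param vol 3D numeric array.
#' @param points length-3 vector or n x 3 matrix of continuous voxel
#'   coordinates.
#' @param fill value returned for out-of-bounds points (default 0).
#' @return numeric vector of sampled values with a logical `"oob"` attribute
#'   marking out-of-bounds points.
#' @export
trilinear_sample <- function(vol, points, fill = 0) {
  d <- dim(vol)
  if (length(d) != 3L) stop("'vol' must be a 3D array")
  p <- as_point_matrix(points)
  n <- nrow(p)
  oob <- p[, 1] < 0 | p[, 1] > d[1] - 1 |
         p[, 2] < 0 | p[, 2] > d[2] - 1 |
         p[, 3] < 0 | p[, 3] > d[3] - 1
  oob <- oob | apply(!is.finite(p), 1L, any)
  out <- rep(as.numeric(fill), n)
  if (any(!oob)) {
    q <- p[!oob, , drop = FALSE]
    lo <- floor(q)
    fr <- q - lo
    i0 <- lo[, 1] + 1L; j0 <- lo[, 2] + 1L; k0 <- lo[, 3] + 1L
    # points on the upper face have zero fractional weight towards the
    # clamped corner, so clamping keeps the 8-corner stencil in bounds
    i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2]); k1 <- pmin(k0 + 1L, d[3])
    fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
    at <- function(ii, jj, kk) vol[cbind(ii, jj, kk)]
    val <-
      at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
      at(i1, j0, k0) * fx       * (1 - fy) * (1 - fz) +
      at(i0, j1, k0) * (1 - fx) * fy       * (1 - fz) +
      at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz       +
      at(i1, j1, k0) * fx       * fy       * (1 - fz) +
      at(i1, j0, k1) * fx       * (1 - fy) * fz       +
      at(i0, j1, k1) * (1 - fx) * fy       * fz       +
      at(i1, j1, k1) * fx       * fy       * fz
    out[!oob] <- val
  }
  attr(out, "oob") <- oob
  out
}

#' Study design table
#'
#' One row per subject: identifier, psilocybin dose in mg/kg (0 = vehicle,
#' 0.03, 0.3 or 3.0) and sex. Stored as UTF-8 tab-separated text with a
#' header row.
#'
#' @param subject_id character vector of unique subject ids.
#' @param dose_mg_per_kg numeric vector drawn from `{0, 0.03, 0.3, 3}`.
#' @param sex character vector, `"male"` or `"female"`.
#' @return data.frame of class `study_design`.
#' @export
study_design <- function(subject_id, dose_mg_per_kg, sex) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("subject ids must be unique")
  dose_mg_per_kg <- as.numeric(dose_mg_per_kg)
  if (!all(dose_mg_per_kg %in% dose_levels()))
    stop(sprintf("doses must be one of {%s} mg/kg",
                 paste(dose_levels(), collapse = ", ")))
  sex <- rep_len(as.character(sex), length(subject_id))
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  df <- data.frame(subject_id = subject_id, dose_mg_per_kg = dose_mg_per_kg,
                   sex = sex,
                   stringsAsFactors = FALSE)
  class(df) <- c("study_design", "data.frame")
  df
}

#' @rdname study_design
#' @export
dose_levels <- function() c(0, 0.03, 0.3, 3)

#' @rdname study_design
#' @param path tab-separated file.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  study_design(df$subject_id, df$dose_mg_per_kg, df$sex)
}

#' @rdname study_design
#' @param design a `study_design` to write.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
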