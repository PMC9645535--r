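#' Resample a volume onto an isotropic grid
#'
#' Converts a (possibly anisotropic) volume to isotropic voxels of size
#' `target_mm`, preserving the physical extent to within one target voxel per
#' axis. Images use trilinear interpolation; label masks must use nearest
#' neighbour so that no new labels are invented.
#'
#' @param v a [ct_volume()] or [label_mask()].
#' @param target_mm target isotropic voxel size in mm (default 1).
#' @param interpolation `"linear"` or `"nearest"`. Defaults to `"nearest"`
#'   for label masks and `"linear"` otherwise.
#' @return A resampled volume of the same class as `v`.
#' @export
resample_isotropic <- function(v, target_mm = 1,
                               interpolation = if (inherits(v, "label_mask"))
                                 "nearest" else "linear") {
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("resample_isotropic: target_mm must be a positive scalar", call. = FALSE)
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  if (inherits(v, "label_mask") && interpolation != "nearest")
    stop("resample_isotropic: label masks must use nearest interpolation",
         call. = FALSE)
  dims_out <- pmax(1L, as.integer(round(dim(v$data) * v$spacing / target_mm)))
  resample_to_geometry(v, dims_out, rep(target_mm, 3), v$origin, interpolation)
}

#' Resample a volume onto an explicit output geometry
#'
#' @param v a [ct_volume()] or [label_mask()].
#' @param dims_out integer length-3 output grid.
#' @param spacing_out,origin_out output voxel geometry (mm).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return A volume of the same class as `v` on the requested grid.
#' @export
resample_to_geometry <- function(v, dims_out, spacing_out, origin_out,
                                 interpolation = if (inherits(v, "label_mask"))
                                   "nearest" else "linear") {
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  out <- resample_grid_cpp(v$data * 1.0, v$spacing, v$origin,
                           as.integer(dims_out), as.numeric(spacing_out),
                           as.numeric(origin_out),
                           interpolation == "nearest")
  if (inherits(v, "label_mask"))
    label_mask(out, spacing_out, origin_out)
  else
    ct_volume(out, spacing_out, origin_out)
}

#' Down-sample a volume for the ROI-detection stage
#'
#' Every axis is divided by `factor`; output dimensions are rounded half away
#' from zero, so a 512 x 512 in-plane grid at the default factor 3.2 becomes
#' 160 x 160. The down-sampled rendition is only used to localize the aorta;
#' segmentation itself runs at full resolution on the cropped ROIs.
#'
#' @param v a [ct_volume()] or [label_mask()].
#' @param factor linear down-sampling factor, must be > 1.
#' @return A volume of the same class as `v`.
#' @export
downsample_for_roi <- function(v, factor = 3.2) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 1)
    stop("downsample_for_roi: factor must be > 1", call. = FALSE)
  dims_out <- pmax(1L, round_half_up(dim(v$data) / factor))
  spacing_out <- v$spacing * dim(v$data) / dims_out
  resample_to_geometry(v, dims_out, spacing_out, v$origin)
}

# round half away from zero (base round() goes to even)
round_half_up <- function(x) as.integer(trunc(x + 0.5 * sign(x)))

#' Clip and rescale intensities to \[0, 1\]
#'
#' Values are clipped to `window` and affinely mapped so that
#' `window[1] -> 0` and `window[2] -> 1`. The default window (-100, 400)
#' HU-like units spans soft tissue through contrast-enhanced blood.
#'
#' @param v a [ct_volume()].
#' @param window numeric length-2 `(low, high)`, `low < high`.
#' @return A [ct_volume()] with values in \[0, 1\].
#' @export
normalize_intensity <- function(v, window = c(-100, 400)) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("normalize_intensity: window must satisfy low < high", call. = FALSE)
  x <- pmin(pmax(v$data, window[1]), window[2])
  ct_volume((x - window[1]) / (window[2] - window[1]), v$spacing, v$origin)
}
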