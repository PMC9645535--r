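#' Axis-aligned bounding box (0-based, half-open)
#'
#' @param lo,hi integer voxel indices per axis; `lo` inclusive, `hi`
#'   exclusive, 0-based (the package-wide convention).
#' @param region anatomical tag, `"thoracic"` or `"abdominal"`.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(lo, hi, region = c("abdominal", "thoracic")) {
  region <- match.arg(region)
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (any(lo >= hi)) stop("bounding_box: lo must be < hi per axis", call. = FALSE)
  structure(list(lo = lo, hi = hi, region = region), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> %s [%s) x [%s) x [%s)\n", x$region,
              paste(x$lo[1], x$hi[1], sep = ","),
              paste(x$lo[2], x$hi[2], sep = ","),
              paste(x$lo[3], x$hi[3], sep = ",")))
  invisible(x)
}

clip_box <- function(lo, hi, dims) {
  lo <- pmax(lo, 0L); hi <- pmin(hi, as.integer(dims))
  if (any(lo >= hi)) return(NULL)
  list(lo = lo, hi = hi)
}

#' Detect aortic ROI bounding boxes from a low-resolution probability map
#'
#' Thresholds the foreground probability, keeps the largest connected
#' component (components below `min_volume_mm3` are discarded as noise), and
#' derives bounding boxes. For contrast volumes the component is split into
#' a thoracic and a descending/abdominal box: scanning axial slices from
#' superior, the thoracic box ends at the most inferior slice where the
#' aorta has at least two in-plane components (ascending plus descending,
#' i.e. below the arch), with a margin added to both boxes; without such a
#' slice a single abdominal box is returned. Non-contrast volumes always
#' yield one abdominal box. Boxes are padded, clipped, and mapped back to
#' the high-resolution grid through `factor`.
#'
#' @param prob a `prob_volume` from [predict.unet3d()] (foreground
#'   probability = 1 - background class), or a [ct_volume()] holding a
#'   foreground-probability grid.
#' @param contrast logical: split into thoracic + abdominal boxes.
#' @param threshold foreground probability threshold.
#' @param factor linear factor mapping the low-resolution grid back to the
#'   full-resolution one (the ROI down-sampling factor).
#' @param pad padding in (low-resolution) voxels on every side.
#' @param margin_mm craniocaudal margin around the thoracic/abdominal split.
#' @param min_volume_mm3 components smaller than this are ignored.
#' @return List of [bounding_box()]es in high-resolution voxel coordinates.
#' @export
detect_rois <- function(prob, contrast = TRUE, threshold = 0.5, factor = 3.2,
                        pad = 10L, margin_mm = 20, min_volume_mm3 = 1000) {
  if (inherits(prob, "prob_volume")) {
    C <- dim(prob$probs)[4]
    fg <- 1 - prob$probs[, , , 1]
    spacing <- prob$spacing
  } else {
    fg <- prob$data
    spacing <- prob$spacing
  }
  if (min(fg) < -1e-6 || max(fg) > 1 + 1e-6)
    stop("detect_rois: probabilities must lie in [0, 1]", call. = FALSE)
  sel <- fg >= threshold
  if (!any(sel))
    stop("detect_rois: no voxel above threshold ", threshold,
         " (empty detection)", call. = FALSE)
  lab <- cc_label_cpp(array(as.integer(sel), dim(sel)), 26L)
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab * prod(spacing) >= min_volume_mm3)
  if (!length(keep)) keep <- which.max(tab)
  main <- which.max(tab)
  comp <- array(lab == main, dim(sel))
  d <- dim(comp)
  pad <- as.integer(pad)

  box_from <- function(sel3, region) {
    w <- which(sel3, arr.ind = TRUE)
    lo <- apply(w, 2, min) - 1L - pad
    hi <- apply(w, 2, max) + pad  # half-open: max index + 1 + pad - 1
    cl <- clip_box(as.integer(lo), as.integer(hi), d)
    scale_box(bounding_box(cl$lo, cl$hi, region), factor, d)
  }
  scale_box <- function(b, f, dims_low) {
    dims_high <- as.integer(round(dims_low * f))
    lo <- as.integer(floor(b$lo * f))
    hi <- as.integer(ceiling(b$hi * f))
    cl <- clip_box(lo, hi, dims_high)
    bounding_box(cl$lo, cl$hi, b$region)
  }

  if (!contrast) return(list(box_from(comp, "abdominal")))

  ncomp_per_slice <- vapply(seq_len(d[3]), function(k) {
    sl <- comp[, , k]
    if (!any(sl)) return(0L)
    l2 <- cc_label_cpp(array(as.integer(sl), c(d[1:2], 1L)), 26L)
    max(l2)
  }, integer(1))
  multi <- which(ncomp_per_slice >= 2L)
  if (!length(multi)) {
    message("detect_rois: no arch found in contrast volume; ",
            "returning a single abdominal box")
    return(list(box_from(comp, "abdominal")))
  }
  z_split <- min(multi)  # most inferior slice still showing two limbs
  m_vox <- as.integer(round(margin_mm / spacing[3]))
  zfg <- range(which(apply(comp, 3, any)))
  thor_lo <- max(zfg[1], z_split - m_vox)
  abd_hi <- min(zfg[2], z_split + m_vox)
  thor <- comp; thor[, , seq_len(d[3]) < thor_lo] <- FALSE
  abd <- comp; abd[, , seq_len(d[3]) > abd_hi] <- FALSE
  out <- list()
  if (any(thor)) out <- c(out, list(box_from(thor, "thoracic")))
  if (any(abd)) out <- c(out, list(box_from(abd, "abdominal")))
  out
}

#' Crop a volume to a bounding box
#'
#' Spacing is preserved and the origin shifted so world coordinates remain
#' consistent.
#'
#' @param v a [ct_volume()] or [label_mask()].
#' @param box a [bounding_box()] (0-based, half-open).
#' @return A volume of the same class as `v`.
#' @export
crop_volume <- function(v, box) {
  d <- dim(v$data)
  cl <- clip_box(box$lo, box$hi, d)
  if (is.null(cl)) stop("crop_volume: box empty after clipping to grid",
                        call. = FALSE)
  ix <- (cl$lo[1] + 1):cl$hi[1]
  iy <- (cl$lo[2] + 1):cl$hi[2]
  iz <- (cl$lo[3] + 1):cl$hi[3]
  data <- v$data[ix, iy, iz, drop = FALSE]
  origin <- v$origin + cl$lo * v$spacing
  if (inherits(v, "label_mask")) label_mask(data, v$spacing, origin)
  else ct_volume(data, v$spacing, origin)
}

#' Stitch ROI probability maps back into a full-grid label mask
#'
#' Each part's class probabilities are placed into the full grid; where
#' boxes overlap, the class with the maximum probability wins. Voxels
#' outside every box are background.
#'
#' @param parts list of `list(prob = prob_volume, box = bounding_box)`.
#' @param full_shape integer length-3 full grid.
#' @param spacing,origin geometry of the full grid.
#' @param n_classes number of classes (inferred from the parts by default).
#' @return A [label_mask()] on the full grid.
#' @export
stitch_predictions <- function(parts, full_shape, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0), n_classes = NULL) {
  full_shape <- as.integer(full_shape)
  if (is.null(n_classes))
    n_classes <- max(vapply(parts, function(p) dim(p$prob$probs)[4], integer(1)))
  best_p <- array(0, full_shape)   # winning probability
  best_c <- array(0L, full_shape)  # winning class
  for (p in parts) {
    cl <- clip_box(p$box$lo, p$box$hi, full_shape)
    if (is.null(cl)) stop("stitch_predictions: box empty after clipping",
                          call. = FALSE)
    ix <- (cl$lo[1] + 1):cl$hi[1]
    iy <- (cl$lo[2] + 1):cl$hi[2]
    iz <- (cl$lo[3] + 1):cl$hi[3]
    pr <- p$prob$probs
    stopifnot(all(dim(pr)[1:3] == cl$hi - cl$lo))
    C <- dim(pr)[4]
    m <- matrix(pr, ncol = C)
    cls <- max.col(m, ties.method = "first") - 1L
    val <- m[cbind(seq_len(nrow(m)), cls + 1L)]
    cur_p <- best_p[ix, iy, iz]
    cur_c <- best_c[ix, iy, iz]
    take <- val > as.vector(cur_p)
    cur_p[take] <- val[take]
    cur_c[take] <- cls[take]
    best_p[ix, iy, iz] <- cur_p
    best_c[ix, iy, iz] <- cur_c
  }
  label_mask(best_c, spacing, origin)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

run_cascade <- function(v, models, contrast, window, iso_mm, roi_factor,
                        threshold = 0.5, provenance_dir = NULL) {
  stopifnot(inherits(v, "ct_volume"))
  norm <- pipeline_stage("normalize", normalize_intensity(v, window))
  iso <- pipeline_stage("isotropic", resample_isotropic(norm, iso_mm))
  low <- pipeline_stage("roi_downsample", downsample_for_roi(iso, roi_factor))
  roi_prob <- pipeline_stage("roi_predict", predict(models$roi, low))
  boxes <- pipeline_stage("detect_rois",
                          detect_rois(roi_prob, contrast = contrast,
                                      threshold = threshold,
                                      factor = roi_factor))
  parts <- lapply(boxes, function(b) {
    mdl <- if (contrast) {
      if (b$region == "thoracic" && !is.null(models$thoracic))
        models$thoracic else models$abdominal
    } else models$abdominal
    crop <- pipeline_stage(paste0("crop_", b$region), crop_volume(iso, b))
    pr <- pipeline_stage(paste0("segment_", b$region), predict(mdl, crop))
    list(prob = pr, box = b)
  })
  stitched <- pipeline_stage("stitch",
                             stitch_predictions(parts, dim(iso$data),
                                                iso$spacing, iso$origin))
  out <- pipeline_stage("to_input_grid",
                        resample_to_geometry(stitched, dim(v$data), v$spacing,
                                             v$origin, "nearest"))
  if (!is.null(provenance_dir)) {
    if (!dir.exists(provenance_dir)) dir.create(provenance_dir, recursive = TRUE)
    prov <- list(contrast = contrast, window = window, iso_mm = iso_mm,
                 roi_factor = roi_factor, threshold = threshold,
                 boxes = lapply(boxes, function(b)
                   list(lo = b$lo, hi = b$hi, region = b$region)))
    jsonlite::write_json(prov, file.path(provenance_dir, "pipeline.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the full contrast-CT segmentation cascade
#'
#' Normalize, resample to isotropic voxels, down-sample for ROI detection,
#' predict the aortic mask at low resolution, derive the thoracic and
#' descending/abdominal bounding boxes, segment each cropped ROI at full
#' resolution, stitch, and resample the multi-class mask (background /
#' lumen / WS-ILT) back onto the input grid.
#'
#' @param v the contrast-enhanced [ct_volume()] (raw HU-like intensities).
#' @param models list with fitted [fit_unet()] models: `roi` (2-class, on
#'   the down-sampled grid), `abdominal` and optionally `thoracic`
#'   (3-class, full resolution).
#' @param window intensity normalization window.
#' @param iso_mm isotropic working resolution, mm.
#' @param roi_factor ROI down-sampling factor.
#' @param provenance_dir if given, per-stage provenance is written there as
#'   JSON.
#' @return A [label_mask()] with classes `{0, 1, 2}` on the input grid.
#' @export
run_contrast <- function(v, models, window = c(-100, 400), iso_mm = 1,
                         roi_factor = 3.2, provenance_dir = NULL) {
  run_cascade(v, models, contrast = TRUE, window = window, iso_mm = iso_mm,
              roi_factor = roi_factor, provenance_dir = provenance_dir)
}

#' Run the non-contrast segmentation cascade
#'
#' As [run_contrast()], but a single abdominal bounding box is derived and
#' the output is a single-class aorta mask `{0, 1}`.
#'
#' @inheritParams run_contrast
#' @param models list with `roi` and `abdominal` (both 2-class).
#' @return A [label_mask()] with classes `{0, 1}` on the input grid.
#' @export
run_noncontrast <- function(v, models, window = c(-100, 400), iso_mm = 1,
                            roi_factor = 3.2, provenance_dir = NULL) {
  run_cascade(v, models, contrast = FALSE, window = window, iso_mm = iso_mm,
              roi_factor = roi_factor, provenance_dir = provenance_dir)
}
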