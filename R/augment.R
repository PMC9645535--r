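#' Divergence warp field
#'
#' A sum of Gaussian-windowed radial displacement bumps
#' `u(x) = sum_k m_k (x - c_k)/||x - c_k|| exp(-||x - c_k||^2 / (2 sigma_k^2))`
#' applied by backward warping: positive magnitudes locally dilate the image
#' around the control point, negative magnitudes contract it. This realizes
#' a locally divergent/convergent non-linear deformation at predefined
#' locations with few parameters.
#'
#' @param control_points m x 3 matrix of control points, 0-based voxel indices.
#' @param magnitudes signed displacement magnitude per point, mm.
#' @param radii Gaussian window sigma per point, mm (> 0).
#' @return An object of class `warp_field`.
#' @export
warp_field <- function(control_points, magnitudes, radii) {
  cp <- matrix(as.numeric(control_points), ncol = 3)
  if (length(magnitudes) != nrow(cp) || length(radii) != nrow(cp))
    stop("warp_field: need one magnitude and radius per control point",
         call. = FALSE)
  if (any(radii <= 0)) stop("warp_field: radii must be > 0", call. = FALSE)
  if (any(!is.finite(magnitudes)))
    stop("warp_field: magnitudes must be finite", call. = FALSE)
  structure(list(control_points = cp, magnitudes = as.numeric(magnitudes),
                 radii = as.numeric(radii)), class = "warp_field")
}

#' Apply a divergence warp jointly to an image and its mask
#'
#' Both outputs are produced by the same backward displacement field; the
#' image is interpolated trilinearly and the mask by nearest neighbour, so
#' the mask label set never grows.
#'
#' @param img a [ct_volume()].
#' @param mask a [label_mask()] sharing `img`'s geometry.
#' @param field a [warp_field()].
#' @return List with warped `img` and `mask`.
#' @export
divergence_warp <- function(img, mask, field) {
  stop_if_geometry_mismatch(img, mask, "img and mask")
  stopifnot(inherits(field, "warp_field"))
  centers_world <- sweep(field$control_points, 2, img$spacing, `*`)
  centers_world <- sweep(centers_world, 2, img$origin, `+`)
  wi <- divergence_warp_cpp(img$data * 1.0, img$spacing, img$origin,
                            centers_world, field$magnitudes, field$radii, FALSE)
  wm <- divergence_warp_cpp(mask$data * 1.0, mask$spacing, mask$origin,
                            centers_world, field$magnitudes, field$radii, TRUE)
  list(img = ct_volume(wi, img$spacing, img$origin),
       mask = label_mask(wm, mask$spacing, mask$origin))
}

draw_warp_field <- function(mask, n_points = 3, magnitude_mm = 5, sigma_mm = 15) {
  # control points sampled inside the (dilated) aorta so the deformation
  # targets the structure of interest
  fg <- which(mask$data > 0L)
  if (!length(fg)) fg <- seq_along(mask$data)
  pick <- sample(fg, n_points, replace = length(fg) < n_points)
  d <- dim(mask$data)
  idx <- cbind((pick - 1) %% d[1],
               ((pick - 1) %/% d[1]) %% d[2],
               (pick - 1) %/% (d[1] * d[2]))
  jitter_mm <- matrix(stats::runif(3 * n_points, -5, 5), ncol = 3)
  idx <- idx + sweep(jitter_mm, 2, mask$spacing, `/`)
  warp_field(idx,
             magnitudes = stats::runif(n_points, -magnitude_mm, magnitude_mm),
             radii = rep(sigma_mm, n_points))
}

#' Offline 10:1 divergence-transform augmentation of a cohort
#'
#' Each case is expanded into `ratio` warped copies plus the retained
#' original, so `n` cases become `n * (ratio + 1)` image/mask sets (75 cases
#' at the default ratio give 825 sets). Every augmented copy records the
#' seed and warp parameters that produced it.
#'
#' @param cases list of cases; each must have elements `img` ([ct_volume()])
#'   and `mask` ([label_mask()]). [generate_phantom()] cases are accepted and
#'   use the contrast volume and multi-class mask.
#' @param ratio augmented copies per case (>= 0).
#' @param seed integer seed.
#' @param n_points,magnitude_mm,sigma_mm warp-field sampling parameters.
#' @return List of length `length(cases) * (ratio + 1)`; each element has
#'   `img`, `mask`, `case_id`, `augmented` and (for copies) `warp` + `seed`.
#' @export
offline_augment <- function(cases, ratio = 10, seed = 1L,
                            n_points = 3, magnitude_mm = 5, sigma_mm = 15) {
  if (!is.numeric(ratio) || ratio < 0)
    stop("offline_augment: ratio must be >= 0", call. = FALSE)
  ratio <- as.integer(ratio)
  norm_case <- function(cs, id) {
    if (inherits(cs, "phantom_case"))
      list(img = cs$contrast, mask = cs$truth$label_mask, case_id = id,
           augmented = FALSE)
    else
      list(img = cs$img, mask = cs$mask, case_id = id, augmented = FALSE)
  }
  out <- vector("list", length(cases) * (ratio + 1L))
  j <- 0L
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  for (i in seq_along(cases)) {
    base <- norm_case(cases[[i]], i)
    j <- j + 1L
    out[[j]] <- base
    for (k in seq_len(ratio)) {
      sub_seed <- sample.int(.Machine$integer.max, 1)
      set.seed(sub_seed)
      fld <- draw_warp_field(base$mask, n_points, magnitude_mm, sigma_mm)
      w <- divergence_warp(base$img, base$mask, fld)
      j <- j + 1L
      out[[j]] <- list(img = w$img, mask = w$mask, case_id = i,
                       augmented = TRUE, seed = sub_seed, warp = fld)
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  out
}

#' Draw the parameters of a random 3D affine augmentation
#'
#' Rotation angle uniform on \[0, 15\] degrees about a uniformly random axis,
#' isotropic scale uniform on \[0.7, 1.3\], translation uniform within
#' +/- 10 % of the field of view per axis.
#'
#' @param extent_mm world extent of the volume, mm (length 3).
#' @return List with `angle_deg`, `axis`, `scale`, `translation_mm`.
#' @export
draw_affine_params <- function(extent_mm) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  list(angle_deg = stats::runif(1, 0, 15),
       axis = ax,
       scale = stats::runif(1, 0.7, 1.3),
       translation_mm = stats::runif(3, -0.1, 0.1) * extent_mm)
}

rotation_matrix <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Random 3D affine augmentation of an image/mask pair
#'
#' Applies the same rotation/scale/translation (about the volume centre) to
#' the image (trilinear) and the mask (nearest neighbour); reproducible from
#' `seed`. With `params` forced to the identity the inputs are returned
#' unchanged up to interpolation.
#'
#' @param img a [ct_volume()].
#' @param mask a [label_mask()] sharing `img`'s geometry.
#' @param seed integer seed used when `params` is `NULL`.
#' @param params optional parameter list as from [draw_affine_params()].
#' @return List with warped `img`, `mask` and the `params` used.
#' @export
random_affine_3d <- function(img, mask, seed = NULL, params = NULL) {
  stop_if_geometry_mismatch(img, mask, "img and mask")
  if (is.null(params)) {
    if (!is.null(seed)) set.seed(seed)
    params <- draw_affine_params(volume_extent(img))
  }
  ctr <- img$origin + (dim(img$data) - 1) * img$spacing / 2
  R <- rotation_matrix(params$axis, params$angle_deg * pi / 180)
  # forward: p' = ctr + s R (p - ctr) + t  =>  backward map
  M <- t(R) / params$scale
  off <- as.numeric(ctr - M %*% (ctr + params$translation_mm))
  wi <- affine_warp_cpp(img$data * 1.0, img$spacing, img$origin, M, off, FALSE)
  wm <- affine_warp_cpp(mask$data * 1.0, mask$spacing, mask$origin, M, off, TRUE)
  list(img = ct_volume(wi, img$spacing, img$origin),
       mask = label_mask(wm, mask$spacing, mask$origin),
       params = params)
}
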