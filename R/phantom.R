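#' Specification of a synthetic aneurysmal-aorta phantom
#'
#' Defines the geometry and intensity model of a paired contrast /
#' non-contrast CT phantom: a tube of varying radius swept along a smooth
#' centerline curve, surrounded by a thin wall, with an optional aneurysmal
#' bulge carrying a crescentic intraluminal thrombus. The defaults emulate
#' routine aortic CT: a 512 x 512 axial matrix, 1.25 mm slices for the
#' contrast-enhanced volume and 2.5 mm slices for the non-contrast rendition,
#' a bright lumen on contrast, and a lumen nearly iso-intense with
#' surrounding tissue on non-contrast.
#'
#' @param grid_shape integer length-3 voxel grid of the contrast volume.
#' @param spacing voxel spacing in mm (x, y, z) of the contrast volume.
#' @param centerline_control_points m x 3 matrix of world-mm control points
#'   of the vessel centerline, interpolated by a cubic spline. `NULL` gives a
#'   gently curved craniocaudal course through the grid centre.
#' @param lumen_radius_profile two-column matrix `(arc_fraction, radius_mm)`;
#'   lumen radius as a piecewise-linear function of fractional arc length.
#'   The default is a 9 mm tube dilating to a 22 mm-radius abdominal bulge.
#' @param wall_thickness wall thickness in mm (> 0).
#' @param thrombus_fraction angular fraction in \[0, 1\] of the wall annulus
#'   occupied by the thrombus crescent in the bulge (0 = none, 1 = full ring).
#' @param thrombus_angle centre angle (radians) of the crescent in the plane
#'   orthogonal to the centerline; 0 points along +x, `pi/2` along +y (anterior).
#' @param thrombus_depth_frac fraction of the local bulge excess radius
#'   `r(s) - min(r)` that the crescent thickens inward at its centre.
#' @param intensity_model named list of mean HU-like values:
#'   `lumen_contrast`, `lumen_noncontrast`, `wall`, `thrombus`, `background`.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param noncontrast_slice_mm slice thickness of the non-contrast rendition.
#' @param seed integer seed controlling the noise draws (labels are a
#'   deterministic function of the geometry alone).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(512, 512, 160),
                         spacing = c(0.78, 0.78, 1.25),
                         centerline_control_points = NULL,
                         lumen_radius_profile = cbind(
                           arc_fraction = c(0, 0.35, 0.55, 0.75, 1),
                           radius_mm = c(9, 9, 22, 9, 9)),
                         wall_thickness = 2,
                         thrombus_fraction = 0.5,
                         thrombus_angle = pi / 2,
                         thrombus_depth_frac = 0.7,
                         intensity_model = list(lumen_contrast = 300,
                                                lumen_noncontrast = 45,
                                                wall = 60, thrombus = 40,
                                                background = 30),
                         noise_sd = 15,
                         noncontrast_slice_mm = 2.5,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  prof <- as.matrix(lumen_radius_profile)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("phantom_spec: grid_shape must be 3 integers >= 4", call. = FALSE)
  if (any(spacing <= 0)) stop("phantom_spec: spacing must be > 0", call. = FALSE)
  if (ncol(prof) != 2L || any(prof[, 2] <= 0) ||
      any(prof[, 1] < 0) || any(prof[, 1] > 1) || is.unsorted(prof[, 1]))
    stop("phantom_spec: lumen_radius_profile must be (arc_fraction, radius_mm)",
         " with fractions increasing in [0,1] and radii > 0", call. = FALSE)
  if (wall_thickness <= 0)
    stop("phantom_spec: wall_thickness must be > 0", call. = FALSE)
  if (thrombus_fraction < 0 || thrombus_fraction > 1)
    stop("phantom_spec: thrombus_fraction must be in [0,1]", call. = FALSE)
  if (is.null(centerline_control_points)) {
    ext <- grid_shape * spacing
    z <- seq(0, ext[3], length.out = 5)
    centerline_control_points <- cbind(
      ext[1] / 2 + 5 * sin(seq(0, pi, length.out = 5)),
      ext[2] / 2, z)
  }
  cp <- as.matrix(centerline_control_points)
  if (ncol(cp) != 3L || nrow(cp) < 2L)
    stop("phantom_spec: centerline_control_points must be an m x 3 matrix",
         call. = FALSE)
  need <- c("lumen_contrast", "lumen_noncontrast", "wall", "thrombus", "background")
  if (!all(need %in% names(intensity_model)))
    stop("phantom_spec: intensity_model must name ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 centerline_control_points = cp,
                 lumen_radius_profile = prof,
                 wall_thickness = wall_thickness,
                 thrombus_fraction = thrombus_fraction,
                 thrombus_angle = thrombus_angle,
                 thrombus_depth_frac = thrombus_depth_frac,
                 intensity_model = intensity_model,
                 noise_sd = noise_sd,
                 noncontrast_slice_mm = noncontrast_slice_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> grid %s, spacing %s mm\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  cat(sprintf("  lumen radius %.1f-%.1f mm, wall %.1f mm, thrombus fraction %.2f\n",
              min(x$lumen_radius_profile[, 2]), max(x$lumen_radius_profile[, 2]),
              x$wall_thickness, x$thrombus_fraction))
  invisible(x)
}

# Interpolating cubic spline through the control points; arc length by dense
# polyline summation (0.1 mm tolerance), resampled at uniform arc steps.
build_curve <- function(spec, step = NULL) {
  cp <- spec$centerline_control_points
  chord <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  t <- chord / max(chord)
  fx <- stats::splinefun(t, cp[, 1], method = "natural")
  fy <- stats::splinefun(t, cp[, 2], method = "natural")
  fz <- stats::splinefun(t, cp[, 3], method = "natural")
  nd <- max(1000L, ceiling(max(chord) / 0.1))
  td <- seq(0, 1, length.out = nd)
  Pd <- cbind(fx(td), fy(td), fz(td))
  arc_d <- c(0, cumsum(sqrt(rowSums(diff(Pd)^2))))
  L <- max(arc_d)
  if (is.null(step)) step <- 0.5 * min(spec$spacing)
  s <- seq(0, L, by = step)
  if (max(s) < L) s <- c(s, L)
  tt <- stats::approx(arc_d, td, xout = s, rule = 2)$y
  P <- cbind(fx(tt), fy(tt), fz(tt))
  Tn <- cbind(fx(tt, deriv = 1), fy(tt, deriv = 1), fz(tt, deriv = 1))
  Tn <- Tn / sqrt(rowSums(Tn^2))
  list(points = P, tangents = Tn, arc = s, length = L)
}

curve_radii <- function(spec, curve) {
  prof <- spec$lumen_radius_profile
  stats::approx(prof[, 1] * curve$length, prof[, 2], xout = curve$arc,
                rule = 2)$y
}

crescent_geometry <- function(spec, radii) {
  halfang <- pi * spec$thrombus_fraction
  depth <- if (halfang > 0)
    spec$thrombus_depth_frac * pmax(0, radii - min(spec$lumen_radius_profile[, 2]))
  else rep(0, length(radii))
  depth <- pmin(depth, 0.9 * radii)  # keep the lumen channel open
  list(theta0 = spec$thrombus_angle, halfang = halfang, depth = depth,
       ref = c(1, 0, 0))
}

check_geometry_fits <- function(spec, curve, radii) {
  ext <- spec$grid_shape * spec$spacing
  rr <- radii + spec$wall_thickness
  bad <- curve$points[, 1] - rr < 0 | curve$points[, 1] + rr > ext[1] |
         curve$points[, 2] - rr < 0 | curve$points[, 2] + rr > ext[2] |
         curve$points[, 3] < 0 | curve$points[, 3] > ext[3]
  if (any(bad))
    stop("generate_phantom: grid too small to contain the curve plus the ",
         "maximum outer radius", call. = FALSE)
  invisible(TRUE)
}

rasterize_labels <- function(spec, curve, radii, cres, dims, spacing, subdiv = 1L) {
  rasterize_phantom_cpp(as.integer(dims), as.numeric(spacing), c(0, 0, 0),
                        curve$points, curve$tangents, radii,
                        spec$wall_thickness, cres$theta0, cres$halfang,
                        cres$depth, cres$ref, as.integer(subdiv))
}

# high-accuracy quadrature of the cross-section areas along arc length
analytic_volumes <- function(spec, curve, radii, cres) {
  w <- spec$wall_thickness
  total_area <- pi * (radii + w)^2
  lumen_area <- pi * radii^2
  if (cres$halfang > 0 && any(cres$depth > 0)) {
    th <- seq(-cres$halfang, cres$halfang, length.out = 201L)
    taper <- cos(pi / 2 * th / cres$halfang)
    dth <- th[2] - th[1]
    for (i in which(cres$depth > 0)) {
      rin <- pmax(0, radii[i] - cres$depth[i] * taper)
      lumen_area[i] <- lumen_area[i] -
        sum(0.5 * (radii[i]^2 - rin^2)) * dth +
        0.25 * (radii[i]^2 - rin[1]^2 + radii[i]^2 - rin[length(rin)]^2) * dth
    }
  }
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(curve$arc))
  lumen <- trap(lumen_area)
  total <- trap(total_area)
  list(lumen_mm3 = lumen, ws_ilt_mm3 = total - lumen, total_mm3 = total)
}

#' Generate a paired contrast / non-contrast phantom with ground truth
#'
#' Rasterizes the phantom geometry onto the voxel grid (each voxel is
#' classified by its centre point; no anti-aliasing), assigns mean
#' intensities per tissue and adds Gaussian noise. The non-contrast
#' rendition is rasterized independently on its thicker-slice grid and its
#' lumen is nearly iso-intense with background. Identical spec and seed give
#' bit-identical output; the label masks are a deterministic function of the
#' geometry alone.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_case`: a list with elements
#'   `contrast` ([ct_volume()]), `noncontrast` ([ct_volume()]) and `truth`,
#'   where `truth` holds the multi-class [label_mask()] (contrast geometry),
#'   the binary non-contrast mask, the ground-truth centerline samples, the
#'   lumen/outer diameter oracle and analytic volumes.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  curve <- build_curve(spec)
  radii <- curve_radii(spec, curve)
  cres <- crescent_geometry(spec, radii)
  check_geometry_fits(spec, curve, radii)
  ints <- spec$intensity_model

  ras <- rasterize_labels(spec, curve, radii, cres,
                          spec$grid_shape, spec$spacing)
  lab4 <- ras$labels
  lab3 <- lab4
  lab3[lab3 == 3L] <- 2L
  mask <- label_mask(lab3, spec$spacing, c(0, 0, 0))
  lut_c <- c(ints$background, ints$lumen_contrast, ints$wall, ints$thrombus)

  nz_nc <- max(1L, round_half_up(spec$grid_shape[3] * spec$spacing[3] /
                                   spec$noncontrast_slice_mm))
  dims_nc <- c(spec$grid_shape[1:2], nz_nc)
  spacing_nc <- c(spec$spacing[1:2], spec$noncontrast_slice_mm)
  ras_nc <- rasterize_labels(spec, curve, radii, cres, dims_nc, spacing_nc)
  lab4_nc <- ras_nc$labels
  lut_n <- c(ints$background, ints$lumen_noncontrast, ints$wall, ints$thrombus)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  img_c <- array(lut_c[lab4 + 1L] + stats::rnorm(length(lab4), sd = spec$noise_sd),
                 dim = spec$grid_shape)
  img_n <- array(lut_n[lab4_nc + 1L] + stats::rnorm(length(lab4_nc), sd = spec$noise_sd),
                 dim = dims_nc)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  L <- curve$length
  rfun <- stats::approxfun(curve$arc, radii, rule = 2)
  truth <- list(
    label_mask = mask,
    nc_mask = label_mask(array(as.integer(lab4_nc > 0L), dims_nc),
                         spacing_nc, c(0, 0, 0)),
    centerline = list(points = curve$points, tangents = curve$tangents,
                      arc = curve$arc),
    length_mm = L,
    radius = rfun,
    wall_thickness = spec$wall_thickness,
    crescent = cres,
    volumes = analytic_volumes(spec, curve, radii, cres),
    spec = spec)
  structure(list(contrast = ct_volume(img_c, spec$spacing, c(0, 0, 0)),
                 noncontrast = ct_volume(img_n, spacing_nc, c(0, 0, 0)),
                 truth = truth),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case>\n  contrast: ")
  print(x$contrast)
  cat("  noncontrast: ")
  print(x$noncontrast)
  v <- x$truth$volumes
  cat(sprintf("  truth: lumen %.0f mm3, WS/ILT %.0f mm3, centerline %.0f mm\n",
              v$lumen_mm3, v$ws_ilt_mm3, x$truth$length_mm))
  invisible(x)
}

#' Sub-voxel volume oracle for a phantom
#'
#' Re-rasterizes the phantom with each voxel subdivided `subdiv^3` times and
#' counts sub-centres per class, quantifying the discretization error of the
#' voxel-centre label mask.
#'
#' @param spec a [phantom_spec()].
#' @param subdiv subdivision factor per axis (default 5).
#' @return List with `lumen_mm3`, `ws_ilt_mm3`, `total_mm3`.
#' @export
oracle_volumes <- function(spec, subdiv = 5L) {
  stopifnot(inherits(spec, "phantom_spec"))
  curve <- build_curve(spec)
  radii <- curve_radii(spec, curve)
  cres <- crescent_geometry(spec, radii)
  ras <- rasterize_labels(spec, curve, radii, cres, spec$grid_shape,
                          spec$spacing, subdiv = subdiv)
  vv <- prod(spec$spacing)
  lum <- ras$counts[2] * vv
  ws <- (ras$counts[3] + ras$counts[4]) * vv
  list(lumen_mm3 = lum, ws_ilt_mm3 = ws, total_mm3 = lum + ws)
}

#' True outer/lumen diameter profile of a phantom
#'
#' Samples the analytic diameter oracle along arc length: the lumen diameter
#' is `2 r(s)` and the outer diameter `2 (r(s) + wall)`; the thrombus
#' crescent thickens the wall inward, so the outer surface is unchanged.
#'
#' @param truth the `truth` element of a [generate_phantom()] case.
#' @param step arc-length sampling step in mm.
#' @return A data frame with columns `arc_length_mm`, `lumen_diameter_mm`,
#'   `outer_diameter_mm` and `diameter_mm` (alias of the outer diameter).
#' @export
analytic_profile <- function(truth, step = 1) {
  if (step <= 0) stop("analytic_profile: step must be > 0", call. = FALSE)
  if (step > truth$length_mm)
    stop("analytic_profile: step exceeds the curve length", call. = FALSE)
  s <- seq(0, truth$length_mm, by = step)
  r <- truth$radius(s)
  data.frame(arc_length_mm = s,
             lumen_diameter_mm = 2 * r,
             outer_diameter_mm = 2 * (r + truth$wall_thickness),
             diameter_mm = 2 * (r + truth$wall_thickness))
}

#' Centerline control points for a phantom, with optional aortic arch
#'
#' Builds control points for either a gently wavy craniocaudal (abdominal)
#' course or a candy-cane course with an arch: ascending limb, a 180-degree
#' turn at the top, and a descending limb.
#'
#' @param extent world extent of the grid in mm (length 3).
#' @param arch logical; include an aortic arch.
#' @param wiggle_amp lateral wiggle amplitude in mm.
#' @param wiggle_phase phase of the wiggle (radians).
#' @param margin_mm clearance kept from the lateral grid faces.
#' @return An m x 3 matrix of control points.
#' @export
make_centerline <- function(extent, arch = FALSE, wiggle_amp = 5,
                            wiggle_phase = 0, margin_mm = 30) {
  cx <- extent[1] / 2
  cy <- extent[2] / 2
  if (!arch) {
    z <- seq(0, extent[3], length.out = 7)
    cbind(cx + wiggle_amp * sin(wiggle_phase + seq(0, 1.5 * pi, length.out = 7)),
          cy + 0.5 * wiggle_amp * sin(wiggle_phase / 2 + seq(0, pi, length.out = 7)),
          z)
  } else {
    sep <- min(25, (extent[1] - 2 * margin_mm) / 4)  # half-distance of limbs
    ztop <- extent[3] - margin_mm
    zarc <- ztop - sep
    asc <- cbind(cx - sep, cy, c(0.45 * extent[3], zarc))
    th <- seq(pi, 0, length.out = 5)[2:4]
    top <- cbind(cx + sep * cos(th), cy, zarc + sep * sin(th))
    desc <- cbind(cx + sep + wiggle_amp * sin(wiggle_phase + seq(0, pi, length.out = 5)) * 0.3,
                  cy, seq(zarc, 0, length.out = 5))
    rbind(asc, top, desc[-1, ])
  }
}

#' Generate a randomized phantom cohort
#'
#' Draws per-case anatomy from documented ranges around `base_spec` and
#' generates each phantom. Ranges (uniform unless noted): baseline lumen
#' radius 8-12 mm, bulge peak radius 15-27 mm (clipped so the geometry fits
#' the grid), bulge centre at 45-65 % of arc length, bulge half-width
#' 12-25 % of arc length, wall thickness 1.5-3 mm, thrombus angular fraction
#' 0.2-0.8, crescent angle 0-2pi, lateral wiggle 0-6 mm. Reproducible from
#' `seed`.
#'
#' @param n number of cases (>= 1).
#' @param base_spec template [phantom_spec()]; grid, spacing, intensities and
#'   noise are taken from it.
#' @param seed integer seed for the cohort draws.
#' @param arch logical; give the cases an aortic arch.
#' @return A list of `n` [generate_phantom()] cases.
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(), seed = 1L,
                            arch = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("generate_cohort: n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  ext <- base_spec$grid_shape * base_spec$spacing
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    wall <- stats::runif(1, 1.5, 3)
    wig <- stats::runif(1, 0, 6)
    r_allow <- min(ext[1:2]) / 2 - wall - wig - 4
    r0 <- stats::runif(1, min(8, 0.6 * r_allow), min(12, 0.8 * r_allow))
    rb <- stats::runif(1, min(15, r_allow), min(27, r_allow))
    rb <- max(rb, 1.2 * r0)  # aneurysm is a dilatation
    c0 <- stats::runif(1, 0.45, 0.65)
    hw <- stats::runif(1, 0.12, 0.25)
    prof <- cbind(arc_fraction = c(0, max(0, c0 - hw), c0, min(1, c0 + hw), 1),
                  radius_mm = c(r0, r0, rb, r0, r0))
    spec <- phantom_spec(
      grid_shape = base_spec$grid_shape,
      spacing = base_spec$spacing,
      centerline_control_points = make_centerline(
        ext, arch = arch, wiggle_amp = wig,
        wiggle_phase = stats::runif(1, 0, 2 * pi)),
      lumen_radius_profile = prof,
      wall_thickness = wall,
      thrombus_fraction = stats::runif(1, 0.2, 0.8),
      thrombus_angle = stats::runif(1, 0, 2 * pi),
      thrombus_depth_frac = base_spec$thrombus_depth_frac,
      intensity_model = base_spec$intensity_model,
      noise_sd = base_spec$noise_sd,
      noncontrast_slice_mm = base_spec$noncontrast_slice_mm,
      seed = sample.int(.Machine$integer.max, 1))
    out[[i]] <- generate_phantom(spec)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  out
}

#' Write a phantom case to disk
#'
#' Writes the paired volumes and label masks as NIfTI, the spec as JSON and
#' the diameter oracle as CSV (`arc_length_mm, lumen_diameter_mm,
#' outer_diameter_mm`).
#'
#' @param case a [generate_phantom()] case.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param profile_step arc step of the oracle CSV, mm.
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir, prefix = "phantom", profile_step = 1) {
  stopifnot(inherits(case, "phantom_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(s) file.path(dir, paste0(prefix, "_", s))
  write_volume(case$contrast, p("contrast.nii.gz"))
  write_volume(case$noncontrast, p("noncontrast.nii.gz"))
  write_volume(case$truth$label_mask, p("labels.nii.gz"))
  write_volume(case$truth$nc_mask, p("nc_labels.nii.gz"))
  prof <- analytic_profile(case$truth, step = profile_step)
  utils::write.csv(prof[, c("arc_length_mm", "lumen_diameter_mm",
                            "outer_diameter_mm")],
                   p("truth_profile.csv"), row.names = FALSE)
  spec <- case$truth$spec
  spec_json <- spec
  spec_json$centerline_control_points <-
    apply(spec$centerline_control_points, 1, as.numeric, simplify = FALSE)
  spec_json$lumen_radius_profile <-
    apply(spec$lumen_radius_profile, 1, as.numeric, simplify = FALSE)
  class(spec_json) <- NULL
  jsonlite::write_json(spec_json, p("spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
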