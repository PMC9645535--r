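#' Dice overlap between two masks for one class
#'
#' `2|A n B| / (|A| + |B|)` on the binary sets of voxels equal to `cls`;
#' if both sets are empty the score is 1 by convention.
#'
#' @param a,b [label_mask()]s sharing geometry.
#' @param cls class label (default 1). Use `cls = "foreground"` for the
#'   combined aorta (any non-zero label).
#' @return Scalar in \[0, 1\].
#' @export
dice_score <- function(a, b, cls = 1L) {
  stop_if_geometry_mismatch(a, b, "masks")
  if (identical(cls, "foreground")) {
    av <- a$data > 0L; bv <- b$data > 0L
  } else {
    av <- a$data == cls; bv <- b$data == cls
  }
  sa <- sum(av); sb <- sum(bv)
  if (sa + sb == 0) return(1)
  2 * sum(av & bv) / (sa + sb)
}

#' Per-class volumes of a mask (mm^3)
#'
#' @param m a [label_mask()].
#' @return Named list `lumen_mm3`, `ws_ilt_mm3`, `total_mm3` (voxel count
#'   times voxel volume).
#' @export
class_volumes <- function(m) {
  vv <- prod(m$spacing)
  lum <- sum(m$data == 1L) * vv
  ws <- sum(m$data == 2L) * vv
  list(lumen_mm3 = lum, ws_ilt_mm3 = ws, total_mm3 = lum + ws)
}

slice_component <- function(sl, cls) {
  # largest in-plane 4-connected component of `cls`; NULL if absent
  sel <- if (identical(cls, "foreground")) sl > 0L else sl == cls
  if (!any(sel)) return(NULL)
  d <- dim(sl)
  lab <- cc_label_cpp(array(as.integer(sel), c(d, 1L)), 6L)
  tab <- tabulate(lab[lab > 0])
  which(array(lab, d) == which.max(tab), arr.ind = TRUE)
}

#' Per-slice anteroposterior and transverse caliper diameters
#'
#' For every axial slice containing the class, the extent of its largest
#' in-plane connected component along the fixed anatomical axes: AP along y,
#' transverse along x, in mm. This is the axial caliper used clinically;
#' diameters in oblique planes use the maximum Feret diameter instead
#' (see [orthogonal_diameter_profile()]).
#'
#' @param m a [label_mask()].
#' @param cls class label, or `"foreground"` for the combined aorta.
#' @return Data frame with `slice` (1-based z index), `ap_mm`, `transverse_mm`.
#' @export
axial_diameters <- function(m, cls = "foreground") {
  d <- dim(m$data)
  out <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    px <- slice_component(m$data[, , k], cls)
    if (is.null(px)) next
    out[[k]] <- data.frame(
      slice = k,
      ap_mm = (max(px[, 2]) - min(px[, 2]) + 1) * m$spacing[2],
      transverse_mm = (max(px[, 1]) - min(px[, 1]) + 1) * m$spacing[1])
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Maximum cross-sectional area over axial slices (mm^2)
#'
#' @inheritParams axial_diameters
#' @return Scalar mm^2 (0 for an empty mask).
#' @export
max_axial_area <- function(m, cls = "foreground") {
  sel <- if (identical(cls, "foreground")) m$data > 0L else m$data == cls
  if (!any(sel)) return(0)
  counts <- apply(sel, 3, sum)
  max(counts) * m$spacing[1] * m$spacing[2]
}

#' Six diameters from the three-slice protocol
#'
#' AP and transverse diameters at the slice with the maximum AP diameter and
#' at the slices 1 cm above and below it (nearest slice by spacing). If the
#' mask does not span the 1 cm offset the protocol is truncated and flagged.
#'
#' @inheritParams axial_diameters
#' @param offset_mm craniocaudal offset of the flanking slices (default 10).
#' @return List with `measurements` (data frame: `slice`, `role`, `ap_mm`,
#'   `transverse_mm`), `max_ap_slice` and `complete` (logical flag).
#' @export
three_slice_protocol <- function(m, cls = "foreground", offset_mm = 10) {
  di <- axial_diameters(m, cls)
  if (is.null(di) || !nrow(di))
    stop("three_slice_protocol: class absent from mask", call. = FALSE)
  # middle slice among (near-)tied maxima, so a uniform tube centres the span
  ties <- di$slice[di$ap_mm >= max(di$ap_mm) - 1e-9]
  kmax <- ties[ceiling(length(ties) / 2)]
  dk <- max(1L, round(offset_mm / m$spacing[3]))
  want <- data.frame(slice = c(kmax, kmax + dk, kmax - dk),
                     role = c("max_ap", "above", "below"))
  res <- merge(want, di, by = "slice", all.x = TRUE, sort = FALSE)
  complete <- !any(is.na(res$ap_mm))
  list(measurements = res[!is.na(res$ap_mm), ],
       max_ap_slice = kmax, complete = complete)
}

largest_component <- function(m, cls) {
  sel <- if (identical(cls, "foreground")) m$data > 0L else m$data == cls
  if (!any(sel)) stop("largest_component: class absent from mask", call. = FALSE)
  lab <- cc_label_cpp(array(as.integer(sel), dim(m$data)), 26L)
  tab <- tabulate(lab[lab > 0])
  if (length(tab) > 1L)
    message("largest_component: ", length(tab),
            " components; keeping the largest")
  array(as.integer(lab == which.max(tab)), dim(m$data))
}

#' Extract a centerline by homotopic thinning
#'
#' Topology-preserving (homotopic) thinning of the class region, ordered by
#' the Euclidean distance transform so the surviving voxels stay medial,
#' followed by pruning to the longest geodesic path through the skeleton
#' (ties broken by lexicographic endpoint order). The path is ordered
#' superior to inferior and converted to world mm with cumulative arc
#' length. If the class region has several components the largest is used
#' (with a message).
#'
#' @param m a [label_mask()].
#' @param cls class label or `"foreground"`.
#' @return An object of class `centerline`: list with `points` (n x 3 world
#'   mm), `arc` (cumulative mm from 0).
#' @export
extract_centerline <- function(m, cls = "foreground") {
  comp <- largest_component(m, cls)
  dist <- edt_cpp(comp, m$spacing)
  sk <- skeletonize_cpp(comp, dist)
  idx <- which(sk > 0L)
  d <- dim(sk)
  vox <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  if (nrow(vox) == 1L) {
    pts <- sweep(vox * rep(m$spacing, each = 1), 2, m$origin, `+`)
    return(structure(list(points = pts, arc = 0), class = "centerline"))
  }
  # longest geodesic path on the 26-neighbour graph with mm edge weights
  key <- idx
  pos <- match(key, key)
  edges <- NULL
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  lut <- new.env(hash = TRUE)
  for (r in seq_along(idx)) assign(as.character(idx[r]), r, envir = lut)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(off))) {
    nb <- vox + matrix(off[r, ], nrow(vox), 3, byrow = TRUE)
    ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
      nb[, 1] < d[1] & nb[, 2] < d[2] & nb[, 3] < d[3]
    nidx <- nb[, 1] + d[1] * (nb[, 2] + d[2] * nb[, 3]) + 1
    tgt <- match(nidx, key)
    ok <- ok & !is.na(tgt)
    if (!any(ok)) next
    from <- c(from, which(ok))
    to <- c(to, tgt[ok])
    w <- c(w, rep(sqrt(sum((off[r, ] * m$spacing)^2)), sum(ok)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE, vertices = data.frame(name = seq_along(idx)))
  comp_mem <- igraph::components(g)$membership
  main <- which(comp_mem == which.max(tabulate(comp_mem)))
  sub <- igraph::induced_subgraph(g, main)
  # tree-diameter heuristic: farthest vertex from an arbitrary start, then
  # farthest from that; lexicographic tie-break on endpoint voxel index
  dd <- igraph::distances(sub, v = 1)
  cand <- which(dd == max(dd[is.finite(dd)]))
  v1 <- cand[order(as.integer(igraph::V(sub)$name[cand]))][1]
  dd2 <- igraph::distances(sub, v = v1)
  cand2 <- which(dd2 == max(dd2[is.finite(dd2)]))
  v2 <- cand2[order(as.integer(igraph::V(sub)$name[cand2]))][1]
  sp <- igraph::shortest_paths(sub, from = v1, to = v2, output = "vpath")
  path <- as.integer(igraph::V(sub)$name[as.integer(sp$vpath[[1]])])
  pts <- sweep(vox[path, , drop = FALSE] %*% diag(m$spacing), 2, m$origin, `+`)
  if (pts[1, 3] < pts[nrow(pts), 3]) pts <- pts[rev(seq_len(nrow(pts))), ]
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  structure(list(points = pts, arc = arc), class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, %.1f mm\n", nrow(x$points),
              max(x$arc)))
  invisible(x)
}

as_points <- function(c1) {
  if (inherits(c1, "centerline")) c1$points else as.matrix(c1)
}

cross_dist <- function(A, B) {
  # pairwise Euclidean distances, n x m
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Mean closest-point deviation between two centerlines (mm)
#'
#' The mean over the points of one line of the distance to the closest point
#' of the other; symmetrized by averaging the two directions (both directed
#' values are returned as attributes).
#'
#' @param c1,c2 `centerline`s or n x 3 point matrices.
#' @return Scalar mm, with attributes `directed_12` and `directed_21`.
#' @export
centerline_deviation <- function(c1, c2) {
  A <- as_points(c1); B <- as_points(c2)
  if (!nrow(A) || !nrow(B))
    stop("centerline_deviation: empty centerline", call. = FALSE)
  D <- cross_dist(A, B)
  d12 <- mean(apply(D, 1, min))
  d21 <- mean(apply(D, 2, min))
  structure((d12 + d21) / 2, directed_12 = d12, directed_21 = d21)
}

#' Hausdorff distance between two centerlines (mm)
#'
#' The greatest distance from a point of one line to the closest point of
#' the other, symmetrized as the maximum of the two directed distances; it
#' upper-bounds the mean closest-point deviation.
#'
#' @param c1,c2 `centerline`s or n x 3 point matrices.
#' @return Scalar mm.
#' @export
hausdorff_distance <- function(c1, c2) {
  A <- as_points(c1); B <- as_points(c2)
  if (!nrow(A) || !nrow(B))
    stop("hausdorff_distance: empty centerline", call. = FALSE)
  D <- cross_dist(A, B)
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

smooth_moving_average <- function(x, k = 5L) {
  n <- nrow(x)
  if (n <= k) return(x)
  out <- x
  h <- k %/% 2L
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i, ] <- colMeans(x[lo:hi, , drop = FALSE])
  }
  out
}

centerline_frames <- function(cl, step_mm) {
  # resample at uniform arc steps; tangents from smoothed finite differences,
  # in-plane frame propagated for continuity
  pts <- smooth_moving_average(as_points(cl), 5L)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  L <- max(arc)
  s <- seq(0, L, by = step_mm)
  P <- cbind(stats::approx(arc, pts[, 1], xout = s, rule = 2)$y,
             stats::approx(arc, pts[, 2], xout = s, rule = 2)$y,
             stats::approx(arc, pts[, 3], xout = s, rule = 2)$y)
  n <- nrow(P)
  Tn <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
    Tn[i, ] <- P[hi, ] - P[lo, ]
  }
  nr <- sqrt(rowSums(Tn^2))
  nr[nr == 0] <- 1
  Tn <- Tn / nr
  E1 <- matrix(0, n, 3); E2 <- matrix(0, n, 3)
  e1 <- c(1, 0, 0)
  if (abs(sum(e1 * Tn[1, ])) > 0.9) e1 <- c(0, 1, 0)
  for (i in seq_len(n)) {
    e1 <- e1 - sum(e1 * Tn[i, ]) * Tn[i, ]
    if (sqrt(sum(e1^2)) < 1e-6) {
      e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * Tn[i, ]) * Tn[i, ]
      if (sqrt(sum(e1^2)) < 1e-6)
        e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * Tn[i, ]) * Tn[i, ]
    }
    e1 <- e1 / sqrt(sum(e1^2))
    E1[i, ] <- e1
    E2[i, ] <- c(Tn[i, 2] * e1[3] - Tn[i, 3] * e1[2],
                 Tn[i, 3] * e1[1] - Tn[i, 1] * e1[3],
                 Tn[i, 1] * e1[2] - Tn[i, 2] * e1[1])
  }
  list(s = s, P = P, Tn = Tn, E1 = E1, E2 = E2)
}

#' Maximum diameter profile orthogonal to a centerline
#'
#' At each arc-length step the mask is resampled (nearest neighbour) on a 2D
#' plane orthogonal to the local tangent; the diameter is the maximum Feret
#' diameter of the in-plane connected component containing the centerline
#' point, in mm. Samples whose plane exits the grid or misses the component
#' are `NA`.
#'
#' @param m a [label_mask()].
#' @param cl a `centerline`.
#' @param step_mm arc sampling step (default 1).
#' @param cls class or `"foreground"`.
#' @param half_width_mm half-width of the sampling plane; defaults to a
#'   generous bound from the mask extent.
#' @return Data frame of class `diameter_profile` with `arc_length_mm`,
#'   `diameter_mm`.
#' @export
orthogonal_diameter_profile <- function(m, cl, step_mm = 1,
                                        cls = "foreground",
                                        half_width_mm = NULL) {
  sel <- if (identical(cls, "foreground")) m$data > 0L else m$data == cls
  vol <- array(as.numeric(sel), dim(m$data))
  if (is.null(half_width_mm))
    half_width_mm <- 0.35 * max(volume_extent(m))
  fr <- centerline_frames(cl, step_mm)
  px <- min(m$spacing[1:2])
  uu <- seq(-half_width_mm, half_width_mm, by = px)
  grid <- as.matrix(expand.grid(u = uu, v = uu))
  nu <- length(uu)
  ctr_idx <- which.min(abs(uu))  # plane coordinate (0,0)
  diam <- rep(NA_real_, length(fr$s))
  for (i in seq_along(fr$s)) {
    Q <- matrix(fr$P[i, ], nrow(grid), 3, byrow = TRUE) +
      grid[, 1] %o% fr$E1[i, ] + grid[, 2] %o% fr$E2[i, ]
    vals <- sample_points_cpp(vol, m$spacing, m$origin, Q, TRUE)
    plane <- array(as.integer(vals > 0.5), c(nu, nu, 1L))
    if (!any(plane > 0)) next
    lab <- cc_label_cpp(plane, 26L)
    lab <- array(lab, c(nu, nu))
    ctr_lab <- lab[ctr_idx, ctr_idx]
    if (ctr_lab == 0L) {
      # centerline point on a voxel edge: look in a small neighbourhood
      nb <- lab[max(1, ctr_idx - 2):min(nu, ctr_idx + 2),
                max(1, ctr_idx - 2):min(nu, ctr_idx + 2)]
      nz <- nb[nb > 0]
      if (!length(nz)) next
      ctr_lab <- as.integer(names(which.max(table(nz))))
    }
    px_idx <- which(lab == ctr_lab, arr.ind = TRUE)
    hull <- grDevices::chull(px_idx)
    hp <- px_idx[hull, , drop = FALSE] * px
    diam[i] <- max(cross_dist(hp, hp)) + px  # caliper over pixel squares
  }
  structure(data.frame(arc_length_mm = fr$s, diameter_mm = diam),
            class = c("diameter_profile", "data.frame"))
}

#' Compare two diameter profiles
#'
#' Profiles are aligned on their overlapping arc range by linear
#' interpolation; returns the root-mean-square error and the mean percentage
#' difference `mean(|d1 - d2| / mean(d1, d2)) * 100`.
#'
#' @param p1,p2 data frames with `arc_length_mm` and a diameter column.
#' @param column diameter column name (default `diameter_mm`).
#' @return List with `rmse_mm` and `pct_diff`.
#' @export
compare_profiles <- function(p1, p2, column = "diameter_mm") {
  ok1 <- !is.na(p1[[column]]); ok2 <- !is.na(p2[[column]])
  lo <- max(min(p1$arc_length_mm[ok1]), min(p2$arc_length_mm[ok2]))
  hi <- min(max(p1$arc_length_mm[ok1]), max(p2$arc_length_mm[ok2]))
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("compare_profiles: no overlapping arc range", call. = FALSE)
  s <- seq(lo, hi, by = min(diff(p1$arc_length_mm)[1], diff(p2$arc_length_mm)[1]))
  d1 <- stats::approx(p1$arc_length_mm[ok1], p1[[column]][ok1], xout = s)$y
  d2 <- stats::approx(p2$arc_length_mm[ok2], p2[[column]][ok2], xout = s)$y
  keep <- !is.na(d1) & !is.na(d2)
  d1 <- d1[keep]; d2 <- d2[keep]
  list(rmse_mm = sqrt(mean((d1 - d2)^2)),
       pct_diff = mean(abs(d1 - d2) / ((d1 + d2) / 2)) * 100)
}

#' Straightened (curved planar) view along a centerline
#'
#' Resamples the volume on planes orthogonal to the centerline and stacks
#' them along arc length, so the output z axis is arc length and the vessel
#' appears straight.
#'
#' @param v a [ct_volume()].
#' @param cl a `centerline`.
#' @param half_width_mm half-width of each plane, mm.
#' @param step_mm arc step between planes, mm.
#' @return A [ct_volume()] with spacing `(px, px, step_mm)` where `px` is
#'   the input in-plane spacing.
#' @export
straightened_view <- function(v, cl, half_width_mm = 40, step_mm = 1) {
  fr <- centerline_frames(cl, step_mm)
  px <- min(v$spacing[1:2])
  uu <- seq(-half_width_mm, half_width_mm, by = px)
  grid <- as.matrix(expand.grid(u = uu, v = uu))
  nu <- length(uu)
  out <- array(0, c(nu, nu, length(fr$s)))
  for (i in seq_along(fr$s)) {
    Q <- matrix(fr$P[i, ], nrow(grid), 3, byrow = TRUE) +
      grid[, 1] %o% fr$E1[i, ] + grid[, 2] %o% fr$E2[i, ]
    out[, , i] <- sample_points_cpp(v$data * 1.0, v$spacing, v$origin, Q, FALSE)
  }
  ct_volume(out, c(px, px, step_mm), c(-half_width_mm, -half_width_mm, 0))
}

#' Agreement statistics between paired measurements
#'
#' Bland-Altman bias (`measured - reference`) with its 95 % confidence
#' interval and limits of agreement, Spearman rank correlation, the
#' intraclass correlation coefficient (two-way, absolute agreement, single
#' measurement: ICC(A,1)), and the within-pair coefficient of variation
#' (root mean square over pairs of each pair's SD over its mean, as a
#' percentage; zero-mean pairs are excluded with a message).
#'
#' @param measured,reference numeric vectors of paired measurements
#'   (n >= 3).
#' @return List with `n`, `bias`, `bias_ci95` (length 2), `loa` (length-2
#'   limits of agreement), `spearman_r`, `icc`, `icc_variant`, `pct_cv`.
#' @export
agreement_stats <- function(measured, reference) {
  ok <- is.finite(measured) & is.finite(reference)
  x <- measured[ok]; y <- reference[ok]
  n <- length(x)
  if (n < 3) stop("agreement_stats: need at least 3 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  means <- (x + y) / 2
  nz <- means != 0
  if (any(!nz)) message("agreement_stats: excluding ", sum(!nz),
                        " zero-mean pair(s) from %CV")
  cv <- sqrt(mean((apply(cbind(x, y)[nz, , drop = FALSE], 1, stats::sd) /
                     means[nz])^2)) * 100
  # ICC(A,1) from the two-way ANOVA mean squares
  k <- 2
  grand <- mean(c(x, y))
  MSR <- k * sum((means - grand)^2) / (n - 1)
  colm <- c(mean(x), mean(y))
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  SSE <- sum((x - means - colm[1] + grand)^2 + (y - means - colm[2] + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
  list(n = n,
       bias = bias,
       bias_ci95 = bias + c(-1, 1) * 1.96 * sdd / sqrt(n),
       loa = bias + c(-1, 1) * 1.96 * sdd,
       spearman_r = if (stats::sd(x) == 0 && stats::sd(y) == 0) 1
                    else suppressWarnings(stats::cor(x, y, method = "spearman")),
       icc = icc,
       icc_variant = "ICC(A,1) two-way absolute agreement, single rater",
       pct_cv = cv)
}

#' Full morphometry report for one mask
#'
#' Bundles the 1-D/2-D/3-D measurements: maximum axial AP and transverse
#' diameters, the three-slice protocol, maximum axial area, per-class
#' volumes, the centerline and the centerline-orthogonal diameter profile.
#'
#' @param m a [label_mask()].
#' @param cls class used for the outer contour (default `"foreground"`).
#' @param profile_step_mm arc step of the diameter profile.
#' @return An object of class `morphometry_report`.
#' @export
morphometry_report <- function(m, cls = "foreground", profile_step_mm = 1) {
  di <- axial_diameters(m, cls)
  cl <- extract_centerline(m, cls)
  prof <- orthogonal_diameter_profile(m, cl, step_mm = profile_step_mm, cls = cls)
  structure(list(
    max_ap_diameter_mm = max(di$ap_mm),
    max_transverse_diameter_mm = max(di$transverse_mm),
    max_axial_area_mm2 = max_axial_area(m, cls),
    volumes = class_volumes(m),
    three_slice = three_slice_protocol(m, cls),
    centerline = cl,
    diameter_profile = prof,
    max_orthogonal_diameter_mm = suppressWarnings(max(prof$diameter_mm, na.rm = TRUE))),
    class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("<morphometry_report>\n")
  cat(sprintf("  max AP diameter      %8.1f mm (axial)\n", x$max_ap_diameter_mm))
  cat(sprintf("  max transverse diam. %8.1f mm (axial)\n",
              x$max_transverse_diameter_mm))
  cat(sprintf("  max orthogonal diam. %8.1f mm (centerline)\n",
              x$max_orthogonal_diameter_mm))
  cat(sprintf("  max axial area       %8.0f mm2\n", x$max_axial_area_mm2))
  v <- x$volumes
  cat(sprintf("  volumes: lumen %.0f, WS/ILT %.0f, total %.0f mm3\n",
              v$lumen_mm3, v$ws_ilt_mm3, v$total_mm3))
  cat(sprintf("  centerline length    %8.1f mm\n", max(x$centerline$arc)))
  invisible(x)
}

#' Agreement report between a predicted and a reference mask
#'
#' Computes per-class Dice, centerline deviation and Hausdorff distance,
#' and the orthogonal diameter profile RMSE / percentage difference.
#'
#' @param pred,truth [label_mask()]s sharing geometry.
#' @param profile_step_mm arc step of the diameter profiles.
#' @return An object of class `agreement_report`.
#' @export
compare_masks <- function(pred, truth, profile_step_mm = 1) {
  stop_if_geometry_mismatch(pred, truth, "masks")
  classes <- sort(setdiff(unique(c(pred$data, truth$data)), 0L))
  dice <- c(vapply(classes, function(cl) dice_score(pred, truth, cl), numeric(1)),
            foreground = dice_score(pred, truth, "foreground"))
  names(dice)[seq_along(classes)] <- paste0("class", classes)
  cp <- extract_centerline(pred, "foreground")
  ct <- extract_centerline(truth, "foreground")
  pp <- orthogonal_diameter_profile(pred, cp, step_mm = profile_step_mm)
  pt <- orthogonal_diameter_profile(truth, ct, step_mm = profile_step_mm)
  cmp <- compare_profiles(pp, pt)
  structure(list(dice = dice,
                 centerline_mean_euclidean_mm = as.numeric(centerline_deviation(cp, ct)),
                 centerline_hausdorff_mm = hausdorff_distance(cp, ct),
                 profile_rmse_mm = cmp$rmse_mm,
                 profile_pct_diff = cmp$pct_diff),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n  Dice:",
      paste(sprintf("%s %.3f", names(x$dice), x$dice), collapse = ", "), "\n")
  cat(sprintf("  centerline deviation %.2f mm (Hausdorff %.2f mm)\n",
              x$centerline_mean_euclidean_mm, x$centerline_hausdorff_mm))
  cat(sprintf("  diameter profile RMSE %.2f mm (%.1f%% difference)\n",
              x$profile_rmse_mm, x$profile_pct_diff))
  invisible(x)
}

#' Write a morphometry or agreement report as JSON
#'
#' @param report a `morphometry_report` or `agreement_report`.
#' @param path output `.json` path; profiles are written alongside as CSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  if (!is.null(x$centerline)) {
    x$centerline_length_mm <- max(x$centerline$arc)
    x$centerline <- NULL
  }
  if (!is.null(x$diameter_profile)) {
    csv <- sub("\\.json$", "_profile.csv", path)
    utils::write.csv(x$diameter_profile, csv, row.names = FALSE)
    x$diameter_profile <- NULL
  }
  if (!is.null(x$three_slice)) x$three_slice$measurements <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
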