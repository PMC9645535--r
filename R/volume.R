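#' @useDynLib aortaseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' CT-like volume with voxel geometry
#'
#' A `ct_volume` carries a 3D scalar grid together with its voxel spacing
#' (mm per axis) and world origin (mm). The coordinate convention used
#' throughout the package is: 0-based voxel indices, half-open boxes,
#' `world = origin + index * spacing`; axis x is transverse (left-right),
#' axis y is anteroposterior (AP), axis z is craniocaudal with +z superior.
#'
#' @param data numeric 3D array of voxel values.
#' @param spacing numeric length-3, mm per axis; strictly positive.
#' @param origin numeric length-3, world-mm position of voxel (0,0,0).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("ct_volume: `data` must be a 3D array, got ",
         length(dim(data)), " dims", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: spacing must be 3 strictly positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("ct_volume: origin must be 3 finite numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' Multi-class label mask sharing a volume's geometry
#'
#' Voxel values are restricted to `{0 (background), 1 (lumen),
#' 2 (wall structure / intraluminal thrombus)}`.
#'
#' @param data integer 3D array with values in `{0, 1, 2}`.
#' @inheritParams ct_volume
#' @return An object of class `label_mask` (also a `ct_volume`).
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "integer"
  bad <- setdiff(unique(as.vector(data)), 0:2)
  if (length(bad))
    stop("label_mask: values outside {0,1,2}: ", paste(bad, collapse = ", "),
         call. = FALSE)
  v <- ct_volume(data, spacing, origin)
  class(v) <- c("label_mask", class(v))
  v
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) mm, value range [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_mismatch <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b))
    stop(what, " must share grid, spacing and origin", call. = FALSE)
  invisible(TRUE)
}

#' Read a volume from a NIfTI file
#'
#' Spacing and origin are taken from the sform/qform affine; axis direction
#' signs are folded into the origin so that spacing is always positive.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask logical; if `TRUE` the payload is validated and returned as a
#'   [label_mask()].
#' @return A [ct_volume()] (or [label_mask()]).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path, call. = FALSE)
  im <- RNifti::readNifti(path)
  a <- as.array(im)
  attributes(a) <- list(dim = dim(a))  # drop NIfTI header attributes
  if (length(dim(a)) != 3L)
    stop("read_volume: expected a 3D payload, got ",
         length(dim(a)), "D", call. = FALSE)
  aff <- RNifti::xform(im)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(spacing <= 0)) spacing <- abs(RNifti::pixdim(im))[1:3]
  origin <- aff[1:3, 4]
  if (mask) label_mask(round(a), spacing, origin) else
    ct_volume(a * 1.0, spacing, origin)
}

#' Write a volume to a NIfTI file
#'
#' @param v a [ct_volume()] or [label_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "ct_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("write_volume: directory does not exist: ", dir,
                             call. = FALSE)
  im <- RNifti::asNifti(v$data)
  RNifti::pixdim(im) <- v$spacing
  aff <- diag(c(v$spacing, 1))
  aff[1:3, 4] <- v$origin
  im <- RNifti::`sform<-`(im, structure(aff, code = 2L))
  im <- RNifti::`qform<-`(im, structure(aff, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' World extent of a volume (mm per axis)
#' @param v a [ct_volume()].
#' @return numeric length-3: `dim * spacing`.
#' @export
volume_extent <- function(v) dim(v$data) * v$spacing
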