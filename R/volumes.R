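#' Volume containers
#'
#' Minimal 3D volume containers used throughout the package. A volume is a
#' 3D array plus voxel-size metadata and a voxel-to-world affine. Voxel
#' indices are 0-based in the affine convention (NIfTI), 1-based when
#' indexing the R array.
#'
#' @param data 3D array (numeric for intensities, integer-valued for labels,
#'   logical for masks).
#' @param voxel_size_mm per-axis voxel edge lengths in mm; a scalar is
#'   recycled to all three axes.
#' @param affine 4x4 voxel-to-world matrix; default is diagonal in
#'   `voxel_size_mm`.
#' @return An object of class `intensity_volume`, `label_volume` or
#'   `mask_volume`: a list with elements `data`, `voxel_size_mm`, `affine`
#'   (and `provenance` for masks).
#' @name volumes
NULL

default_affine <- function(voxel_size_mm) {
  a <- diag(c(voxel_size_mm, 1))
  a
}

check_grid3 <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array", call. = FALSE)
}

check_voxel_size <- function(voxel_size_mm) {
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive finite lengths", call. = FALSE)
  as.numeric(voxel_size_mm)
}

#' @rdname volumes
#' @export
intensity_volume <- function(data, voxel_size_mm = 1, affine = NULL) {
  check_grid3(data)
  if (any(!is.finite(data))) stop("intensity volume must be finite", call. = FALSE)
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  if (is.null(affine)) affine <- default_affine(voxel_size_mm)
  structure(list(data = data, voxel_size_mm = voxel_size_mm, affine = affine),
            class = "intensity_volume")
}

#' @rdname volumes
#' @export
label_volume <- function(data, voxel_size_mm = 1, affine = NULL) {
  check_grid3(data)
  if (any(data < 0) || any(data != round(data)))
    stop("labels must be non-negative integers (0 = background)", call. = FALSE)
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  if (is.null(affine)) affine <- default_affine(voxel_size_mm)
  storage.mode(data) <- "integer"
  structure(list(data = data, voxel_size_mm = voxel_size_mm, affine = affine),
            class = "label_volume")
}

#' @rdname volumes
#' @param provenance short string describing how the mask was constructed.
#' @export
mask_volume <- function(data, voxel_size_mm = 1, affine = NULL,
                        provenance = "mask") {
  check_grid3(data)
  if (!is.logical(data)) storage.mode(data) <- "logical"
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  if (is.null(affine)) affine <- default_affine(voxel_size_mm)
  structure(list(data = data, voxel_size_mm = voxel_size_mm, affine = affine,
                 provenance = provenance),
            class = "mask_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<intensity_volume> %s voxels, %s mm; range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$data))), 0L)
  cat(sprintf("<label_volume> %s voxels, %s mm; %d labels\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"), length(labs)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s voxels; %d true; provenance: %s\n",
              paste(dim(x$data), collapse = "x"), sum(x$data), x$provenance))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data))
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti}. Label volumes are written as integer
#' images and re-read with `as_labels = TRUE`.
#'
#' @param path file path, usually `.nii` or `.nii.gz`.
#' @param vol a volume container.
#' @param as_labels logical; read as a `label_volume`.
#' @return `read_volume` returns an `intensity_volume` or `label_volume`;
#'   `write_volume` returns `path` invisibly.
#' @export
read_volume <- function(path, as_labels = FALSE) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  vox <- RNifti::pixdim(img)[seq_len(3)]
  aff <- matrix(RNifti::xform(img), 4, 4)
  if (as_labels) label_volume(round(data), vox, aff)
  else intensity_volume(data, vox, aff)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data * 1)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Gaussian smoothing of a 3D volume in millimetre space
#'
#' Separable discrete Gaussian convolution. The kernel standard deviation is
#' `fwhm_mm / (2 * sqrt(2 * log(2)))` converted to voxel units per axis;
#' kernel taps are normal densities at integer offsets, normalised to unit
#' sum, truncated at 4 sigma. Boundaries are handled by reflection.
#'
#' @param x 3D numeric array.
#' @param fwhm_mm full width at half maximum of the kernel, in mm; 0 returns
#'   `x` unchanged.
#' @param voxel_size_mm per-axis voxel sizes (scalar recycled).
#' @return a smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(x, fwhm_mm, voxel_size_mm = 1) {
  check_grid3(x)
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(x)
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / voxel_size_mm[axis]
    x <- smooth_axis(x, sigma_vox, axis)
  }
  x
}

gauss_kernel <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  w <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  w / sum(w)
}

# reflected index: 1,2,...,n,n,...; standard "reflect" (half-sample) padding
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p  # 0-based period-2n position
  ifelse(j < n, j + 1L, p - j)
}

# convolve along one axis as a weighted sum of index-shifted arrays
smooth_axis <- function(x, sigma_vox, axis) {
  if (sigma_vox <= 0) return(x)
  w <- gauss_kernel(sigma_vox)
  r <- (length(w) - 1L) / 2L
  n <- dim(x)[axis]
  out <- array(0, dim = dim(x))
  idx <- list(quote(expr =), quote(expr =), quote(expr =))
  for (k in seq_along(w)) {
    off <- k - r - 1L
    src <- reflect_index(seq_len(n) + off, n)
    args <- idx
    args[[axis]] <- src
    shifted <- do.call(`[`, c(list(x), args, list(drop = FALSE)))
    out <- out + w[k] * shifted
  }
  out
}
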