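#' Build a binary mask from parcellation labels
#'
#' A voxel is included iff its label belongs to the union of the label sets
#' of the requested roles.
#'
#' @param labels a `label_volume`.
#' @param spec a `region_spec`.
#' @param roles character vector of role names, a subset of `names(spec)`.
#' @return a `mask_volume` on the same grid.
#' @export
build_mask <- function(labels, spec, roles) {
  stopifnot(inherits(labels, "label_volume"), inherits(spec, "region_spec"))
  missing_roles <- setdiff(roles, names(spec))
  if (length(missing_roles))
    stop("roles not in spec: ", paste(missing_roles, collapse = ", "),
         call. = FALSE)
  ids <- unique(unlist(spec[roles], use.names = FALSE))
  m <- array(labels$data %in% ids, dim = dim(labels$data))
  if (!any(m))
    stop("mask is empty for role(s): ", paste(roles, collapse = ", "),
         call. = FALSE)
  mask_volume(m, labels$voxel_size_mm, labels$affine,
              provenance = paste("labels:", paste(roles, collapse = "+")))
}

#' Erode a white-matter mask by smoothing and thresholding
#'
#' The binarised mask (1 inside, 0 outside) is Gaussian-smoothed at
#' `fwhm_mm` in millimetre space and voxels whose smoothed value is at
#' least `threshold` are retained, which removes voxels near the mask
#' surface where gray-matter signal would spill in. The result is
#' intersected with the input mask, so it is always a subset of it.
#'
#' Defaults follow the established composite-reference construction:
#' smoothing to 8 mm FWHM and thresholding at 0.70.
#'
#' @param wm_mask a non-empty `mask_volume`.
#' @param fwhm_mm smoothing FWHM in mm (>= 0; 0 keeps the mask unchanged).
#' @param threshold retain voxels with smoothed value >= this, in (0, 1).
#' @return an eroded `mask_volume`.
#' @export
erode_white_matter <- function(wm_mask, fwhm_mm = 8, threshold = 0.70) {
  stopifnot(inherits(wm_mask, "mask_volume"))
  if (!any(wm_mask$data)) stop("input mask is empty", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0", call. = FALSE)
  sm <- gaussian_smooth(wm_mask$data * 1.0, fwhm_mm, wm_mask$voxel_size_mm)
  keep <- (sm >= threshold) & wm_mask$data
  if (!any(keep))
    stop("eroded mask is empty: mask too thin for fwhm_mm = ", fwhm_mm,
         ", threshold = ", threshold, call. = FALSE)
  mask_volume(keep, wm_mask$voxel_size_mm, wm_mask$affine,
              provenance = sprintf("%s |> erode(fwhm=%gmm, thr=%g)",
                                   wm_mask$provenance, fwhm_mm, threshold))
}

#' Mean uptake over a mask
#'
#' @param pet an `intensity_volume`.
#' @param mask a non-empty `mask_volume` on the same grid.
#' @return the arithmetic mean of the PET values over the mask.
#' @export
mean_uptake <- function(pet, mask) {
  stopifnot(inherits(pet, "intensity_volume"), inherits(mask, "mask_volume"))
  if (!same_grid(pet, mask))
    stop("PET and mask grids differ; resample onto a common grid first",
         call. = FALSE)
  if (!any(mask$data)) stop("mask is empty", call. = FALSE)
  mean(pet$data[mask$data])
}

#' Composite reference uptake
#'
#' The composite reference value is the unweighted average of the three
#' regional mean uptakes (whole cerebellum, brainstem, eroded subcortical
#' white matter): each region contributes equally regardless of its volume.
#' Set `pooled = TRUE` to instead pool all voxels of the three masks into
#' one mean (a volume-weighted alternative, kept for sensitivity analysis).
#'
#' @param pet an `intensity_volume`.
#' @param wc,brainstem,eroded_wm non-empty `mask_volume`s on the PET grid.
#' @param pooled logical; see Details.
#' @return the composite reference uptake (scalar).
#' @export
composite_reference_uptake <- function(pet, wc, brainstem, eroded_wm,
                                       pooled = FALSE) {
  if (pooled) {
    u <- wc$data | brainstem$data | eroded_wm$data
    return(mean_uptake(pet, mask_volume(u, pet$voxel_size_mm, pet$affine,
                                        provenance = "composite-pooled")))
  }
  (mean_uptake(pet, wc) + mean_uptake(pet, brainstem) +
     mean_uptake(pet, eroded_wm)) / 3
}

#' Compute an SUVR for one reference region
#'
#' The target value is the pooled-voxel mean over the union of the four
#' cortical target lobes (frontal, cingulate, lateral parietal, lateral
#' temporal). The reference value is the mean uptake in the named reference
#' region: `"WC"` (whole cerebellum), `"CG"` (cerebellar gray), `"pons"`,
#' or `"composite"` (unweighted average of whole cerebellum, brainstem and
#' eroded subcortical white matter; see
#' [composite_reference_uptake()]).
#'
#' @param pet an `intensity_volume`.
#' @param labels a co-aligned `label_volume`.
#' @param spec a `region_spec`.
#' @param reference_name one of `"WC"`, `"CG"`, `"pons"`, `"composite"`.
#' @param pipeline_tag label-source identifier recorded in the result
#'   (e.g. `"FS"`, `"CT"`).
#' @param erode_fwhm_mm,erode_threshold white-matter erosion parameters for
#'   the composite reference.
#' @param target_weighting `"pooled"` (one mean over the union mask,
#'   default) or `"mean_of_means"` (average of the four lobar means).
#' @param composite_pooled pass-through to [composite_reference_uptake()].
#' @return a `suvr_result`: list with `target_mean`, `ref_mean`, `suvr`,
#'   `reference_name`, `pipeline_tag`.
#' @export
compute_suvr <- function(pet, labels, spec,
                         reference_name = c("WC", "CG", "pons", "composite"),
                         pipeline_tag = "FS",
                         erode_fwhm_mm = 8, erode_threshold = 0.70,
                         target_weighting = c("pooled", "mean_of_means"),
                         composite_pooled = FALSE) {
  reference_name <- match.arg(reference_name)
  target_weighting <- match.arg(target_weighting)
  if (!same_grid(pet, labels))
    stop("PET and label grids differ; resample labels first", call. = FALSE)

  if (target_weighting == "pooled") {
    tmask <- build_mask(labels, spec, target_roles())
    target_mean <- mean_uptake(pet, tmask)
  } else {
    target_mean <- mean(vapply(target_roles(), function(r)
      mean_uptake(pet, build_mask(labels, spec, r)), numeric(1)))
  }

  ref_mean <- switch(reference_name,
    WC = mean_uptake(pet, build_mask(labels, spec, "whole_cerebellum")),
    CG = mean_uptake(pet, build_mask(labels, spec, "cerebellar_gray")),
    pons = mean_uptake(pet, build_mask(labels, spec, "pons")),
    composite = {
      wm <- build_mask(labels, spec, "subcortical_white_matter")
      composite_reference_uptake(
        pet,
        wc = build_mask(labels, spec, "whole_cerebellum"),
        brainstem = build_mask(labels, spec, "brainstem"),
        eroded_wm = erode_white_matter(wm, erode_fwhm_mm, erode_threshold),
        pooled = composite_pooled)
    })
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference mean uptake must be positive", call. = FALSE)

  structure(list(target_mean = target_mean, ref_mean = ref_mean,
                 suvr = target_mean / ref_mean,
                 reference_name = reference_name,
                 pipeline_tag = pipeline_tag),
            class = "suvr_result")
}

#' @export
print.suvr_result <- function(x, ...) {
  cat(sprintf("SUVR [%s, ref %s] = %.4f (target %.4f / ref %.4f)\n",
              x$pipeline_tag, x$reference_name, x$suvr, x$target_mean,
              x$ref_mean))
  invisible(x)
}

#' Resample a label volume onto a target grid by nearest neighbour
#'
#' Each target voxel centre is mapped to world space through the target
#' affine, back into source voxel space through the inverse source affine,
#' and assigned the label of the nearest source voxel (background 0 outside
#' the source grid). No new label IDs can appear.
#'
#' @param labels source `label_volume`.
#' @param target volume whose grid and affine define the output.
#' @return a `label_volume` on the target grid.
#' @export
resample_labels_nearest <- function(labels, target) {
  stopifnot(inherits(labels, "label_volume"))
  if (abs(det(labels$affine)) < .Machine$double.eps ||
      abs(det(target$affine)) < .Machine$double.eps)
    stop("singular affine", call. = FALSE)
  dt <- dim(target$data)
  if (identical(dt, dim(labels$data)) &&
      isTRUE(all.equal(labels$affine, target$affine)))
    return(label_volume(labels$data, target$voxel_size_mm, target$affine))
  # 0-based voxel index grids of the target
  g <- as.matrix(expand.grid(i = seq_len(dt[1]) - 1L, j = seq_len(dt[2]) - 1L,
                             k = seq_len(dt[3]) - 1L))
  xyz1 <- cbind(g, 1)
  src <- xyz1 %*% t(solve(labels$affine) %*% target$affine)
  src_idx <- round(src[, 1:3]) + 1L  # back to 1-based array indices
  ds <- dim(labels$data)
  inside <- src_idx[, 1] >= 1 & src_idx[, 1] <= ds[1] &
            src_idx[, 2] >= 1 & src_idx[, 2] <= ds[2] &
            src_idx[, 3] >= 1 & src_idx[, 3] <= ds[3]
  out <- integer(nrow(src_idx))
  out[inside] <- labels$data[src_idx[inside, , drop = FALSE]]
  label_volume(array(out, dim = dt), target$voxel_size_mm, target$affine)
}
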