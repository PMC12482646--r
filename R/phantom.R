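# Synthetic PET/parcellation phantoms and cohorts.
#
# The phantoms are deliberately geometric (axis-aligned blocks or
# ellipsoids): the downstream analysis only consumes label-conditioned mean
# uptakes, so anatomical realism buys nothing at desk scale. What the
# generator does reproduce is the statistical structure the analysis
# assumes: region-wise uptake, a Gaussian point-spread blur (4 mm FWHM by
# default, the post-reconstruction smoothing of the emulated scans),
# additive noise, and a pair of parcellations that disagree slightly at
# region boundaries.

# evaluate `code` under a temporary RNG state so generator streams stay
# independent of the caller's RNG and of each other
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, stream, i = 0L) {
  (as.numeric(seed) * 1009 + stream * 7919 + i) %% 2147483629
}

#' Phantom specification
#'
#' Defines the geometry and noise model of a synthetic PET/parcellation
#' pair. The default layout places nine non-overlapping blocks (the four
#' cortical target lobes, cerebellar white and gray matter, pons, the rest
#' of the brainstem, and subcortical white matter) on a 48^3 grid of 2 mm
#' voxels; [phantom_region_spec()] maps the nine semantic roles onto those
#' blocks (whole cerebellum = gray + white blocks, brainstem = pons + rest).
#'
#' @param grid_shape voxels per axis (each >= 16).
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param region_layout list of regions, each a list with `role`, `label`,
#'   `shape` (`"block"` or `"ellipsoid"`), `center` (1-based voxel
#'   coordinates) and `half_size` (half extents in voxels).
#' @param psf_fwhm_mm point-spread FWHM in mm (default 4).
#' @param noise_sd additive Gaussian noise SD in uptake units.
#' @param seed integer seed for the noise stream.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48), voxel_size_mm = 2,
                         region_layout = default_region_layout(),
                         psf_fwhm_mm = 4, noise_sd = 0, seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 16))
    stop("grid_shape must be three sizes, all >= 16", call. = FALSE)
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be > 0", call. = FALSE)
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 region_layout = region_layout,
                 psf_fwhm_mm = psf_fwhm_mm, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_region_layout <- function() {
  blk <- function(role, label, center, half_size)
    list(role = role, label = label, shape = "block", center = center,
         half_size = half_size)
  list(
    blk("frontal",                  1L, c(8, 8, 8),    c(5, 5, 5)),
    blk("cingulate",                2L, c(24, 8, 8),   c(5, 5, 5)),
    blk("lateral_parietal",         3L, c(40, 8, 8),   c(5, 5, 5)),
    blk("lateral_temporal",         4L, c(8, 24, 8),   c(5, 5, 5)),
    blk("cerebellum_white",         5L, c(24, 24, 8),  c(5, 5, 5)),
    blk("cerebellum_gray",          6L, c(40, 24, 8),  c(5, 5, 5)),
    blk("pons",                     7L, c(8, 40, 8),   c(5, 5, 5)),
    blk("brainstem_rest",           8L, c(24, 40, 8),  c(5, 5, 5)),
    blk("subcortical_wm",           9L, c(24, 24, 32), c(7, 7, 7))
  )
}

#' @rdname phantom_spec
#' @export
phantom_region_spec <- function() {
  region_spec(list(
    frontal = 1L, cingulate = 2L, lateral_parietal = 3L,
    lateral_temporal = 4L,
    whole_cerebellum = c(5L, 6L), cerebellar_gray = 6L,
    pons = 7L, brainstem = c(7L, 8L),
    subcortical_white_matter = 9L))
}

region_voxels <- function(region, grid_shape) {
  c0 <- region$center
  h <- region$half_size
  lo <- pmax(1L, ceiling(c0 - h))
  hi <- pmin(grid_shape, floor(c0 + h))
  g <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  if (identical(region$shape, "ellipsoid")) {
    d2 <- ((g$i - c0[1]) / h[1])^2 + ((g$j - c0[2]) / h[2])^2 +
          ((g$k - c0[3]) / h[3])^2
    g <- g[d2 <= 1, , drop = FALSE]
  } else if (!identical(region$shape, "block")) {
    stop("unknown region shape: ", region$shape, call. = FALSE)
  }
  as.matrix(g)
}

#' Synthesise a PET/parcellation phantom
#'
#' Builds the label volume from the layout, paints each region with its
#' nominal uptake (background 0), convolves with the Gaussian point-spread
#' function, and adds i.i.d. Gaussian noise. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param regional_uptake named numeric vector/list, uptake per layout role
#'   (every name must exist in the layout; values >= 0). Layout roles
#'   without an entry default to 0.
#' @return list with elements `pet` (an `intensity_volume`) and `labels`
#'   (a `label_volume`).
#' @export
make_phantom <- function(spec, regional_uptake) {
  stopifnot(inherits(spec, "phantom_spec"))
  layout_roles <- vapply(spec$region_layout, `[[`, "", "role")
  unknown <- setdiff(names(regional_uptake), layout_roles)
  if (length(unknown))
    stop("unknown role(s) in regional_uptake: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(unlist(regional_uptake) < 0))
    stop("uptake values must be >= 0", call. = FALSE)

  labs <- array(0L, dim = spec$grid_shape)
  upt <- array(0, dim = spec$grid_shape)
  for (region in spec$region_layout) {
    vox <- region_voxels(region, spec$grid_shape)
    if (any(labs[vox] != 0L))
      stop("region layout overlaps at role ", region$role, call. = FALSE)
    labs[vox] <- region$label
    u <- regional_uptake[[region$role]]
    if (!is.null(u)) upt[vox] <- u
  }

  img <- gaussian_smooth(upt, spec$psf_fwhm_mm, spec$voxel_size_mm)
  if (spec$noise_sd > 0) {
    img <- img + with_seed(derive_seed(spec$seed, 1L),
                           array(stats::rnorm(length(img), 0, spec$noise_sd),
                                 dim = dim(img)))
  }
  list(pet = intensity_volume(img, spec$voxel_size_mm),
       labels = label_volume(labs, spec$voxel_size_mm))
}

#' Parcellation perturbation
#'
#' Emulates the boundary-level disagreement between two parcellation
#' sources (e.g. an MRI-based and a CT-based segmentation of the same
#' head). Only voxels within `boundary_shift_voxels` (6-connected steps) of
#' a label boundary are eligible; each eligible voxel is, with probability
#' `flip_fraction`, reassigned the label of a uniformly chosen 6-neighbour
#' carrying a different label (voxels whose neighbours all agree are left
#' unchanged). No new label IDs are ever introduced.
#'
#' @param boundary_shift_voxels max depth from a boundary (>= 0; 0 disables
#'   the perturbation entirely).
#' @param flip_fraction probability in `[0, 1]` that an eligible voxel is
#'   reassigned.
#' @param seed integer seed.
#' @return an object of class `parcellation_perturbation`.
#' @export
parcellation_perturbation <- function(boundary_shift_voxels = 1,
                                      flip_fraction = 0.5, seed = 1L) {
  if (boundary_shift_voxels < 0)
    stop("boundary_shift_voxels must be >= 0", call. = FALSE)
  if (flip_fraction < 0 || flip_fraction > 1)
    stop("flip_fraction must be in [0, 1]", call. = FALSE)
  structure(list(boundary_shift_voxels = as.integer(boundary_shift_voxels),
                 flip_fraction = flip_fraction, seed = as.integer(seed)),
            class = "parcellation_perturbation")
}

# 6-neighbour shifted copies with edge replication; returns a list of arrays
shift6 <- function(x) {
  d <- dim(x)
  ix <- function(n, off) pmin(pmax(seq_len(n) + off, 1L), n)
  list(x[ix(d[1], -1L), , , drop = FALSE], x[ix(d[1], 1L), , , drop = FALSE],
       x[, ix(d[2], -1L), , drop = FALSE], x[, ix(d[2], 1L), , drop = FALSE],
       x[, , ix(d[3], -1L), drop = FALSE], x[, , ix(d[3], 1L), drop = FALSE])
}

boundary_mask <- function(labs) {
  nb <- shift6(labs)
  b <- array(FALSE, dim = dim(labs))
  for (s in nb) b <- b | (s != labs)
  b
}

dilate6 <- function(m, times) {
  for (t in seq_len(times)) {
    nb <- shift6(m)
    for (s in nb) m <- m | s
  }
  m
}

#' Perturb a parcellation at its region boundaries
#'
#' @param labels a `label_volume`.
#' @param pert a [parcellation_perturbation()].
#' @return a `label_volume` differing from the input only near boundaries.
#' @export
perturb_parcellation <- function(labels, pert) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(pert, "parcellation_perturbation"))
  if (pert$boundary_shift_voxels == 0L || pert$flip_fraction == 0)
    return(labels)
  labs <- labels$data
  eligible <- dilate6(boundary_mask(labs), pert$boundary_shift_voxels - 1L)
  idx <- which(eligible)
  if (!length(idx)) return(labels)

  nb <- shift6(labs)
  nb_mat <- vapply(nb, function(s) s[idx], integer(length(idx)))
  own <- labs[idx]
  diff_mask <- nb_mat != own

  with_seed(derive_seed(pert$seed, 2L), {
    do_flip <- stats::runif(length(idx)) < pert$flip_fraction
    pick_u <- stats::runif(length(idx))
  })
  n_diff <- rowSums(diff_mask)
  sel <- do_flip & n_diff > 0L
  if (any(sel)) {
    # uniformly pick among the differing neighbours of each selected voxel
    choice <- 1L + floor(pick_u[sel] * n_diff[sel])
    rows <- which(sel)
    new_lab <- vapply(seq_along(rows), function(r) {
      cand <- nb_mat[rows[r], diff_mask[rows[r], ]]
      cand[choice[r]]
    }, integer(1))
    labs[idx[rows]] <- new_lab
  }
  label_volume(labs, labels$voxel_size_mm, labels$affine)
}

#' Cohort specification
#'
#' Per-group Centiloid distributions for a synthetic three-group cohort
#' (young controls, amyloid-negative patients, amyloid-positive ADCI
#' patients) plus the inverse linear map that converts a drawn Centiloid
#' value back into a target-region SUVR. Group CL means/SDs default to the
#' reported CT-parcellation whole-cerebellum summaries for ADCI
#' (85.15 / 27.91) and YC (0.99 / 3.57); no amyloid-negative distribution
#' is published, so a sub-threshold default (5 / 10) is used.
#'
#' @param n_per_group named counts for `YC`, `Abeta_negative`, `ADCI`.
#' @param group_cl_mean,group_cl_sd named per-group CL distribution
#'   parameters.
#' @param inverse_map a [linear_map()] from CL to target-region SUVR;
#'   default is the inverse of the CT whole-cerebellum CL equation.
#' @param seed integer seed for the CL draw stream.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(YC = 23, Abeta_negative = 76,
                                        ADCI = 207),
                        group_cl_mean = c(YC = 0.99, Abeta_negative = 5,
                                          ADCI = 85.15),
                        group_cl_sd = c(YC = 3.57, Abeta_negative = 10,
                                        ADCI = 27.91),
                        inverse_map = NULL, seed = 1L) {
  groups <- c("YC", "Abeta_negative", "ADCI")
  if (!all(groups %in% names(n_per_group)))
    stop("n_per_group must name YC, Abeta_negative, ADCI", call. = FALSE)
  if (any(n_per_group < 0) || any(group_cl_sd[groups] < 0))
    stop("counts and SDs must be >= 0", call. = FALSE)
  if (is.null(inverse_map)) inverse_map <- invert_map(ct_wc_cl_map())
  if (inverse_map$slope == 0) stop("inverse_map slope must be non-zero",
                                   call. = FALSE)
  structure(list(n_per_group = n_per_group[groups],
                 group_cl_mean = group_cl_mean[groups],
                 group_cl_sd = group_cl_sd[groups],
                 inverse_map = inverse_map, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of phantom subjects
#'
#' For each subject a true Centiloid value is drawn from its group's normal
#' distribution, mapped through `cohort$inverse_map` to a target-region
#' SUVR, and a phantom is synthesised with the four target lobes at that
#' SUVR times the reference uptake (all reference regions at uptake 1).
#' Each subject carries two label volumes: the generating parcellation
#' (`labels_fs`, "FS-like") and a boundary-perturbed copy (`labels_ct`,
#' "CT-like"). The simulated visual read is positive iff the true CL
#' exceeds `visual_threshold`; `visual_noise_rate` optionally flips reads
#' at random to emulate reader disagreement.
#'
#' @param cohort a [cohort_spec()].
#' @param phantom a [phantom_spec()]; per-subject noise seeds are derived
#'   from `phantom$seed`.
#' @param pert a [parcellation_perturbation()]; per-subject seeds derived
#'   from `pert$seed`.
#' @param visual_threshold CL threshold of the simulated visual read
#'   (default 30, inside the published 25-35 consensus band).
#' @param visual_noise_rate probability of flipping a simulated read.
#' @param volumes logical; `FALSE` skips volume synthesis and returns only
#'   the per-subject table columns (fast path for statistics tests).
#' @return a list of subject records, each a list with `subject_id`,
#'   `group`, `true_cl`, `true_suvr`, `visual_read`, and (when
#'   `volumes = TRUE`) `pet`, `labels_fs`, `labels_ct`.
#' @export
make_cohort <- function(cohort, phantom = phantom_spec(),
                        pert = parcellation_perturbation(),
                        visual_threshold = 30, visual_noise_rate = 0,
                        volumes = TRUE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n_tot <- sum(cohort$n_per_group)
  if (n_tot == 0) stop("empty cohort", call. = FALSE)
  groups <- rep(names(cohort$n_per_group), cohort$n_per_group)

  true_cl <- with_seed(derive_seed(cohort$seed, 3L),
    stats::rnorm(n_tot, mean = cohort$group_cl_mean[groups],
                 sd = cohort$group_cl_sd[groups]))
  reads <- true_cl > visual_threshold
  if (visual_noise_rate > 0) {
    flip <- with_seed(derive_seed(cohort$seed, 4L),
                      stats::runif(n_tot) < visual_noise_rate)
    reads <- xor(reads, flip)
  }
  true_suvr <- apply_map(cohort$inverse_map, true_cl)

  lapply(seq_len(n_tot), function(i) {
    rec <- list(subject_id = sprintf("S%03d", i), group = groups[i],
                true_cl = true_cl[i], true_suvr = true_suvr[i],
                visual_read = reads[i])
    if (volumes) {
      target_roles_layout <- c("frontal", "cingulate", "lateral_parietal",
                               "lateral_temporal")
      upt <- stats::setNames(rep(1, 9), vapply(phantom$region_layout,
                                               `[[`, "", "role"))
      upt[target_roles_layout] <- max(true_suvr[i], 0)
      spec_i <- phantom
      spec_i$seed <- as.integer(derive_seed(phantom$seed, 5L, i))
      ph <- make_phantom(spec_i, as.list(upt))
      pert_i <- pert
      pert_i$seed <- as.integer(derive_seed(pert$seed, 6L, i))
      rec$pet <- ph$pet
      rec$labels_fs <- ph$labels
      rec$labels_ct <- perturb_parcellation(ph$labels, pert_i)
    }
    rec
  })
}

#' Cohort manifest as a data frame
#'
#' @param subjects output of [make_cohort()].
#' @return data frame with `subject_id`, `group`, `true_cl`, `visual_read`.
#' @export
cohort_manifest <- function(subjects) {
  data.frame(subject_id = vapply(subjects, `[[`, "", "subject_id"),
             group = vapply(subjects, `[[`, "", "group"),
             true_cl = vapply(subjects, `[[`, 0, "true_cl"),
             visual_read = vapply(subjects, `[[`, TRUE, "visual_read"),
             stringsAsFactors = FALSE)
}
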