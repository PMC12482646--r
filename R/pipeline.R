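# End-to-end orchestration: cohort -> dual-parcellation SUVR table ->
# cross-pipeline calibration -> Centiloid table -> validation statistics.
# Each stage is a plain function over data frames so the steps can also be
# driven interactively; run_pipeline() chains them from one config.

#' Quantify SUVRs for a cohort under both parcellation sources
#'
#' Computes, for every subject, SUVRs for each requested reference region
#' under both label volumes ("FS"-like `labels_fs` and "CT"-like
#' `labels_ct`). Subjects for which any mask construction or grid check
#' fails are excluded with a machine-readable reason; remaining subjects
#' are unaffected.
#'
#' @param subjects list of subject records as produced by [make_cohort()]
#'   (each with `subject_id`, `group`, `visual_read`, `pet`, `labels_fs`,
#'   `labels_ct`).
#' @param spec a [region_spec()] (defaults to the phantom layout spec).
#' @param references reference regions to quantify.
#' @param ... passed to [compute_suvr()].
#' @return list with `suvr` (data frame: subject_id, group, visual_read,
#'   pipeline, reference, target_mean, ref_mean, suvr) and `exclusions`
#'   (data frame: subject_id, reason).
#' @export
run_quantify <- function(subjects, spec = phantom_region_spec(),
                         references = c("WC", "CG", "pons", "composite"),
                         ...) {
  stopifnot(length(subjects) > 0)
  rows <- list(); excl <- list()
  for (rec in subjects) {
    res <- tryCatch({
      sub_rows <- list()
      for (pipe in c("FS", "CT")) {
        labs <- if (pipe == "FS") rec$labels_fs else rec$labels_ct
        for (ref in references) {
          sr <- compute_suvr(rec$pet, labs, spec, reference_name = ref,
                             pipeline_tag = pipe, ...)
          sub_rows[[length(sub_rows) + 1L]] <- data.frame(
            subject_id = rec$subject_id, group = rec$group,
            visual_read = rec$visual_read, pipeline = pipe, reference = ref,
            target_mean = sr$target_mean, ref_mean = sr$ref_mean,
            suvr = sr$suvr, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, sub_rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(subject_id = rec$subject_id,
                                              reason = conditionMessage(res),
                                              stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("no subject processed successfully", call. = FALSE)
  list(suvr = do.call(rbind, rows),
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(subject_id = character(),
                                    reason = character()))
}

#' Calibrate the CT-like SUVR scale against the FS-like scale
#'
#' For each reference region, regresses paired FS-pipeline SUVRs on
#' CT-pipeline SUVRs ([cl_calibrate()]), applies [level1_acceptance()],
#' and builds the collapsed CT-SUVR-to-Centiloid chain through the
#' published FS equation (available for the WC and composite references).
#'
#' @param suvr_table SUVR data frame from [run_quantify()].
#' @return named list per reference: `fit` (`cl_calibration`), `level1`
#'   (`level1_report`), and `chain` (`conversion_chain`, `NULL` when no
#'   published FS-to-CL equation exists for that reference).
#' @export
run_calibrate <- function(suvr_table) {
  refs <- unique(suvr_table$reference)
  fs_to_cl <- list(WC = fs_wc_cl_map(), composite = fs_composite_cl_map())
  out <- list()
  for (ref in refs) {
    fs <- suvr_table[suvr_table$pipeline == "FS" &
                       suvr_table$reference == ref, ]
    ct <- suvr_table[suvr_table$pipeline == "CT" &
                       suvr_table$reference == ref, ]
    m <- merge(ct[, c("subject_id", "suvr")], fs[, c("subject_id", "suvr")],
               by = "subject_id", suffixes = c("_ct", "_fs"))
    if (nrow(m) < 3) stop("fewer than 3 complete SUVR pairs for reference ",
                          ref, call. = FALSE)
    fit <- cl_calibrate(suvr_fs ~ suvr_ct, m,
                        from = "SUVR_CT", to = "SUVR_FS")
    chain <- if (!is.null(fs_to_cl[[ref]]))
      build_ct_to_cl_chain(fit$map, fs_to_cl[[ref]]) else NULL
    out[[ref]] <- list(fit = fit, level1 = level1_acceptance(fit),
                       chain = chain)
  }
  out
}

#' Convert a SUVR table to Centiloids through calibrated chains
#'
#' FS rows go through the published FS-to-CL equation directly; CT rows go
#' through the calibrated CT-to-FS map composed with the same equation.
#' References without a published FS equation are dropped.
#'
#' @param suvr_table SUVR data frame from [run_quantify()].
#' @param calibration output of [run_calibrate()].
#' @return the input rows for convertible references, with a `cl` column.
#' @export
suvr_to_cl_table <- function(suvr_table, calibration) {
  fs_to_cl <- list(WC = fs_wc_cl_map(), composite = fs_composite_cl_map())
  keep <- suvr_table$reference %in% names(fs_to_cl)
  tab <- suvr_table[keep, ]
  tab$cl <- NA_real_
  for (ref in unique(tab$reference)) {
    i_fs <- tab$reference == ref & tab$pipeline == "FS"
    i_ct <- tab$reference == ref & tab$pipeline == "CT"
    tab$cl[i_fs] <- apply_map(fs_to_cl[[ref]], tab$suvr[i_fs])
    if (!is.null(calibration[[ref]]$chain))
      tab$cl[i_ct] <- apply_chain(calibration[[ref]]$chain, tab$suvr[i_ct])
  }
  tab[!is.na(tab$cl), ]
}

#' Cohort-level validation statistics on a Centiloid table
#'
#' Per (pipeline x reference): ADCI-vs-YC effect size with bootstrap CI.
#' Across pipelines: Levene's test on YC Centiloid values for the
#' whole-cerebellum reference, plus Bonferroni-corrected pairwise F tests.
#' Per pipeline: ROC of CL against the visual read with the
#' Youden-optimal cutoff.
#'
#' @param cl_table data frame with columns `subject_id`, `group`,
#'   `visual_read`, `pipeline`, `reference`, `cl`.
#' @param n_boot bootstrap resamples for effect-size CIs.
#' @param seed integer seed for the bootstrap.
#' @param roc_reference reference region whose CL values feed the ROC.
#' @return list with `effect_sizes` (data frame), `variance` (Levene +
#'   pairwise F tests on YC values), and `roc` (per-pipeline
#'   `roc_result`s).
#' @export
run_stats <- function(cl_table, n_boot = 10000, seed = 1L,
                      roc_reference = "WC") {
  needed <- c("group", "visual_read", "pipeline", "reference", "cl")
  stopifnot(all(needed %in% names(cl_table)))
  combos <- unique(cl_table[, c("pipeline", "reference")])
  es_rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- cl_table[cl_table$pipeline == combos$pipeline[i] &
                      cl_table$reference == combos$reference[i], ]
    pos <- sub$cl[sub$group == "ADCI"]
    neg <- sub$cl[sub$group == "YC"]
    if (length(pos) < 2 || length(neg) < 2) {
      warning("skipping effect size for ", combos$pipeline[i], "-",
              combos$reference[i], ": missing group")
      next
    }
    ci <- bootstrap_effect_size_ci(pos, neg, n_boot = n_boot,
                                   seed = derive_seed(seed, 7L, i))
    es_rows[[length(es_rows) + 1L]] <- data.frame(
      pipeline = combos$pipeline[i], reference = combos$reference[i],
      d = ci$d, ci_low = ci$ci_low, ci_high = ci$ci_high,
      stringsAsFactors = FALSE)
  }

  yc <- cl_table[cl_table$group == "YC" &
                   cl_table$reference == roc_reference, ]
  variance <- NULL
  if (nrow(yc) > 0 && length(unique(yc$pipeline)) >= 2) {
    groups <- split(yc$cl, yc$pipeline)
    variance <- list(levene = levene_test(groups),
                     pairwise = pairwise_f_tests(groups))
  }

  roc <- list()
  for (pipe in unique(cl_table$pipeline)) {
    sub <- cl_table[cl_table$pipeline == pipe &
                      cl_table$reference == roc_reference, ]
    roc[[pipe]] <- tryCatch(roc_analysis(sub$cl, sub$visual_read),
                            error = function(e) {
                              warning("ROC skipped for ", pipe, ": ",
                                      conditionMessage(e))
                              NULL
                            })
  }
  list(effect_sizes = do.call(rbind, es_rows), variance = variance,
       roc = roc)
}

#' Run the full synthetic-cohort analysis from a configuration
#'
#' Chains cohort generation, dual-parcellation quantification, calibration
#' and statistics, and (optionally) writes the tables and JSON reports to
#' an output directory.
#'
#' @param config a named list or a YAML/JSON file path; recognised fields
#'   (all optional): `n_per_group`, `psf_fwhm_mm`, `noise_sd`,
#'   `boundary_shift_voxels`, `flip_fraction`, `references`, `n_boot`,
#'   `seed`, `visual_threshold`, `out_dir`.
#' @param seed overrides `config$seed` when given.
#' @return list with `subjects`, `suvr`, `exclusions`, `calibration`,
#'   `cl`, `stats`.
#' @export
run_pipeline <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  get_cfg <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  seed <- as.integer(if (is.null(seed)) get_cfg("seed", 1L) else seed)
  n_per_group <- unlist(get_cfg("n_per_group",
                                c(YC = 10, Abeta_negative = 10, ADCI = 20)))
  cohort <- cohort_spec(n_per_group = n_per_group, seed = seed)
  phantom <- phantom_spec(psf_fwhm_mm = get_cfg("psf_fwhm_mm", 4),
                          noise_sd = get_cfg("noise_sd", 0.02),
                          seed = seed)
  pert <- parcellation_perturbation(
    boundary_shift_voxels = get_cfg("boundary_shift_voxels", 1),
    flip_fraction = get_cfg("flip_fraction", 0.5), seed = seed)

  subjects <- make_cohort(cohort, phantom, pert,
                          visual_threshold = get_cfg("visual_threshold", 30))
  q <- run_quantify(subjects,
                    references = get_cfg("references",
                                         c("WC", "CG", "pons", "composite")))
  calib <- run_calibrate(q$suvr)
  cl_tab <- suvr_to_cl_table(q$suvr, calib)
  stats <- run_stats(cl_tab, n_boot = get_cfg("n_boot", 2000), seed = seed)

  out <- list(subjects = subjects, suvr = q$suvr,
              exclusions = q$exclusions, calibration = calib, cl = cl_tab,
              stats = stats)
  out_dir <- get_cfg("out_dir", NULL)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @rdname run_pipeline
#' @param path YAML or JSON configuration file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
  else yaml::read_yaml(path)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$suvr, file.path(out_dir, "suvr.csv"),
                   row.names = FALSE)
  utils::write.csv(result$cl, file.path(out_dir, "cl.csv"),
                   row.names = FALSE)
  utils::write.csv(result$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  calib <- lapply(result$calibration, function(x) list(
    slope = x$fit$map$slope, intercept = x$fit$map$intercept,
    r_squared = x$fit$r_squared, n = x$fit$n, level1_pass = x$level1$pass,
    chain = if (!is.null(x$chain))
      list(slope = x$chain$collapsed$slope,
           intercept = x$chain$collapsed$intercept)))
  jsonlite::write_json(calib, file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  st <- list(effect_sizes = result$stats$effect_sizes,
             roc = lapply(result$stats$roc, function(r) if (!is.null(r))
               r[c("auc", "optimal_threshold", "accuracy", "sensitivity",
                   "specificity")]))
  if (!is.null(result$stats$variance)) {
    st$levene <- result$stats$variance$levene[c("levene_stat", "levene_p")]
    st$pairwise_f <- result$stats$variance$pairwise
  }
  jsonlite::write_json(st, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Conversion-equation report
#'
#' Formats the fitted and published Centiloid conversion equations as a
#' small table: one row per reference region, with the FS-pipeline
#' published equation, the collapsed CT-pipeline equation, and (for the
#' whole cerebellum) the standard-pipeline equation.
#'
#' @param calibration output of [run_calibrate()].
#' @return data frame with columns `reference`, `pipeline`, `slope`,
#'   `intercept`.
#' @export
conversion_table <- function(calibration) {
  fs_to_cl <- list(WC = fs_wc_cl_map(), composite = fs_composite_cl_map())
  rows <- list()
  for (ref in names(calibration)) {
    if (!is.null(fs_to_cl[[ref]])) {
      m <- fs_to_cl[[ref]]
      rows[[length(rows) + 1L]] <- data.frame(
        reference = ref, pipeline = "FS", slope = m$slope,
        intercept = m$intercept, stringsAsFactors = FALSE)
    }
    if (!is.null(calibration[[ref]]$chain)) {
      m <- calibration[[ref]]$chain$collapsed
      rows[[length(rows) + 1L]] <- data.frame(
        reference = ref, pipeline = "CT", slope = m$slope,
        intercept = m$intercept, stringsAsFactors = FALSE)
    }
  }
  std <- standard_cl_map()
  rows[[length(rows) + 1L]] <- data.frame(
    reference = "WC", pipeline = "standard", slope = std$slope,
    intercept = std$intercept, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
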