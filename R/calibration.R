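#' Linear maps: the currency of SUVR and Centiloid conversion
#'
#' Every conversion in the Centiloid workflow is affine: cross-pipeline
#' SUVR harmonisation, the tracer surrogate conversion, and the anchor
#' scaling to Centiloid units. `linear_map` represents `y = slope * x +
#' intercept`, tagged with input/output units so chains cannot be composed
#' out of order.
#'
#' @param slope finite slope (non-zero if the map is to be inverted).
#' @param intercept finite intercept, in output units.
#' @param from,to unit tags (free-form strings, e.g. `"SUVR_CT"`, `"CL"`).
#' @return an object of class `linear_map`.
#' @examples
#' m <- linear_map(2, 1, "x", "y")
#' apply_map(m, 0:2)
#' compose_maps(m, invert_map(m))  # identity
#' @export
linear_map <- function(slope, intercept, from = "x", to = "y") {
  if (!is.finite(slope) || !is.finite(intercept))
    stop("slope and intercept must be finite", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, from = from, to = to),
            class = "linear_map")
}

#' @rdname linear_map
#' @param map a `linear_map`.
#' @param x numeric vector.
#' @export
apply_map <- function(map, x) {
  stopifnot(inherits(map, "linear_map"))
  map$slope * x + map$intercept
}

#' @rdname linear_map
#' @export
invert_map <- function(map) {
  stopifnot(inherits(map, "linear_map"))
  if (map$slope == 0) stop("cannot invert a zero-slope map", call. = FALSE)
  linear_map(1 / map$slope, -map$intercept / map$slope,
             from = map$to, to = map$from)
}

#' @rdname linear_map
#' @param first,then maps applied in that order; `then`'s input tag must
#'   match `first`'s output tag.
#' @export
compose_maps <- function(first, then) {
  stopifnot(inherits(first, "linear_map"), inherits(then, "linear_map"))
  if (!identical(first$to, then$from))
    stop(sprintf("unit mismatch: cannot feed '%s' into a map expecting '%s'",
                 first$to, then$from), call. = FALSE)
  linear_map(then$slope * first$slope,
             then$slope * first$intercept + then$intercept,
             from = first$from, to = then$to)
}

#' @export
print.linear_map <- function(x, ...) {
  cat(sprintf("%s = %.6g * %s %+.6g\n", x$to, x$slope, x$from, x$intercept))
  invisible(x)
}

#' Published calibration constants
#'
#' One versioned table of the published constants used by the conversion
#' chains, with provenance strings; convenience constructors return them as
#' ready-made [linear_map()]s. Nothing else in the package hard-codes these
#' numbers.
#'
#' @return `cl_constants()` returns a data frame (`name`, `value`,
#'   `provenance`); the `*_map()` helpers return `linear_map`s.
#' @export
cl_constants <- function() {
  read.csv(system.file("extdata", "cl_constants.csv", package = "centiloidr"),
           stringsAsFactors = FALSE)
}

cl_const <- function(name) {
  tab <- cl_constants()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown constant: ", name, call. = FALSE)
  tab$value[i]
}

#' @rdname cl_constants
#' @export
anchor_pair <- function() {
  list(yc_mean = cl_const("anchor_yc_pib_suvr"),
       ad_mean = cl_const("anchor_ad_pib_suvr"))
}

#' Anchor-point Centiloid map
#'
#' Constructs `CL = 100 * (s - yc) / (ad - yc)` from the anchor cohort
#' means: the map sends the young-control anchor mean to 0 CL and the AD
#' anchor mean to 100 CL exactly.
#'
#' @param anchors list with `yc_mean` and `ad_mean` PiB-SUVR anchor means;
#'   defaults to the published pair (1.012, 2.077).
#' @return a `linear_map` from `"PiB_SUVR"` to `"CL"`.
#' @export
anchor_cl_map <- function(anchors = anchor_pair()) {
  yc <- anchors$yc_mean; ad <- anchors$ad_mean
  if (!(ad > yc)) stop("ad_mean must exceed yc_mean", call. = FALSE)
  linear_map(100 / (ad - yc), -100 * yc / (ad - yc),
             from = "PiB_SUVR", to = "CL")
}

#' Tracer surrogate conversion
#'
#' Florbetaben (FBB) SUVR to the PiB-SUVR scale on which the Centiloid
#' anchors are defined: `PiB = (FBB - offset) / scale` with the published
#' offset 0.39 and scale 0.61.
#'
#' @param offset,scale conversion constants; defaults are the published
#'   values.
#' @return a `linear_map` from `"FBB_SUVR"` to `"PiB_SUVR"`.
#' @export
fbb_to_pib_map <- function(offset = cl_const("fbb_pib_offset"),
                           scale = cl_const("fbb_pib_scale")) {
  if (scale == 0) stop("scale must be non-zero", call. = FALSE)
  linear_map(1 / scale, -offset / scale, from = "FBB_SUVR", to = "PiB_SUVR")
}

#' @rdname cl_constants
#' @export
fs_wc_cl_map <- function()
  linear_map(cl_const("fs_wc_slope"), cl_const("fs_wc_intercept"),
             from = "SUVR_FS", to = "CL")

#' @rdname cl_constants
#' @export
fs_composite_cl_map <- function()
  linear_map(cl_const("fs_comp_slope"), cl_const("fs_comp_intercept"),
             from = "SUVR_FS", to = "CL")

#' @rdname cl_constants
#' @export
ct_wc_cl_map <- function()
  linear_map(cl_const("ct_wc_slope"), cl_const("ct_wc_intercept"),
             from = "SUVR_CT", to = "CL")

#' @rdname cl_constants
#' @export
standard_cl_map <- function()
  compose_maps(fbb_to_pib_map(), anchor_cl_map())

#' Conversion chains
#'
#' An ordered sequence of [linear_map()]s with matching unit tags, plus its
#' collapsed single-map composition. Typical chains are SUVR_CT -> SUVR_FS
#' -> CL and FBB_SUVR -> PiB_SUVR -> CL.
#'
#' @param maps list of `linear_map`s, adjacent unit tags matching.
#' @return an object of class `conversion_chain` with elements `maps` and
#'   `collapsed`.
#' @export
conversion_chain <- function(maps) {
  stopifnot(length(maps) >= 1, all(vapply(maps, inherits, TRUE, "linear_map")))
  collapsed <- Reduce(compose_maps, maps)
  structure(list(maps = maps, collapsed = collapsed),
            class = "conversion_chain")
}

#' @rdname conversion_chain
#' @param ct_to_fs cross-pipeline SUVR harmonisation map.
#' @param fs_to_cl published SUVR_FS to CL map for the same reference
#'   region (defaults to the whole-cerebellum equation).
#' @export
build_ct_to_cl_chain <- function(ct_to_fs, fs_to_cl = fs_wc_cl_map()) {
  conversion_chain(list(ct_to_fs, fs_to_cl))
}

#' @export
print.conversion_chain <- function(x, ...) {
  cat("<conversion_chain>\n")
  for (m in x$maps) { cat("  "); print(m) }
  cat("  collapsed: "); print(x$collapsed)
  invisible(x)
}

#' @rdname conversion_chain
#' @param chain a `conversion_chain`.
#' @param x numeric vector in the chain's input units.
#' @param stagewise logical; `TRUE` returns a matrix of all intermediate
#'   stages.
#' @export
apply_chain <- function(chain, x, stagewise = FALSE) {
  stopifnot(inherits(chain, "conversion_chain"))
  if (!stagewise) return(apply_map(chain$collapsed, x))
  out <- matrix(NA_real_, nrow = length(x), ncol = length(chain$maps) + 1L)
  out[, 1] <- x
  for (i in seq_along(chain$maps)) out[, i + 1] <- apply_map(chain$maps[[i]],
                                                             out[, i])
  colnames(out) <- c(chain$maps[[1]]$from,
                     vapply(chain$maps, `[[`, "", "to"))
  out
}

#' Calibrate one pipeline's SUVR scale against another
#'
#' Fits the cross-pipeline harmonisation line by ordinary least squares.
#' The convention follows the CT-parcellation workflow: the MRI-based
#' (FreeSurfer-like) SUVR is the response and the CT-based SUVR the
#' predictor, so the fitted map converts `SUVR_CT` into calculated
#' `SUVR_FS`, which the published FS equations then carry to Centiloids. A
#' Deming fit (errors in both variables, ratio 1) is available for
#' sensitivity analysis; it is not the default.
#'
#' @param formula model formula, response ~ predictor (e.g.
#'   `suvr_fs ~ suvr_ct`).
#' @param data data frame containing both variables.
#' @param method `"ols"` (default) or `"deming"`.
#' @param from,to unit tags for the fitted map; defaults taken from the
#'   formula variable names.
#' @return an object of class `cl_calibration`: list with `map`
#'   (a [linear_map()]), `r_squared`, `n`, `residual_sd`, `method`, plus
#'   the underlying `lm` fit for OLS. Supports `print`, `summary`, `coef`,
#'   `predict`, `residuals` and `plot`.
#' @examples
#' d <- data.frame(suvr_ct = seq(0.8, 2.4, length.out = 20))
#' d$suvr_fs <- 0.97 * d$suvr_ct + 0.05
#' fit <- cl_calibrate(suvr_fs ~ suvr_ct, d)
#' coef(fit)
#' @export
cl_calibrate <- function(formula, data, method = c("ols", "deming"),
                         from = NULL, to = NULL) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data)
  y <- mf[[1]]; x <- mf[[2]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("predictor has zero variance", call. = FALSE)
  if (is.null(from)) from <- all.vars(formula)[2]
  if (is.null(to)) to <- all.vars(formula)[1]

  if (method == "ols") {
    lmfit <- stats::lm(y ~ x)
    b <- unname(stats::coef(lmfit))
    slope <- b[2]; intercept <- b[1]
    res <- stats::residuals(lmfit)
  } else {
    # Deming with error-variance ratio 1 (orthogonal regression)
    sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
    slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
    intercept <- mean(y) - slope * mean(x)
    res <- y - (slope * x + intercept)
    lmfit <- NULL
  }
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(map = linear_map(slope, intercept, from, to),
                 r_squared = r_squared, n = n,
                 residual_sd = sqrt(ss_res / max(n - 2, 1)),
                 pearson_r_squared = stats::cor(x, y)^2,
                 method = method, lm = lmfit,
                 formula = formula),
            class = "cl_calibration")
}

#' @rdname cl_calibrate
#' @param x,y numeric vectors (predictor, response); convenience interface
#'   mirroring the formula method.
#' @export
fit_linear <- function(x, y) {
  cl_calibrate(y ~ x, data.frame(x = x, y = y))
}

#' @export
print.cl_calibration <- function(x, ...) {
  cat(sprintf("Linear calibration (%s), n = %d\n", x$method, x$n))
  cat("  "); print(x$map)
  cat(sprintf("  R-squared = %.4f, residual SD = %.4g\n",
              x$r_squared, x$residual_sd))
  invisible(x)
}

#' @export
coef.cl_calibration <- function(object, ...) {
  c(intercept = object$map$intercept, slope = object$map$slope)
}

#' @export
predict.cl_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$lm))
      stop("provide newdata for a Deming fit", call. = FALSE)
    return(unname(stats::fitted(object$lm)))
  }
  if (is.data.frame(newdata)) newdata <- newdata[[object$map$from]]
  apply_map(object$map, newdata)
}

#' @export
residuals.cl_calibration <- function(object, ...) {
  if (is.null(object$lm)) stop("residuals stored only for OLS", call. = FALSE)
  unname(stats::residuals(object$lm))
}

#' @export
summary.cl_calibration <- function(object, ...) {
  out <- list(fit = object, level1 = level1_acceptance(object))
  class(out) <- "summary.cl_calibration"
  out
}

#' @export
print.summary.cl_calibration <- function(x, ...) {
  print(x$fit)
  print(x$level1)
  invisible(x)
}

#' @export
plot.cl_calibration <- function(x, ...) {
  if (is.null(x$lm)) stop("plot available for OLS fits", call. = FALSE)
  xv <- x$lm$model$x; yv <- x$lm$model$y
  graphics::plot(xv, yv, xlab = x$map$from, ylab = x$map$to, ...)
  graphics::abline(a = x$map$intercept, b = x$map$slope)
  graphics::abline(a = 0, b = 1, lty = 2)
  invisible(x)
}

#' Level-1 acceptance check of a calibration fit
#'
#' The standard Centiloid validation requires the regression of local
#' against published CL values to satisfy: R-squared strictly greater than
#' 0.98, slope within [0.98, 1.02] and intercept within [-2, 2] (slope and
#' intercept bounds inclusive; the R-squared bound is strict as printed).
#'
#' @param fit a `cl_calibration`, or a list with elements `slope`,
#'   `intercept`, `r_squared`.
#' @param slope_range,intercept_range,r_squared_min acceptance bounds.
#' @return an object of class `level1_report`: per-criterion logicals and
#'   the overall conjunction.
#' @export
level1_acceptance <- function(fit, slope_range = c(0.98, 1.02),
                              intercept_range = c(-2, 2),
                              r_squared_min = 0.98) {
  if (inherits(fit, "cl_calibration"))
    fit <- list(slope = fit$map$slope, intercept = fit$map$intercept,
                r_squared = fit$r_squared)
  slope_ok <- fit$slope >= slope_range[1] && fit$slope <= slope_range[2]
  intercept_ok <- fit$intercept >= intercept_range[1] &&
    fit$intercept <= intercept_range[2]
  r2_ok <- fit$r_squared > r_squared_min
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared,
                 slope_ok = slope_ok, intercept_ok = intercept_ok,
                 r_squared_ok = r2_ok,
                 pass = slope_ok && intercept_ok && r2_ok,
                 bounds = list(slope = slope_range,
                               intercept = intercept_range,
                               r_squared_min = r_squared_min)),
            class = "level1_report")
}

#' @export
print.level1_report <- function(x, ...) {
  mark <- function(ok) if (ok) "PASS" else "FAIL"
  cat("Level-1 acceptance:\n")
  cat(sprintf("  slope     %.4f in [%.2f, %.2f]  %s\n", x$slope,
              x$bounds$slope[1], x$bounds$slope[2], mark(x$slope_ok)))
  cat(sprintf("  intercept %.4f in [%.0f, %.0f]      %s\n", x$intercept,
              x$bounds$intercept[1], x$bounds$intercept[2],
              mark(x$intercept_ok)))
  cat(sprintf("  R-squared %.4f > %.2f           %s\n", x$r_squared,
              x$bounds$r_squared_min, mark(x$r_squared_ok)))
  cat(sprintf("  overall: %s\n", mark(x$pass)))
  invisible(x)
}

#' Run the Level-1 check on a user-supplied CL comparison table
#'
#' Hook for replicating the standard calibration-dataset analysis: accepts
#' a CSV of published versus locally computed CL values (columns
#' `published_cl`, `local_cl`), regresses local on published, and applies
#' [level1_acceptance()]. Both the regression R-squared and the squared
#' Pearson correlation are reported (identical for a simple straight-line
#' fit).
#'
#' @param path CSV path.
#' @return list with the `cl_calibration` fit and its `level1_report`.
#' @export
level1_from_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("published_cl", "local_cl") %in% names(tab)))
    stop("CSV needs columns published_cl, local_cl", call. = FALSE)
  fit <- cl_calibrate(local_cl ~ published_cl, tab,
                      from = "CL_published", to = "CL_local")
  list(fit = fit, report = level1_acceptance(fit))
}
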