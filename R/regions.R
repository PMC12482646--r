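#' Region specifications
#'
#' A region spec maps semantic region roles to sets of integer parcellation
#' label IDs. Nine roles are recognised: the four cortical target lobes
#' (`frontal`, `cingulate`, `lateral_parietal`, `lateral_temporal`) and the
#' reference-region substrates (`whole_cerebellum`, `cerebellar_gray`,
#' `pons`, `brainstem`, `subcortical_white_matter`).
#'
#' A default lookup table in the Desikan-Killiany-Tourville (DKT) labelling
#' convention ships with the package and can be edited or replaced; label
#' IDs vary between parcellation tools, so the spec is always
#' user-overridable.
#'
#' @param roles named list mapping each role to a non-empty integer vector
#'   of label IDs.
#' @return An object of class `region_spec` (a named list of integer
#'   vectors).
#' @examples
#' spec <- region_spec(list(frontal = 1:2, cingulate = 3,
#'                          lateral_parietal = 4, lateral_temporal = 5,
#'                          whole_cerebellum = 6:7, cerebellar_gray = 7,
#'                          pons = 8, brainstem = 8:9,
#'                          subcortical_white_matter = 10))
#' target_roles()
#' @export
region_spec <- function(roles) {
  required <- c(target_roles(), "whole_cerebellum", "cerebellar_gray",
                "pons", "brainstem", "subcortical_white_matter")
  if (!all(names(roles) %in% c(required)) || is.null(names(roles)))
    stop("unknown role(s): ",
         paste(setdiff(names(roles), required), collapse = ", "),
         call. = FALSE)
  roles <- lapply(roles, function(v) {
    v <- as.integer(v)
    if (length(v) == 0L) stop("each role needs >= 1 label ID", call. = FALSE)
    sort(unique(v))
  })
  tg <- intersect(names(roles), target_roles())
  if (length(tg) > 1L) {
    all_ids <- unlist(roles[tg], use.names = FALSE)
    if (anyDuplicated(all_ids))
      stop("target roles must have pairwise disjoint label IDs", call. = FALSE)
  }
  structure(roles, class = "region_spec")
}

#' @rdname region_spec
#' @export
target_roles <- function() {
  c("frontal", "cingulate", "lateral_parietal", "lateral_temporal")
}

#' @rdname region_spec
#' @param path JSON or YAML file mapping role names to label-ID lists;
#'   `NULL` loads the bundled DKT-convention defaults.
#' @export
read_region_spec <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dkt_regions.json", package = "centiloidr")
  roles <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(roles[[".comment"]])) roles[[".comment"]] <- NULL
  region_spec(roles)
}

#' @export
print.region_spec <- function(x, ...) {
  cat("<region_spec>\n")
  for (r in names(x))
    cat(sprintf("  %-26s %s\n", r, paste(x[[r]], collapse = " ")))
  invisible(x)
}
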