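#' The fixed ERP feature inventory
#'
#' The analyses all operate on the same 56-column feature inventory:
#' peak amplitude and latency of the three infant face-sensitive ERP
#' components (P1, N290, P400) for each of the six stimulus conditions
#' (FD direct gaze, FA averted gaze, F static face, N visual noise,
#' SD gaze shift toward the viewer, SA gaze shift away), the corresponding
#' three condition contrasts, plus gender and age.
#'
#' Ordering is deterministic: the 36 averaged features first (component
#' outer, measure middle, condition inner), then the 18 differential
#' features (same nesting over the three contrasts), then `gender`, `age`.
#'
#' Contrast definitions: `FvN = F - N` (face minus noise), `DvA = FD - FA`
#' (direct minus averted), `TvA = SD - SA` (toward minus away).
#'
#' @return Character vector of 56 feature names.
#' @export
#' @examples
#' inv <- build_feature_inventory()
#' length(inv) # 56
build_feature_inventory <- function() {
  comps <- c("P1", "N290", "P400")
  meas <- c("amp", "lat")
  conds <- c("FD", "FA", "F", "N", "SD", "SA")
  contrasts <- c("FvN", "DvA", "TvA")
  averaged <- as.vector(t(outer(
    paste(rep(comps, each = 2), rep(meas, times = 3), sep = "_"),
    conds, paste, sep = "_")))
  differential <- as.vector(t(outer(
    paste(rep(comps, each = 2), rep(meas, times = 3), sep = "_"),
    contrasts, paste, sep = "_")))
  c(averaged, differential, "gender", "age")
}

#' @rdname build_feature_inventory
#' @export
erp_feature_names <- function() setdiff(build_feature_inventory(), c("gender", "age"))

#' @rdname build_feature_inventory
#' @export
averaged_feature_names <- function() {
  inv <- build_feature_inventory()
  inv[1:36]
}

#' @rdname build_feature_inventory
#' @export
differential_feature_names <- function() {
  inv <- build_feature_inventory()
  inv[37:54]
}

# parents of each contrast, in (minuend, subtrahend) order
contrast_parents <- function() {
  list(FvN = c("F", "N"), DvA = c("FD", "FA"), TvA = c("SD", "SA"))
}

# "P400_lat_TvA" -> list(component, measure, suffix, is_contrast)
parse_feature_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) != 3) return(NULL)
  list(component = parts[1], measure = parts[2], suffix = parts[3],
       is_contrast = parts[3] %in% names(contrast_parents()))
}

# recompute the 18 differential columns from the 36 averaged ones
apply_contrasts <- function(tab) {
  cp <- contrast_parents()
  for (nm in differential_feature_names()) {
    f <- parse_feature_name(nm)
    par <- cp[[f$suffix]]
    a <- paste(f$component, f$measure, par[1], sep = "_")
    b <- paste(f$component, f$measure, par[2], sep = "_")
    tab[[nm]] <- tab[[a]] - tab[[b]]
  }
  tab
}
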