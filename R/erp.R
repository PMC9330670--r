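#' Component search windows
#'
#' Default peak-search windows and polarities for the three infant
#' face-sensitive ERP components: P1 positive in 70-170 ms, N290 negative in
#' 200-350 ms, P400 positive in 350-600 ms. These are the standard infant
#' face-ERP windows consistent with the component names; all are configurable.
#'
#' @param P1,N290,P400 numeric length-2 windows (ms, closed intervals).
#' @return data.frame with columns `component`, `lo`, `hi`, `polarity`.
#' @export
component_windows <- function(P1 = c(70, 170), N290 = c(200, 350),
                              P400 = c(350, 600)) {
  w <- data.frame(component = c("P1", "N290", "P400"),
                  lo = c(P1[1], N290[1], P400[1]),
                  hi = c(P1[2], N290[2], P400[2]),
                  polarity = c(1, -1, 1),
                  stringsAsFactors = FALSE)
  stopifnot(all(w$lo < w$hi), all(w$lo > 0), all(w$hi <= 800),
            w$hi[1] <= w$lo[2], w$hi[2] <= w$lo[3]) # ordered, non-overlapping
  w
}

#' Reject high-amplitude artifact epochs
#'
#' A simplified amplitude-threshold rule: any epoch whose absolute value
#' exceeds `abs_threshold_uV` on any designated occipito-temporal channel is
#' removed; if fewer than `min_epochs` survive, the epoch set is flagged
#' `"too-few-epochs"` (and downstream features become missing).
#'
#' @param epochs an [epoch_set()].
#' @param abs_threshold_uV rejection threshold in microvolts (default 200).
#' @param min_epochs minimum surviving epochs (default 10).
#' @return The filtered `epoch_set`.
#' @export
reject_artifacts <- function(epochs, abs_threshold_uV = 200, min_epochs = 10) {
  stopifnot(inherits(epochs, "epoch_set"), abs_threshold_uV > 0)
  ne <- dim(epochs$data)[1]
  if (ne == 0) stop("empty epoch set")
  keep <- vapply(seq_len(ne), function(i) {
    max(abs(epochs$data[i, epochs$ot_channels, , drop = FALSE])) <= abs_threshold_uV
  }, logical(1))
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  if (sum(keep) < min_epochs) epochs$flag <- "too-few-epochs"
  epochs
}

#' Average epochs with prestimulus baseline correction
#'
#' Pointwise arithmetic mean over epochs, then per-channel subtraction of the
#' mean over the full prestimulus segment (time <= 0).
#'
#' @param epochs an [epoch_set()].
#' @return A channels x samples matrix with the time axis as attribute.
#' @export
average_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[1] == 0) stop("no surviving epochs to average")
  avg <- apply(epochs$data, c(2, 3), mean)
  pre <- epochs$time <= 0
  avg <- avg - rowMeans(avg[, pre, drop = FALSE])
  attr(avg, "time") <- epochs$time
  attr(avg, "ot_channels") <- epochs$ot_channels
  avg
}

#' Detect a component peak in an averaged waveform
#'
#' The signal is the mean over the designated occipito-temporal channels.
#' The peak is the largest (positive polarity) or smallest (negative polarity)
#' local extremum inside the closed search window; a window containing only a
#' monotone run (no interior extremum) is flagged `"no-peak"`. Ties go to the
#' earliest sample.
#'
#' @param avg channels x samples average from [average_epochs()].
#' @param window one row of [component_windows()].
#' @param ot_channels occipito-temporal channel indices (defaults to the
#'   attribute carried by `avg`).
#' @return List: `component`, `amplitude` (microvolts), `latency` (ms),
#'   `flag`.
#' @export
detect_peak <- function(avg, window, ot_channels = attr(avg, "ot_channels")) {
  time <- attr(avg, "time")
  if (is.null(time)) stop("avg must carry a time axis")
  if (window$lo < min(time) || window$hi > max(time))
    stop("search window outside the time axis")
  signal <- colMeans(avg[ot_channels, , drop = FALSE])
  idx <- which(time >= window$lo & time <= window$hi)
  pol <- window$polarity
  s <- signal * pol
  # local maxima of the polarity-oriented signal over the whole axis
  n <- length(s)
  interior <- idx[idx > 1 & idx < n]
  is_max <- s[interior] >= s[interior - 1] & s[interior] >= s[interior + 1]
  cand <- interior[is_max]
  if (length(cand) == 0) {
    return(list(component = window$component, amplitude = NA_real_,
                latency = NA_real_, flag = "no-peak"))
  }
  best <- cand[which.max(s[cand])] # which.max returns the earliest on ties
  list(component = window$component, amplitude = signal[best],
       latency = time[best], flag = "ok")
}

#' Extract the full ERP feature row for one subject
#'
#' Runs peak detection for every component in every condition average, fills
#' the 36 averaged features, and computes the 18 differential features as
#' exact differences of the parent-condition features. Flagged conditions
#' (`"no-peak"`, `"too-few-epochs"`) propagate `NA` into every feature they
#' touch; nothing is silently zero-filled.
#'
#' @param averages named list (by condition, all six of FD FA F N SD SA) of
#'   averaged matrices from [average_epochs()], or `NA` for a condition
#'   flagged upstream.
#' @param windows a [component_windows()] table.
#' @return Named numeric vector over the 54 ERP inventory features.
#' @export
extract_features <- function(averages, windows = component_windows()) {
  conds <- c("FD", "FA", "F", "N", "SD", "SA")
  stopifnot(all(conds %in% names(averages)))
  out <- setNames(rep(NA_real_, 54), erp_feature_names())
  for (cond in conds) {
    avg <- averages[[cond]]
    if (!is.matrix(avg)) next # condition flagged: stays NA
    for (k in seq_len(nrow(windows))) {
      pk <- detect_peak(avg, windows[k, ])
      if (pk$flag == "ok") {
        out[paste0(pk$component, "_amp_", cond)] <- pk$amplitude
        out[paste0(pk$component, "_lat_", cond)] <- pk$latency
      }
    }
  }
  cp <- contrast_parents()
  for (nm in differential_feature_names()) {
    f <- parse_feature_name(nm)
    par <- cp[[f$suffix]]
    a <- paste(f$component, f$measure, par[1], sep = "_")
    b <- paste(f$component, f$measure, par[2], sep = "_")
    out[nm] <- out[a] - out[b]
  }
  out
}

#' Waveforms to feature table for a whole cohort
#'
#' Applies artifact rejection, averaging and peak extraction to every subject
#' of a waveform-level cohort and assembles the standard feature table.
#'
#' @param cohort a `synthetic_cohort` from [generate_waveforms()] (or any
#'   object with the same `epochs` layout and `truth$meta`).
#' @param windows component search windows.
#' @param abs_threshold_uV,min_epochs artifact-rejection parameters.
#' @return The cohort with `$features` filled in.
#' @export
extract_cohort_features <- function(cohort, windows = component_windows(),
                                    abs_threshold_uV = 200, min_epochs = 10) {
  stopifnot(!is.null(cohort$epochs))
  rows <- lapply(cohort$epochs, function(by_cond) {
    averages <- lapply(by_cond, function(es) {
      es <- reject_artifacts(es, abs_threshold_uV, min_epochs)
      if (es$flag == "too-few-epochs") return(NA)
      average_epochs(es)
    })
    extract_features(averages, windows)
  })
  feat <- as.data.frame(do.call(rbind, rows))
  meta <- cohort$truth$meta
  features <- cbind(meta[, c("subject", "group", "asd")],
                    outcome = if ("outcome" %in% names(meta)) meta$outcome else NA_real_,
                    feat,
                    gender = meta$gender, age = meta$age)
  rownames(features) <- NULL
  cohort$features <- features
  cohort
}
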