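#' Construct an epoch set
#'
#' Container for the stimulus-locked epochs of one subject in one condition:
#' an epochs x channels x samples array in microvolts on a millisecond time
#' axis spanning the peristimulus window, with a designated occipito-temporal
#' channel subset.
#'
#' @param data numeric array, epochs x channels x samples.
#' @param time strictly increasing time axis in ms containing 0.
#' @param ot_channels integer indices of the occipito-temporal channels.
#' @param subject,condition identifying labels.
#' @param flag quality flag, `"ok"`, `"no-peak"` or `"too-few-epochs"`.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, time, ot_channels, subject = NA, condition = NA,
                      flag = "ok") {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(time),
            all(diff(time) > 0), any(time == 0) || (min(time) < 0 && max(time) > 0),
            length(ot_channels) >= 1, all(ot_channels <= dim(data)[2]))
  structure(list(data = data, time = time, ot_channels = as.integer(ot_channels),
                 subject = subject, condition = condition, flag = flag),
            class = "epoch_set")
}

# Gaussian bump: amp * exp(-((t - lat) / width)^2 / 2)
component_bump <- function(time, lat, amp, width) {
  amp * exp(-0.5 * ((time - lat) / width)^2)
}

#' Generate a waveform-level synthetic cohort
#'
#' For every subject and condition, epochs are built as baseline Gaussian
#' noise plus three Gaussian-bump components (P1 positive, N290 negative,
#' P400 positive) at the subject's planted latencies and amplitudes, full
#' amplitude on the designated occipito-temporal channels and attenuated
#' (x 0.2) elsewhere. Group-by-condition effect specs shift the planted
#' latency/amplitude parameters by `d` between-subject SDs, split over the
#' contrast's two parent conditions exactly as in [generate_feature_table()].
#' All planted parameters are recorded in `$truth$waveform_params`.
#'
#' @param config a [generator_config()].
#' @return A `synthetic_cohort` whose `epochs` element is a list (by subject)
#'   of lists (by condition) of [epoch_set()] objects.
#' @export
generate_waveforms <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cpar <- config$component_params
  # components must be separated by at least one combined width
  o <- order(cpar$latency)
  sep <- diff(cpar$latency[o])
  wsum <- cpar$width[o][-nrow(cpar)] + cpar$width[o][-1]
  if (any(sep < wsum))
    stop("component windows overlap beyond tolerance: increase separation or reduce widths")
  set.seed(derive_seed(config$seed, "waveforms"))
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n <- length(groups)
  conds <- c("FD", "FA", "F", "N", "SD", "SA")
  dt <- 1000 / config$sample_rate
  time <- seq(config$epoch_window[1], config$epoch_window[2], by = dt)
  nchan <- config$n_channels
  ot <- seq_len(config$n_ot_channels)
  gain <- rep(0.2, nchan); gain[ot] <- 1

  # per-subject base parameters
  base <- list()
  for (k in seq_len(nrow(cpar))) {
    base[[cpar$component[k]]] <- list(
      lat = cpar$latency[k] + rnorm(n, 0, cpar$lat_sd[k]),
      amp = cpar$amplitude[k] + rnorm(n, 0, cpar$amp_sd[k]))
  }

  # group x condition parameter shifts from the effect specs
  shift <- array(0, dim = c(n, nrow(cpar), 2, length(conds)),
                 dimnames = list(NULL, cpar$component, c("amp", "lat"), conds))
  cp <- contrast_parents()
  for (e in config$effects) {
    f <- parse_feature_name(e$feature_name)
    rows <- groups == e$group
    k <- match(f$component, cpar$component)
    unit <- if (f$measure == "lat") cpar$lat_sd[k] else cpar$amp_sd[k]
    if (f$is_contrast) {
      par <- cp[[f$suffix]]
      half <- e$d * sqrt(2) / 2 * unit
      shift[rows, f$component, f$measure, par[1]] <-
        shift[rows, f$component, f$measure, par[1]] + half
      shift[rows, f$component, f$measure, par[2]] <-
        shift[rows, f$component, f$measure, par[2]] - half
    } else {
      shift[rows, f$component, f$measure, f$suffix] <-
        shift[rows, f$component, f$measure, f$suffix] + e$d * unit
    }
  }

  epochs <- vector("list", n)
  params <- list()
  subj_ids <- sprintf("S%03d", seq_len(n))
  for (i in seq_len(n)) {
    by_cond <- list()
    for (cond in conds) {
      clean <- matrix(0, nchan, length(time))
      for (k in seq_len(nrow(cpar))) {
        comp <- cpar$component[k]
        lat <- base[[comp]]$lat[i] + shift[i, comp, "lat", cond]
        amp <- base[[comp]]$amp[i] + shift[i, comp, "amp", cond]
        bump <- component_bump(time, lat, amp, cpar$width[k])
        clean <- clean + outer(gain, bump)
        params[[length(params) + 1]] <- data.frame(
          subject = subj_ids[i], condition = cond, component = comp,
          latency = lat, amplitude = amp, stringsAsFactors = FALSE)
      }
      dat <- array(0, dim = c(config$n_epochs, nchan, length(time)))
      for (ep in seq_len(config$n_epochs)) {
        noise <- if (config$noise_sd > 0)
          matrix(rnorm(nchan * length(time), 0, config$noise_sd), nchan) else 0
        dat[ep, , ] <- clean + noise
      }
      by_cond[[cond]] <- epoch_set(dat, time, ot, subj_ids[i], cond)
    }
    epochs[[i]] <- by_cond
  }
  names(epochs) <- subj_ids
  meta <- data.frame(subject = subj_ids, group = groups,
                     asd = as.integer(groups == "EL-ASD"),
                     gender = rbinom(n, 1, 0.5), age = rnorm(n),
                     stringsAsFactors = FALSE)
  structure(list(features = NULL, epochs = epochs,
                 truth = list(waveform_params = do.call(rbind, params),
                              meta = meta, config = config)),
            class = "synthetic_cohort")
}
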