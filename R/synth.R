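#' Planted group effects for the synthetic cohort generator
#'
#' An effect spec plants a standardized mean shift (Cohen's d) on one feature
#' for one outcome group, relative to the grand baseline. Effects may target
#' an averaged feature or a differential (contrast) feature; for a contrast
#' feature the shift is split symmetrically over the two parent conditions
#' (scaled by `sqrt(2)`, the contrast's standard deviation under unit-variance
#' independent parents) so the contrast itself carries the requested d.
#'
#' @param feature_name a name from [build_feature_inventory()].
#' @param group one of `"TL"`, `"EL-noASD"`, `"EL-ASD"`.
#' @param d finite standardized mean shift.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(feature_name, group, d) {
  inv <- build_feature_inventory()
  if (!feature_name %in% inv)
    stop("unknown feature in effect spec: ", feature_name)
  group <- match.arg(group, c("TL", "EL-noASD", "EL-ASD"))
  stopifnot(is.finite(d))
  structure(list(feature_name = feature_name, group = group, d = d),
            class = "effect_spec")
}

#' Default planted effects
#'
#' The generator's default group-by-condition effect structure mirrors the
#' effects reported for this task at 8 months: the typical-likelihood (TL)
#' and EL-no-ASD groups show longer P1 latency to gaze shifts toward versus
#' away (d = 0.74 and 0.43) and longer N290 latency to faces versus noise
#' (d = 0.61 and 0.52) while the EL-ASD group shows no face-noise latency
#' differentiation and reversed dynamic-gaze effects; P400 latency toward
#' versus away is positive in EL-ASD with the opposite effect in TL
#' (d magnitude 0.55) and EL-no-ASD (0.47); P400 amplitude toward versus
#' away is enhanced in EL-ASD (d = 0.46) and EL-no-ASD (0.41) and reversed
#' in TL. Magnitudes that are not reported (EL-ASD dynamic-gaze latency,
#' the reversed TL amplitude effect) default to the 0.4-0.5 range typical
#' of the reported effects.
#'
#' @return List of [effect_spec()] objects.
#' @export
default_effects <- function() {
  list(
    # P1 latency, toward - away
    effect_spec("P1_lat_TvA", "TL", 0.74),
    effect_spec("P1_lat_TvA", "EL-noASD", 0.43),
    effect_spec("P1_lat_TvA", "EL-ASD", -0.40),
    # N290 latency, face - noise (EL-ASD: no differentiation)
    effect_spec("N290_lat_FvN", "TL", 0.61),
    effect_spec("N290_lat_FvN", "EL-noASD", 0.52),
    # P400 latency, toward - away
    effect_spec("P400_lat_TvA", "EL-ASD", 0.50),
    effect_spec("P400_lat_TvA", "TL", -0.55),
    effect_spec("P400_lat_TvA", "EL-noASD", -0.47),
    # P400 amplitude, toward - away
    effect_spec("P400_amp_TvA", "EL-ASD", 0.46),
    effect_spec("P400_amp_TvA", "EL-noASD", 0.41),
    effect_spec("P400_amp_TvA", "TL", -0.40)
  )
}

#' Default linear outcome model
#'
#' Coefficients mapping standardized features to the continuous social-skills
#' outcome. The dominant negative weight sits on the N290 latency face-noise
#' contrast (faster N290 to noise than faces going with better later social
#' functioning), gender carries a negative weight (males coded 1, so females
#' score higher), and age a smaller negative weight.
#'
#' @return Named numeric vector over inventory features.
#' @export
default_outcome_beta <- function() {
  c(N290_lat_FvN = -0.40, P1_lat_TvA = -0.25, P400_amp_TvA = 0.20,
    P1_amp_N = 0.15, gender = -0.30, age = -0.20)
}

#' Generator configuration for synthetic cohorts
#'
#' @param n_per_group named counts per outcome group; defaults to the cohort
#'   scale of the study design (68 TL, 115 EL-no-ASD, 33 EL-ASD).
#' @param effects list of [effect_spec()]; defaults to [default_effects()].
#' @param outcome_beta named coefficient vector; see [default_outcome_beta()].
#' @param outcome_noise_sd residual SD of the linear outcome model on the
#'   standardized scale (default 1).
#' @param outcome_center,outcome_scale location/scale mapping the standardized
#'   outcome onto an adaptive-behavior-like score (default 100 and 15).
#' @param within_subject_rho correlation between conditions of the same
#'   component measure induced by a subject-level random effect (default
#'   0.5), mirroring the shared per-subject component parameters of the
#'   waveform generator; marginal feature variance stays 1.
#' @param miss_rate expected fraction of missing ERP cells in `[0, 1)`.
#' @param miss_mechanism `"MCAR"` or `"MAR-age"`.
#' @param n_channels,n_ot_channels waveform mode: channel count and number of
#'   designated occipito-temporal channels.
#' @param sample_rate sampling rate in Hz (waveform mode).
#' @param epoch_window c(start, end) in ms around stimulus onset.
#' @param n_epochs epochs simulated per subject and condition.
#' @param noise_sd waveform noise SD in microvolts.
#' @param component_params data.frame with one row per component: mean latency
#'   (ms), mean amplitude (microvolts, signed by polarity), width (ms), and
#'   between-subject SDs of latency and amplitude.
#' @param cluster_spec optional list from [make_cluster_spec()].
#' @param seed integer RNG seed.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n_per_group = c("TL" = 68, "EL-noASD" = 115, "EL-ASD" = 33),
                             effects = default_effects(),
                             outcome_beta = default_outcome_beta(),
                             outcome_noise_sd = 1,
                             outcome_center = 100, outcome_scale = 15,
                             within_subject_rho = 0.5,
                             miss_rate = 0.05, miss_mechanism = c("MCAR", "MAR-age"),
                             n_channels = 20, n_ot_channels = 6,
                             sample_rate = 250,
                             epoch_window = c(-200, 800),
                             n_epochs = 50, noise_sd = 5,
                             component_params = default_component_params(),
                             cluster_spec = NULL,
                             seed = 1L) {
  miss_mechanism <- match.arg(miss_mechanism)
  stopifnot(all(n_per_group >= 0),
            within_subject_rho >= 0, within_subject_rho < 1,
            miss_rate >= 0, miss_rate < 1,
            epoch_window[1] < 0, epoch_window[2] > 0,
            outcome_noise_sd > 0, outcome_scale > 0,
            all(component_params$width > 0),
            all(component_params$lat_sd > 0), all(component_params$amp_sd > 0))
  inv <- build_feature_inventory()
  for (e in effects) {
    if (!inherits(e, "effect_spec")) stop("effects must be effect_spec objects")
  }
  if (length(outcome_beta) && !all(names(outcome_beta) %in% inv))
    stop("outcome_beta names must be inventory features")
  if (!is.null(cluster_spec)) {
    stopifnot(abs(sum(cluster_spec$weights) - 1) < 1e-8,
              nrow(cluster_spec$centroids) == length(cluster_spec$weights))
  }
  structure(list(n_per_group = n_per_group, effects = effects,
                 outcome_beta = outcome_beta, outcome_noise_sd = outcome_noise_sd,
                 outcome_center = outcome_center, outcome_scale = outcome_scale,
                 within_subject_rho = within_subject_rho,
                 miss_rate = miss_rate, miss_mechanism = miss_mechanism,
                 n_channels = n_channels, n_ot_channels = n_ot_channels,
                 sample_rate = sample_rate, epoch_window = epoch_window,
                 n_epochs = n_epochs, noise_sd = noise_sd,
                 component_params = component_params,
                 cluster_spec = cluster_spec, seed = as.integer(seed)),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_component_params <- function() {
  data.frame(component = c("P1", "N290", "P400"),
             latency = c(120, 290, 450),
             amplitude = c(8, -8, 6),
             width = c(25, 40, 70),
             lat_sd = c(12, 15, 20),
             amp_sd = c(2, 2, 1.5),
             stringsAsFactors = FALSE)
}

#' Generate a feature-level synthetic cohort
#'
#' Draws the 36 averaged ERP features per subject as standardized Gaussians,
#' applies the planted group effects, computes the 18 differential features as
#' exact condition differences, draws gender (0 female / 1 male) and
#' standardized age, builds the continuous outcome from the linear model, and
#' records everything planted in `$truth`.
#'
#' @param config a [generator_config()].
#' @return A `synthetic_cohort` list with elements `features` (data frame:
#'   `subject`, `group`, `asd`, `outcome`, then the 56 inventory columns) and
#'   `truth`.
#' @export
generate_feature_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(derive_seed(config$seed, "features"))
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n <- length(groups)
  rho <- config$within_subject_rho
  # subject-level random effect shared by the 6 conditions of each
  # component measure, plus condition-specific noise; unit marginal variance
  avg <- matrix(NA_real_, n, 36,
                dimnames = list(NULL, averaged_feature_names()))
  comps <- c("P1", "N290", "P400")
  for (comp in comps) for (meas in c("amp", "lat")) {
    u <- rnorm(n)
    for (cond in c("FD", "FA", "F", "N", "SD", "SA")) {
      avg[, paste(comp, meas, cond, sep = "_")] <-
        sqrt(rho) * u + sqrt(1 - rho) * rnorm(n)
    }
  }
  # planted shifts; a contrast feature has SD sqrt(2 (1 - rho)), so the
  # split parent shifts are scaled to land the requested standardized d
  cp <- contrast_parents()
  for (e in config$effects) {
    rows <- groups == e$group
    f <- parse_feature_name(e$feature_name)
    if (is.null(f)) { # gender/age cannot carry an effect spec here
      stop("effect on non-ERP feature not supported: ", e$feature_name)
    }
    if (f$is_contrast) {
      par <- cp[[f$suffix]]
      a <- paste(f$component, f$measure, par[1], sep = "_")
      b <- paste(f$component, f$measure, par[2], sep = "_")
      shift <- e$d * sqrt(2 * (1 - rho)) / 2
      avg[rows, a] <- avg[rows, a] + shift
      avg[rows, b] <- avg[rows, b] - shift
    } else {
      avg[rows, e$feature_name] <- avg[rows, e$feature_name] + e$d
    }
  }
  tab <- as.data.frame(avg)
  tab <- apply_contrasts(tab)
  tab$gender <- rbinom(n, 1, 0.5)
  tab$age <- rnorm(n)
  tab <- tab[, build_feature_inventory()]

  # outcome: linear model on standardized features + Gaussian noise
  eta <- rep(0, n)
  if (length(config$outcome_beta)) {
    Xb <- as.matrix(tab[, names(config$outcome_beta), drop = FALSE])
    Xb <- standardize_cols(Xb)
    eta <- drop(Xb %*% config$outcome_beta)
  }
  z <- eta + rnorm(n, 0, config$outcome_noise_sd)
  outcome <- config$outcome_center + config$outcome_scale * z

  features <- data.frame(subject = sprintf("S%03d", seq_len(n)),
                         group = groups,
                         asd = as.integer(groups == "EL-ASD"),
                         outcome = outcome,
                         stringsAsFactors = FALSE)
  features <- cbind(features, tab)
  structure(list(features = features,
                 epochs = NULL,
                 truth = list(effects = config$effects,
                              outcome_beta = config$outcome_beta,
                              outcome_noise_sd = config$outcome_noise_sd,
                              linear_predictor = eta,
                              missingness = "none",
                              config = config)),
            class = "synthetic_cohort")
}

#' Mask feature cells as missing
#'
#' @param cohort a `synthetic_cohort`.
#' @param miss_rate expected missing fraction in `[0, 1)`.
#' @param mechanism `"MCAR"` (each ERP cell independently) or `"MAR-age"`
#'   (per-subject masking probability a logistic function of age only, with
#'   the intercept solved so the expected overall rate equals `miss_rate`).
#' @param slope logistic slope on standardized age for `"MAR-age"`.
#' @param seed optional seed; defaults to one derived from the generator seed.
#' @return The cohort with masked entries set `NA` and the mechanism recorded
#'   in `$truth`.
#' @export
inject_missingness <- function(cohort, miss_rate, mechanism = c("MCAR", "MAR-age"),
                               slope = 1.5, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (miss_rate >= 1 || miss_rate < 0) stop("miss_rate must be in [0, 1)")
  if (miss_rate == 0) return(cohort)
  if (is.null(seed)) seed <- derive_seed(cohort$truth$config$seed, "missingness")
  set.seed(seed)
  # masking happens at the level of the 36 averaged features (a lost peak);
  # the differential features are recomputed so a missing parent propagates
  cols <- averaged_feature_names()
  n <- nrow(cohort$features)
  complete_tab <- cohort$features
  if (mechanism == "MCAR") {
    mask <- matrix(runif(n * length(cols)) < miss_rate, n, length(cols))
  } else {
    age <- cohort$features$age
    f <- function(a) mean(plogis(a + slope * age)) - miss_rate
    a0 <- uniroot(f, c(-30, 30))$root
    p_subj <- plogis(a0 + slope * age)
    mask <- matrix(runif(n * length(cols)), n, length(cols)) <
      matrix(p_subj, n, length(cols))
  }
  for (j in seq_along(cols)) {
    cohort$features[[cols[j]]][mask[, j]] <- NA_real_
  }
  cohort$features <- apply_contrasts(cohort$features)
  cohort$truth$missingness <- mechanism
  cohort$truth$miss_rate <- miss_rate
  cohort$truth$complete_features <- complete_tab
  cohort
}

#' Build a separated cluster specification
#'
#' Centroids are the vertices of a regular simplex, scaled so every pair of
#' centroids sits `separation` within-cluster SD units apart per feature
#' dimension (root-mean-square over dimensions; the pairwise Euclidean
#' distance is `separation * sqrt(p)`), and rotated by a seeded random
#' orthonormal basis so the between-cluster differences are spread diffusely
#' over all features. This emulates subgroup structure in which clusters
#' differ on broad profiles of ERP responses rather than on one or two
#' features.
#'
#' @param K number of clusters (>= 1).
#' @param separation per-dimension RMS centroid separation, in noise-SD units.
#' @param weights mixing weights (default equal).
#' @param p feature-space dimension (default 36 averaged features).
#' @param seed seed for the rotation.
#' @return List with `centroids` (K x p) and `weights`.
#' @export
make_cluster_spec <- function(K, separation = 3, weights = rep(1 / K, K),
                              p = 36, seed = 1) {
  stopifnot(K >= 1, separation >= 0, length(weights) == K)
  weights <- weights / sum(weights)
  C <- matrix(0, K, p)
  if (K > 1) {
    E <- diag(K) - matrix(1 / K, K, K)  # centered simplex, pairwise dist sqrt(2)
    set.seed(seed)
    Q <- qr.Q(qr(matrix(rnorm(p * p), p)))[, seq_len(K), drop = FALSE]
    C <- (E * (separation * sqrt(p) / sqrt(2))) %*% t(Q)
  }
  colnames(C) <- averaged_feature_names()[seq_len(p)]
  list(centroids = C, weights = weights)
}

#' Generate a cohort with planted latent clusters
#'
#' Subjects are assigned to mixture components by the cluster weights; the
#' averaged-feature block is drawn as unit-variance Gaussian noise around the
#' assigned centroid; differential features, gender, age and the outcome are
#' built as in [generate_feature_table()]. Assignments are recorded in truth.
#'
#' @param config a [generator_config()] whose `cluster_spec` is set.
#' @return A `synthetic_cohort` with `$truth$cluster` the planted assignment.
#' @export
plant_clusters <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cs <- config$cluster_spec
  if (is.null(cs)) stop("config$cluster_spec is required")
  n <- sum(config$n_per_group)
  K <- length(cs$weights)
  if (K > n) stop("more clusters than subjects")
  cohort <- generate_feature_table(config)
  set.seed(derive_seed(config$seed, "clusters"))
  assign <- sample.int(K, n, replace = TRUE, prob = cs$weights)
  p <- ncol(cs$centroids)
  cols <- colnames(cs$centroids)
  shift <- cs$centroids[assign, , drop = FALSE]
  for (j in seq_len(p)) {
    cohort$features[[cols[j]]] <- cohort$features[[cols[j]]] + shift[, j]
  }
  cohort$features <- apply_contrasts(cohort$features)
  cohort$truth$cluster <- assign
  cohort$truth$cluster_spec <- cs
  cohort
}
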