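#' Split-plot ANOVA for a two-level within-subject factor
#'
#' Classical repeated-measures (split-plot) ANOVA with condition as the
#' within-subjects factor (exactly two levels, e.g. the two sides of one
#' stimulus contrast) and outcome group as the between-subjects factor, with
#' an optional extra between-subjects factor (e.g. cohort). Computed from the
#' exact two-level decomposition: the between stratum is a one-way ANOVA on
#' subject means, the within stratum an ANOVA on the condition difference
#' scores, which for two within levels reproduces the classical split-plot
#' sums of squares. Sequential (Type I) sums of squares are used when the
#' extra between factor is present. With two within levels sphericity is not
#' at issue, so no Greenhouse-Geisser correction is applied.
#'
#' Subjects missing either condition value are dropped (with a message).
#'
#' @param values n x 2 numeric matrix, one column per condition level.
#' @param group between-subjects factor (3 outcome groups in the main design).
#' @param extra_between optional second between-subjects factor.
#' @return data.frame: effect, F, df1, df2, p, pes (partial eta squared).
#' @export
splitplot_anova <- function(values, group, extra_between = NULL) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == 2)
  group <- factor(group)
  keep <- complete.cases(values)
  if (!is.null(extra_between)) keep <- keep & !is.na(extra_between)
  if (any(!keep)) {
    message(sum(!keep), " subject(s) dropped for missing condition values")
    values <- values[keep, , drop = FALSE]
    group <- droplevels(group[keep])
    if (!is.null(extra_between)) extra_between <- factor(extra_between[keep])
  }
  if (any(table(group) < 2)) stop("need >= 2 subjects per group")
  n <- nrow(values)
  m <- rowMeans(values)                 # between-stratum projection
  w <- (values[, 1] - values[, 2]) / sqrt(2) # within-stratum projection

  between <- if (is.null(extra_between)) ~group else ~group * extra_between
  dat <- data.frame(m = m, w = w, group = group)
  if (!is.null(extra_between)) dat$extra_between <- extra_between

  res <- list()
  # between stratum (scaled by 2 = number of within levels; F unaffected)
  ab <- anova(lm(update(between, m ~ .), data = dat))
  err_b <- ab[nrow(ab), ]
  for (i in seq_len(nrow(ab) - 1)) {
    res[[length(res) + 1]] <- anova_row(rownames(ab)[i], ab$`Sum Sq`[i],
                                        ab$Df[i], err_b$`Sum Sq`, err_b$Df)
  }
  # within stratum: condition main effect, then condition x between terms
  aw <- anova(lm(update(between, w ~ .), data = dat))
  err_w <- aw[nrow(aw), ]
  ss_cond <- n * mean(w)^2
  res[[length(res) + 1]] <- anova_row("condition", ss_cond, 1L,
                                      err_w$`Sum Sq`, err_w$Df)
  for (i in seq_len(nrow(aw) - 1)) {
    res[[length(res) + 1]] <- anova_row(paste0("condition:", rownames(aw)[i]),
                                        aw$`Sum Sq`[i], aw$Df[i],
                                        err_w$`Sum Sq`, err_w$Df)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

anova_row <- function(effect, ss, df1, ss_err, df2) {
  # degenerate stratum (all values equal up to rounding): report F = 0, p = 1
  if (ss_err <= 1e-12 && ss <= 1e-12) {
    return(data.frame(effect = effect, F = 0, df1 = df1, df2 = df2, p = 1,
                      pes = 0))
  }
  F <- (ss / df1) / (ss_err / df2)
  data.frame(effect = effect, F = F, df1 = df1, df2 = df2,
             p = pf(F, df1, df2, lower.tail = FALSE),
             pes = ss / (ss + ss_err))
}

#' Covariate-adjusted split-plot tests
#'
#' Reruns the split-plot tests after partialling numeric covariates (age at
#' EEG, nonverbal ability, ...) out of the stratum projections by linear
#' regression residualization; error degrees of freedom are reduced by the
#' number of covariates retained. Constant or collinear covariates are
#' dropped with a warning.
#'
#' @param values,group as in [splitplot_anova()].
#' @param covariates data.frame of numeric covariates.
#' @return data.frame as in [splitplot_anova()].
#' @export
ancova_adjust <- function(values, group, covariates) {
  values <- as.matrix(values)
  covariates <- as.data.frame(covariates)
  keep <- complete.cases(values) & complete.cases(covariates)
  if (any(!keep)) {
    message(sum(!keep), " subject(s) dropped for missing values")
    values <- values[keep, , drop = FALSE]
    group <- droplevels(factor(group)[keep])
    covariates <- covariates[keep, , drop = FALSE]
  }
  # drop degenerate covariates
  ok <- vapply(covariates, function(x) is.numeric(x) && sd(x) > 0, logical(1))
  if (any(!ok)) {
    warning("dropping constant/non-numeric covariates: ",
            paste(names(covariates)[!ok], collapse = ", "))
    covariates <- covariates[, ok, drop = FALSE]
  }
  if (ncol(covariates) > 1) {
    Z <- scale(as.matrix(covariates), scale = FALSE)
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) {
      drop_idx <- qrz$pivot[-seq_len(qrz$rank)]
      warning("dropping collinear covariates: ",
              paste(names(covariates)[drop_idx], collapse = ", "))
      covariates <- covariates[, -drop_idx, drop = FALSE]
    }
  }
  q <- ncol(covariates)
  resid_keep_mean <- function(v) {
    if (q == 0) return(v)
    residuals(lm(v ~ ., data = covariates)) + mean(v)
  }
  m <- resid_keep_mean(rowMeans(values))
  w <- resid_keep_mean((values[, 1] - values[, 2]) / sqrt(2))
  group <- factor(group)
  g <- nlevels(group)
  n <- length(m)
  res <- list()
  ssb <- anova(lm(m ~ group))
  res[[1]] <- anova_row("group", ssb$`Sum Sq`[1], ssb$Df[1],
                        ssb$`Sum Sq`[2], ssb$Df[2] - q)
  ssw <- anova(lm(w ~ group))
  res[[2]] <- anova_row("condition", n * mean(w)^2, 1L,
                        ssw$`Sum Sq`[2], ssw$Df[2] - q)
  res[[3]] <- anova_row("condition:group", ssw$`Sum Sq`[1], ssw$Df[1],
                        ssw$`Sum Sq`[2], ssw$Df[2] - q)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pairwise post-hoc comparison with effect size
#'
#' Welch (unequal-variance) t-test plus pooled-SD Cohen's d for one pair of
#' groups, with the Sidak family-wise adjustment `1 - (1 - p)^m`.
#'
#' @param x,y values in the two groups.
#' @param m Sidak family size (default 1 = no adjustment).
#' @return data.frame: t, df, p, p_sidak, d.
#' @export
posthoc_d <- function(x, y, m = 1) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per group")
  d <- cohens_d(x, y)
  if (sd(x) == 0 && sd(y) == 0) {
    return(data.frame(t = NA, df = NA, p = if (mean(x) == mean(y)) 1 else NA,
                      p_sidak = NA, d = NA))
  }
  tt <- t.test(x, y)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, p_sidak = sidak_adjust(tt$p.value, m), d = d)
}

#' All pairwise post-hoc comparisons across groups
#'
#' @param values numeric vector (typically a contrast difference score).
#' @param group grouping factor.
#' @return data.frame with one row per pair, Sidak-adjusted over the family
#'   of all pairs.
#' @export
posthoc_table <- function(values, group) {
  group <- factor(group)
  lv <- levels(group)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    r <- posthoc_d(values[group == pr[1]], values[group == pr[2]], m = m)
    cbind(data.frame(group1 = pr[1], group2 = pr[2]), r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
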