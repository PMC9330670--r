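#' Pipeline configuration
#'
#' One configuration drives the full analysis: cohort generation (or a
#' user-supplied feature table), eligibility filtering and EM imputation,
#' then the four analysis arms (group-level ANOVA, GA/SVM classification,
#' elastic-net prediction, BHC stratification). Two resampling profiles are
#' shipped: `"study"` uses the study-scale replication counts (10000
#' permutations, 10000 bootstrap resamples, 100 evolutions, 1000 RMSE
#' bootstrap) and `"test"` a desk-scale profile (200/200/8/200 with a
#' smaller GA) for fast end-to-end runs.
#'
#' @param mode `"synthetic"` or `"user-data"`.
#' @param generator a [generator_config()] (synthetic mode).
#' @param feature_table a data.frame in the standard layout (user-data mode).
#' @param stages character subset of
#'   `c("groupstats", "select", "enet", "bhc")`.
#' @param seed root seed; every stage derives its own stream from it.
#' @param profile `"test"` or `"study"`.
#' @param out_dir optional output directory; when set, every stage writes its
#'   tables there.
#' @param overrides named list of per-stage parameter overrides (see the
#'   profile defaults in the source).
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "user-data"),
                            generator = generator_config(),
                            feature_table = NULL,
                            stages = c("groupstats", "select", "enet", "bhc"),
                            seed = 1, profile = c("test", "study"),
                            out_dir = NULL, overrides = list()) {
  mode <- match.arg(mode)
  profile <- match.arg(profile)
  stages <- match.arg(stages, several.ok = TRUE)
  if (mode == "user-data" && is.null(feature_table))
    stop("user-data mode requires a feature table")
  pars <- if (profile == "study") {
    list(n_perm = 10000, n_boot = 10000, ga_runs = 100, ga_pop = 50,
         ga_gens = 100, enet_boot = 1000, enet_reps = 10, enet_nlambda = 50,
         enet_alphas = c(0.1, 0.3, 0.5, 0.7, 0.9, 1), bhc_loo = TRUE)
  } else {
    list(n_perm = 200, n_boot = 200, ga_runs = 8, ga_pop = 14, ga_gens = 8,
         enet_boot = 200, enet_reps = 2, enet_nlambda = 20,
         enet_alphas = c(0.5, 1), bhc_loo = FALSE)
  }
  pars <- modifyList(pars, overrides)
  structure(list(mode = mode, generator = generator,
                 feature_table = feature_table, stages = stages,
                 seed = seed, profile = profile, out_dir = out_dir,
                 pars = pars),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (cohort, eligibility +
#' imputation, then the four arms), logging every stage's seed. A failure in
#' one analysis arm is caught and recorded without aborting the others. The
#' run is deterministic for a fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @return List of stage results plus `summary` (the cross-arm feature flag
#'   matrix from [build_summary()]) and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  pars <- config$pars
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- paste0("[", stage, "] ", paste0(...))
  }

  # --- cohort ---------------------------------------------------------------
  if (config$mode == "synthetic") {
    gen <- config$generator
    gen$seed <- derive_seed(config$seed, "synth")
    cohort <- generate_feature_table(gen)
    if (gen$miss_rate > 0)
      cohort <- inject_missingness(cohort, gen$miss_rate,
                                   if (gen$miss_mechanism == "MAR-age") "MAR-age" else "MCAR")
    tab <- cohort$features
    note("synth", "generated ", nrow(tab), " subjects, seed ", gen$seed)
  } else {
    cohort <- NULL
    tab <- config$feature_table
    note("input", "user table with ", nrow(tab), " subjects")
  }

  # --- eligibility + imputation --------------------------------------------
  el <- tab[tab$group != "TL", , drop = FALSE]
  el <- eligibility_filter(el)
  note("impute", "eligible EL subjects: ", nrow(el))
  imp <- em_impute(el)
  el_imp <- imp$table
  note("impute", "EM iterations: ", imp$model$iterations)

  results <- list(cohort = cohort, table = tab, eligible = el,
                  imputed = el_imp, imputation = imp$model)
  flags <- list()
  arm <- function(name, expr) {
    if (!(name %in% config$stages)) return(NULL)
    tryCatch(expr, error = function(e) {
      note(name, "FAILED: ", conditionMessage(e))
      NULL
    })
  }

  inv <- build_feature_inventory()

  # --- group-level ANOVA ----------------------------------------------------
  results$groupstats <- arm("groupstats", {
    rows <- list()
    sig <- character(0)
    cp <- contrast_parents()
    for (nm in differential_feature_names()) {
      f <- parse_feature_name(nm)
      par <- cp[[f$suffix]]
      a <- paste(f$component, f$measure, par[1], sep = "_")
      b <- paste(f$component, f$measure, par[2], sep = "_")
      vals <- as.matrix(tab[, c(a, b)])
      keep <- complete.cases(vals)
      res <- suppressMessages(splitplot_anova(vals[keep, ], tab$group[keep]))
      int <- res[res$effect == "condition:group", ]
      rows[[nm]] <- cbind(feature = nm, int)
      if (is.finite(int$p) && int$p < 0.05) sig <- c(sig, nm)
    }
    anova_tab <- do.call(rbind, rows)
    rownames(anova_tab) <- NULL
    posthocs <- lapply(setNames(sig, sig), function(nm)
      posthoc_table(tab[[nm]], tab$group))
    note("groupstats", length(sig), " significant interactions")
    list(anova = anova_tab, posthoc = posthocs, significant = sig)
  })
  if (!is.null(results$groupstats))
    flags[["group-significant"]] <- results$groupstats$significant

  # --- GA / SVM classification ---------------------------------------------
  results$select <- arm("select", {
    seed <- derive_seed(config$seed, "select")
    split <- stratified_split(el_imp$asd, 0.70, seed = seed)
    main <- el[split$main, , drop = FALSE]
    hold <- el[split$holdout, , drop = FALSE]
    # split-first imputation: fit on main, apply to holdout
    imp_main <- em_impute(main)
    main <- imp_main$table
    hold <- em_apply(hold, imp_main$model)
    Xm <- as.matrix(main[, inv]); ym <- main$asd
    Xh <- as.matrix(hold[, inv]); yh <- hold$asd
    archive <- run_evolutions(Xm, ym, n_runs = pars$ga_runs, seed = seed,
                              pop_size = pars$ga_pop,
                              generations = pars$ga_gens)
    opt <- optimal_mask(archive)
    inc <- aggregate_incidence(archive)
    note("select", "qualifying runs: ", inc$n_qualifying)
    masks <- list(optimal = opt)
    if (!inc$empty && any(inc$mask)) masks$incidence <- inc$mask
    masks <- c(masks, topdown_sets(inv))
    reports <- list()
    shuffle <- list()
    for (nm in names(masks)) {
      if (!any(masks[[nm]])) next
      reports[[nm]] <- evaluate_holdout(Xm, ym, Xh, yh, masks[[nm]],
                                        n_boot = pars$n_boot,
                                        seed = derive_seed(seed, nm))
    }
    X_all <- rbind(Xm, Xh)
    is_main <- c(rep(TRUE, nrow(Xm)), rep(FALSE, nrow(Xh)))
    for (nm in intersect(c("optimal", "incidence"), names(reports))) {
      mk <- masks[[nm]]
      stat <- function(X, y) {
        holdout_auc(X[is_main, , drop = FALSE], y[is_main],
                    X[!is_main, , drop = FALSE], y[!is_main], mk)
      }
      shuffle[[nm]] <- shuffle_test(stat, X_all, c(ym, yh),
                                    n_perm = pars$n_perm,
                                    seed = derive_seed(seed, paste0("shuf", nm)))
      note("select", nm, " shuffle p = ",
           format(shuffle[[nm]]$p, digits = 3))
    }
    list(split = split, archive = archive, optimal = opt, incidence = inc,
         reports = reports, masks = masks, shuffle = shuffle)
  })
  if (!is.null(results$select)) {
    flags[["GA-selected-optimal"]] <- names(which(results$select$optimal))
    if (!results$select$incidence$empty)
      flags[["GA-selected-incidence"]] <- names(which(results$select$incidence$mask))
  }

  # --- elastic net ----------------------------------------------------------
  results$enet <- arm("enet", {
    X <- as.matrix(el_imp[, inv])
    y <- el_imp$outcome
    rep <- nested_cv_enet(X, y, alphas = pars$enet_alphas,
                          nlambda = pars$enet_nlambda, inner_k = 10,
                          inner_reps = pars$enet_reps,
                          n_boot = pars$enet_boot,
                          seed = derive_seed(config$seed, "enet"))
    note("enet", sprintf("RMSE %.2f (relative %.1f%%)", rep$rmse,
                         100 * rep$relative_error))
    rep
  })
  if (!is.null(results$enet))
    flags[["enet-selected"]] <- results$enet$always_selected$feature

  # --- BHC stratification ---------------------------------------------------
  results$bhc <- arm("bhc", {
    Xa <- standardize_cols(as.matrix(el_imp[, averaged_feature_names()]))
    tree <- build_tree(Xa, bhc_hyperparams())
    part <- cut_tree(tree)
    note("bhc", "clusters found: ", max(part))
    stability <- if (pars$bhc_loo) loo_stability(Xa, bhc_hyperparams()) else NULL
    char <- if (max(part) >= 2) {
      characterize_clusters(part,
                            el_imp[, averaged_feature_names()],
                            el_imp[, "outcome", drop = FALSE])
    } else NULL
    list(tree = tree, partition = part, stability = stability,
         characterization = char)
  })
  if (!is.null(results$bhc) && !is.null(results$bhc$characterization)) {
    fr <- results$bhc$characterization$features
    flags[["cluster-discriminating"]] <- fr$variable[fr$p_holm < 0.05]
  }

  results$flags <- flags
  results$summary <- build_summary(flags)
  results$log <- unlist(log)

  if (!is.null(config$out_dir)) write_pipeline_outputs(results, config)
  results
}

#' Holdout AUC of a mask-restricted linear SVM
#'
#' Trains on the main sample (standardization from the main sample only) and
#' returns the holdout AUC; the unit re-run inside shuffle tests.
#'
#' @param X_main,y_main,X_hold,y_hold the two samples.
#' @param mask feature mask.
#' @param C SVM cost.
#' @param pos_label positive-class value.
#' @return Holdout AUC (fraction).
#' @export
holdout_auc <- function(X_main, y_main, X_hold, y_hold, mask = NULL, C = 1,
                        pos_label = 1) {
  X_main <- as.matrix(X_main); X_hold <- as.matrix(X_hold)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    X_main <- X_main[, mask, drop = FALSE]
    X_hold <- X_hold[, mask, drop = FALSE]
  }
  Xtr <- standardize_cols(X_main)
  fit <- linear_svm(Xtr, y_main, C = C, pos_label = pos_label)
  Xte <- standardize_cols(X_hold, center = attr(Xtr, "center"),
                          scale = attr(Xtr, "scale"))
  auc(predict(fit, Xte), y_hold, pos_label)
}

#' Cross-arm summary of flagged features
#'
#' Cross-tabulates which features each analysis arm flagged (significant
#' group interaction, selected by the GA's optimal or highest-incidence set,
#' always selected by the elastic net, discriminating between clusters) and
#' marks features flagged in at least three arms as convergent.
#'
#' @param flags named list of character vectors of feature names per arm.
#' @return data.frame with one row per flagged feature, one logical column
#'   per arm, and a `convergent` column.
#' @export
build_summary <- function(flags) {
  flags <- flags[vapply(flags, length, integer(1)) > 0]
  if (!length(flags))
    return(data.frame(feature = character(0), convergent = logical(0)))
  feats <- sort(unique(unlist(flags)))
  out <- data.frame(feature = feats)
  for (nm in names(flags)) out[[nm]] <- feats %in% flags[[nm]]
  out$convergent <- rowSums(as.matrix(out[, -1, drop = FALSE])) >= 3
  out
}

write_pipeline_outputs <- function(results, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    write.table(x, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wt(results$table, "cohort.tsv")
  wt(results$imputed, "imputed.tsv")
  if (!is.null(results$groupstats)) wt(results$groupstats$anova, "groupstats.tsv")
  if (!is.null(results$select)) {
    metr <- do.call(rbind, lapply(names(results$select$reports), function(nm)
      cbind(set = nm, results$select$reports[[nm]]$metrics)))
    wt(metr, "classification.tsv")
    wt(cbind(run = seq_len(nrow(results$select$archive$masks)),
             fitness = results$select$archive$fitness,
             results$select$archive$masks * 1L), "ga_archive.tsv")
  }
  if (!is.null(results$enet)) {
    wt(data.frame(rmse = results$enet$rmse,
                  rmse_lo = results$enet$rmse_ci[1],
                  rmse_hi = results$enet$rmse_ci[2],
                  relative_error = results$enet$relative_error,
                  pearson_r = results$enet$pearson_r),
       "enet_metrics.tsv")
    wt(results$enet$always_selected, "enet_selected.tsv")
  }
  if (!is.null(results$bhc)) {
    wt(data.frame(subject = results$imputed$subject,
                  cluster = results$bhc$partition), "bhc_partition.tsv")
    writeLines(format_tree(results$bhc$tree),
               file.path(config$out_dir, "bhc_tree.txt"))
  }
  wt(results$summary, "summary.tsv")
  writeLines(results$log, file.path(config$out_dir, "pipeline.log"))
  invisible(NULL)
}
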