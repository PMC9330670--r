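#' Genetic-algorithm feature search over the inventory
#'
#' Binary-chromosome genetic algorithm whose fitness is the 10-fold
#' cross-validated linear-SVM AUC of the masked feature set ([cv_auc()]).
#' Tournament selection, single-point crossover, independent per-bit
#' mutation, elitism of one. The fold assignment is fixed for the whole
#' evolution so fitness values are comparable across generations, and
#' fitness values are memoized per mask. An all-zero chromosome is repaired
#' by setting one random bit.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param seed evolution seed.
#' @param pop_size population size (default 50; must be >= 4).
#' @param generations number of generations (default 100; 0 returns the best
#'   of the random initial population).
#' @param p_crossover crossover probability (default 0.8).
#' @param p_mutation per-bit mutation probability (default `1/ncol(X)`).
#' @param tournament tournament size (default 3).
#' @param elitism number of elites carried over unchanged (default 1).
#' @param init_density expected fraction of bits set in the initial
#'   population (default 0.1). Sparse initialization is the usual choice for
#'   wrapper feature selection: candidate sets stay small, the classifier
#'   fits are cheap, and informative features are assembled by crossover
#'   rather than pruned out of dense random masks.
#' @param k,C cross-validation folds and SVM cost for the fitness.
#' @param pos_label positive-class value.
#' @return List: `mask` (logical), `fitness`, `history` (best fitness per
#'   generation), `evals` (distinct masks evaluated).
#' @export
ga_evolve <- function(X, y, seed = 1, pop_size = 50, generations = 100,
                      p_crossover = 0.8, p_mutation = NULL, tournament = 3,
                      elitism = 1, init_density = 0.1, k = 10, C = 1,
                      pos_label = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (pop_size < 4) stop("pop_size must be >= 4")
  if (is.null(p_mutation)) p_mutation <- 1 / p
  set.seed(seed)
  fold_seed <- sample.int(2^30, 1) # one fold layout per evolution
  memo <- new.env(parent = emptyenv())
  fitness_of <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- cv_auc(X, y, mask, k = k, seed = fold_seed, C = C,
                  pos_label = pos_label)
    memo[[key]] <- val
    val
  }
  repair <- function(mask) {
    if (!any(mask)) mask[sample.int(p, 1)] <- TRUE
    mask
  }
  pop <- lapply(seq_len(pop_size), function(i)
    repair(runif(p) < init_density))
  fit <- vapply(pop, fitness_of, numeric(1))
  history <- max(fit)
  if (generations > 0) {
    for (gen in seq_len(generations)) {
      ord <- order(fit, decreasing = TRUE)
      newpop <- pop[ord[seq_len(elitism)]]
      while (length(newpop) < pop_size) {
        pick <- function() {
          cand <- sample.int(pop_size, tournament)
          pop[[cand[which.max(fit[cand])]]]
        }
        a <- pick(); b <- pick()
        if (runif(1) < p_crossover && p >= 2) {
          cut <- sample.int(p - 1, 1)
          child <- c(a[seq_len(cut)], b[(cut + 1):p])
        } else child <- a
        flip <- runif(p) < p_mutation
        child <- xor(child, flip)
        newpop[[length(newpop) + 1]] <- repair(child)
      }
      pop <- newpop
      fit <- vapply(pop, fitness_of, numeric(1))
      history <- c(history, max(fit))
    }
  }
  best <- which.max(fit)
  list(mask = pop[[best]], fitness = fit[best], history = history,
       evals = length(ls(memo)))
}

#' Repeated evolutions and the archive of best masks
#'
#' Runs `n_runs` independent evolutions (the study-scale default is 100) and
#' archives each run's best mask and fitness.
#'
#' @inheritParams ga_evolve
#' @param n_runs number of evolutions.
#' @param ... further arguments to [ga_evolve()].
#' @return `evolution_archive`: `masks` (n_runs x p logical matrix, columns
#'   named by the features) and `fitness`.
#' @export
run_evolutions <- function(X, y, n_runs = 100, seed = 1, ...) {
  X <- as.matrix(X)
  runs <- lapply(seq_len(n_runs), function(r)
    ga_evolve(X, y, seed = derive_seed(seed, paste0("evolution", r)), ...))
  masks <- do.call(rbind, lapply(runs, `[[`, "mask"))
  colnames(masks) <- colnames(X)
  structure(list(masks = masks, fitness = vapply(runs, `[[`, numeric(1), "fitness")),
            class = "evolution_archive")
}

#' The "optimal" feature set of an archive
#'
#' The single best-fitness mask across all evolutions; ties are broken
#' toward fewer features, then lexicographically on the bit pattern.
#'
#' @param archive an `evolution_archive`.
#' @return Logical feature mask.
#' @export
optimal_mask <- function(archive) {
  f <- archive$fitness
  best <- which(f == max(f))
  if (length(best) > 1) {
    sizes <- rowSums(archive$masks[best, , drop = FALSE])
    best <- best[sizes == min(sizes)]
    if (length(best) > 1) {
      keys <- apply(archive$masks[best, , drop = FALSE], 1, paste, collapse = "")
      best <- best[order(keys)][1]
    }
  }
  archive$masks[best[1], ]
}

#' The "highest incidence" feature set of an archive
#'
#' Restricts to runs whose fitness strictly exceeds `auc_floor`, computes the
#' per-feature incidence among those best masks, and returns the features
#' whose incidence strictly exceeds `incidence_floor` (both inequalities
#' strict, matching the > 85% AUC and > 80% incidence selection rule).
#'
#' @param archive an `evolution_archive`.
#' @param auc_floor qualifying-run AUC floor (default 0.85).
#' @param incidence_floor incidence floor (default 0.80).
#' @return List: `mask`, `incidence` (named, over all features),
#'   `n_qualifying`, `empty` (TRUE when no run qualifies).
#' @export
aggregate_incidence <- function(archive, auc_floor = 0.85,
                                incidence_floor = 0.80) {
  qual <- archive$fitness > auc_floor
  if (!any(qual)) {
    p <- ncol(archive$masks)
    return(list(mask = setNames(rep(FALSE, p), colnames(archive$masks)),
                incidence = setNames(rep(NA_real_, p), colnames(archive$masks)),
                n_qualifying = 0L, empty = TRUE))
  }
  inc <- colMeans(archive$masks[qual, , drop = FALSE])
  list(mask = inc > incidence_floor, incidence = inc,
       n_qualifying = sum(qual), empty = FALSE)
}

#' Top-down (manually defined) feature sets
#'
#' Masks over the inventory defined by stimulus condition, by contrast, by
#' measure type (amplitude/latency) and by component, mirroring manual
#' feature-set selection by stimuli and type of measure. Gender and age are
#' not part of any top-down set.
#'
#' @param inventory feature-name vector (default the standard inventory).
#' @return Named list of logical masks over `inventory`.
#' @export
topdown_sets <- function(inventory = build_feature_inventory()) {
  suffix <- vapply(inventory, function(nm) {
    f <- parse_feature_name(nm)
    if (is.null(f)) NA_character_ else f$suffix
  }, character(1))
  measure <- vapply(inventory, function(nm) {
    f <- parse_feature_name(nm)
    if (is.null(f)) NA_character_ else f$measure
  }, character(1))
  component <- vapply(inventory, function(nm) {
    f <- parse_feature_name(nm)
    if (is.null(f)) NA_character_ else f$component
  }, character(1))
  sets <- list()
  for (cond in c("FD", "FA", "F", "N", "SD", "SA"))
    sets[[cond]] <- !is.na(suffix) & suffix == cond
  for (ct in c("FvN", "DvA", "TvA"))
    sets[[ct]] <- !is.na(suffix) & suffix == ct
  sets[["amplitude"]] <- !is.na(measure) & measure == "amp"
  sets[["latency"]] <- !is.na(measure) & measure == "lat"
  for (cm in c("P1", "N290", "P400"))
    sets[[cm]] <- !is.na(component) & component == cm
  lapply(sets, function(m) setNames(m, inventory))
}
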