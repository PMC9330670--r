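# shared fixture builders; everything is generated in code at test time

# feature table of iid standard Gaussians with a subset of columns shifted
# for the positive class -- used to probe the selection machinery against
# genuinely uninformative competitors
iid_class_table <- function(n = 300, p = 56, planted = integer(0), d = 1,
                            seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  X[y == 1, planted] <- X[y == 1, planted] + d
  list(X = X, y = y, planted = planted)
}

# small feature-level cohort with defaults scaled down
small_cohort <- function(n_tl = 15, n_el = 15, n_asd = 15, seed = 1, ...) {
  generate_feature_table(generator_config(
    n_per_group = c("TL" = n_tl, "EL-noASD" = n_el, "EL-ASD" = n_asd),
    miss_rate = 0, seed = seed, ...))
}

# waveform config with narrow, well-separated bumps for round-trip tests
narrow_wave_config <- function(n_per_group = c("TL" = 2, "EL-noASD" = 2, "EL-ASD" = 2),
                               noise_sd = 0, n_epochs = 3, seed = 5, ...) {
  generator_config(
    n_per_group = n_per_group, n_epochs = n_epochs, noise_sd = noise_sd,
    seed = seed,
    component_params = data.frame(
      component = c("P1", "N290", "P400"),
      latency = c(120, 290, 450), amplitude = c(8, -8, 6),
      width = c(20, 30, 40), lat_sd = c(8, 8, 8), amp_sd = c(1, 1, 1)),
    ...)
}

# independent reimplementation of greedy BHC for n <= 6: explicit set
# bookkeeping, no shared tree code (the marginal likelihood itself is
# checked against closed forms elsewhere)
oracle_bhc_merges <- function(X, hyper) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), function(i) list(
    members = i,
    log_d = log(hyper$alpha),
    log_pt = marginal_likelihood(X[i, , drop = FALSE], hyper)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      ci <- clusters[[a]]; cj <- clusters[[b]]
      mem <- c(ci$members, cj$members)
      nk <- length(mem)
      lg <- log(hyper$alpha) + lgamma(nk)
      ldk <- max(lg, ci$log_d + cj$log_d) +
        log1p(exp(min(lg, ci$log_d + cj$log_d) - max(lg, ci$log_d + cj$log_d)))
      lpi <- lg - ldk
      lml <- marginal_likelihood(X[mem, , drop = FALSE], hyper)
      t1 <- lpi + lml
      t2 <- (ci$log_d + cj$log_d - ldk) + ci$log_pt + cj$log_pt
      lpt <- max(t1, t2) + log1p(exp(min(t1, t2) - max(t1, t2)))
      r <- exp(t1 - lpt)
      if (is.null(best) || r > best$r + 1e-12) {
        best <- list(a = a, b = b, r = r, log_d = ldk, log_pt = lpt, members = mem)
      }
    }
    merges[[length(merges) + 1]] <- sort(best$members)
    clusters[[best$a]] <- list(members = best$members, log_d = best$log_d,
                               log_pt = best$log_pt)
    clusters[[best$b]] <- NULL
  }
  merges
}

# merge sequence of a built tree, as sorted member sets in merge order
tree_merges <- function(tree) {
  ids <- (tree$n + 1):length(tree$nodes)
  lapply(ids, function(k) sort(tree$nodes[[k]]$members))
}
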