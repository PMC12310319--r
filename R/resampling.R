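#' Nonparametric bootstrap of edge weights
#'
#' Resamples subjects with replacement, re-estimates the network on each
#' replicate, and summarises every unique edge by its bootstrap mean and
#' empirical confidence interval.  Also performs the bootstrap
#' edge-difference test: a pair of edges differs significantly when the
#' bootstrap interval of their difference excludes zero.  Replicates on
#' which the estimator emits warnings (e.g. a constant column isolating a
#' node) are retained and counted, never dropped.
#'
#' @param m a [binary_symptoms()] matrix.
#' @param estimator function mapping a binary matrix to an
#'   [ising_network()]; defaults to [fit_ising()].
#' @param B number of bootstrap replicates (default 1000).
#' @param seed master seed; one sub-seed per replicate.
#' @param conf confidence level for the intervals (default 0.95).
#' @return A list of class `bootstrap_edges`: `edges` data.frame (observed,
#'   boot mean, CI bounds, excludes-zero flag), `diff_significant` logical
#'   matrix over edge pairs, `samples` (B x n_edges), `n_warnings`.
#' @export
bootstrap_edges <- function(m, estimator = fit_ising, B = 1000, seed = 1,
                            conf = 0.95) {
  x <- as.matrix(m)
  n <- nrow(x)
  observed_net <- estimator(m)
  observed <- upper_tri_vec(observed_net$weights)
  enames <- edge_names(observed_net$item_labels)
  seeds <- derive_seeds(seed, B)
  samples <- matrix(NA_real_, B, length(observed))
  n_warnings <- 0L
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[b], sample.int(n, n, replace = TRUE))
    mb <- binary_symptoms(x[idx, , drop = FALSE],
                          item_labels = observed_net$item_labels)
    net_b <- withCallingHandlers(
      estimator(mb),
      warning = function(w) {
        n_warnings <<- n_warnings + 1L
        invokeRestart("muffleWarning")
      })
    samples[b, ] <- upper_tri_vec(net_b$weights)
  }
  a <- (1 - conf) / 2
  lo <- apply(samples, 2, quantile, probs = a)
  hi <- apply(samples, 2, quantile, probs = 1 - a)
  edges <- data.frame(edge = enames, observed = observed,
                      boot_mean = colMeans(samples),
                      ci_lower = lo, ci_upper = hi,
                      excludes_zero = lo > 0 | hi < 0,
                      row.names = NULL)
  ne <- length(observed)
  diff_sig <- matrix(FALSE, ne, ne, dimnames = list(enames, enames))
  for (a_i in seq_len(ne - 1)) {
    d <- samples[, (a_i + 1):ne, drop = FALSE] - samples[, a_i]
    dlo <- apply(d, 2, quantile, probs = a)
    dhi <- apply(d, 2, quantile, probs = 1 - a)
    sig <- dlo > 0 | dhi < 0
    diff_sig[a_i, (a_i + 1):ne] <- sig
    diff_sig[(a_i + 1):ne, a_i] <- sig
  }
  structure(list(edges = edges, diff_significant = diff_sig,
                 samples = samples, n_warnings = n_warnings,
                 B = B, conf = conf, seed = seed),
            class = "bootstrap_edges")
}

#' Bootstrap test of centrality differences
#'
#' Same machinery as [bootstrap_edges()], applied to node centralities: two
#' nodes differ significantly when the bootstrap interval of their
#' centrality difference excludes zero.
#'
#' @inheritParams bootstrap_edges
#' @param centrality_fn function mapping a network to a named numeric vector
#'   of node centralities; defaults to raw strength.
#' @return A list of class `bootstrap_centrality`: `nodes` data.frame,
#'   `diff_significant` node-pair matrix, `samples`.
#' @export
bootstrap_centrality_diff <- function(m, estimator = fit_ising,
                                      centrality_fn = node_strength_vector,
                                      B = 1000, seed = 1, conf = 0.95) {
  x <- as.matrix(m)
  n <- nrow(x)
  observed_net <- estimator(m)
  observed <- centrality_fn(observed_net)
  labels <- observed_net$item_labels
  seeds <- derive_seeds(seed, B)
  samples <- matrix(NA_real_, B, length(observed))
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[b], sample.int(n, n, replace = TRUE))
    mb <- binary_symptoms(x[idx, , drop = FALSE], item_labels = labels)
    net_b <- suppressWarnings(estimator(mb))
    samples[b, ] <- centrality_fn(net_b)
  }
  a <- (1 - conf) / 2
  p <- length(observed)
  diff_sig <- matrix(FALSE, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p - 1)) {
    d <- samples[, (i + 1):p, drop = FALSE] - samples[, i]
    dlo <- apply(d, 2, quantile, probs = a)
    dhi <- apply(d, 2, quantile, probs = 1 - a)
    sig <- dlo > 0 | dhi < 0
    diff_sig[i, (i + 1):p] <- sig
    diff_sig[(i + 1):p, i] <- sig
  }
  nodes <- data.frame(node = labels, observed = observed,
                      boot_mean = colMeans(samples),
                      ci_lower = apply(samples, 2, quantile, probs = a),
                      ci_upper = apply(samples, 2, quantile, probs = 1 - a),
                      row.names = NULL)
  structure(list(nodes = nodes, diff_significant = diff_sig,
                 samples = samples, B = B, conf = conf, seed = seed),
            class = "bootstrap_centrality")
}

#' Raw strength vector of a network
#'
#' Convenience centrality accessor for the resampling functions.
#'
#' @param net an [ising_network()].
#' @return Named numeric vector of node strengths.
#' @export
node_strength_vector <- function(net) {
  s <- rowSums(abs(net$weights))
  names(s) <- net$item_labels
  s
}

#' Case-dropping bootstrap and the correlation-stability coefficient
#'
#' For each drop proportion q in `grid`, draws `B` subsamples of size
#' n(1 - q) without replacement, recomputes the chosen centrality on each,
#' and correlates it with the full-sample centrality.  The CS-coefficient is
#' the largest q at which the correlation stays at or above `threshold_r`
#' with probability at least `confidence` — the standard benchmark being
#' r >= 0.7 with 95% probability; values of CS below 0.25 indicate an
#' unstable centrality ordering, values above 0.5 a stable one.
#'
#' @param m a [binary_symptoms()] matrix.
#' @param estimator network estimator, as in [bootstrap_edges()].
#' @param centrality_fn network -> numeric vector of node centralities.
#' @param grid drop proportions (default 0.05 to 0.75 in steps of 0.05; the
#'   ceiling of 0.75 is the largest reportable CS value).
#' @param B subsamples per grid point (default 1000).
#' @param threshold_r correlation benchmark (default 0.7).
#' @param confidence required probability of exceeding it (default 0.95).
#' @param seed master seed.
#' @param cor_method `"pearson"` (default) or `"spearman"` for the
#'   subset-vs-full correlation.
#' @return A list of class `case_drop_result`: `cs`, `grid`, `prop_ok`
#'   (per-q probability of r >= threshold), `correlations` (B x length(grid)).
#' @export
cs_coefficient <- function(m, estimator = fit_ising,
                           centrality_fn = node_strength_vector,
                           grid = seq(0.05, 0.75, by = 0.05), B = 1000,
                           threshold_r = 0.7, confidence = 0.95, seed = 1,
                           cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  stopifnot(all(grid > 0), all(grid <= 0.75))
  x <- as.matrix(m)
  n <- nrow(x)
  p <- ncol(x)
  labels <- item_labels_of(m)
  full <- centrality_fn(suppressWarnings(estimator(m)))
  seeds <- derive_seeds(seed, length(grid))
  cors <- matrix(NA_real_, B, length(grid))
  skipped <- logical(length(grid))
  for (g in seq_along(grid)) {
    keep_n <- floor(n * (1 - grid[g]))
    if (keep_n <= p) {
      warning(sprintf("drop proportion %.2f leaves %d <= p rows; skipped",
                      grid[g], keep_n))
      skipped[g] <- TRUE
      next
    }
    sub_seeds <- derive_seeds(seeds[g], B)
    for (b in seq_len(B)) {
      idx <- with_seed(sub_seeds[b], sample.int(n, keep_n))
      mb <- binary_symptoms(x[idx, , drop = FALSE], item_labels = labels)
      cb <- centrality_fn(suppressWarnings(estimator(mb)))
      r <- suppressWarnings(cor(full, cb, method = cor_method))
      cors[b, g] <- if (is.na(r)) -Inf else r  # degenerate subset: unstable
    }
  }
  prop_ok <- colMeans(cors >= threshold_r)
  ok <- !skipped & !is.na(prop_ok) & prop_ok >= confidence
  cs <- if (any(ok)) max(grid[ok]) else 0
  structure(list(cs = cs, grid = grid, prop_ok = prop_ok,
                 correlations = cors, threshold_r = threshold_r,
                 confidence = confidence, B = B, seed = seed,
                 skipped = skipped),
            class = "case_drop_result")
}
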