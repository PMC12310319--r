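#' Edge replicability between two networks
#'
#' Vectorises the unique (upper-triangle) edges of both networks and
#' computes (i) the phi correlation of the edge-presence indicators (the
#' Pearson correlation of two binary vectors; presence means an exactly
#' nonzero estimated weight) and (ii) the Spearman rank correlation of the
#' edge weights.  Phi is undefined (NA) when either network has all edges
#' present or all absent.
#'
#' @param net1,net2 [ising_network()] objects on the same node set and
#'   order.
#' @return A list: `phi`, `phi_p`, `rho`, `rho_p`, `n_edges`.
#' @export
edge_replicability <- function(net1, net2) {
  if (!identical(net1$item_labels, net2$item_labels)) {
    stop("networks must share the same node set and order")
  }
  e1 <- upper_tri_vec(net1$weights)
  e2 <- upper_tri_vec(net2$weights)
  p1 <- as.numeric(e1 != 0)
  p2 <- as.numeric(e2 != 0)
  if (var(p1) == 0 || var(p2) == 0) {
    phi <- NA_real_; phi_p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(p1, p2, method = "pearson"))
    phi <- unname(ct$estimate); phi_p <- ct$p.value
  }
  rt <- suppressWarnings(stats::cor.test(e1, e2, method = "spearman"))
  list(phi = phi, phi_p = phi_p,
       rho = unname(rt$estimate), rho_p = rt$p.value,
       n_edges = length(e1))
}

# Invariance statistics between two estimated networks.
invariance_stats <- function(net1, net2) {
  d <- abs(upper_tri_vec(net1$weights) - upper_tri_vec(net2$weights))
  s1 <- global_strength(net1)
  s2 <- global_strength(net2)
  c(M = max(d), S1 = s1, S2 = s2, delta_S = abs(s1 - s2))
}

#' Permutation test of network invariance
#'
#' Compares two datasets through their estimated networks: M is the maximum
#' absolute edge-weight difference, delta-S the absolute difference in
#' global strength.  The null distribution is built by permutation —
#' unpaired: group labels are shuffled over the pooled rows; paired: each
#' subject's two rows are swapped independently with probability 1/2
#' (appropriate when the two datasets are the same subjects measured twice).
#' p-values use the add-one convention p = (1 + #{perm >= observed}) /
#' (1 + n_perm).  An estimator failure on a permutation is retried once with
#' a fresh draw and otherwise counted as a failure (excluded from the null
#' sample, reported in the result).
#'
#' @param data1,data2 [binary_symptoms()] matrices on the same items;
#'   `paired = TRUE` additionally requires equal n with aligned rows.
#' @param estimator network estimator (default [fit_ising()]).
#' @param n_perm number of permutations (default 1000).
#' @param paired use the within-subject swap scheme? Default `FALSE`
#'   (independent-groups label shuffling).
#' @param seed master seed.
#' @return A list of class `comparison_result`: observed `M`, `S1`, `S2`,
#'   `delta_S`, permutation p-values `p_M` and `p_S`, replicability `phi`
#'   and `rho` of the two observed networks, `n_perm`, `n_failures`.
#' @export
invariance_test <- function(data1, data2, estimator = fit_ising,
                            n_perm = 1000, paired = FALSE, seed = 1) {
  x1 <- as.matrix(data1)
  x2 <- as.matrix(data2)
  if (ncol(x1) != ncol(x2)) stop("datasets must share the same items")
  if (paired && nrow(x1) != nrow(x2)) {
    stop("paired comparison requires equal n with aligned rows")
  }
  labels <- item_labels_of(data1)
  as_bin <- function(m) binary_symptoms(m, item_labels = labels)
  net1 <- suppressWarnings(estimator(as_bin(x1)))
  net2 <- suppressWarnings(estimator(as_bin(x2)))
  obs <- invariance_stats(net1, net2)
  rep_stats <- edge_replicability(net1, net2)

  n1 <- nrow(x1); n2 <- nrow(x2)
  pooled <- rbind(x1, x2)
  seeds <- derive_seeds(seed, n_perm)
  perm_M <- rep(NA_real_, n_perm)
  perm_S <- rep(NA_real_, n_perm)
  n_failures <- 0L
  one_perm <- function(s) {
    if (paired) {
      swap <- with_seed(s, runif(n1) < 0.5)
      a <- x1; b <- x2
      a[swap, ] <- x2[swap, , drop = FALSE]
      b[swap, ] <- x1[swap, , drop = FALSE]
    } else {
      idx <- with_seed(s, sample.int(n1 + n2))
      a <- pooled[idx[seq_len(n1)], , drop = FALSE]
      b <- pooled[idx[n1 + seq_len(n2)], , drop = FALSE]
    }
    na <- suppressWarnings(estimator(as_bin(a)))
    nb <- suppressWarnings(estimator(as_bin(b)))
    invariance_stats(na, nb)
  }
  for (k in seq_len(n_perm)) {
    st <- tryCatch(one_perm(seeds[k]), error = function(e) NULL)
    if (is.null(st)) {
      st <- tryCatch(one_perm(seeds[k] + 1L), error = function(e) NULL)
    }
    if (is.null(st)) {
      n_failures <- n_failures + 1L
    } else {
      perm_M[k] <- st["M"]
      perm_S[k] <- st["delta_S"]
    }
  }
  ok <- !is.na(perm_M)
  n_eff <- sum(ok)
  p_M <- (1 + sum(perm_M[ok] >= obs["M"])) / (1 + n_eff)
  p_S <- (1 + sum(perm_S[ok] >= obs["delta_S"])) / (1 + n_eff)
  structure(list(M = unname(obs["M"]), S1 = unname(obs["S1"]),
                 S2 = unname(obs["S2"]), delta_S = unname(obs["delta_S"]),
                 p_M = p_M, p_S = p_S,
                 phi = rep_stats$phi, rho = rep_stats$rho,
                 n_perm = n_perm, n_failures = n_failures,
                 paired = paired, seed = seed,
                 net1 = net1, net2 = net2),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Network comparison (%s, %d permutations)\n",
              if (x$paired) "paired" else "independent groups", x$n_perm))
  cat(sprintf("  M = %.3f (p = %.3f)\n", x$M, x$p_M))
  cat(sprintf("  S1 = %.3f, S2 = %.3f, delta-S = %.3f (p = %.3f)\n",
              x$S1, x$S2, x$delta_S, x$p_S))
  cat(sprintf("  edge replicability: phi = %.3f, rho = %.3f\n",
              x$phi, x$rho))
  invisible(x)
}
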