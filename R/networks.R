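#' Undirected Ising network
#'
#' Symmetric signed edge-weight matrix plus node thresholds, as produced by
#' nodewise logistic regression on binary data.
#'
#' @param weights symmetric p x p numeric matrix, zero diagonal.
#' @param thresholds length-p numeric vector of node thresholds (intercepts
#'   of the selected nodewise models).
#' @param item_labels length-p character vector.
#' @param estimation_meta optional list of estimation settings (EBIC gamma,
#'   lambda grid description, per-node selected lambda, symmetrisation rule).
#' @return An object of class `ising_network`.
#' @export
ising_network <- function(weights, thresholds, item_labels = NULL,
                          estimation_meta = list()) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (ncol(weights) != p) stop("weights must be square")
  if (!all(is.finite(weights)) || !all(is.finite(thresholds))) {
    stop("weights and thresholds must be finite")
  }
  if (max(abs(weights - t(weights))) > 1e-10) stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("weights must have zero diagonal")
  if (length(thresholds) != p) stop("thresholds length mismatch")
  if (is.null(item_labels)) {
    item_labels <- colnames(weights)
    if (is.null(item_labels)) item_labels <- paste0("V", seq_len(p))
  }
  dimnames(weights) <- list(item_labels, item_labels)
  structure(list(weights = weights, thresholds = as.numeric(thresholds),
                 item_labels = item_labels, estimation_meta = estimation_meta),
            class = "ising_network")
}

#' @export
print.ising_network <- function(x, ...) {
  p <- length(x$item_labels)
  ne <- sum(upper_tri_vec(x$weights) != 0)
  cat(sprintf("Ising network: %d nodes, %d/%d nonzero edges, global strength %.3f\n",
              p, ne, p * (p - 1) / 2, global_strength(x)))
  invisible(x)
}

#' Directed cross-lagged panel network
#'
#' Entry (i, j) of `coefficients` is the regularised log-odds effect of item
#' i at Wave 1 on item j at Wave 2; the diagonal holds autoregressive
#' effects.  The matrix is in general asymmetric.
#'
#' @param coefficients p x p numeric matrix of cross-lagged coefficients.
#' @param intercepts length-p numeric vector (one per Wave-2 outcome).
#' @param item_labels length-p character vector.
#' @param lambda_info optional per-outcome list/data.frame with lambda_min
#'   and lambda_1se.
#' @param fold_seed seed used for cross-validation fold assignment.
#' @return An object of class `clpn_network`.
#' @export
clpn_network <- function(coefficients, intercepts, item_labels = NULL,
                         lambda_info = NULL, fold_seed = NA_integer_) {
  coefficients <- as.matrix(coefficients)
  p <- nrow(coefficients)
  if (ncol(coefficients) != p) stop("coefficients must be square")
  if (!all(is.finite(coefficients)) || !all(is.finite(intercepts))) {
    stop("coefficients and intercepts must be finite")
  }
  if (length(intercepts) != p) stop("intercepts length mismatch")
  if (is.null(item_labels)) {
    item_labels <- colnames(coefficients)
    if (is.null(item_labels)) item_labels <- paste0("V", seq_len(p))
  }
  dimnames(coefficients) <- list(item_labels, item_labels)
  structure(list(coefficients = coefficients,
                 intercepts = as.numeric(intercepts),
                 item_labels = item_labels, lambda_info = lambda_info,
                 fold_seed = fold_seed),
            class = "clpn_network")
}

#' @export
print.clpn_network <- function(x, ...) {
  p <- length(x$item_labels)
  off <- x$coefficients; diag(off) <- 0
  cat(sprintf("Cross-lagged panel network: %d nodes, %d/%d nonzero directed edges (excl. autoregressive)\n",
              p, sum(off != 0), p * (p - 1)))
  cat(sprintf("Autoregressive effects: %s\n",
              paste(sprintf("%.2f", diag(x$coefficients)), collapse = " ")))
  invisible(x)
}

#' Serialise a network to CSV + JSON sidecar
#'
#' The adjacency (weights or cross-lagged coefficients) is written as a CSV
#' with row/column labels; everything else (thresholds or intercepts, labels,
#' estimation metadata) goes to a JSON sidecar `<path>.json`.  Floats are
#' stored with full double precision so that [read_network()] reproduces the
#' object exactly.
#'
#' @param net an `ising_network` or `clpn_network`.
#' @param path CSV path for the adjacency matrix.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  is_ising <- inherits(net, "ising_network")
  if (!is_ising && !inherits(net, "clpn_network")) {
    stop("net must be an ising_network or clpn_network")
  }
  adj <- if (is_ising) net$weights else net$coefficients
  num <- as.data.frame(lapply(as.data.frame(adj),
                              function(col) sprintf("%.17g", col)),
                       check.names = FALSE)
  df <- data.frame(item = rownames(adj), num, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta <- list(
    class = if (is_ising) "ising_network" else "clpn_network",
    item_labels = net$item_labels)
  if (is_ising) {
    meta$thresholds <- net$thresholds
    meta$estimation_meta <- net$estimation_meta
  } else {
    meta$intercepts <- net$intercepts
    meta$lambda_info <- net$lambda_info
    meta$fold_seed <- net$fold_seed
  }
  jsonlite::write_json(meta, paste0(path, ".json"), digits = I(17),
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path CSV path used at write time (the `<path>.json` sidecar must
#'   sit next to it).
#' @return The deserialised `ising_network` or `clpn_network`.
#' @export
read_network <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(path, check.names = FALSE)
  labels <- as.character(meta$item_labels)
  if (!identical(as.character(df$item), labels) ||
      !identical(names(df)[-1L], labels)) {
    stop("label mismatch between adjacency CSV and JSON sidecar")
  }
  adj <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(adj) <- "double"
  rownames(adj) <- labels
  if (identical(meta$class, "ising_network")) {
    ising_network(adj, thresholds = as.numeric(meta$thresholds),
                  item_labels = labels,
                  estimation_meta = meta$estimation_meta)
  } else if (identical(meta$class, "clpn_network")) {
    li <- meta$lambda_info
    clpn_network(adj, intercepts = as.numeric(meta$intercepts),
                 item_labels = labels, lambda_info = li,
                 fold_seed = meta$fold_seed)
  } else {
    stop("unknown network class in sidecar: ", meta$class)
  }
}
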