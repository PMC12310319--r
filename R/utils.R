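#' @keywords internal
"_PACKAGE"

#' @importFrom stats plogis qlogis quantile rbinom runif sd var cor coef
#'   pchisq uniroot predict
#' @importFrom utils read.csv write.csv head
#' @importFrom Rcpp sourceCpp
#' @useDynLib symptomnet, .registration = TRUE
NULL

#' CESD-10 item labels
#'
#' The ten item labels in fixed instrument order.  The two positively worded
#' items (D5 "felt hopeful", D8 "felt happy") appear under their negated
#' names ("hopelessness", "lack of happiness") once recoded.
#'
#' @param recoded return the post-recoding (negated) names? Default `TRUE`.
#' @return Character vector of length 10.
#' @export
cesd10_labels <- function(recoded = TRUE) {
  if (recoded) {
    c("D1: bothered by things",
      "D2: had trouble keeping in mind",
      "D3: felt depressed",
      "D4: everything an effort",
      "D5: hopelessness",
      "D6: felt fear",
      "D7: sleep was restless",
      "D8: lack of happiness",
      "D9: felt lonely",
      "D10: could not get going")
  } else {
    c("D1: bothered by things",
      "D2: had trouble keeping in mind",
      "D3: felt depressed",
      "D4: everything an effort",
      "D5: felt hopeful",
      "D6: felt fear",
      "D7: sleep was restless",
      "D8: felt happy",
      "D9: felt lonely",
      "D10: could not get going")
  }
}

#' Indices of the positively worded (reverse-scored) CESD-10 items
#'
#' @return Integer vector: items 5 and 8.
#' @export
cesd10_positive_items <- function() c(5L, 8L)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.  All stochastic operations in the package
# funnel through this so that results depend only on the seed argument.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive `k` child seeds from a master seed.  Replicates seeded this way are
# independent of execution order, which keeps bootstrap/permutation loops
# reproducible even if they are ever parallelised.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# z-standardise with population SD (divisor n); degenerate spread -> zeros.
standardize_scores <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) rep(0, length(x)) else (x - m) / s
}

upper_tri_vec <- function(m) m[upper.tri(m)]

# Names for the p*(p-1)/2 unique undirected edges, row-major upper triangle.
edge_names <- function(labels) {
  p <- length(labels)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  paste(labels[idx[, 1]], labels[idx[, 2]], sep = " -- ")
}
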