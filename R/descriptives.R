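#' Per-item endorsement counts and percentages across two waves
#'
#' @param w1,w2 [binary_symptoms()] matrices with matching shape and item
#'   labels (same subjects in the same order).
#' @return A data.frame with one row per item: counts, percentages (full
#'   precision; round at the reporting layer).
#' @export
endorsement_table <- function(w1, w2) {
  if (!identical(dim(w1), dim(w2))) stop("wave shape mismatch")
  n <- nrow(w1)
  data.frame(
    item = item_labels_of(w1),
    wave1_count = colSums(w1),
    wave2_count = colSums(w2),
    wave1_pct = 100 * colMeans(w1),
    wave2_pct = 100 * colMeans(w2),
    row.names = NULL)
}

#' McNemar's test for paired change in a binary symptom
#'
#' Tests marginal frequency change between waves from the discordant pair
#' counts b (1 at Wave 1, 0 at Wave 2) and c (0 at Wave 1, 1 at Wave 2):
#' chi-square = (b - c)^2 / (b + c), or (|b - c| - 1)^2 / (b + c) with the
#' continuity correction.  With no discordant pairs the statistic is 0 and
#' p = 1.
#'
#' @param w1_item,w2_item paired binary vectors of equal length.
#' @param correction apply the continuity correction? Default `FALSE`.
#' @return A list: `b`, `c`, `statistic`, `p_value`.
#' @export
mcnemar_change <- function(w1_item, w2_item, correction = FALSE) {
  if (length(w1_item) != length(w2_item)) stop("length mismatch")
  b <- sum(w1_item == 1 & w2_item == 0)
  cc <- sum(w1_item == 0 & w2_item == 1)
  if (b + cc == 0) {
    stat <- 0
    p <- 1
  } else {
    num <- if (correction) (abs(b - cc) - 1)^2 else (b - cc)^2
    stat <- num / (b + cc)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(b = b, c = cc, statistic = stat, p_value = p)
}

#' Paired change table across all items
#'
#' Combines [endorsement_table()] with per-item [mcnemar_change()] results
#' and significance flags at the 0.05 and 0.001 levels.
#'
#' @inheritParams endorsement_table
#' @param correction forwarded to [mcnemar_change()].
#' @return A data.frame, one row per item.
#' @export
paired_change_table <- function(w1, w2, correction = FALSE) {
  tab <- endorsement_table(w1, w2)
  tests <- lapply(seq_len(ncol(w1)), function(j) {
    mcnemar_change(w1[, j], w2[, j], correction = correction)
  })
  tab$b_1to0 <- vapply(tests, `[[`, numeric(1), "b")
  tab$c_0to1 <- vapply(tests, `[[`, numeric(1), "c")
  tab$chisq <- vapply(tests, `[[`, numeric(1), "statistic")
  tab$p_value <- vapply(tests, `[[`, numeric(1), "p_value")
  tab$sig <- ifelse(tab$p_value < 0.001, "**",
                    ifelse(tab$p_value < 0.05, "*", ""))
  tab
}

#' Cronbach's alpha for a binary item set
#'
#' alpha = p/(p - 1) * (1 - sum of item variances / variance of total
#' scores).  For 0/1 items this equals the Kuder-Richardson formula 20.
#'
#' @param m a [binary_symptoms()] matrix (or any numeric matrix) with at
#'   least two columns.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(m) {
  m <- unclass(as.matrix(m))
  p <- ncol(m)
  if (p < 2) stop("alpha requires at least two items")
  total_var <- var(rowSums(m))
  if (total_var == 0) stop("zero total-score variance")
  p / (p - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}
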