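#' Two-wave symptom panel
#'
#' Container for raw two-wave Likert responses (0--3) on the same subjects.
#' Both waves must have identical shape and subject ordering; subjects with
#' any missing or out-of-range value are expected to have been dropped at
#' ingestion (see [read_panel_csv()]).
#'
#' @param wave1_raw,wave2_raw integer matrices (n x p), values in 0..3.
#' @param subject_id character vector of length n, unique.
#' @param item_labels length-p character vector; defaults to the CESD-10
#'   item names in instrument order.
#' @param positive_items integer indices of positively worded items that are
#'   reverse-scored before binarisation; defaults to the CESD-10 convention
#'   (items 5 and 8).
#' @return An object of class `symptom_panel`.
#' @export
symptom_panel <- function(wave1_raw, wave2_raw, subject_id = NULL,
                          item_labels = cesd10_labels(recoded = FALSE),
                          positive_items = cesd10_positive_items()) {
  wave1_raw <- as.matrix(wave1_raw)
  wave2_raw <- as.matrix(wave2_raw)
  if (!identical(dim(wave1_raw), dim(wave2_raw))) {
    stop("wave1_raw and wave2_raw must have identical dimensions")
  }
  n <- nrow(wave1_raw)
  p <- ncol(wave1_raw)
  if (is.null(subject_id)) subject_id <- as.character(seq_len(n))
  if (length(subject_id) != n) stop("subject_id length must equal nrow")
  if (anyDuplicated(subject_id)) stop("duplicate subject_id")
  if (length(item_labels) != p) stop("item_labels length must equal ncol")
  check_raw_values(wave1_raw, "wave1")
  check_raw_values(wave2_raw, "wave2")
  if (any(positive_items < 1L | positive_items > p)) {
    stop("positive_items out of range")
  }
  structure(
    list(wave1_raw = wave1_raw, wave2_raw = wave2_raw,
         subject_id = as.character(subject_id),
         item_labels = item_labels,
         positive_items = as.integer(positive_items)),
    class = "symptom_panel")
}

check_raw_values <- function(m, wave) {
  bad <- which(!(m %in% 0:3) | is.na(m))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop(sprintf("value outside {0,1,2,3} in %s at row %d, column %d",
                 wave, rc[1L], rc[2L]))
  }
  invisible(TRUE)
}

#' @export
print.symptom_panel <- function(x, ...) {
  cat(sprintf("Two-wave symptom panel: %d subjects, %d items\n",
              nrow(x$wave1_raw), ncol(x$wave1_raw)))
  invisible(x)
}

#' Binary symptom matrix
#'
#' An n x p matrix of 0/1 symptom endorsements for a single wave.
#'
#' @param values numeric/integer matrix with entries in {0, 1}.
#' @param item_labels length-p character vector of item names.
#' @param wave_tag short string identifying the wave (e.g. "wave1").
#' @return An object of class `binary_symptoms` (a matrix with attributes).
#' @export
binary_symptoms <- function(values, item_labels = NULL, wave_tag = "wave1") {
  values <- as.matrix(values)
  if (any(is.na(values)) || !all(values %in% c(0, 1))) {
    stop("values must be 0/1 with no missing entries")
  }
  if (is.null(item_labels)) {
    item_labels <- colnames(values)
    if (is.null(item_labels)) item_labels <- paste0("V", seq_len(ncol(values)))
  }
  if (length(item_labels) != ncol(values)) {
    stop("item_labels length must equal number of columns")
  }
  storage.mode(values) <- "integer"
  colnames(values) <- item_labels
  structure(values, wave_tag = wave_tag, class = c("binary_symptoms", "matrix"))
}

#' @export
print.binary_symptoms <- function(x, ...) {
  cat(sprintf("Binary symptom matrix [%s]: %d subjects, %d items\n",
              attr(x, "wave_tag"), nrow(x), ncol(x)))
  cat("Endorsement rates:\n")
  print(round(colMeans(x), 3))
  invisible(x)
}

item_labels_of <- function(m) colnames(m)

#' Recode raw CESD-10 responses to binary endorsements
#'
#' Negatively worded items are binarised directly: 0 ("rarely") stays 0, any
#' higher frequency becomes 1.  Positively worded items are reverse-coded
#' (r' = 3 - r) first and then binarised, which is equivalent to scoring 1
#' whenever the raw response is at most 2; their labels are replaced by the
#' negated symptom names ("hopelessness", "lack of happiness" for the CESD-10
#' defaults).
#'
#' @param panel a [symptom_panel()].
#' @return A list with components `wave1` and `wave2`, each a
#'   [binary_symptoms()] matrix with recoded labels.
#' @export
recode_cesd <- function(panel) {
  stopifnot(inherits(panel, "symptom_panel"))
  labels <- panel$item_labels
  pos <- panel$positive_items
  if (identical(labels, cesd10_labels(recoded = FALSE)) &&
      identical(pos, cesd10_positive_items())) {
    labels <- cesd10_labels(recoded = TRUE)
  } else if (length(pos)) {
    labels[pos] <- paste0(labels[pos], " (reversed)")
  }
  bin <- function(raw, tag) {
    out <- ifelse(raw == 0L, 0L, 1L)
    if (length(pos)) {
      # positive item: 1 iff raw <= 2, i.e. reversed score 3 - r nonzero
      out[, pos] <- ifelse(raw[, pos] <= 2L, 1L, 0L)
    }
    binary_symptoms(out, item_labels = labels, wave_tag = tag)
  }
  list(wave1 = bin(panel$wave1_raw, "wave1"),
       wave2 = bin(panel$wave2_raw, "wave2"))
}

#' Read a two-wave symptom panel from CSV
#'
#' Expects a header row, one row per subject, an identifier column, and one
#' column per item and wave.  Rows with any missing or out-of-range value in
#' the mapped columns are dropped (listwise deletion across both waves) and
#' counted; network estimation downstream does not accommodate missing data.
#' Rows are ordered deterministically by subject identifier.
#'
#' @param path CSV file path.
#' @param id_col name of the subject identifier column.
#' @param wave1_cols,wave2_cols character vectors naming the item columns of
#'   each wave, in item order.
#' @param item_labels,positive_items forwarded to [symptom_panel()].
#' @return A list: `panel` (a [symptom_panel()]) and `n_dropped` (number of
#'   incomplete rows removed).
#' @export
read_panel_csv <- function(path, id_col = "id",
                           wave1_cols = paste0("w1_d", 1:10),
                           wave2_cols = paste0("w2_d", 1:10),
                           item_labels = cesd10_labels(recoded = FALSE),
                           positive_items = cesd10_positive_items()) {
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty panel file: ", path)
  needed <- c(id_col, wave1_cols, wave2_cols)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing mapped column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df[[id_col]])) stop("duplicate subject_id in ", path)
  w1 <- as.matrix(df[wave1_cols])
  w2 <- as.matrix(df[wave2_cols])
  ok <- function(m) {
    suppressWarnings(storage.mode(m) <- "numeric")
    rowSums(is.na(m) | !(m %in% 0:3)) == 0
  }
  keep <- ok(w1) & ok(w2)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  ord <- order(as.character(df[[id_col]]))
  df <- df[ord, , drop = FALSE]
  w1 <- as.matrix(df[wave1_cols]); storage.mode(w1) <- "integer"
  w2 <- as.matrix(df[wave2_cols]); storage.mode(w2) <- "integer"
  panel <- symptom_panel(w1, w2, subject_id = as.character(df[[id_col]]),
                         item_labels = item_labels,
                         positive_items = positive_items)
  list(panel = panel, n_dropped = n_dropped)
}

#' Write a two-wave panel to CSV
#'
#' Inverse of [read_panel_csv()] for binary or raw panels.
#'
#' @param panel a [symptom_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "symptom_panel"))
  p <- ncol(panel$wave1_raw)
  df <- data.frame(id = panel$subject_id, check.names = FALSE)
  w1 <- as.data.frame(panel$wave1_raw)
  names(w1) <- paste0("w1_d", seq_len(p))
  w2 <- as.data.frame(panel$wave2_raw)
  names(w2) <- paste0("w2_d", seq_len(p))
  write.csv(cbind(df, w1, w2), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
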