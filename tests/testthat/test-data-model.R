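test_that("recoding binarises negative items and reverse-codes positive ones", {
  # one subject per raw level, all ten items at that level
  raw <- matrix(rep(0:3, each = 10), nrow = 4, byrow = TRUE)
  panel <- symptom_panel(raw, raw)
  rec <- recode_cesd(panel)
  w1 <- unclass(rec$wave1)
  neg <- setdiff(1:10, cesd10_positive_items())
  # negative items: 0 -> 0, anything higher -> 1
  expect_equal(unname(w1[1, neg]), rep(0L, length(neg)))
  expect_equal(unname(w1[2, neg]), rep(1L, length(neg)))
  expect_equal(unname(w1[3, neg]), rep(1L, length(neg)))
  # positive items: reversed then binarised -> 1 iff raw <= 2
  pos <- cesd10_positive_items()
  expect_equal(unname(w1[1, pos]), rep(1L, 2))
  expect_equal(unname(w1[2, pos]), rep(1L, 2))
  expect_equal(unname(w1[4, pos]), rep(0L, 2))
  # labels renamed to negated forms
  expect_true(any(grepl("hopelessness", colnames(w1), ignore.case = TRUE)))
  expect_true(any(grepl("lack of happiness", colnames(w1),
                        ignore.case = TRUE)))
})

test_that("one-step rule for positive items equals the two-step form", {
  set.seed(7)
  raw <- matrix(sample(0:3, 200, replace = TRUE), 20, 10)
  panel <- symptom_panel(raw, raw)
  rec <- recode_cesd(panel)
  pos <- cesd10_positive_items()
  two_step <- ifelse((3 - raw[, pos]) == 0, 0L, 1L)
  expect_equal(unname(unclass(rec$wave1)[, pos]), unname(two_step))
})

test_that("recoding is idempotent on already-binary negative items", {
  raw <- matrix(sample(0:1, 120, replace = TRUE), 12, 10)
  panel <- symptom_panel(raw, raw)
  rec <- recode_cesd(panel)
  neg <- setdiff(1:10, cesd10_positive_items())
  expect_equal(unname(unclass(rec$wave1)[, neg]), unname(raw[, neg]))
})

test_that("panel construction rejects out-of-range values with location", {
  raw <- matrix(0L, 3, 10)
  bad <- raw
  bad[2, 4] <- 5L
  expect_error(symptom_panel(bad, raw), "row 2, column 4")
  expect_error(symptom_panel(raw, raw, subject_id = c("a", "a", "b")),
               "duplicate")
})

test_that("CSV reading drops incomplete rows, orders by id, errors usefully", {
  path <- write_toy_panel_csv()
  rd <- read_panel_csv(path)
  expect_equal(nrow(rd$panel$wave1_raw), 5)
  expect_equal(rd$n_dropped, 0)
  expect_equal(rd$panel$subject_id, sort(rd$panel$subject_id))

  path2 <- write_toy_panel_csv(incomplete_rows = 1)
  rd2 <- read_panel_csv(path2)
  expect_equal(nrow(rd2$panel$wave1_raw), 5)
  expect_equal(rd2$n_dropped, 1)

  empty <- tempfile(fileext = ".csv")
  writeLines("id", empty)
  expect_error(read_panel_csv(empty))
  expect_error(read_panel_csv(path, id_col = "nope"), "missing mapped")
})

test_that("panel CSV round-trips through write_panel_csv", {
  set.seed(11)
  raw1 <- matrix(sample(0:3, 60, replace = TRUE), 6, 10)
  raw2 <- matrix(sample(0:3, 60, replace = TRUE), 6, 10)
  panel <- symptom_panel(raw1, raw2, subject_id = sprintf("p%02d", 1:6))
  path <- tempfile(fileext = ".csv")
  write_panel_csv(panel, path)
  back <- read_panel_csv(path)$panel
  expect_equal(unname(back$wave1_raw), unname(raw1))
  expect_equal(unname(back$wave2_raw), unname(raw2))
  expect_equal(back$subject_id, panel$subject_id)
})

test_that("network serialization round-trips exactly", {
  W <- random_weights(10, seed = 3)
  net <- ising_network(W, thresholds = rnorm(10),
                       estimation_meta = list(gamma = 0.5))
  path <- tempfile(fileext = ".csv")
  write_network(net, path)
  back <- read_network(path)
  expect_identical(back$weights, net$weights)
  expect_identical(back$thresholds, net$thresholds)

  # zero network
  z <- ising_network(matrix(0, 10, 10), thresholds = rep(0, 10))
  write_network(z, path)
  expect_identical(read_network(path)$weights, z$weights)

  # asymmetric CLPN matrix preserved exactly
  set.seed(4)
  B <- matrix(rnorm(100), 10, 10)
  cn <- clpn_network(B, intercepts = rnorm(10), fold_seed = 9L)
  write_network(cn, path)
  back2 <- read_network(path)
  expect_identical(back2$coefficients, cn$coefficients)
  expect_identical(back2$intercepts, cn$intercepts)
  expect_s3_class(back2, "clpn_network")
})

test_that("reading a network with tampered labels fails", {
  net <- ising_network(random_weights(4, seed = 5), thresholds = rep(0, 4),
                       item_labels = c("a", "b", "c", "d"))
  path <- tempfile(fileext = ".csv")
  write_network(net, path)
  df <- read.csv(path, check.names = FALSE)
  df$item[1] <- "z"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_network(path), "label mismatch")
})
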