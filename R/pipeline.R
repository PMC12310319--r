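#' Default pipeline configuration
#'
#' Analysis defaults for the full two-wave pipeline: EBIC gamma 0.5, AND
#' symmetrisation, 1000 bootstrap replicates, 10 CV folds, 1000
#' permutations, case-dropping grid up to 0.75.  Override any entry through
#' the `config` argument of [run_pipeline()].
#'
#' @return A named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    gamma = 0.5,
    rule = "and",
    n_lambda = 100,
    lambda_min_ratio = 0.01,
    standardize = FALSE,
    boots = 1000,
    cs_boots = NULL,  # defaults to `boots`
    k_folds = 10,
    clpn_rule = "1se",
    n_perm = 1000,
    paired = FALSE,
    cs_grid_max = 0.75,
    cs_threshold_r = 0.7,
    cs_confidence = 0.95,
    mcnemar_correction = FALSE)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(pipeline_defaults(), config)
  cfg
}

#' Run the full two-wave network analysis pipeline
#'
#' Orchestrates every stage in order: data ingestion (CSV panel or simulated
#' preset), recoding, descriptive change tests, cross-sectional Ising
#' network per wave, bootstrap accuracy and case-dropping stability,
#' between-wave comparison, cross-lagged panel network, and centrality
#' tables.  All outputs are written as CSV/JSON under `out_dir` together
#' with a reproducibility manifest (seeds, parameter echo, drop counts,
#' stage timings).  Outputs are a pure function of the input data and the
#' configuration.
#'
#' @param config a named list or a YAML file path.  Recognised keys include
#'   everything in [pipeline_defaults()] plus either `input_csv` (with
#'   optional column-mapping keys of [read_panel_csv()]) or `simulate` (a
#'   list with `n` and optional `seed`) to run on the bundled synthetic
#'   preset; `raw_likert = FALSE` declares the CSV already binary.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    res
  }

  n_dropped <- 0L
  dat <- stage("ingest", {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      if (is.null(sim$n)) stop("config key simulate$n is required")
      params <- two_wave_preset(seed = sim$preset_seed %||% 2020)
      sample_two_wave(params, n = sim$n, seed = sim$seed %||% cfg$seed)
    } else if (!is.null(cfg$input_csv)) {
      args <- cfg[intersect(names(cfg),
                            c("id_col", "wave1_cols", "wave2_cols"))]
      rd <- do.call(read_panel_csv, c(list(path = cfg$input_csv), args))
      n_dropped <- rd$n_dropped
      if (isFALSE(cfg$raw_likert)) {
        list(wave1 = binary_symptoms(1 * (rd$panel$wave1_raw > 0),
                                     rd$panel$item_labels, "wave1"),
             wave2 = binary_symptoms(1 * (rd$panel$wave2_raw > 0),
                                     rd$panel$item_labels, "wave2"))
      } else {
        recode_cesd(rd$panel)
      }
    } else {
      stop("config must provide either 'input_csv' or 'simulate'")
    }
  })
  w1 <- dat$wave1; w2 <- dat$wave2

  desc <- stage("describe", {
    tab <- paired_change_table(w1, w2, correction = cfg$mcnemar_correction)
    tab$wave1_pct <- round(tab$wave1_pct, 2)
    tab$wave2_pct <- round(tab$wave2_pct, 2)
    write.csv(tab, file.path(out_dir, "descriptives.csv"), row.names = FALSE)
    tab
  })

  nets <- stage("ising", {
    n1 <- fit_ising(w1, gamma = cfg$gamma, rule = cfg$rule,
                    n_lambda = cfg$n_lambda,
                    lambda_min_ratio = cfg$lambda_min_ratio,
                    standardize = cfg$standardize)
    n2 <- fit_ising(w2, gamma = cfg$gamma, rule = cfg$rule,
                    n_lambda = cfg$n_lambda,
                    lambda_min_ratio = cfg$lambda_min_ratio,
                    standardize = cfg$standardize)
    write_network(n1, file.path(out_dir, "ising_wave1.csv"))
    write_network(n2, file.path(out_dir, "ising_wave2.csv"))
    list(wave1 = n1, wave2 = n2)
  })

  cent <- stage("centrality", {
    ct <- rbind(cbind(wave = "wave1", strength(nets$wave1)),
                cbind(wave = "wave1", expected_influence(nets$wave1)),
                cbind(wave = "wave1", closeness_betweenness(nets$wave1)),
                cbind(wave = "wave2", strength(nets$wave2)),
                cbind(wave = "wave2", expected_influence(nets$wave2)),
                cbind(wave = "wave2", closeness_betweenness(nets$wave2)))
    write.csv(ct, file.path(out_dir, "centrality_cross_sectional.csv"),
              row.names = FALSE)
    ct
  })

  est <- function(mm) fit_ising(mm, gamma = cfg$gamma, rule = cfg$rule,
                                n_lambda = cfg$n_lambda,
                                lambda_min_ratio = cfg$lambda_min_ratio,
                                standardize = cfg$standardize)
  stab <- stage("stability", {
    seeds <- derive_seeds(cfg$seed, 4L)
    boot1 <- bootstrap_edges(w1, est, B = cfg$boots, seed = seeds[1])
    boot2 <- bootstrap_edges(w2, est, B = cfg$boots, seed = seeds[2])
    grid <- seq(0.05, cfg$cs_grid_max, by = 0.05)
    cs_b <- cfg$cs_boots %||% cfg$boots
    cs1 <- cs_coefficient(w1, est, grid = grid, B = cs_b,
                          threshold_r = cfg$cs_threshold_r,
                          confidence = cfg$cs_confidence, seed = seeds[3])
    cs2 <- cs_coefficient(w2, est, grid = grid, B = cs_b,
                          threshold_r = cfg$cs_threshold_r,
                          confidence = cfg$cs_confidence, seed = seeds[4])
    write.csv(rbind(cbind(wave = "wave1", boot1$edges),
                    cbind(wave = "wave2", boot2$edges)),
              file.path(out_dir, "bootstrap_edges.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(cs_strength_wave1 = cs1$cs, cs_strength_wave2 = cs2$cs,
           threshold_r = cfg$cs_threshold_r, confidence = cfg$cs_confidence,
           B = cs_b),
      file.path(out_dir, "cs_coefficients.json"),
      auto_unbox = TRUE, digits = NA)
    list(boot1 = boot1, boot2 = boot2, cs1 = cs1, cs2 = cs2)
  })

  comp <- stage("compare", {
    seeds <- derive_seeds(cfg$seed + 1L, 1L)
    res <- invariance_test(w1, w2, est, n_perm = cfg$n_perm,
                           paired = cfg$paired, seed = seeds[1])
    jsonlite::write_json(
      res[c("M", "p_M", "S1", "S2", "delta_S", "p_S", "phi", "rho",
            "n_perm", "paired")],
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
    res
  })

  clpn <- stage("clpn", {
    net <- fit_clpn(w1, w2, seed = cfg$seed, k_folds = cfg$k_folds,
                    rule = cfg$clpn_rule, n_lambda = cfg$n_lambda,
                    lambda_min_ratio = cfg$lambda_min_ratio,
                    standardize = cfg$standardize)
    write_network(net, file.path(out_dir, "clpn.csv"))
    ei <- out_in_ei(net)
    write.csv(ei, file.path(out_dir, "centrality_clpn.csv"),
              row.names = FALSE)
    list(network = net, ei = ei)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("symptomnet")),
    r_version = R.version.string,
    config = cfg[setdiff(names(cfg), "simulate")],
    simulate = cfg$simulate,
    n_subjects = nrow(w1),
    n_dropped = n_dropped,
    stage_seconds = timings,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(data = dat, descriptives = desc, networks = nets,
                 centrality = cent, stability = stab, comparison = comp,
                 clpn = clpn, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
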