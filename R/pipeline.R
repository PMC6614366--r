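#' Two-sided Wilcoxon rank-sum comparison of score groups
#'
#' Used to compare high- versus low-predicted-synergy groups of
#' experimental scores. Degenerate all-tied input returns p = 1 with a
#' warning instead of erroring.
#'
#' @param x,y numeric score vectors (>= 3 observations each).
#' @return list with \code{p.value} and \code{statistic}.
#' @export
compareGroups <- function(x, y) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  if (length(unique(c(x, y))) == 1) {
    warning("degenerate comparison: all observations tied")
    return(list(p.value = 1, statistic = NA_real_))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  list(p.value = wt$p.value, statistic = unname(wt$statistic))
}

defaultPipelineConfig <- function() {
  list(
    seed = 1,
    fold_timma = 50, fold_deconv = 10, expr_min_log2 = 6, d_threshold = 1,
    max_size = 8,
    stages = list(predict = TRUE, score = TRUE, deconvolve = TRUE,
                  simulate = FALSE),
    screen = list(n_drugs = 41, n_kinases = 385, n_essential = 3,
                  rule = "OR", sigma = 0.05),
    surface = list(delta = 5, sigma = 3, n = 8),
    simulate = list(n_runs = 3, t_end = 150, window = 50,
                    n_cells = 6, cap = 100))
}

#' Run the polypharmacology pipeline end to end
#'
#' Orchestrates the four analysis stages on synthetic inputs with planted
#' ground truth: (1) predict - fit the TIMMA model to a generated kinome
#' screen and score all drug combinations; (2) score - generate
#' dose-response surfaces for the top and bottom predicted combinations
#' and compute their Bliss scores, comparing groups by rank-sum test;
#' (3) deconvolve - build the target-pair catalog for the two top
#' combinations; (4) simulate (off by default; heavier) - demo-motif
#' silencing experiments. Thresholds and sizes live in a single config
#' (YAML file or list), and a JSON manifest records the config hash,
#' seeds and output checksums so reruns are byte-reproducible.
#'
#' @param config path to a YAML config or a named list; omitted entries
#'   fall back to defaults.
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly; stage outputs are written to
#'   \code{outDir}.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("polysynergy")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaultPipelineConfig(), config)
  stopifnot(cfg$fold_timma >= 1, cfg$fold_deconv >= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(obj, name) {
    p <- file.path(outDir, name)
    writeResults(obj, p)
    outputs <<- c(outputs, p)
    p
  }
  results <- list()

  if (isTRUE(cfg$stages$predict)) {
    scr <- genScreen(cfg$screen$n_drugs, cfg$screen$n_kinases,
                     cfg$screen$n_essential, rule = cfg$screen$rule,
                     sigma = cfg$screen$sigma, seed = cfg$seed)
    model <- fitTimmaModel(scr$kd, scr$dss, fold = cfg$fold_timma,
                           maxSize = cfg$max_size, seed = cfg$seed)
    combos <- predictAllCombinations(model)
    combos <- combos[order(-combos$synergy), ]
    emit(scr$kd, "kd_matrix.csv")
    emit(model, "timma_model.json")
    emit(combos, "predicted_combinations.csv")
    results$model <- model
    results$combos <- combos
    results$screen <- scr
  }

  if (isTRUE(cfg$stages$score) && !is.null(results$combos)) {
    combos <- results$combos
    nTop <- min(10, nrow(combos) %/% 2)
    planted <- c(rep(cfg$surface$delta, nTop), rep(0, nTop))
    sel <- rbind(utils::head(combos, nTop), utils::tail(combos, nTop))
    scores <- vapply(seq_len(nrow(sel)), function(i) {
      m <- genSurface(delta = planted[i], sigma = cfg$surface$sigma,
                      n = cfg$surface$n, seed = cfg$seed + i)
      blissScore(m)$score
    }, numeric(1))
    scored <- data.frame(drug1 = sel$drug1, drug2 = sel$drug2,
                         predicted = sel$synergy, bliss = scores,
                         group = rep(c("high", "low"), each = nTop))
    cmp <- compareGroups(scores[seq_len(nTop)], scores[-seq_len(nTop)])
    scored$rank_sum_p <- cmp$p.value
    emit(scored, "bliss_scores.csv")
    results$scored <- scored
  }

  if (isTRUE(cfg$stages$deconvolve) && !is.null(results$combos)) {
    scr <- results$screen
    expr <- data.frame(gene = kinaseNames(scr$kd),
                       log2_expression = 8)          # all expressed
    top <- utils::head(results$combos, 2)
    catalog <- tryCatch(
      pairCatalog(c(top$drug1[1], top$drug2[1]),
                  c(top$drug1[2], top$drug2[2]),
                  scr$kd, expr, fold = cfg$fold_deconv,
                  minLog2 = cfg$expr_min_log2),
      error = function(e) NULL)
    if (!is.null(catalog)) {
      emit(catalog, "target_pair_catalog.csv")
      results$catalog <- catalog
    }
  }

  if (isTRUE(cfg$stages$simulate)) {
    sys <- demoSignalingModel()
    sim <- cfg$simulate
    viab <- list()
    ctrl <- NULL
    for (combo in list("AURKB", "ZAK", c("AURKB", "ZAK"),
                       c("AURKB", "CSF1R"))) {
      kx <- knockoutExperiment(sys, combo, nRuns = sim$n_runs,
                               tEnd = sim$t_end, window = sim$window,
                               nCells = sim$n_cells, cap = sim$cap,
                               seed = cfg$seed, control = ctrl)
      ctrl <- kx$control_counts
      viab[[paste(combo, collapse = "+")]] <- kx$viability
    }
    p <- file.path(outDir, "silencing_viability.json")
    jsonlite::write_json(viab, p, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, p)
    results$viability <- viab
  }

  manifest <- list(
    config = cfg,
    config_hash = digestConfig(cfg),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))))
  mp <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest, outDir = outDir)))
}

# Stable hash of the (sorted, serialized) config list.
digestConfig <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
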