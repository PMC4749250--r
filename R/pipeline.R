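#' Configuration for the end-to-end pipeline
#'
#' Bundles the per-stage settings of the simulate -> infer -> scan ->
#' selection-coefficient pipeline.  Defaults use the reduced simulation
#' scale of [sim_config_reduced()] and the study's phasing switch-error
#' rates (2% for the cohort and the Amerindian-proxy training panel, 1%
#' for the European/African-proxy panels).
#'
#' @param sim a [sim_config()] for the simulation stage.
#' @param panel_opts options for [generate_source_panels()]
#'   (`n_haps_per_pop`, `differentiation`, `n_founders`, `switch_rate`).
#' @param phase_errors list with `cohort` (rate) and `training` (vector of
#'   per-population rates); `NULL` rates disable injection.
#' @param drop_training character vector of training-panel names withheld
#'   from inference (partial mode), e.g. `"AMR"`.
#' @param model options for [two_layer_fit()] (`n_lower`, `em_steps`,
#'   `em_runs`, `w_t`, `w_c`, `lambda`).
#' @param scan options: `families` (family map or `NULL`), `threshold`
#'   (explicit region dosage threshold; `NULL` = adaptive midway rule),
#'   `margin` (minimum peak excess over the genome-wide median, dosage
#'   units, below which no region is called), `smooth_window` (markers in
#'   the running mean used by the region rule; `NULL` = automatic).
#' @param selcoef options: `models`, `epsilon`.
#' @param seed global seed; every stochastic stage derives from it.
#' @param out_dir optional output directory; when set, every stage
#'   persists its artifacts there.
#' @param verbose stage-tagged progress on stderr.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config_reduced(),
                            panel_opts = list(),
                            phase_errors = list(
                              cohort = 0.02,
                              training = c(AMR = 0.02, EUR = 0.01,
                                           AFR = 0.01)),
                            drop_training = character(0),
                            model = list(),
                            scan = list(families = NULL, threshold = NULL,
                                        margin = 0.10, smooth_window = NULL),
                            selcoef = list(models = c("simple", "dominance",
                                                      "additive"),
                                           epsilon = 1e-8),
                            seed = 1, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(sim, "sim_config"))
  panel_opts <- utils::modifyList(
    list(n_haps_per_pop = 600, differentiation = 0.12,
         n_founders = 20, switch_rate = 100), panel_opts)
  model <- utils::modifyList(
    list(n_lower = 15, em_steps = 20, em_runs = 10,
         w_t = 1, w_c = NULL, lambda = 100), model)
  scan <- utils::modifyList(list(families = NULL, threshold = NULL,
                                 margin = 0.10, smooth_window = NULL), scan)
  selcoef <- utils::modifyList(
    list(models = c("simple", "dominance", "additive"), epsilon = 1e-8),
    selcoef)
  if (panel_opts$n_haps_per_pop <= sim$n_training_haps_per_pop)
    stop("source panels must exceed the training set-aside")
  structure(list(sim = sim, panel_opts = panel_opts,
                 phase_errors = phase_errors,
                 drop_training = drop_training, model = model,
                 scan = scan, selcoef = selcoef, seed = seed,
                 out_dir = out_dir, verbose = verbose),
            class = "pipeline_config")
}

stage_log <- function(config, stage, msg) {
  if (isTRUE(config$verbose))
    message(sprintf("[%s] %s", stage, msg))
}

#' Run the full simulate -> infer -> scan -> selcoef pipeline
#'
#' Simulates an admixed cohort under selection (or ingests a user-supplied
#' cohort), injects phasing switch errors, infers local ancestry dosages
#' with [two_layer_fit()], scans average dosages, calls the selected
#' region, and estimates the selection coefficient under each configured
#' model.  All artifacts and a reproducibility record (seed, package
#' version, configuration hash) are collected in the returned report and,
#' when `out_dir` is set, written to disk.
#'
#' When no explicit scan threshold is configured, the region rule runs on
#' a lightly smoothed copy of the selected ancestry's average-dosage track
#' (the selected region spans many consecutive markers, single-marker
#' spikes are inference noise): if the smoothed peak exceeds the
#' genome-wide median by less than `scan$margin` (dosage units) the report
#' says no positive-selection signal; otherwise all markers above the
#' midpoint of median and peak are called, and `p1` is the smoothed peak.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built `admixed_cohort` or cohort panel
#'   (skips the simulate stage).
#' @param training optional named list of training [haplotype_panel()]s
#'   (required if `cohort` is not an `admixed_cohort`).
#' @return An object of class `admixsel_report`.
#' @export
run_pipeline <- function(config, cohort = NULL, training = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  # hash covers the scientific configuration, not where it is written
  hash <- config_hash(unclass(config)[setdiff(names(config),
                                              c("out_dir", "verbose"))])
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)

  # --- simulate ---
  if (is.null(cohort)) {
    stage_log(config, "simulate", "generating source panels and cohort")
    panels <- do.call(generate_source_panels, c(
      list(n_markers = n_markers_of(config$sim),
           region_length = config$sim$region_length,
           cm_per_mb = config$sim$cm_per_mb),
      config$panel_opts))
    cohort <- simulate_admixture(panels, config$sim)
  }
  if (inherits(cohort, "admixed_cohort")) {
    if (is.null(training)) training <- cohort$training
    truth <- truth_dosages(cohort)
  } else truth <- NULL

  # --- switch errors ---
  pe <- config$phase_errors
  if (!is.null(pe$cohort) && pe$cohort > 0 &&
      inherits(cohort, "admixed_cohort")) {
    stage_log(config, "simulate",
              sprintf("injecting %.1f%% cohort switch errors",
                      100 * pe$cohort))
    cohort <- inject_switch_errors(cohort, pe$cohort)
  }
  if (!is.null(pe$training) && length(training)) {
    for (nm in names(training)) {
      r <- pe$training[nm]
      if (!is.na(r) && r > 0)
        training[[nm]] <- inject_switch_errors(training[[nm]], r)
    }
  }

  # --- infer ---
  use_training <- training[setdiff(names(training), config$drop_training)]
  stage_log(config, "infer",
            sprintf("fitting two-layer model (%d panels)",
                    length(use_training)))
  fit_seed <- sample.int(.Machine$integer.max, 1)
  fit <- do.call(two_layer_fit, c(
    list(cohort = cohort, training = use_training, n_upper = 3,
         generations = config$sim$generations,
         ancestries = if (inherits(cohort, "admixed_cohort"))
           cohort$ancestries else NULL,
         seed = fit_seed, verbose = config$verbose),
    config$model))

  # --- scan ---
  stage_log(config, "scan", "averaging dosages and standardizing")
  avg <- average_dosages(fitted(fit), config$scan$families)
  markers <- fit$markers
  scan <- zscan(avg, markers = markers)
  sel_name <- fit$ancestries[config$sim$selected_ancestry]
  if (!sel_name %in% colnames(avg)) sel_name <- colnames(avg)[3]

  # region rule: work on a lightly smoothed track, since the selected
  # region spans many consecutive markers while single-marker spikes are
  # inference noise; require a minimum peak excess before calling anything
  w <- config$scan$smooth_window
  if (is.null(w)) w <- max(5, 2 * (nrow(avg) %/% 120) + 1)
  track <- stats::filter(avg[, sel_name], rep(1 / w, w), sides = 2)
  track[is.na(track)] <- avg[is.na(track), sel_name]
  track <- as.numeric(track)
  thr <- config$scan$threshold
  med <- stats::median(track)
  peak <- max(track)
  signal <- TRUE
  if (is.null(thr)) {
    if (peak - med < config$scan$margin) {
      signal <- FALSE
      thr <- peak  # nothing exceeds it
    } else thr <- (med + peak) / 2
  }
  region <- call_region(cbind(track), 1, thr)
  region$ancestry <- sel_name
  if (!length(region$markers)) signal <- FALSE

  # --- selcoef ---
  sel_fits <- NULL
  phenotype <- NULL
  if (signal) {
    p0 <- scan$mean[sel_name]
    p1 <- max(track[region$markers])
    stage_log(config, "selcoef",
              sprintf("p0 = %.4f, p1 = %.4f", p0, p1))
    sel_fits <- lapply(config$selcoef$models, function(m)
      solve_s(p0, p1, n = config$sim$generations, model = m,
              epsilon = config$selcoef$epsilon))
    names(sel_fits) <- config$selcoef$models
    phenotype <- define_phenotype(fitted(fit), region, sel_name)
  } else {
    stage_log(config, "selcoef", "no positive-selection signal")
  }

  report <- structure(list(
    fit = fit, scan = scan, region = region, signal = signal,
    selection = sel_fits, phenotype = phenotype,
    truth = truth, selected_ancestry = sel_name,
    p0 = if (signal) unname(scan$mean[sel_name]) else NA_real_,
    p1 = if (signal) max(track[region$markers]) else NA_real_,
    seed = config$seed, config_hash = hash,
    package_version = as.character(utils::packageVersion("admixsel")),
    config = config), class = "admixsel_report")

  if (!is.null(out)) {
    stage_log(config, "write", paste("writing artifacts to", out))
    write_dosages(fitted(fit), markers, file.path(out, "dosages.tsv"),
                  stage = "infer", config_hash = hash)
    con <- file(file.path(out, "scan.tsv"), "w")
    writeLines(sprintf("# admixsel stage=scan config=%s", hash), con)
    tab <- data.frame(id = markers$id, avg, z = scan$z,
                      check.names = FALSE)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    summ <- list(stage = "report", config_hash = hash, seed = config$seed,
                 mean = as.list(scan$mean), ssd = as.list(scan$ssd),
                 signal = signal,
                 region = if (signal) as.list(region$range) else NULL,
                 p0 = report$p0, p1 = report$p1,
                 s_hat = if (signal)
                   lapply(sel_fits, function(f) f$s_hat) else NULL)
    jsonlite::write_json(summ, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.admixsel_report <- function(x, ...) {
  cat("admixsel pipeline report\n")
  cat(sprintf("  seed %d, config %s\n", x$seed, x$config_hash))
  cat(sprintf("  selected ancestry: %s\n", x$selected_ancestry))
  if (!x$signal) {
    cat("  no positive-selection signal\n")
    return(invisible(x))
  }
  cat(sprintf("  region: markers %d-%d (%s)\n", x$region$range[1],
              x$region$range[2],
              if (x$region$contiguous) "contiguous" else "fragmented"))
  cat(sprintf("  p0 = %.4f (genome-wide mean), p1 = %.4f (peak)\n",
              x$p0, x$p1))
  for (m in names(x$selection))
    cat(sprintf("  s_hat (%s) = %.3f\n", m, x$selection[[m]]$s_hat))
  invisible(x)
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [pipeline_config()]; `sim` keys mirror
#' [sim_config()].
#'
#' @param path file path (`.yaml`/`.yml` needs the yaml package, `.json`
#'   uses jsonlite).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(pipeline_config, raw)
}
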