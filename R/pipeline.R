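# End-to-end orchestration: simulate (or read real-schema input), build
# networks, compute metrics and exposures, fit the participation models,
# run the threshold sweep, and write all artifacts with a manifest.

#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `sim` (a [sim_config()]) or the three input paths must be
#' given.
#'
#' @param sim a [sim_config()] for simulate mode.
#' @param billing_path,physicians_path,hospitals_path delimited input files
#'   matching the schemas written by [write_study()].
#' @param physician_window date window for the shared-patient physician
#'   network (defaults to the simulation window in simulate mode, calendar
#'   2019 otherwise).
#' @param hospital_window date window for the shared-physician hospital
#'   network (defaults to the physician window in simulate mode,
#'   2020-03-01..2021-05-31 otherwise).
#' @param a_low,mode binarization threshold and comparison mode.
#' @param cutoffs threshold sweep cutoffs.
#' @param transform across-exposure transform.
#' @param out_dir output directory.
#' @param seed root seed recorded in outputs (drives simulation in
#'   simulate mode).
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = NULL, billing_path = NULL,
                       physicians_path = NULL, hospitals_path = NULL,
                       physician_window = NULL, hospital_window = NULL,
                       a_low = 0, mode = "strict",
                       cutoffs = c(1, 10, 50, 100, 500, 1000),
                       transform = "ln1p-percent",
                       out_dir = "peernet-run", seed = 1L) {
  simulate_mode <- !is.null(sim)
  paths_given <- !is.null(billing_path)
  if (simulate_mode == paths_given)
    stopf("configuration error: give exactly one of 'sim' or input paths")
  if (paths_given && (is.null(physicians_path) || is.null(hospitals_path)))
    stopf("configuration error: physicians_path and hospitals_path required")
  if (simulate_mode) {
    sim$seed <- as.integer(seed)
    if (is.null(physician_window)) physician_window <- sim$window
    if (is.null(hospital_window)) hospital_window <- sim$window
  } else {
    if (is.null(physician_window))
      physician_window <- c("2019-01-01", "2019-12-31")
    if (is.null(hospital_window))
      hospital_window <- c("2020-03-01", "2021-05-31")
  }
  out <- list(sim = sim, billing_path = billing_path,
              physicians_path = physicians_path,
              hospitals_path = hospitals_path,
              physician_window = as_date_window(physician_window),
              hospital_window = as_date_window(hospital_window),
              a_low = a_low, mode = mode, cutoffs = cutoffs,
              transform = transform, out_dir = out_dir,
              seed = as.integer(seed))
  class(out) <- "run_config"
  out
}

write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full participation-network pipeline
#'
#' Executes the stages in order — input (simulate or read), physician and
#' hospital network construction, network metrics, exposures, univariate
#' screen, participation models, threshold sweep — writing each artifact to
#' the output directory, and finishes with a JSON manifest recording the
#' seed, per-stage timings and status, and MD5 hashes of every output. A
#' stage failure is recorded in the manifest (and stops dependent stages);
#' partial outputs are retained.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, simulate_mode = !is.null(config$sim),
                   stages = list(), outputs = character(0))
  env <- new.env()
  failed <- FALSE

  stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      fun()
      list(status = "ok")
    }, error = function(e) list(status = "error",
                                error = conditionMessage(e)))
    res$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    manifest$stages[[name]] <<- res
    if (res$status == "error") failed <<- TRUE
    invisible(NULL)
  }
  out_path <- function(f) file.path(config$out_dir, f)

  stage("input", function() {
    if (!is.null(config$sim)) {
      study <- simulate_study(config$sim)
      write_study(study, out_path("input"))
      env$billing <- study$billing
      env$physicians <- study$physicians
      env$hospitals <- study$hospitals
    } else {
      env$billing <- read_billing(config$billing_path)
      env$physicians <- read.csv(config$physicians_path,
                                 stringsAsFactors = FALSE)
      env$hospitals <- read.csv(config$hospitals_path,
                                stringsAsFactors = FALSE)
    }
  })

  stage("physician_network", function() {
    records <- filter_window(env$billing, config$physician_window)
    env$Z <- build_encounter_matrix(records)
    env$A <- project_shared_patients(env$Z, "shared-count")
    env$B <- binarize(env$A, config$a_low, config$mode)
    env$attribution <- attribute_physicians(records)
    write_edge_list(env$B, out_path("physician_network_edges.csv"))
    write_graphml(env$B, out_path("physician_network.graphml"))
  })

  stage("hospital_network", function() {
    env$hospital_net <- build_hospital_network(env$billing,
                                               config$hospital_window)
    write_edge_list(env$hospital_net,
                    out_path("hospital_network_edges.csv"))
  })

  stage("metrics", function() {
    env$metrics <- network_metrics(env$B, env$attribution)
    write_table(env$metrics, out_path("network_metrics.csv"))
    env$subdens <- subnetwork_density(env$B, env$attribution)
    write_table(env$subdens$per_hospital,
                out_path("subnetwork_density.csv"))
  })

  stage("exposures", function() {
    y <- setNames(env$physicians$participated,
                  env$physicians$physician_id)
    steps <- setNames(env$hospitals$step, env$hospitals$hospital_id)
    env$exposures <- exposure_table(env$B, env$attribution, y, steps,
                                    transform = config$transform)
    write_table(env$exposures, out_path("exposures.csv"))
    env$analysis <- merge(
      cbind(env$physicians[c("physician_id", "age", "sex",
                             "years_org", "participated")],
            derive_covariates(env$physicians)),
      env$exposures, by = "physician_id")
  })

  stage("univariate", function() {
    rep_ <- univariate_tests(
      env$analysis, outcome = "participated",
      continuous = c("age", "years_org", "n_sites", "H", "within_degree",
                     "across_degree", "wy_wi", "wy_ac"),
      categorical = "sex")
    write_table(as.data.frame(rep_), out_path("univariate.csv"))
  })

  stage("models", function() {
    d <- env$analysis
    fits <- list(
      network_fixed = fit_participation(
        model_spec(c("H", "wy_wi", "wy_ac_trans", "H:wy_ac_trans")), d),
      # simultaneity default: within exposure excluded under a hospital
      # random intercept
      network_random = fit_participation(
        model_spec(c("H", "wy_ac_trans", "H:wy_ac_trans"),
                   random_intercept = "primary_hospital_id"), d),
      physician_fixed = fit_participation(
        model_spec(c("age", "years_c")), d))
    env$fits <- fits
    write_table(render_tables(fits), out_path("model_tables.csv"))
  })

  stage("threshold_sweep", function() {
    sweep <- threshold_sweep(env$A, env$attribution, config$cutoffs,
                             mode = config$mode)
    write_table(as.data.frame(sweep), out_path("threshold_sweep.csv"))
  })

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, out_path("manifest.json"))
  manifest$outputs <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render fitted models as formatted result tables
#'
#' Formats odds ratios to 2 decimals, confidence intervals as "(lo, hi)",
#' and p-values with the "<0.01" convention.
#'
#' @param fits a named list of `peer_fit` objects (or a single fit).
#' @return data.frame with model, term, OR, `95% CI`, p columns (empty but
#'   with a header when no fits are given).
#' @export
render_tables <- function(fits) {
  if (inherits(fits, "peer_fit")) fits <- list(model = fits)
  empty <- data.frame(model = character(0), term = character(0),
                      OR = character(0), `95% CI` = character(0),
                      p = character(0), check.names = FALSE)
  if (length(fits) == 0) return(empty)
  fmt_p <- function(p) ifelse(p < 0.01, "<0.01", sprintf("%.2f", p))
  rows <- lapply(names(fits), function(nm) {
    ct <- fits[[nm]]$coefficients
    ct <- ct[ct$term != "(Intercept)", , drop = FALSE]
    data.frame(model = nm, term = ct$term,
               OR = sprintf("%.2f", ct$or),
               `95% CI` = sprintf("(%.2f, %.2f)", ct$ci_low, ct$ci_high),
               p = fmt_p(ct$p_value),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty), rows))
  rownames(out) <- NULL
  out
}
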