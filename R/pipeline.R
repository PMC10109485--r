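#' Run the full analysis pipeline
#'
#' End-to-end orchestration: design of experiments over the operating
#' domain, batch indicator evaluation, surrogate training with validation
#' metrics, interval uncertainty analysis of the unoptimized condition, and
#' the reliability-level sweep of the interval optimization.  Every
#' intermediate artifact is written as plain CSV/JSON so the run is
#' inspectable and diffable, and a manifest records the configuration and
#' seeds needed to reproduce it exactly.
#'
#' All randomness flows from the single `seed`: the design uses `seed`, the
#' validation design `seed + 1`, and the per-level optimizer seeds are
#' derived inside [rpdi_sweep()] from `seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param simulator `"pseudo"` for the closed-form pseudo-simulator or
#'   `"pde"` for the finite-volume Pennes solver.
#' @param n_train,n_valid Training / validation design sizes.
#' @param seed Root seed.
#' @param lambdas Reliability levels for the sweep.
#' @param allowable Allowable skin surface temperature, deg C.
#' @param base_config [simulation_config()] for the PDE backend (ignored
#'   for the pseudo backend); pass a coarse grid here to trade accuracy for
#'   speed.
#' @param ga_pop,ga_generations Outer GA settings for the sweep.
#' @return Invisibly, a list with the in-memory artifacts (`design`,
#'   `responses`, `model`, `metrics`, `uq`, `sweep`, `manifest`).
#' @examples
#' \donttest{
#' run <- run_pipeline(tempfile("moxirun"), simulator = "pseudo",
#'                     ga_pop = 16, ga_generations = 20)
#' run$sweep
#' }
#' @export
run_pipeline <- function(out_dir, simulator = c("pseudo", "pde"),
                         n_train = 50L, n_valid = 20L, seed = 42L,
                         lambdas = c(0.8, 0.9, 1.0, 1.1),
                         allowable = 45.5,
                         base_config = simulation_config(dr = 1, dz = 1,
                                                         dt = 2),
                         ga_pop = 40L, ga_generations = 100L) {
  simulator <- match.arg(simulator)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  sim_fn <- switch(simulator,
                   pseudo = simulator_pseudo(make_pseudo_simulator(seed)),
                   pde = simulator_pde(base_config))
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  design <- stage("doe", latin_hypercube(n_train, seed = seed))
  write.csv(design, file.path(out_dir, "design.csv"), row.names = FALSE)

  responses <- stage("evaluate", evaluate_responses(design, sim_fn))
  write.csv(responses, file.path(out_dir, "responses.csv"),
            row.names = FALSE)

  model <- stage("train", rbnn(design, responses[, c("HPM", "ST")]))
  rbnn_to_json(model, file.path(out_dir, "model.json"))

  vdesign <- stage("validate", latin_hypercube(n_valid, seed = seed + 1L))
  vresp <- stage("validate", evaluate_responses(vdesign, sim_fn))
  vpred <- predict(model, vdesign)
  metrics <- list(
    HPM = fit_metrics(vresp$HPM, vpred[, "HPM"]),
    ST = fit_metrics(vresp$ST, vpred[, "ST"])
  )
  jsonlite::write_json(
    lapply(metrics, function(m) m[c("RE", "RMSE", "R2", "SSE", "SST", "k")]),
    file.path(out_dir, "metrics.json"), digits = NA, auto_unbox = TRUE)

  uq <- stage("uq", analyze_uncertainty(model, allowable = allowable,
                                        seed = seed))
  jsonlite::write_json(list(
    HPM = unclass(uq$HPM)[1:2], ST = unclass(uq$ST)[1:2],
    allowable = uq$allowable, reliable = uq$reliable, rpdi = uq$rpdi
  ), file.path(out_dir, "uq_report.json"), digits = NA, auto_unbox = TRUE)

  problem <- interval_problem(model, allowable = allowable)
  sweep_tab <- stage("sweep", rpdi_sweep(problem, lambdas, seed = seed,
                                         pop = ga_pop,
                                         generations = ga_generations))
  write.csv(as.data.frame(sweep_tab)[
    , c("lambda", "ST_lo", "ST_hi", "HPM_lo", "HPM_hi")],
    file.path(out_dir, "sweep.csv"), row.names = FALSE)

  manifest <- list(
    package = "moxiopt",
    version = as.character(utils::packageVersion("moxiopt")),
    simulator = simulator, n_train = n_train, n_valid = n_valid,
    seed = seed, lambdas = lambdas, allowable = allowable,
    ga = list(pop = ga_pop, generations = ga_generations),
    wall_clock_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(design = design, responses = responses, model = model,
                 metrics = metrics, uq = uq, sweep = sweep_tab,
                 manifest = manifest))
}

#' Summarize the artifacts of a pipeline run
#'
#' Renders a human-readable summary of a [run_pipeline()] output directory:
#' the surrogate accuracy block (relative-error range and R-squared per
#' indicator) and the reliability-sweep comparison table.  Missing
#' artifacts are listed, not fatal.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return Invisibly, a list of parsed artifacts.
#' @export
moxi_report <- function(out_dir) {
  parsed <- list()
  missing <- character()
  grab <- function(file, reader) {
    path <- file.path(out_dir, file)
    if (!file.exists(path)) { missing <<- c(missing, file); return(NULL) }
    reader(path)
  }
  parsed$metrics <- grab("metrics.json",
                         function(p) jsonlite::read_json(p,
                                                         simplifyVector = TRUE))
  parsed$uq <- grab("uq_report.json",
                    function(p) jsonlite::read_json(p, simplifyVector = TRUE))
  parsed$sweep <- grab("sweep.csv", read.csv)
  if (length(parsed) == 0 || all(vapply(parsed, is.null, logical(1)))) {
    cat("nothing to summarize in", out_dir, "\n")
    return(invisible(parsed))
  }
  cat("pipeline run summary:", out_dir, "\n")
  if (!is.null(parsed$metrics)) {
    cat("\nsurrogate validation accuracy\n")
    for (nm in names(parsed$metrics)) {
      m <- parsed$metrics[[nm]]
      cat(sprintf("  %-4s RE [%.3f%%, %.3f%%], R2 %.4f, RMSE %.4g\n",
                  nm, m$RE[1], m$RE[2], m$R2, m$RMSE))
    }
  }
  if (!is.null(parsed$uq)) {
    cat(sprintf(
      "\nunoptimized condition: ST in [%.2f, %.2f] degC (allowable %.1f) -> %s\n",
      parsed$uq$ST[1], parsed$uq$ST[2], parsed$uq$allowable,
      if (isTRUE(parsed$uq$reliable)) "reliable" else "unreliable"))
  }
  if (!is.null(parsed$sweep)) {
    cat("\noptimal solutions per reliability level\n")
    print(parsed$sweep, row.names = FALSE)
  }
  if (length(missing))
    cat("\nmissing artifacts:", paste(missing, collapse = ", "), "\n")
  invisible(parsed)
}
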