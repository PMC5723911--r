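# Pipeline orchestration: simulate -> standardize -> fit -> report over a
# single YAML configuration. These functions are the package's equivalent of
# a subcommand interface; each stage reads and writes plain CSV/JSON files
# so runs are scriptable and reproducible.

#' Read a pipeline configuration
#'
#' YAML with optional sections `paths` (file locations; `outdir` required),
#' `generator` (arguments of [generatorConfig()]), `truth` (arguments of
#' [sampleTruth()]), `model` (arguments of [modelSpec()]), `sampler`
#' (arguments of [samplerConfig()]), `pairs` (list of
#' `outcome`/`exposure` pairs to fit and report; default: the single pair in
#' `model`), and a top-level master `seed` from which every stage's seed is
#' derived deterministically.
#'
#' @param x path to a YAML file, or an already-assembled list.
#' @return the configuration list with defaults filled in.
#' @export
readPipelineConfig <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  stopifnot(is.list(cfg))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$paths <- cfg$paths %||% list()
  cfg$paths$outdir <- cfg$paths$outdir %||% "bym_output"
  cfg$generator <- cfg$generator %||% list()
  cfg$truth <- cfg$truth %||% list()
  cfg$model <- cfg$model %||% list()
  cfg$sampler <- cfg$sampler %||% list()
  if (is.null(cfg$pairs))
    cfg$pairs <- list(list(outcome = cfg$model$outcome %||% "stroke",
                           exposure = cfg$model$exposure %||% "smoking_rate"))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polynomial rolling checksum of the serialized configuration
#' @noRd
.configChecksum <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(cfg))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @noRd
.writeMetadata <- function(cfg, outdir, stage) {
  jsonlite::write_json(
    list(stage = stage, seed = cfg$seed,
         config_checksum = .configChecksum(cfg),
         package = paste0("bymGamma ",
                          as.character(utils::packageVersion("bymGamma")))),
    file.path(outdir, paste0("run_metadata_", stage, ".json")),
    auto_unbox = TRUE)
}

#' Simulate synthetic survey data to disk
#'
#' Draws a ground truth and writes, under `paths$outdir`: `records.csv`
#' (individual respondents), `panel_outcomes.csv` / `panel_covariates.csv`
#' (the forward-model panel), `adjacency.txt`, `truth.json`, and a metadata
#' sidecar with the seed and config checksum. Same-seed reruns are
#' byte-identical.
#'
#' @param config a YAML path or config list ([readPipelineConfig()]).
#' @param records also write individual-level records (default `TRUE`).
#' @return the output directory, invisibly.
#' @export
pipelineSimulate <- function(config, records = TRUE) {
  cfg <- readPipelineConfig(config)
  outdir <- cfg$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- cfg$generator
  gen$seed <- cfg$seed
  gc <- do.call(generatorConfig, gen)
  truth <- do.call(sampleTruth, c(list(config = gc), cfg$truth))
  panel <- generatePanel(truth, gc)
  writePanel(panel, file.path(outdir, "panel_outcomes.csv"),
             file.path(outdir, "panel_covariates.csv"))
  writeAdjacency(gc$graph, file.path(outdir, "adjacency.txt"))
  writeTruth(truth, file.path(outdir, "truth.json"))
  if (records) {
    rec <- generateSurveyRecords(truth, gc)
    write.csv(rec, file.path(outdir, "records.csv"), row.names = FALSE)
  }
  .writeMetadata(cfg, outdir, "simulate")
  message("simulated ", nRegions(gc$graph), " regions x ",
          length(gc$years), " years (seed ", cfg$seed, ") -> ", outdir)
  invisible(outdir)
}

#' Standardize survey records into the observation panel
#'
#' Reads `paths$records` (default `<outdir>/records.csv`) and an optional
#' standard-population CSV `paths$standard`, builds the region-year panel by
#' direct sex/age standardization and writes it to
#' `<outdir>/panel_outcomes.csv` / `panel_covariates.csv`.
#'
#' @param config a YAML path or config list.
#' @return the output directory, invisibly.
#' @export
pipelineStandardize <- function(config) {
  cfg <- readPipelineConfig(config)
  outdir <- cfg$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  recpath <- cfg$paths$records %||% file.path(outdir, "records.csv")
  rec <- readSurveyRecords(recpath)
  if (!nrow(rec)) stop("no survey records in ", recpath)
  standardByYear <- NULL
  if (!is.null(cfg$paths$standard)) {
    std <- readStandardPopulation(cfg$paths$standard)
    standardByYear <- setNames(
      rep(list(std), length(unique(rec$year))),
      as.character(sort(unique(rec$year))))
  }
  panel <- buildPanel(rec, standardByYear)
  writePanel(panel, file.path(outdir, "panel_outcomes.csv"),
             file.path(outdir, "panel_covariates.csv"))
  .writeMetadata(cfg, outdir, "standardize")
  invisible(outdir)
}

#' Fit the hierarchical model for every configured pair
#'
#' For each outcome-exposure pair, fits the BYM gamma regression on the
#' panel in `paths` and writes `samples_<outcome>_<exposure>.csv` plus
#' `diagnostics_<outcome>_<exposure>.json`. Errors if any split-Rhat
#' exceeds 1.2 unless `force = TRUE`.
#'
#' @param config a YAML path or config list.
#' @param force proceed despite Rhat > 1.2 (default `FALSE`).
#' @return named list of [PosteriorSamples-class], invisibly.
#' @export
pipelineFit <- function(config, force = FALSE) {
  cfg <- readPipelineConfig(config)
  outdir <- cfg$paths$outdir
  panel <- readPanel(
    cfg$paths$panelOutcomes %||% file.path(outdir, "panel_outcomes.csv"),
    cfg$paths$panelCovariates %||% file.path(outdir, "panel_covariates.csv"))
  graph <- readAdjacency(cfg$paths$adjacency %||%
                           file.path(outdir, "adjacency.txt"))
  fits <- list()
  for (pi in seq_along(cfg$pairs)) {
    pair <- cfg$pairs[[pi]]
    margs <- cfg$model
    margs$outcome <- pair$outcome
    margs$exposure <- pair$exposure
    spec <- do.call(modelSpec, margs)
    sargs <- cfg$sampler
    sargs$seed <- cfg$seed + 100L * pi
    sc <- do.call(samplerConfig, sargs)
    message("fitting ", pair$outcome, " ~ ", pair$exposure, " ...")
    samples <- runSampler(panel, spec, graph, sc)
    tag <- paste0(pair$outcome, "_", pair$exposure)
    writeSamples(samples, file.path(outdir, paste0("samples_", tag, ".csv")))
    diag <- samplerDiagnostics(samples)
    jsonlite::write_json(
      list(pair = pair, accept = as.list(attr(diag, "accept")),
           max_rhat = max(diag$rhat, na.rm = TRUE),
           min_ess = min(diag$ess, na.rm = TRUE),
           n_degenerate = sum(diag$degenerate)),
      file.path(outdir, paste0("diagnostics_", tag, ".json")),
      auto_unbox = TRUE, digits = NA)
    if (!force && any(diag$rhat > 1.2, na.rm = TRUE))
      stop("Rhat > 1.2 for ", tag,
           "; rerun longer or call pipelineFit(force = TRUE)")
    fits[[tag]] <- samples
  }
  .writeMetadata(cfg, outdir, "fit")
  invisible(fits)
}

#' Rebuild a PosteriorSamples object from a persisted draws table
#'
#' @param df data.frame from [readSamplesTable()].
#' @param spec the [ModelSpec-class] that produced it.
#' @param config the [SamplerConfig-class] used (defaults suffice for
#'   summarisation).
#' @return a [PosteriorSamples-class].
#' @export
samplesFromTable <- function(df, spec, config = samplerConfig()) {
  chains <- sort(unique(df$chain))
  keep <- setdiff(names(df), c("chain", "iteration"))
  draws <- lapply(chains, function(ch) {
    m <- as.matrix(df[df$chain == ch, keep, drop = FALSE])
    rownames(m) <- NULL
    m
  })
  ids <- sub("^b\\.", "", grep("^b\\.", keep, value = TRUE))
  new("PosteriorSamples", draws = draws,
      accept = c(beta = NA_real_, u = NA_real_, v = NA_real_, b = NA_real_,
                 alpha = NA_real_),
      regionIds = ids, spec = spec, config = config)
}

#' Summarise fitted samples into relative-risk reports
#'
#' For each configured pair, reads `samples_<outcome>_<exposure>.csv` and
#' writes `region_rr_<pair>.csv`, `ranking_<pair>.csv` and one combined
#' `national_rr.json` with the RR per `delta`-point exposure increase and
#' its 95 percent credibility interval.
#'
#' @param config a YAML path or config list.
#' @param delta exposure increment in percentage points (default 5).
#' @param k ranking slice size (default 5).
#' @return the national RR list, invisibly.
#' @export
pipelineReport <- function(config, delta = 5, k = 5L) {
  cfg <- readPipelineConfig(config)
  outdir <- cfg$paths$outdir
  national <- list()
  for (pair in cfg$pairs) {
    tag <- paste0(pair$outcome, "_", pair$exposure)
    spath <- file.path(outdir, paste0("samples_", tag, ".csv"))
    if (!file.exists(spath)) stop("missing samples file: ", spath)
    margs <- cfg$model
    margs$outcome <- pair$outcome
    margs$exposure <- pair$exposure
    spec <- do.call(modelSpec, margs)
    samples <- samplesFromTable(readSamplesTable(spath), spec)
    nat <- nationalRR(samples, delta = delta)
    reg <- regionalRR(samples, delta = delta)
    rk <- rankRegions(reg, k = min(k, nrow(reg)))
    exportRegionTable(reg, file.path(outdir, paste0("region_rr_", tag, ".csv")),
                      outcome = pair$outcome, exposure = pair$exposure)
    write.csv(rbind(cbind(slice = "top", rk$top),
                    cbind(slice = "bottom", rk$bottom)),
              file.path(outdir, paste0("ranking_", tag, ".csv")),
              row.names = FALSE)
    national[[tag]] <- list(outcome = pair$outcome, exposure = pair$exposure,
                            rr = nat$rr_mean, ci_low = nat$rr_ci_low,
                            ci_high = nat$rr_ci_high, delta = delta)
  }
  jsonlite::write_json(national, file.path(outdir, "national_rr.json"),
                       auto_unbox = TRUE, digits = NA)
  .writeMetadata(cfg, outdir, "report")
  invisible(national)
}
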