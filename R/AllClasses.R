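#' @import methods
#' @importFrom stats rnorm rgamma runif rbinom dgamma quantile sd var median
#'   shapiro.test lm coef setNames plogis acf
#' @importFrom utils read.csv write.csv read.table head tail
#' @useDynLib bymGamma, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Region adjacency graph for areal data
#'
#' Undirected graph over opaque region identifiers. Regions are kept in
#' lexicographic order of their ids; edges are stored once as index pairs
#' `(i, j)` with `i < j` into that ordering. The graph is the sole source of
#' the neighbourhood structure used by the Besag-York-Mollie (BYM) spatial
#' random intercept.
#'
#' @slot regionIds character vector of region identifiers, sorted.
#' @slot edges two-column integer matrix of edge index pairs, `i < j`,
#'   deduplicated, no self-loops.
#'
#' @seealso [readAdjacency()], [latticeGraph()], [icarStructure()]
#' @export
setClass("SpatialGraph",
  representation(regionIds = "character", edges = "matrix"),
  validity = function(object) {
    msg <- character()
    n <- length(object@regionIds)
    if (n < 1L) msg <- c(msg, "graph must contain at least one region")
    if (is.unsorted(object@regionIds, strictly = TRUE))
      msg <- c(msg, "regionIds must be strictly sorted and unique")
    e <- object@edges
    if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
    if (nrow(e) > 0L) {
      if (!is.numeric(e)) msg <- c(msg, "edges must be an integer matrix")
      else {
        if (any(e < 1L | e > n)) msg <- c(msg, "edge endpoint out of range")
        if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loop in edge set")
        if (any(e[, 1L] > e[, 2L])) msg <- c(msg, "edges must be stored with i < j")
        if (anyDuplicated(paste(e[, 1L], e[, 2L]))) msg <- c(msg, "duplicated edge")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Intrinsic CAR precision structure
#'
#' Precision matrix of the intrinsic conditional autoregressive (ICAR) prior:
#' vertex degree on the diagonal, -1 for neighbouring pairs, 0 elsewhere.
#' Every row sums to zero, so the matrix is singular positive semi-definite
#' with rank `n - (number of connected components)`.
#'
#' @slot precision symmetric numeric matrix with region-id dimnames.
#' @slot components integer vector assigning each region to a connected
#'   component (1-based, named by region id).
#' @slot rank integer, rank of the precision matrix.
#'
#' @seealso [icarStructure()], [icarQuadraticForm()]
#' @export
setClass("ICARStructure",
  representation(precision = "matrix", components = "integer", rank = "integer"),
  validity = function(object) {
    msg <- character()
    Q <- object@precision
    if (nrow(Q) != ncol(Q)) msg <- c(msg, "precision must be square")
    if (length(object@components) != nrow(Q))
      msg <- c(msg, "components length must equal matrix dimension")
    if (nrow(Q) > 0L) {
      if (max(abs(Q - t(Q))) > 0) msg <- c(msg, "precision must be symmetric")
      if (max(abs(rowSums(Q))) > 1e-12) msg <- c(msg, "precision rows must sum to 0")
      if (any(diag(Q) < 0)) msg <- c(msg, "diagonal must be nonnegative")
    }
    expected_rank <- nrow(Q) - length(unique(object@components))
    if (object@rank != expected_rank)
      msg <- c(msg, "rank must equal n - number of components")
    if (length(msg)) msg else TRUE
  }
)

#' Region-year observation panel
#'
#' The model's observation table: directly standardized prevalence (percent)
#' per region-year-outcome, alongside region-year covariates (standardized
#' exposure rates, mean BMI, drinking rate). Produced by [buildPanel()] from
#' survey records or by [generatePanel()] from a synthetic truth.
#'
#' @slot outcomes data.frame with columns `region_id`, `year`, `outcome`,
#'   `prevalence` (percent), `expected` (model-expected percent where known,
#'   otherwise `NA`), `n` (respondents contributing) and `nonpositive`
#'   (flag: cell unusable for a gamma response).
#' @slot covariates data.frame with columns `region_id`, `year`,
#'   `smoking_rate`, `passive_home_rate`, `passive_work_rate`, `mean_bmi`,
#'   `drinking_rate`, `n`.
#'
#' @seealso [buildPanel()], [generatePanel()], [runSampler()]
#' @export
setClass("RegionYearPanel",
  representation(outcomes = "data.frame", covariates = "data.frame"),
  validity = function(object) {
    msg <- character()
    need_o <- c("region_id", "year", "outcome", "prevalence", "expected",
                "n", "nonpositive")
    need_c <- c("region_id", "year", "smoking_rate", "passive_home_rate",
                "passive_work_rate", "mean_bmi", "drinking_rate", "n")
    if (!all(need_o %in% names(object@outcomes)))
      msg <- c(msg, paste("outcomes missing columns:",
                          paste(setdiff(need_o, names(object@outcomes)), collapse = ", ")))
    if (!all(need_c %in% names(object@covariates)))
      msg <- c(msg, paste("covariates missing columns:",
                          paste(setdiff(need_c, names(object@covariates)), collapse = ", ")))
    if (!length(msg)) {
      p <- object@outcomes$prevalence
      if (any(!is.na(p) & p < 0))
        msg <- c(msg, "prevalence must be nonnegative")
      key <- with(object@outcomes, paste(region_id, year, outcome))
      if (anyDuplicated(key)) msg <- c(msg, "duplicate region-year-outcome row")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Hierarchical model specification
#'
#' Defines one gamma regression: the outcome, the single smoking exposure
#' whose slope carries the relative risk, the confounders, the linear year
#' term, which random-effect blocks enter the linear predictor, and all
#' prior hyperparameters. Random-effect precisions get Gamma(1, 5e-5)
#' priors; fixed effects independent zero-mean normals; the gamma likelihood
#' shape a Gamma(1, 0.01) prior.
#'
#' @slot outcome outcome name (a level of the panel's `outcome` column).
#' @slot exposure covariate column carrying the exposure of interest.
#' @slot confounders further covariate columns entering linearly.
#' @slot yearTerm logical; include a linear term in centered calendar year.
#' @slot includeStructured,includeUnstructured,includeSlope logical switches
#'   for the ICAR intercept u, the iid intercept v and the iid random slope b.
#' @slot priorFixedPrec prior precision of each fixed effect.
#' @slot precPrior length-2 numeric `c(shape, rate)` for every random-effect
#'   precision.
#' @slot shapePrior length-2 numeric `c(shape, rate)` for the likelihood
#'   shape alpha.
#' @slot positivityPolicy `"exclude"` (drop nonpositive prevalence cells,
#'   with a warning) or `"halfmin"` (impute half the smallest positive value).
#' @slot constraintTol tolerance on the per-component mean of the structured
#'   effect.
#'
#' @seealso [modelSpec()], [runSampler()]
#' @export
setClass("ModelSpec",
  representation(outcome = "character", exposure = "character",
                 confounders = "character", yearTerm = "logical",
                 includeStructured = "logical", includeUnstructured = "logical",
                 includeSlope = "logical", priorFixedPrec = "numeric",
                 precPrior = "numeric", shapePrior = "numeric",
                 positivityPolicy = "character", constraintTol = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@outcome) != 1L) msg <- c(msg, "exactly one outcome")
    if (length(object@exposure) != 1L) msg <- c(msg, "exactly one exposure")
    if (object@exposure %in% object@confounders)
      msg <- c(msg, "exposure must appear exactly once (also listed as confounder)")
    if (object@priorFixedPrec <= 0) msg <- c(msg, "priorFixedPrec must be > 0")
    if (length(object@precPrior) != 2L || any(object@precPrior <= 0))
      msg <- c(msg, "precPrior must be positive c(shape, rate)")
    if (length(object@shapePrior) != 2L || any(object@shapePrior <= 0))
      msg <- c(msg, "shapePrior must be positive c(shape, rate)")
    if (!object@positivityPolicy %in% c("exclude", "halfmin"))
      msg <- c(msg, "positivityPolicy must be 'exclude' or 'halfmin'")
    if (object@constraintTol <= 0) msg <- c(msg, "constraintTol must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' MCMC sampler configuration
#'
#' @slot nIter total iterations per chain (including burn-in).
#' @slot nBurnin iterations discarded; proposal scales adapt only here.
#' @slot thin keep every `thin`-th post-burn-in draw.
#' @slot nChains number of independent chains.
#' @slot seed master seed; chain c uses `seed + c - 1`.
#' @slot targetAccept target acceptance rate for scalar random-walk updates.
#' @slot adaptBatch updates per Robbins-Monro adaptation batch.
#' @slot fixed named numeric; any of `alpha`, `tau_u`, `tau_v`, `tau_b` set
#'   here are held fixed instead of sampled (use `NA` entries or omit to
#'   sample).
#'
#' @seealso [samplerConfig()], [runSampler()]
#' @export
setClass("SamplerConfig",
  representation(nIter = "integer", nBurnin = "integer", thin = "integer",
                 nChains = "integer", seed = "integer",
                 targetAccept = "numeric", adaptBatch = "integer",
                 fixed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nIter <= object@nBurnin) msg <- c(msg, "nIter must exceed nBurnin")
    if (object@nBurnin < 0L) msg <- c(msg, "nBurnin must be >= 0")
    if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
    if (object@nChains < 1L) msg <- c(msg, "nChains must be >= 1")
    if (object@targetAccept <= 0 || object@targetAccept >= 1)
      msg <- c(msg, "targetAccept must be in (0, 1)")
    bad <- setdiff(names(object@fixed), c("alpha", "tau_u", "tau_v", "tau_b"))
    if (length(bad)) msg <- c(msg, paste("unknown fixed parameter:", bad[1L]))
    if (length(msg)) msg else TRUE
  }
)

#' Posterior draws from the hierarchical gamma model
#'
#' Thinned post-burn-in draws, one matrix per chain with one named column per
#' scalar parameter: fixed effects `beta.<name>`, structured intercepts
#' `u.<region>`, unstructured intercepts `v.<region>`, random slopes
#' `b.<region>`, precisions `tau_u`, `tau_v`, `tau_b`, likelihood shape
#' `alpha` and the joint log posterior `log_post`.
#'
#' @slot draws list of numeric matrices (iterations x parameters), one per
#'   chain, identical column names.
#' @slot accept named numeric vector of post-burn-in acceptance rates per
#'   update group, averaged over chains.
#' @slot regionIds regions in model order (lexicographic).
#' @slot spec the [ModelSpec-class] that was fitted.
#' @slot config the [SamplerConfig-class] used.
#'
#' @seealso [runSampler()], [drawMatrix()], [samplerDiagnostics()]
#' @export
setClass("PosteriorSamples",
  representation(draws = "list", accept = "numeric", regionIds = "character",
                 spec = "ModelSpec", config = "SamplerConfig"),
  validity = function(object) {
    msg <- character()
    if (!length(object@draws)) msg <- c(msg, "at least one chain required")
    cn <- colnames(object@draws[[1L]])
    for (d in object@draws) {
      if (!identical(colnames(d), cn)) msg <- c(msg, "chains disagree on parameters")
      if (any(!is.finite(d))) msg <- c(msg, "non-finite draw")
    }
    if (length(msg)) unique(msg) else TRUE
  }
)
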