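# Posterior computation: sampler configuration, conjugate updates,
# random-walk Metropolis utilities, the main sampler driver, diagnostics.

#' Create a sampler configuration
#'
#' Defaults are desk-scale for roughly 253 regions by 6 years: 4 chains of
#' 10,000 iterations, 5,000 burn-in, thinning 5. Proposal scales adapt
#' during burn-in only (Robbins-Monro toward 44 percent acceptance for
#' scalar updates) and are frozen afterwards to preserve detailed balance.
#'
#' @param nIter iterations per chain, including burn-in.
#' @param nBurnin burn-in iterations discarded.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param nChains independent chains; chain c is seeded `seed + c - 1`.
#' @param seed master seed.
#' @param targetAccept scalar-update acceptance target.
#' @param adaptBatch iterations per adaptation batch during burn-in.
#' @param fixed named numeric: any of `alpha`, `tau_u`, `tau_v`, `tau_b`
#'   given here are held at that value instead of being sampled.
#' @return a [SamplerConfig-class].
#' @export
samplerConfig <- function(nIter = 10000L, nBurnin = 5000L, thin = 5L,
                          nChains = 4L, seed = 1L, targetAccept = 0.44,
                          adaptBatch = 50L, fixed = numeric()) {
  new("SamplerConfig", nIter = as.integer(nIter),
      nBurnin = as.integer(nBurnin), thin = as.integer(thin),
      nChains = as.integer(nChains), seed = as.integer(seed),
      targetAccept = targetAccept, adaptBatch = as.integer(adaptBatch),
      fixed = fixed)
}

#' Conjugate Gibbs draw for a random-effect precision
#'
#' With a Gamma(a, c) prior on a precision tau and a zero-mean Gaussian
#' vector of effects, the full conditional is `Gamma(a + r/2, c + S/2)`:
#' for iid effects `r = length(e)`, `S = sum(e^2)`; for the ICAR effect
#' `r = rank(Q) = n - #components` and `S = t(e) Q e`, the sum of squared
#' neighbour differences (the pseudo-determinant normalizer of the improper
#' ICAR density contributes the `rank/2` exponent analytically).
#'
#' @param effects numeric vector of current effects.
#' @param structure `"iid"` or `"icar"`.
#' @param prior `c(shape, rate)` of the Gamma prior (default `c(1, 5e-5)`).
#' @param icar an [ICARStructure-class], required for `structure = "icar"`.
#' @return one draw of the precision.
#' @export
gibbsUpdatePrecision <- function(effects, structure = c("iid", "icar"),
                                 prior = c(1, 5e-5), icar = NULL) {
  structure <- match.arg(structure)
  stopifnot(all(is.finite(effects)))
  if (structure == "iid") {
    r <- length(effects)
    S <- sum(effects^2)
  } else {
    if (is.null(icar)) stop("icar structure required")
    r <- icarRank(icar)
    S <- icarQuadraticForm(icar, effects)
  }
  rgamma(1L, shape = prior[1] + r / 2, rate = prior[2] + S / 2)
}

#' One random-walk Metropolis step
#'
#' Gaussian random-walk proposal on a scalar or vector block with symmetric
#' proposal, hence acceptance probability `min(1, exp(dlogtarget))`.
#'
#' @param current numeric scalar or vector, the current block value.
#' @param logTarget function of the block returning the (unnormalized) log
#'   target density; must be finite at `current`.
#' @param scale proposal standard deviation(s), recycled over the block.
#' @return list with `value` (new block), `accepted` (logical) and
#'   `logTarget` (log target at `value`).
#' @export
mhUpdateBlock <- function(current, logTarget, scale) {
  lt0 <- logTarget(current)
  if (!is.finite(lt0))
    stop("log target is not finite at the current value: ", format(lt0))
  prop <- current + rnorm(length(current), 0, scale)
  lt1 <- logTarget(prop)
  if (is.finite(lt1) && log(runif(1L)) < lt1 - lt0)
    list(value = prop, accepted = TRUE, logTarget = lt1)
  else
    list(value = current, accepted = FALSE, logTarget = lt0)
}

#' Fit the hierarchical gamma model by Metropolis-within-Gibbs
#'
#' Runs `nChains` independent chains of the sampler: componentwise
#' random-walk Metropolis for the fixed effects (on internally standardized
#' covariates), single-site updates for the structured intercept u,
#' unstructured intercept v and random slope b, conjugate Gibbs draws for
#' the three precisions, a log-scale Metropolis update for the likelihood
#' shape, Gibbs "sweep" moves along the (intercept, v) and (slope, b)
#' translation directions, and per-component recentering of u with the
#' offset absorbed into the intercept. Identical (data, spec, config) give
#' bit-identical draws.
#'
#' @param panel a [RegionYearPanel-class] with at least 2 regions.
#' @param spec a [ModelSpec-class].
#' @param graph a [SpatialGraph-class] covering every panel region.
#' @param config a [SamplerConfig-class].
#' @return a [PosteriorSamples-class].
#' @export
runSampler <- function(panel, spec, graph, config = samplerConfig()) {
  stopifnot(is(config, "SamplerConfig"))
  md <- modelData(panel, graph, spec)
  if (length(unique(md$region)) < 2L) stop("need at least 2 regions")
  X <- md$X
  p <- ncol(X)
  colM <- c(0, colMeans(X[, -1L, drop = FALSE]))
  colS <- c(1, apply(X[, -1L, drop = FALSE], 2L, sd))
  colS[colS == 0 | !is.finite(colS)] <- 1
  Xs <- X
  for (j in seq_len(p - 1L) + 1L)
    Xs[, j] <- (X[, j] - colM[j]) / colS[j]

  betaStd <- qr.coef(qr(Xs), log(md$y))
  betaStd[!is.finite(betaStd)] <- 0
  mu0 <- exp(drop(Xs %*% betaStd))
  a0 <- 1 / max(var(md$y / mu0), 1e-4)
  a0 <- min(max(a0, 0.5), 1e4)
  if (!all(is.finite(c(betaStd, a0, gammaLogLik(md$y, mu0, a0)))))
    stop("non-finite log posterior at initialization; betaStd = ",
         paste(format(betaStd), collapse = ", "), "; alpha = ", format(a0))

  ids <- md$regionIds
  n <- length(ids)
  em <- graphEdges(graph)
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(em))) {
    i <- em[k, 1L]; j <- em[k, 2L]
    nbrs[[i]] <- c(nbrs[[i]], j - 1L)
    nbrs[[j]] <- c(nbrs[[j]], i - 1L)
  }
  nbrs <- lapply(nbrs, function(x) as.integer(if (is.null(x)) integer() else x))
  comp <- as.integer(.graphComponents(n, em) - 1L)
  edges0 <- em - 1L
  storage.mode(edges0) <- "integer"

  fixed <- c(alpha = NA_real_, tau_u = NA_real_, tau_v = NA_real_,
             tau_b = NA_real_)
  fixed[names(config@fixed)] <- config@fixed
  exposureCol <- match(spec@exposure, colnames(X)) - 1L

  parNames <- c(paste0("beta.", colnames(X)), paste0("u.", ids),
                paste0("v.", ids), paste0("b.", ids),
                "tau_u", "tau_v", "tau_b", "alpha", "log_post")
  draws <- vector("list", config@nChains)
  acc <- NULL
  for (ch in seq_len(config@nChains)) {
    set.seed(config@seed + ch - 1L)
    res <- .run_chain_cpp(md$y, Xs, colM, colS, md$xexp,
                          as.integer(md$region - 1L), nbrs, edges0, comp,
                          exposureCol,
                          spec@includeStructured, spec@includeUnstructured,
                          spec@includeSlope,
                          spec@priorFixedPrec, spec@precPrior[1],
                          spec@precPrior[2], spec@shapePrior[1],
                          spec@shapePrior[2], unname(fixed),
                          as.numeric(betaStd), a0,
                          config@nIter, config@nBurnin, config@thin,
                          config@adaptBatch, config@targetAccept)
    m <- res$draws
    colnames(m) <- parNames
    draws[[ch]] <- m
    acc <- if (is.null(acc)) res$accept else acc + res$accept
  }
  acc <- acc / config@nChains
  new("PosteriorSamples", draws = draws, accept = acc, regionIds = ids,
      spec = spec, config = config)
}

#' Convergence diagnostics for posterior draws
#'
#' Split-Rhat (each chain halved; omitted with a notice for a single chain)
#' and an autocorrelation-based effective sample size (Geyer's initial
#' positive sequence, summed over chains) for every scalar parameter, plus
#' the recorded acceptance rates. Parameters with `Rhat > 1.05` or
#' `ESS < 100` trigger warnings; constant chains are flagged degenerate
#' (`ESS = NA`).
#'
#' @param samples a [PosteriorSamples-class] with at least 100 retained
#'   draws per chain.
#' @return data.frame with columns `parameter`, `rhat`, `ess`, `degenerate`;
#'   acceptance rates attached as attribute `"accept"`.
#' @export
samplerDiagnostics <- function(samples) {
  stopifnot(is(samples, "PosteriorSamples"))
  d <- samples@draws
  nkeep <- nrow(d[[1L]])
  if (nkeep < 100L) stop("need at least 100 retained draws, have ", nkeep)
  single <- length(d) < 2L
  if (single)
    message("single chain: Rhat omitted (need >= 2 chains)")
  pars <- colnames(d[[1L]])
  rhat <- ess <- rep(NA_real_, length(pars))
  degen <- logical(length(pars))
  for (i in seq_along(pars)) {
    xs <- lapply(d, function(m) m[, i])
    if (all(vapply(xs, function(x) sd(x) == 0, logical(1L)))) {
      degen[i] <- TRUE
      next
    }
    if (!single) rhat[i] <- .splitRhat(xs)
    ess[i] <- sum(vapply(xs, .essGeyer, numeric(1L)))
  }
  out <- data.frame(parameter = pars, rhat = rhat, ess = ess,
                    degenerate = degen, stringsAsFactors = FALSE)
  bad_r <- !is.na(out$rhat) & out$rhat > 1.05
  if (any(bad_r))
    warning("Rhat > 1.05 for: ",
            paste(head(out$parameter[bad_r], 5L), collapse = ", "),
            if (sum(bad_r) > 5L) ", ..." else "")
  bad_e <- !is.na(out$ess) & out$ess < 100
  if (any(bad_e))
    warning("ESS < 100 for: ",
            paste(head(out$parameter[bad_e], 5L), collapse = ", "),
            if (sum(bad_e) > 5L) ", ..." else "")
  if (any(out$degenerate))
    warning("degenerate (constant) chain for: ",
            paste(head(out$parameter[out$degenerate], 5L), collapse = ", "))
  attr(out, "accept") <- samples@accept
  out
}

#' Split-Rhat over a list of chains
#' @noRd
.splitRhat <- function(chains) {
  half <- unlist(lapply(chains, function(x) {
    n2 <- floor(length(x) / 2)
    list(x[seq_len(n2)], x[seq_len(n2) + n2])
  }), recursive = FALSE)
  n <- length(half[[1L]])
  means <- vapply(half, mean, numeric(1L))
  vars <- vapply(half, var, numeric(1L))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size, Geyer initial positive sequence
#' @noRd
.essGeyer <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(NA_real_)
  lag.max <- min(n - 1L, 500L)
  rho <- drop(stats::acf(x, lag.max = lag.max, plot = FALSE,
                         demean = TRUE)$acf)[-1L]
  tau <- 1
  k <- 1L
  while (k + 1L <= length(rho)) {
    g <- rho[k] + rho[k + 1L]
    if (g <= 0) break
    tau <- tau + 2 * g
    k <- k + 2L
  }
  n / tau
}

#' Persist posterior draws as a columnar CSV
#'
#' One row per retained draw with `chain` and `iteration` columns followed
#' by every scalar parameter.
#'
#' @param samples a [PosteriorSamples-class].
#' @param path CSV path.
#' @return `path` invisibly (write); a draws data.frame (read).
#' @export
writeSamples <- function(samples, path) {
  stopifnot(is(samples, "PosteriorSamples"))
  tabs <- lapply(seq_along(samples@draws), function(ch) {
    m <- samples@draws[[ch]]
    cbind(data.frame(chain = ch, iteration = seq_len(nrow(m))),
          as.data.frame(m, check.names = FALSE))
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSamples
#' @export
readSamplesTable <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

setMethod("nChains", "PosteriorSamples", function(x) length(x@draws))
setMethod("regionIds", "PosteriorSamples", function(x) x@regionIds)

setMethod("drawMatrix", "PosteriorSamples",
  function(x, pattern = NULL, combine = TRUE) {
    sel <- function(m) {
      if (is.null(pattern)) m
      else m[, grepl(pattern, colnames(m)), drop = FALSE]
    }
    if (combine) do.call(rbind, lapply(x@draws, sel))
    else lapply(x@draws, sel)
  })

setMethod("show", "SamplerConfig", function(object) {
  cat("SamplerConfig:", object@nChains, "chain(s) x", object@nIter,
      "iterations (", object@nBurnin, "burn-in, thin", object@thin,
      "), seed", object@seed, "\n")
  if (length(object@fixed))
    cat("  fixed:", paste(names(object@fixed), "=", object@fixed,
                          collapse = ", "), "\n")
})

setMethod("show", "PosteriorSamples", function(object) {
  cat("PosteriorSamples:", length(object@draws), "chain(s) x",
      nrow(object@draws[[1L]]), "retained draws,",
      ncol(object@draws[[1L]]), "parameters,",
      length(object@regionIds), "regions\n")
  cat("  acceptance:",
      paste(names(object@accept), sprintf("%.2f", object@accept),
            collapse = ", "), "\n")
})
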