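#' Define a synthetic-data scenario
#'
#' The default values are the study conditions of the calibration protocol:
#' 339 checked transcripts across 21 biological replicates, outliers injected
#' into a random 50% of transcripts (one per transcript, in one random
#' replicate) at right-quantile distance `1 - 1e-10` of the generating
#' distribution, and 18 user FPR thresholds spanning 0.2%-10% with three
#' replicate runs each.
#'
#' Generating parameters are drawn from documented priors resembling bulk
#' RNA-seq: natural-log baselines `N(4, 2)`, effects `N(0, 1)` (the checked
#' transcripts emulate significant DE calls, so both directions occur), a
#' mean-overdispersion trend `sigma = 0.5 + 0.45 * lambda + N(0, 0.35)`
#' giving dispersions of roughly 0.4 at low abundance down to 0.02 at high
#' abundance, and sequencing-depth exposures `N(0, 0.25)` centred to zero.
#' Housekeeping anchors have zero effect.
#'
#' @param G number of checked transcripts.
#' @param S number of biological replicates (samples), split over two
#'   conditions.
#' @param nAnchors housekeeping transcripts added for exposure
#'   identification.
#' @param outlierFraction fraction of checked transcripts receiving one
#'   injected outlier.
#' @param injectionQuantile generating-distribution quantile of injected
#'   counts.
#' @param thresholds user FPR grid for calibration sweeps.
#' @param replicates replicate runs per threshold.
#' @param baselineMean,baselineSd,effectSd,trendA,trendB,trendTau,exposureSd
#'   generator hyperparameters (natural-log scale).
#' @param seed integer seed.
#' @return a named list of class `ppc_scenario`.
#' @export
simulationScenario <- function(G = 339L, S = 21L, nAnchors = 30L,
                               outlierFraction = 0.5,
                               injectionQuantile = 1 - 1e-10,
                               thresholds = exp(seq(log(0.002), log(0.1),
                                                    length.out = 18L)),
                               replicates = 3L,
                               baselineMean = 4, baselineSd = 2,
                               effectSd = 1,
                               trendA = 0.5, trendB = 0.45, trendTau = 0.35,
                               exposureSd = 0.25,
                               seed = 1L) {
  stopifnot(G >= 1, S >= 4, outlierFraction >= 0, outlierFraction <= 1,
            injectionQuantile > 0, injectionQuantile < 1)
  out <- list(G = as.integer(G), S = as.integer(S),
              nAnchors = as.integer(nAnchors),
              outlierFraction = outlierFraction,
              injectionQuantile = injectionQuantile,
              thresholds = thresholds, replicates = as.integer(replicates),
              baselineMean = baselineMean, baselineSd = baselineSd,
              effectSd = effectSd, trendA = trendA, trendB = trendB,
              trendTau = trendTau, exposureSd = exposureSd,
              seed = as.integer(seed))
  class(out) <- "ppc_scenario"
  out
}

#' Simulate counts from the generative model (no outliers)
#'
#' Pure negative binomial data with the model's full statistical structure:
#' two balanced conditions, per-transcript baselines and effects, trend-tied
#' overdispersions and centred exposures.  The generating parameters are
#' stored under `metadata()$truth`.
#'
#' @param scenario a [simulationScenario()].
#' @param seed overrides `scenario$seed`.
#' @return a [CountSet-class] with design attached.
#' @export
simulateCounts <- function(scenario, seed = NULL) {
  if (is.null(seed)) seed <- scenario$seed
  set.seed(seed)
  G <- scenario$G; S <- scenario$S; A <- scenario$nAnchors
  Gt <- G + A
  cond <- rep(c("A", "B"), c(floor(S / 2), ceiling(S / 2)))
  samples <- sprintf("s%02d", seq_len(S))
  transcripts <- c(sprintf("g%04d", seq_len(G)),
                   if (A) sprintf("hk%03d", seq_len(A)))
  beta0 <- stats::rnorm(Gt, scenario$baselineMean, scenario$baselineSd)
  beta1 <- c(stats::rnorm(G, 0, scenario$effectSd), rep(0, A))
  sigma <- scenario$trendA + scenario$trendB * beta0 +
    stats::rnorm(Gt, 0, scenario$trendTau)
  e <- stats::rnorm(S, 0, scenario$exposureSd)
  e <- e - mean(e)
  xb <- as.numeric(cond == "B")
  eta <- outer(xb, beta1) + rep(beta0, each = S) + e  # S x Gt
  mu <- exp(eta)
  phi <- matrix(exp(sigma), S, Gt, byrow = TRUE)
  y <- matrix(stats::rnbinom(S * Gt, size = phi, mu = mu), S, Gt,
              dimnames = list(samples, transcripts))
  # pseudo significance consistent with the simulated effect sizes
  pseudo_p <- 2 * stats::pnorm(-abs(beta1[seq_len(G)]) /
                               (scenario$effectSd / 3 + 1e-9))
  cs <- new("CountSet", SummarizedExperiment(
    assays = list(counts = t(y)),
    rowData = DataFrame(
      significance = c(pseudo_p, rep(NA_real_, A)),
      do_check = c(rep(TRUE, G), rep(FALSE, A)),
      row.names = transcripts),
    colData = DataFrame(condition = factor(cond, levels = c("A", "B")),
                        row.names = samples)
  ))
  metadata(cs)$design <- DesignSpec(~ condition,
                                    data.frame(condition = cond,
                                               row.names = samples))
  metadata(cs)$truth <- list(beta0 = beta0, beta1 = beta1, sigma = sigma,
                             exposure = e, mu = mu,
                             samples = samples, transcripts = transcripts,
                             scenario = scenario, seed = seed)
  cs
}

#' Inject extreme outliers into simulated counts
#'
#' For a random `outlierFraction` of checked transcripts, one randomly
#' selected replicate's count is replaced by the smallest count whose
#' generating-distribution CDF reaches `injectionQuantile` (default
#' `1 - 1e-10`).  Truth labels are recorded under `metadata()$truth$outliers`.
#'
#' @param x a simulated [CountSet-class] (from [simulateCounts()]).
#' @param scenario the scenario that generated `x`.
#' @param seed selection seed; default derived from the generation seed.
#' @return `x` with outliers injected and labelled.
#' @export
injectOutliers <- function(x, scenario, seed = NULL) {
  truth <- metadata(x)$truth
  if (is.null(truth)) stop("x carries no generating truth; simulate it first")
  if (is.null(seed)) seed <- truth$seed + 7L
  set.seed(seed)
  G <- scenario$G
  nOut <- round(scenario$outlierFraction * G)
  if (nOut == 0L) {
    metadata(x)$truth$outliers <- data.frame()
    return(x)
  }
  gsel <- sort(sample.int(G, nOut))
  ssel <- sample.int(scenario$S, nOut, replace = TRUE)
  y <- assay(x, "counts")
  lab <- data.frame(
    transcript = truth$transcripts[gsel],
    sample = truth$samples[ssel],
    original = y[cbind(gsel, ssel)],
    mu = truth$mu[cbind(ssel, gsel)],
    sigma = truth$sigma[gsel],
    stringsAsFactors = FALSE
  )
  lab$injected <- stats::qnbinom(scenario$injectionQuantile,
                                 size = exp(lab$sigma), mu = lab$mu)
  y[cbind(gsel, ssel)] <- lab$injected
  SummarizedExperiment::assay(x, "counts") <- y
  metadata(x)$truth$outliers <- lab
  x
}

.flaggedTranscripts <- function(calls) {
  unique(calls$transcript[calls$final_flag])
}

#' Calibration and accuracy experiment
#'
#' Runs the two-step procedure over a grid of user FPR thresholds on
#' replicate synthetic datasets and measures (i) the empirical
#' transcript-level false positive rate on outlier-free data against the
#' nominal rate, and (ii) the false negative rate and ROC for injected
#' outliers, optionally paired with the one-step (discovery-only) mode on
#' the identical data and fits.
#'
#' The discovery fit does not depend on the swept user threshold, so each
#' replicate dataset costs two model fits regardless of the grid size.
#'
#' @param scenario a [simulationScenario()].
#' @param config a [testConfig()]; its `fprTest` is ignored in favour of
#'   `thresholds`.
#' @param thresholds nominal user FPR grid; default `scenario$thresholds`.
#' @param replicates replicate datasets; default `scenario$replicates`.
#' @param mode `"fpr"` (clean data only), `"fnr"` (injected only) or
#'   `"both"`.
#' @param oneStep also evaluate the one-step mode on injected data.
#' @return list of class `ppc_calibration`: `runs` (one row per replicate,
#'   dataset type, mode and threshold), `fprSummary` (slope, intercept, R^2
#'   of empirical vs nominal FPR), `roc`.
#' @export
calibrationExperiment <- function(scenario, config = testConfig(),
                                  thresholds = NULL, replicates = NULL,
                                  mode = c("both", "fpr", "fnr"),
                                  oneStep = TRUE) {
  mode <- match.arg(mode)
  if (is.null(thresholds)) thresholds <- scenario$thresholds
  if (is.null(replicates)) replicates <- scenario$replicates
  runs <- list()
  addRun <- function(df) runs[[length(runs) + 1L]] <<- df

  for (r in seq_len(replicates)) {
    genSeed <- scenario$seed + 1000L * r
    cfg <- config
    cfg$seed <- config$seed + 17L * r
    datasets <- list()
    if (mode %in% c("both", "fpr")) {
      datasets$clean <- simulateCounts(scenario, seed = genSeed)
    }
    if (mode %in% c("both", "fnr")) {
      base <- if (!is.null(datasets$clean)) datasets$clean else
        simulateCounts(scenario, seed = genSeed)
      datasets$injected <- injectOutliers(base, scenario,
                                          seed = genSeed + 7L)
    }
    for (dn in names(datasets)) {
      cs <- datasets[[dn]]
      res <- tryCatch(
        .calibrationRun(cs, cfg, thresholds, dn, r, oneStep),
        error = function(e) {
          warning("replicate ", r, " (", dn, ") failed: ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(res)) addRun(res)
    }
  }
  runs <- do.call(rbind, runs)
  fprRows <- runs[runs$dataset == "clean" & runs$mode == "two_step", ,
                  drop = FALSE]
  fprSummary <- NULL
  if (!is.null(fprRows) && nrow(fprRows) >= 3L) {
    fitlm <- stats::lm(empirical_fpr ~ nominal, data = fprRows)
    fprSummary <- list(slope = unname(stats::coef(fitlm)[2L]),
                       intercept = unname(stats::coef(fitlm)[1L]),
                       r2 = summary(fitlm)$r.squared)
  }
  rocRows <- runs[runs$dataset == "injected", , drop = FALSE]
  roc <- NULL
  if (!is.null(rocRows) && nrow(rocRows)) {
    roc <- stats::aggregate(
      cbind(empirical_fpr, tpr_transcript) ~ mode + nominal,
      data = rocRows, FUN = mean)
  }
  structure(list(runs = runs, fprSummary = fprSummary, roc = roc,
                 thresholds = thresholds, scenario = scenario),
            class = "ppc_calibration")
}

# one dataset, all thresholds; shares discovery and test fits
.calibrationRun <- function(cs, cfg, thresholds, datasetName, replicate,
                            oneStep) {
  G <- sum(rowData(cs)$do_check)
  truthOut <- metadata(cs)$truth$outliers
  injected <- !is.null(truthOut) && nrow(truthOut) > 0
  outTx <- if (injected) truthOut$transcript else character(0)
  outKey <- if (injected) {
    paste(truthOut$sample, truthOut$transcript, sep = "\r")
  } else character(0)
  disc <- runDiscovery(cs, cfg)
  hasQ <- !is.null(disc$quarantine) && nrow(disc$quarantine) > 0
  tst <- if (hasQ) runTest(cs, cfg, disc, fprTest = thresholds) else NULL

  metricRow <- function(calls, nominal, modeName) {
    flagged <- .flaggedTranscripts(calls)
    tp <- sum(flagged %in% outTx)
    fp <- length(flagged) - tp
    nClean <- G - length(outTx)
    fkey <- paste(calls$sample[calls$final_flag],
                  calls$transcript[calls$final_flag], sep = "\r")
    fn_point <- if (injected) sum(!(outKey %in% fkey)) else NA_integer_
    data.frame(
      replicate = replicate, dataset = datasetName, mode = modeName,
      nominal = nominal,
      empirical_fpr = if (nClean > 0) fp / nClean else NA_real_,
      tpr_transcript = if (injected) tp / length(outTx) else NA_real_,
      fnr_transcript = if (injected) 1 - tp / length(outTx) else NA_real_,
      fnr_point = if (injected) fn_point / length(outKey) else NA_real_,
      TP = tp, FP = fp, TN = nClean - fp,
      FN = if (injected) length(outTx) - tp else 0L,
      n_quarantined = if (hasQ) nrow(disc$quarantine) else 0L,
      stringsAsFactors = FALSE
    )
  }

  oneCalls <- if (oneStep && hasQ) oneStepCalls(disc, thresholds, cfg) else
    NULL
  empty <- data.frame(sample = character(0), transcript = character(0),
                      final_flag = logical(0))
  out <- list()
  for (t in thresholds) {
    callsT <- if (hasQ) {
      tst$calls[tst$calls$fpr_test == t, , drop = FALSE]
    } else empty
    out[[length(out) + 1L]] <- metricRow(callsT, t, "two_step")
    if (oneStep) {
      oneT <- if (hasQ) {
        oneCalls[oneCalls$fpr_test == t, , drop = FALSE]
      } else empty
      out[[length(out) + 1L]] <- metricRow(oneT, t, "one_step")
    }
  }
  do.call(rbind, out)
}

#' Truncation-bias study
#'
#' Quantifies how an untruncated maximum-likelihood NB fit reacts to data
#' truncated at the empirical 95th-percentile count, across a grid of
#' mean/overdispersion combinations typical of RNA-seq, and verifies that
#' the right-truncated likelihood removes the bias.  The headline summary is
#' the mean fitted-to-true overdispersion percentage
#' `100 * mean(exp(sigma_true - sigma_hat))` (overdispersion here on the
#' variance-inflation scale, i.e. the factor multiplying `mu^2`): the
#' untruncated fit scales the overdispersion down to about three quarters of
#' its true value, fairly uniformly over the grid.
#'
#' @param muGrid generating means.
#' @param sigmaGrid generating log-size values (see [nbLogPmf()]).
#' @param n simulated counts per grid cell.
#' @param seed integer seed.
#' @return list of class `ppc_truncation_study`: per-cell `table` and a
#'   `summary` list.
#' @export
truncationBiasStudy <- function(muGrid = c(1, 10, 100, 1000, 10000),
                                sigmaGrid = c(-2, -1, 0, 1, 2, 3),
                                n = 10000L, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(mu = muGrid, sigma = sigmaGrid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mu <- grid$mu[i]; sg <- grid$sigma[i]
    y <- stats::rnbinom(n, size = exp(sg), mu = mu)
    q95 <- unname(stats::quantile(y, 0.95, type = 1L))
    yt <- y[y <= q95]
    fu <- tryCatch(.nbFitMl(yt), error = function(e) NULL)
    ft <- tryCatch(.nbFitMlTruncated(yt, q95), error = function(e) NULL)
    fc <- tryCatch(.nbFitMl(y), error = function(e) NULL)
    data.frame(
      mu = mu, sigma = sg, q95 = q95,
      sigmaHatUntrunc = if (is.null(fu)) NA_real_ else fu$sigma,
      sigmaHatTrunc = if (is.null(ft)) NA_real_ else ft$sigma,
      sigmaHatControl = if (is.null(fc)) NA_real_ else fc$sigma,
      converged = !is.null(fu) && fu$converged &&
        !is.null(ft) && ft$converged
    )
  })
  tab <- do.call(rbind, rows)
  tab$overdispRatio <- exp(tab$sigma - tab$sigmaHatUntrunc)
  tab$truncBias <- tab$sigmaHatTrunc - tab$sigma
  tab$controlBias <- tab$sigmaHatControl - tab$sigma
  ok <- !is.na(tab$overdispRatio)
  summary <- list(
    meanOverdispersionRatioPercent = 100 * mean(tab$overdispRatio[ok]),
    meanTruncatedFitBias = mean(tab$truncBias, na.rm = TRUE),
    meanControlBias = mean(tab$controlBias, na.rm = TRUE),
    cellsConverged = sum(tab$converged), cells = nrow(tab)
  )
  structure(list(table = tab, summary = summary),
            class = "ppc_truncation_study")
}

#' Approximation-error experiment
#'
#' Fits one simulated scenario with both backends and compares, per checked
#' data point, the theoretical-distribution mean and central 95% interval
#' endpoints obtained by full predictive sampling against the semi-analytic
#' approximation, and variational against HMC.  All differences are scaled
#' by the predictive mean of the reference combination (HMC, sampled), the
#' scaling under which lower-endpoint errors are small and upper-endpoint
#' errors are amplified for right-skewed counts.
#'
#' @param scenario a [simulationScenario()] (desk scale recommended).
#' @param config a [testConfig()]; `nTheoreticalDraws` controls the sampled
#'   reference.
#' @param coverage central interval coverage.
#' @return list of class `ppc_approximation`: per-point `table`, `summary`
#'   (mean absolute scaled difference per combination and quantity), and the
#'   truth-referenced `summaryTruth`.
#' @export
approximationExperiment <- function(scenario, config = testConfig(),
                                    coverage = 0.95) {
  cs <- simulateCounts(scenario)
  checked <- checkedTranscripts(cs)
  anchors <- estimateExposureAnchors(cs, config$nAnchors)
  model <- buildModel(cs, transcripts = c(checked, anchors))
  fits <- list(
    hmc = fitModel(model, inferenceSettings("hmc", seed = config$seed)),
    vb = fitModel(model, inferenceSettings("vb", seed = config$seed))
  )
  tail <- (1 - coverage) / 2
  nd <- max(config$nTheoreticalDraws, ceiling(50 / tail))

  sampledSummary <- function(fit, seed) {
    set.seed(seed)
    mod <- fit@model
    rows <- lapply(checked, function(g) {
      do.call(rbind, lapply(mod@samples, function(s) {
        xs <- sort(predictiveDraws(fit, s, g, nd))
        data.frame(sample = s, transcript = g, mean = mean(xs),
                   lower = .discreteQuantile(xs, tail),
                   upper = .discreteQuantile(xs, 1 - tail))
      }))
    })
    do.call(rbind, rows)
  }
  approxSummary <- function(fit) {
    ti <- theoreticalIntervals(fit, coverage, "approximated",
                               transcripts = checked)
    data.frame(sample = ti$sample, transcript = ti$transcript,
               mean = ti$predictive_mean, lower = ti$lower,
               upper = ti$upper)
  }
  combos <- list(
    hmc_sampled = sampledSummary(fits$hmc, config$seed + 11L),
    vb_sampled = sampledSummary(fits$vb, config$seed + 12L),
    hmc_approximated = approxSummary(fits$hmc),
    vb_approximated = approxSummary(fits$vb)
  )
  # ground truth from the generating parameters
  truth <- metadata(cs)$truth
  gi <- match(checked, truth$transcripts)
  S <- length(truth$samples)
  muT <- truth$mu[, gi, drop = FALSE]
  phiT <- matrix(exp(truth$sigma[gi]), S, length(gi), byrow = TRUE)
  truthDf <- data.frame(
    sample = rep(truth$samples, times = length(gi)),
    transcript = rep(checked, each = S),
    mean = as.vector(muT),
    lower = as.vector(stats::qnbinom(tail, size = phiT, mu = muT)),
    upper = as.vector(stats::qnbinom(1 - tail, size = phiT, mu = muT))
  )

  key <- function(d) paste(d$sample, d$transcript, sep = "\r")
  ref <- combos$hmc_sampled
  scale_ref <- pmax(ref$mean, 1e-9)
  long <- list()
  for (cn in names(combos)) {
    d <- combos[[cn]][match(key(ref), key(combos[[cn]])), ]
    tD <- truthDf[match(key(ref), key(truthDf)), ]
    for (q in c("mean", "lower", "upper")) {
      long[[length(long) + 1L]] <- data.frame(
        combo = cn, quantity = q,
        sample = ref$sample, transcript = ref$transcript,
        value = d[[q]],
        scaledDiffVsSampled = (d[[q]] - ref[[q]]) / scale_ref,
        scaledDiffVsTruth = (d[[q]] - tD[[q]]) / pmax(tD$mean, 1e-9)
      )
    }
  }
  tab <- do.call(rbind, long)
  agg <- function(col) {
    sm <- stats::aggregate(abs(tab[[col]]),
                           by = list(combo = tab$combo,
                                     quantity = tab$quantity), FUN = mean)
    names(sm)[3L] <- "meanAbsScaledDiff"
    sm
  }
  structure(list(table = tab, summary = agg("scaledDiffVsSampled"),
                 summaryTruth = agg("scaledDiffVsTruth"),
                 diagnostics = lapply(fits, function(f) f@diagnostics)),
            class = "ppc_approximation")
}
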