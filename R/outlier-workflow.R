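#' Per-test tail width allocated from the user false positive rate
#'
#' The test step runs one-sided tests against the refit theoretical
#' distributions; the user-selected false positive rate is divided into a
#' per-test tail width `fpr / (2 * nOutliers)`, the factor of two
#' compensating for the unidirectionality of the tests (only the
#' deleterious side is tested).  The allocation size `nOutliers` is set by
#' `testConfig(allocation=)`: by default the number of quarantined
#' candidate points of the transcript under test.
#'
#' @param fpr user-selected false positive rate in (0, 1).
#' @param nOutliers allocation size (>= 1).
#' @param nTheoreticalDraws if given, warn when a sampled interval at this
#'   tail would need more draws than that (the approximated method is then
#'   used instead).
#' @return the one-sided tail probability per test.
#' @export
allocateTestIntervalWidth <- function(fpr, nOutliers,
                                      nTheoreticalDraws = NULL) {
  stopifnot(fpr > 0, fpr < 1, nOutliers >= 1)
  tail <- fpr / (2 * nOutliers)
  if (!is.null(nTheoreticalDraws) && nTheoreticalDraws * tail < 50) {
    warning("tail probability ", signif(tail, 3), " is too extreme for ",
            nTheoreticalDraws, " sampled draws; the approximated interval ",
            "method is used")
  }
  tail
}

#' Classify data points against a credible interval
#'
#' A point is an outlier when it falls outside `[lower, upper]`; it is
#' deleterious when it lies on the side that inflates the estimated change —
#' above the upper bound for a transcript estimated to have increased, below
#' the lower bound for one estimated to have decreased.
#'
#' @param intervals data.frame from [theoreticalIntervals()].
#' @param observed observed counts aligned with `intervals` rows.
#' @param direction data.frame with columns `transcript`, `sign` (+1 / -1).
#' @param stage label recorded on the calls.
#' @return data.frame of outlier calls.
#' @export
classifyDeleterious <- function(intervals, observed, direction,
                                stage = "discovery") {
  sgn <- direction$sign[match(intervals$transcript, direction$transcript)]
  above <- observed > intervals$upper
  below <- observed < intervals$lower
  data.frame(
    sample = intervals$sample,
    transcript = intervals$transcript,
    observed = observed,
    lower = intervals$lower,
    upper = intervals$upper,
    direction = sgn,
    side = ifelse(above, "above_upper", ifelse(below, "below_lower", NA)),
    outlier = above | below,
    deleterious = (sgn > 0 & above) | (sgn < 0 & below),
    stage = stage,
    stringsAsFactors = FALSE
  )
}

# observed counts aligned to an interval table
.alignObserved <- function(model, intervals) {
  model@counts[cbind(match(intervals$sample, model@samples),
                     match(intervals$transcript, model@transcripts))]
}

#' Discovery step: joint fit and quarantine of candidate outliers
#'
#' Fits the model on the checked transcripts plus exposure anchors, builds
#' the central `1 - fprDiscovery` theoretical interval for every checked
#' data point, determines each transcript's direction of change (sign of the
#' posterior median of the factor-of-interest coefficient), and quarantines
#' the deleterious outliers.
#'
#' @param x a [CountSet-class] with design attached.
#' @param config a [testConfig()].
#' @return list with elements `fit`, `intervals`, `direction`, `calls`,
#'   `quarantine`.
#' @export
runDiscovery <- function(x, config = testConfig()) {
  checked <- checkedTranscripts(x)
  if (!length(checked)) {
    warning("no checked transcripts: nothing to do")
    return(list(fit = NULL, intervals = NULL, direction = NULL,
                calls = NULL, quarantine = NULL))
  }
  anchors <- estimateExposureAnchors(x, config$nAnchors)
  model <- buildModel(x, transcripts = c(checked, anchors))
  settings <- .configSettings(config, seedOffset = 0L)
  fit <- fitModel(model, settings)
  message("discovery: fitted ", length(checked), " checked + ",
          length(anchors), " anchor transcripts over ",
          nrow(model@counts), " samples (", config$backend, ")")
  intervals <- theoreticalIntervals(
    fit, coverage = 1 - config$fprDiscovery,
    method = config$intervalMethod,
    nDraws = config$nTheoreticalDraws,
    seed = config$seed + 101L,
    transcripts = checked)
  direction <- .directionEstimate(fit, checked)
  calls <- classifyDeleterious(intervals, .alignObserved(model, intervals),
                               direction, stage = "discovery")
  quarantine <- calls[calls$deleterious, , drop = FALSE]
  message("discovery: ", sum(calls$outlier), " outliers, ",
          nrow(quarantine), " deleterious (quarantined) at fpr ",
          config$fprDiscovery)
  list(fit = fit, intervals = intervals, direction = direction,
       calls = calls, quarantine = quarantine)
}

# sign of the posterior median of the factor-of-interest coefficient
.directionEstimate <- function(fit, transcripts) {
  ci <- fit@model@coefIndex
  med <- apply(fit@beta[, ci, match(transcripts, fit@model@transcripts),
                        drop = FALSE], 3L, stats::median)
  data.frame(transcript = transcripts,
             sign = ifelse(med >= 0, 1L, -1L),
             estimate = med, stringsAsFactors = FALSE)
}

.configSettings <- function(config, seedOffset = 0L) {
  st <- config$settings
  if (is.null(st)) {
    st <- inferenceSettings(backend = config$backend,
                            seed = config$seed + seedOffset)
  } else {
    st$backend <- config$backend
    st$seed <- config$seed + seedOffset
  }
  st
}

# per-draw-mean analytic quantiles at selected cells only
.pointQuantiles <- function(fit, samples, transcripts, probs,
                            maxDraws = 250L) {
  mod <- fit@model
  si <- match(samples, mod@samples)
  gi <- match(transcripts, mod@transcripts)
  X <- mod@design[si, , drop = FALSE]
  D <- nrow(fit@sigma)
  dsel <- unique(round(seq(1L, D, length.out = min(D, maxDraws))))
  n <- length(si)
  # probs: K-vector (one prob per column) or n x K matrix (per-row probs)
  K <- if (is.matrix(probs)) ncol(probs) else length(probs)
  acc <- matrix(0, n, K)
  for (dd in dsel) {
    b <- matrix(fit@beta[dd, , gi], ncol = n)  # p x n
    eta <- rowSums(X * t(b)) + fit@exposure[dd, si]
    mu <- exp(eta)
    phi <- exp(fit@sigma[dd, gi])
    for (k in seq_len(K)) {
      pk <- if (is.matrix(probs)) probs[, k] else probs[k]
      acc[, k] <- acc[, k] + stats::qnbinom(pk, size = phi, mu = mu)
    }
  }
  acc / length(dsel)
}

#' Test step: truncated refit and FPR-allocated one-sided tests
#'
#' Refits the model with the quarantined data points removed from the
#' likelihood and, compensating for the induced selection, with every
#' retained observation of checked transcripts truncated at its
#' discovery-stage 2.5% / 97.5% theoretical quantiles.  All observed counts
#' of checked transcripts (including the quarantined candidates) are then
#' tested one-sided on their transcript's deleterious side against the new
#' theoretical distributions, at the tail width given by
#' [allocateTestIntervalWidth()] — by default `fprTest / (2 k)` with `k` the
#' transcript's quarantined candidates, which controls the false positive
#' rate of a transcript being labelled as containing an outlier.
#'
#' `fprTest` may be a vector: the (expensive) refit is shared and the
#' allocated thresholds recomputed per value, which is how the calibration
#' sweep is run.
#'
#' @param x the dataset used at discovery.
#' @param config a [testConfig()].
#' @param discovery result of [runDiscovery()].
#' @param fprTest user false positive rate(s); default `config$fprTest`.
#' @return list with `fit`, `calls` (one row per tested point and `fprTest`
#'   value), `untestable` transcript ids, and the allocation size
#'   `nOutliers`.
#' @export
runTest <- function(x, config = testConfig(), discovery,
                    fprTest = NULL) {
  if (is.null(fprTest)) fprTest <- config$fprTest
  quarantine <- discovery$quarantine
  if (is.null(quarantine) || !nrow(quarantine)) {
    stop("empty quarantine: the test step has nothing to evaluate")
  }
  checked <- checkedTranscripts(x)
  fitD <- discovery$fit
  # every observation outside the discovery interval leaves the refit
  # likelihood (both sides), which is exactly the censoring the two-sided
  # truncated likelihood of the retained points then compensates for;
  # the deleterious distinction governs quarantine bookkeeping and flagging
  removed <- discovery$calls[discovery$calls$outlier,
                             c("sample", "transcript"), drop = FALSE]

  # discovery-stage 2.5%/97.5% truncation bounds
  truncTx <- if (config$truncateAllChecked) checked else
    intersect(checked, unique(removed$transcript))
  tr <- theoreticalIntervals(fitD, coverage = 0.95,
                             method = "approximated",
                             transcripts = truncTx)
  obs <- .alignObserved(fitD@model, tr)
  rkey <- paste(removed$sample, removed$transcript, sep = "\r")
  tkey <- paste(tr$sample, tr$transcript, sep = "\r")
  retained <- !(tkey %in% rkey)
  # with a non-default discovery coverage a retained point can still lie
  # outside the fixed 2.5%/97.5% bounds; widen so its term stays defined
  trunc_df <- data.frame(sample = tr$sample[retained],
                         transcript = tr$transcript[retained],
                         lower = pmin(tr$lower[retained], obs[retained]),
                         upper = pmax(tr$upper[retained], obs[retained]))
  model2 <- buildModel(x,
                       transcripts = fitD@model@transcripts,
                       truncation = trunc_df,
                       exclude = removed)
  settings <- .configSettings(config, seedOffset = 1L)
  fit2 <- fitModel(model2, settings, init = fitD)
  message("test: refitted with ", nrow(removed),
          " points excluded (", nrow(quarantine), " deleterious) and ",
          nrow(trunc_df), " truncated likelihood terms")

  untestable <- .untestableTranscripts(model2)
  if (length(untestable)) {
    warning("transcript(s) untestable after quarantine (factor of interest ",
            "has no remaining contrast): ",
            paste(untestable, collapse = ", "))
  }

  calls <- .testAgainstFit(fit2, config, discovery, fprTest, untestable)
  list(fit = fit2, calls = calls, untestable = untestable,
       nOutliers = attr(calls, "nOutliers"),
       nQuarantined = nrow(quarantine),
       observationQuantiles = attr(calls, "observationQuantiles"))
}


# Shared final-test logic: thresholds and one-sided deleterious flags of the
# checked data points against a given fit (the truncated refit for the
# two-step procedure, the discovery fit for the one-step comparison mode).
.testAgainstFit <- function(fit, config, discovery, fprTest,
                            untestable = character(0)) {
  quarantine <- discovery$quarantine
  checked <- discovery$direction$transcript
  S <- nrow(fit@model@counts)
  qkey <- paste(quarantine$sample, quarantine$transcript, sep = "\r")
  kPerGene <- table(quarantine$transcript)
  nAllocOf <- function(tx) {
    switch(config$allocation,
      quarantined = rep(nrow(quarantine), length(tx)),
      perGene = {
        k <- as.integer(kPerGene[tx])
        k[is.na(k)] <- 1L
        pmax(1L, k)
      },
      replicates = rep(max(1, S / 2), length(tx)))
  }
  useSampled <- config$intervalMethod == "sampled"
  maxTail <- allocateTestIntervalWidth(
    max(fprTest), min(nAllocOf(checked)),
    nTheoreticalDraws = if (useSampled) config$nTheoreticalDraws)
  K <- length(fprTest)
  sgnOf <- function(tx) {
    discovery$direction$sign[match(tx, discovery$direction$transcript)]
  }
  tst_oq <- NULL
  if (config$testScope == "all") {
    # Every checked data point is a potential test.  Computing per-draw
    # quantile thresholds at extreme tails for all cells is wasteful (and
    # qnbinom is slow deep in the lower tail), so cells are prescreened by
    # their mixture-CDF tail probability on the deleterious side: only
    # points within a safety factor of the loosest threshold can possibly
    # be flagged and get exact thresholds.
    oq <- .observationQuantiles(fit, checked, maxDraws = 150L)
    sgn_all <- sgnOf(oq$transcript)
    tailProb <- ifelse(sgn_all > 0, oq$right_quantile, oq$quantile)
    okey <- paste(oq$sample, oq$transcript, sep = "\r")
    cand <- tailProb <= pmin(0.4, 8 * maxTail) | (okey %in% qkey)
    if (config$allocation == "perGene") {
      # only transcripts with quarantined candidates are under test
      cand <- cand & oq$transcript %in% names(kPerGene)
    }
    base <- data.frame(sample = oq$sample[cand],
                       transcript = oq$transcript[cand],
                       observed = oq$observed[cand],
                       stringsAsFactors = FALSE)
    tst_oq <- oq
  } else {
    base <- quarantine[, c("sample", "transcript", "observed")]
  }
  sgn <- sgnOf(base$transcript)
  nalloc <- nAllocOf(base$transcript)
  tailM <- outer(1 / (2 * nalloc), fprTest)  # n x K one-sided tails
  up_rows <- which(sgn > 0)
  lo_rows <- which(sgn < 0)
  qup <- matrix(NA_real_, nrow(base), K)
  qlo <- matrix(NA_real_, nrow(base), K)
  if (length(up_rows)) {
    qup[up_rows, ] <- ceiling(.pointQuantiles(
      fit, base$sample[up_rows], base$transcript[up_rows],
      1 - tailM[up_rows, , drop = FALSE]))
  }
  if (length(lo_rows)) {
    qlo[lo_rows, ] <- floor(.pointQuantiles(
      fit, base$sample[lo_rows], base$transcript[lo_rows],
      tailM[lo_rows, , drop = FALSE]))
  }
  quarantined <- paste(base$sample, base$transcript, sep = "\r") %in% qkey
  bad <- base$transcript %in% untestable
  calls <- do.call(rbind, lapply(seq_len(K), function(k) {
    flag <- ifelse(sgn > 0, base$observed > qup[, k],
                   base$observed < qlo[, k])
    data.frame(
      sample = base$sample,
      transcript = base$transcript,
      observed = base$observed,
      direction = sgn,
      side = ifelse(sgn > 0, "above_upper", "below_lower"),
      quarantined = quarantined,
      test_lower = qlo[, k], test_upper = qup[, k],
      tail = tailM[, k], fpr_test = fprTest[k],
      stage = "test",
      untestable = bad,
      final_flag = flag & !bad,
      stringsAsFactors = FALSE
    )
  }))
  attr(calls, "nOutliers") <- kPerGene
  attr(calls, "observationQuantiles") <- tst_oq
  calls
}

# transcripts whose retained samples no longer span the factor of interest
.untestableTranscripts <- function(model) {
  ci <- model@coefIndex
  if (ci == model@interceptIndex) return(character(0))
  xcol <- model@design[, ci]
  bad <- vapply(seq_len(ncol(model@counts)), function(g) {
    keep <- model@include[, g] == 1
    length(unique(xcol[keep])) < 2L
  }, NA)
  model@transcripts[bad & model@checked]
}

#' Identify outlier data points in differential-expression results
#'
#' The full two-step procedure (two iterations are sufficient by design):
#' a discovery fit flags deleterious candidate outliers against the central
#' `1 - fprDiscovery` posterior predictive interval; the model is refitted
#' without them under a truncated likelihood; each candidate is then tested
#' one-sided at the FPR-allocated tail width.  Only candidates that fail the
#' second test are finally flagged.
#'
#' @param x a [CountSet-class]; if `formula` is given a design is (re)built
#'   from `colData(x)`.
#' @param formula optional model formula.
#' @param config a [testConfig()].
#' @param factorOfInterest optional, passed to [DesignSpec()].
#' @return an [OutlierReport-class].
#' @export
identifyOutliers <- function(x, formula = NULL, config = testConfig(),
                             factorOfInterest = NULL) {
  if (!is.null(formula)) {
    designSpec(x) <- DesignSpec(formula, as.data.frame(colData(x)),
                                factorOfInterest)
  }
  checked <- checkedTranscripts(x)
  if (!length(checked)) {
    warning("no checked transcripts: returning an empty report")
    return(new("OutlierReport",
               transcriptSummary = data.frame(),
               calls = data.frame(),
               discovery = NULL, test = NULL, config = unclass(config)))
  }
  disc <- runDiscovery(x, config)
  hasTest <- nrow(disc$quarantine) > 0
  tst <- if (hasTest) runTest(x, config, disc) else NULL

  calls <- disc$calls
  names(calls)[names(calls) %in% c("lower", "upper")] <-
    c("discovery_lower", "discovery_upper")
  calls$quarantined <- calls$deleterious
  calls$test_lower <- NA_real_
  calls$test_upper <- NA_real_
  calls$final_flag <- FALSE
  calls$untestable <- FALSE
  if (hasTest) {
    key <- paste(calls$sample, calls$transcript, sep = "\r")
    tkey <- paste(tst$calls$sample, tst$calls$transcript, sep = "\r")
    i <- match(tkey, key)
    calls$final_flag[i] <- tst$calls$final_flag
    calls$untestable[i] <- tst$calls$untestable
    # reporting interval at the user coverage (the solid bars of the
    # per-transcript plot); flagging itself used the allocated tail width
    ri <- theoreticalIntervals(tst$fit, coverage = 1 - config$fprTest,
                               method = "approximated",
                               transcripts = checked)
    j <- match(paste(ri$sample, ri$transcript, sep = "\r"), key)
    calls$test_lower[j] <- ri$lower
    calls$test_upper[j] <- ri$upper
    oq <- if (!is.null(tst$observationQuantiles)) tst$observationQuantiles
          else .observationQuantiles(tst$fit, checked)
  } else {
    oq <- .observationQuantiles(disc$fit, checked)
  }
  okey <- paste(oq$sample, oq$transcript, sep = "\r")
  calls$posterior_quantile <-
    oq$quantile[match(paste(calls$sample, calls$transcript, sep = "\r"),
                      okey)]
  message("final: ", sum(calls$final_flag), " outlier data point(s) across ",
          length(unique(calls$transcript[calls$final_flag])),
          " transcript(s)")

  rd <- rowData(x)[checked, , drop = FALSE]
  sig <- rd$significance
  ord <- order(sig, checked)
  rank <- integer(length(checked)); rank[ord] <- seq_along(checked)
  ts <- data.frame(
    transcript = checked,
    significance = sig,
    rank = rank,
    contains_outlier = vapply(checked, function(g) {
      any(calls$final_flag[calls$transcript == g])
    }, NA),
    n_outliers = vapply(checked, function(g) {
      sum(calls$final_flag[calls$transcript == g])
    }, 0L),
    untestable = vapply(checked, function(g) {
      any(calls$untestable[calls$transcript == g])
    }, NA),
    stringsAsFactors = FALSE
  )
  rownames(ts) <- NULL
  cfg <- unclass(config)
  cfg$nInferences <- nrow(calls)
  new("OutlierReport", transcriptSummary = ts, calls = calls,
      discovery = disc$fit, test = if (hasTest) tst$fit else NULL,
      config = cfg)
}

#' One-step (discovery-only) outlier calls
#'
#' The comparison mode of the accuracy experiments: the identical
#' FPR-allocated one-sided test, but evaluated against the theoretical
#' distributions of the first (discovery) fit — i.e. without removing the
#' quarantined points and without the truncated refit.  Because outliers
#' inflate the discovery-stage distributions, this mode lacks sensitivity;
#' the contrast quantifies the benefit of the two-step strategy.
#'
#' @param discovery result of [runDiscovery()].
#' @param fpr nominal false positive rate(s).
#' @param config a [testConfig()].
#' @return data.frame of calls with `final_flag`, one row per tested point
#'   and `fpr` value.
#' @export
oneStepCalls <- function(discovery, fpr, config = testConfig()) {
  if (is.null(discovery$quarantine) || !nrow(discovery$quarantine)) {
    return(data.frame(sample = character(0), transcript = character(0),
                      final_flag = logical(0)))
  }
  calls <- .testAgainstFit(discovery$fit, config, discovery, fpr)
  calls$stage <- "one_step"
  calls
}

#' Write the result table
#'
#' @param report an [OutlierReport-class].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(report, path) {
  utils::write.table(outlierCalls(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
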