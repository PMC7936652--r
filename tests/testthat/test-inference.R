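test_that("fits are bit-reproducible under a fixed seed", {
  cs <- fix_counts()
  model <- buildModel(cs, transcripts = rownames(cs)[1:8])
  st <- inferenceSettings("vb", seed = 3, vbDraws = 50L, vbMaxIter = 800L)
  f1 <- fitModel(model, st)
  f2 <- fitModel(model, st)
  expect_identical(f1@sigma, f2@sigma)
  expect_identical(f1@beta, f2@beta)
  expect_identical(f1@exposure, f2@exposure)
})

test_that("a Poisson-like intercept-only fit recovers the log sample mean", {
  set.seed(8)
  S <- 20L
  y <- matrix(rpois(S, 40), 1L, S,
              dimnames = list("g1", paste0("s", seq_len(S))))
  cs <- new("CountSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = y),
    rowData = S4Vectors::DataFrame(significance = 0.01, do_check = TRUE,
                                   row.names = "g1"),
    colData = S4Vectors::DataFrame(row.names = colnames(y))))
  designSpec(cs) <- DesignSpec(~ 1, as.data.frame(colData(cs)),
                               factorOfInterest = NA)
  fit <- fitModel(buildModel(cs), inferenceSettings("vb", seed = 2))
  b0 <- fit@beta[, 1L, 1L]
  expect_lt(abs(mean(b0) - log(mean(y))), 3 * sd(b0) + 0.02)
})

test_that("an unconverged variational fit raises a warning, not silence", {
  cs <- fix_counts()
  model <- buildModel(cs, transcripts = rownames(cs)[1:5])
  expect_warning(
    fit <- fitModel(model, inferenceSettings("vb", seed = 1,
                                             vbMaxIter = 2L,
                                             vbDraws = 20L)),
    "did not reach")
  expect_false(diagnostics(fit)$converged)
})

test_that("HMC converges with Rhat at most 1.01 on simulated data", {
  sc <- simulationScenario(G = 50L, S = 10L, nAnchors = 15L, seed = 21L)
  cs <- simulateCounts(sc)
  model <- buildModel(cs, transcripts = c(checkedTranscripts(cs),
                                          estimateExposureAnchors(cs, 15L)))
  fit <- fitModel(model, inferenceSettings("hmc", seed = 2))
  d <- diagnostics(fit)
  expect_lte(d$maxRhat, 1.01)
  expect_identical(d$divergences, 0L)
  expect_gte(nrow(fit@sigma), 500L)
  # backends agree on predictive summaries: median scaled difference of the
  # theoretical-distribution means stays below 0.1
  fv <- fitModel(model, inferenceSettings("vb", seed = 2))
  cb <- compareBackends(fit, fv)
  dmean <- subset(cb, quantity == "mean")
  expect_lt(median(abs(dmean$scaledDiff)), 0.1)
  # self-comparison is exactly zero
  cb0 <- compareBackends(fv, fv)
  expect_identical(max(abs(cb0$scaledDiff)), 0)
  fix_env$hmc_fit <- fit
  fix_env$hmc_vb <- fv
})

test_that("parameters are recovered from model-generated data", {
  sc <- simulationScenario(G = 100L, S = 12L, seed = 11L)
  cs <- simulateCounts(sc)
  tr <- S4Vectors::metadata(cs)$truth
  model <- buildModel(cs, transcripts = c(checkedTranscripts(cs),
                                          estimateExposureAnchors(cs, 30L)))
  fit <- fitModel(model, inferenceSettings("vb", seed = 2))
  checkedSel <- model@checked
  gi <- match(model@transcripts, tr$transcripts)
  bhat <- apply(fit@beta, c(2L, 3L), mean)[, checkedSel]
  btrue <- rbind(tr$beta0[gi], tr$beta1[gi])[, checkedSel]
  expect_gt(cor(c(bhat), c(btrue)), 0.95)
  expect_lt(max(abs(colMeans(fit@exposure) - tr$exposure)), 0.1)
})

test_that("the trend shrinks dispersion estimates toward the line", {
  # low-count transcripts: joint posterior sigma spread around the trend is
  # smaller than that of independent per-transcript ML estimates
  sc <- simulationScenario(G = 80L, S = 10L, nAnchors = 15L,
                           baselineMean = 2.5, baselineSd = 1, seed = 31L)
  cs <- simulateCounts(sc)
  tr <- S4Vectors::metadata(cs)$truth
  model <- buildModel(cs, transcripts = c(checkedTranscripts(cs),
                                          estimateExposureAnchors(cs, 15L)))
  fit <- fitModel(model, inferenceSettings("vb", seed = 4))
  checked <- checkedTranscripts(cs)
  y <- SummarizedExperiment::assay(cs, "counts")[checked, ]
  mlsig <- vapply(checked, function(g) {
    f <- tryCatch(ppcOutliers:::.nbFitMl(y[g, ]), error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$sigma
  }, 0)
  trendline <- mean(fit@trend[, "a"]) +
    mean(fit@trend[, "b"]) * apply(fit@beta[, 1L, checked], 2L, mean)
  fitsig <- colMeans(fit@sigma)[checked]
  ok <- is.finite(mlsig) & abs(mlsig) < 10
  expect_lt(stats::sd((fitsig - trendline)[ok]),
            stats::sd((mlsig - trendline)[ok]))
})

test_that("diagnostics dump to TSV", {
  fit <- fix_fit()
  p <- tempfile(fileext = ".tsv")
  writeDiagnostics(fit, p)
  d <- utils::read.delim(p)
  expect_identical(d$backend, "vb")
  expect_true(d$converged)
})
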