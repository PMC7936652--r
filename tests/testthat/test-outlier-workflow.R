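test_that("the deleterious rule is one-sided in the direction of change", {
  iv <- data.frame(sample = "s1", transcript = "g1", lower = 4, upper = 20,
                   nominal_coverage = 0.95, method = "approximated",
                   predictive_mean = 10)
  dirn <- data.frame(transcript = "g1", sign = 1L)
  up <- classifyDeleterious(iv, 35, dirn)
  expect_true(up$outlier)
  expect_true(up$deleterious)
  expect_identical(up$side, "above_upper")
  low <- classifyDeleterious(iv, 1, dirn)
  expect_true(low$outlier)
  expect_false(low$deleterious)
  mid <- classifyDeleterious(iv, 12, dirn)
  expect_false(mid$outlier)
  # for a decreasing transcript the rule mirrors
  down <- classifyDeleterious(iv, 1, data.frame(transcript = "g1",
                                                sign = -1L))
  expect_true(down$deleterious)
})

test_that("the FPR allocation follows fpr / (2 n) exactly", {
  expect_identical(allocateTestIntervalWidth(0.01, 5), 0.001)
  expect_identical(allocateTestIntervalWidth(0.02, 1), 0.01)
  expect_warning(
    w <- allocateTestIntervalWidth(0.01, 1000, nTheoreticalDraws = 20000L),
    "approximated")
  expect_identical(w, 5e-06)
})

test_that("the two-step pipeline flags injected outliers and is reproducible", {
  rep1 <- fix_report()
  ts <- transcriptSummary(rep1)
  truth <- S4Vectors::metadata(fix_injected())$truth$outliers
  # an extreme injected count on an estimated-increase transcript must be
  # in the quarantine and finally flagged
  calls <- outlierCalls(rep1)
  tkey <- paste(calls$sample, calls$transcript, sep = "\r")
  okey <- paste(truth$sample, truth$transcript, sep = "\r")
  hit <- calls[match(okey, tkey), ]
  up <- hit$direction > 0
  expect_gt(mean(hit$quarantined[up]), 0.3)
  expect_gt(mean(hit$final_flag[up]), 0.3)
  # flagged transcripts must carry a truly injected outlier far more often
  # than clean ones at these effect sizes
  flagged <- ts$transcript[ts$contains_outlier]
  expect_gt(mean(flagged %in% truth$transcript), 0.8)
  # ranks order by significance, ties by transcript id
  expect_equal(ts$rank, rank(order(order(ts$significance,
                                          ts$transcript))),
               ignore_attr = TRUE)
  # full determinism of the result table
  rep2 <- suppressMessages(suppressWarnings(
    identifyOutliers(fix_injected(),
                     config = testConfig(seed = 11, nAnchors = 10))))
  expect_identical(outlierCalls(rep2), calls)
})

test_that("a single extreme count on a strongly increased transcript is caught", {
  sc <- simulationScenario(G = 24L, S = 12L, nAnchors = 12L,
                           outlierFraction = 0, seed = 55L)
  cs <- simulateCounts(sc)
  tr <- S4Vectors::metadata(cs)$truth
  # the transcript with the largest positive effect, one massive count
  g <- tr$transcripts[which.max(tr$beta1[1:24])]
  s1 <- tr$samples[sc$S]   # a condition-B replicate
  y <- SummarizedExperiment::assay(cs, "counts")
  gi <- match(g, rownames(y))
  y[gi, s1] <- qnbinom(1 - 1e-10, size = exp(tr$sigma[match(g, tr$transcripts)]),
                       mu = tr$mu[sc$S, match(g, tr$transcripts)])
  SummarizedExperiment::assay(cs, "counts") <- y
  disc <- suppressMessages(runDiscovery(cs, testConfig(seed = 2,
                                                       nAnchors = 10)))
  qk <- paste(disc$quarantine$sample, disc$quarantine$transcript)
  expect_true(paste(s1, g) %in% qk)
  tst <- suppressMessages(suppressWarnings(
    runTest(cs, testConfig(seed = 2, nAnchors = 10), disc)))
  flag <- tst$calls$final_flag[tst$calls$sample == s1 &
                               tst$calls$transcript == g]
  expect_true(flag)
})

test_that("a quarantine of size one is tested at tail fpr/2", {
  rep1 <- fix_report()
  calls <- outlierCalls(rep1)
  # reconstruct through the exported pieces: per-gene allocation gives
  # fpr / (2 * k) with k the transcript's quarantined candidates
  disc <- suppressMessages(runDiscovery(fix_injected(),
                                        testConfig(seed = 11, nAnchors = 10)))
  k <- table(disc$quarantine$transcript)
  one_gene <- names(k)[k == 1L][1L]
  skip_if(is.na(one_gene))
  tst <- suppressMessages(runTest(fix_injected(),
                                  testConfig(seed = 11, nAnchors = 10),
                                  disc, fprTest = 0.01))
  got <- unique(tst$calls$tail[tst$calls$transcript == one_gene])
  expect_identical(got, 0.005)
})

test_that("empty checked sets degrade gracefully", {
  cs <- fix_counts()
  SummarizedExperiment::rowData(cs)$do_check <- FALSE
  expect_warning(rep0 <- identifyOutliers(cs, config = testConfig(seed = 1)),
                 "no checked")
  expect_identical(nrow(transcriptSummary(rep0)), 0L)
  expect_warning(d <- runDiscovery(cs, testConfig(seed = 1)), "no checked")
  expect_null(d$fit)
})

test_that("discovery outliers are rare and balanced on clean data", {
  disc <- suppressMessages(runDiscovery(fix_counts(),
                                        testConfig(seed = 7, nAnchors = 10)))
  frac_out <- mean(disc$calls$outlier)
  expect_gt(frac_out, 0)
  expect_lt(frac_out, 0.07)
  # roughly half of the outliers sit on the deleterious side
  expect_gte(mean(disc$calls$deleterious[disc$calls$outlier]), 0.2)
  expect_lte(mean(disc$calls$deleterious[disc$calls$outlier]), 0.8)
})

test_that("result tables and manifests are written", {
  rep1 <- fix_report()
  p <- tempfile(fileext = ".tsv")
  writeResultTable(rep1, p)
  tab <- utils::read.delim(p)
  expect_identical(nrow(tab), nrow(outlierCalls(rep1)))
  pm <- tempfile(fileext = ".json")
  writeRunManifest(rep1, pm)
  man <- jsonlite::fromJSON(pm)
  expect_identical(man$config$seed, 11L)
  expect_identical(man$config$backend, "vb")
})

test_that("per-transcript plots build", {
  rep1 <- fix_report()
  g <- transcriptSummary(rep1)$transcript[1L]
  expect_s3_class(plotTranscript(rep1, g), "ggplot")
  expect_error(plotTranscript(rep1, "nope"), "not in the report")
})
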