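test_that("predictive draws are seeded, sized and mean-correct", {
  fit <- fix_degenerate_fit(mu = 10, sigma = 2)
  g <- fit@model@transcripts[1L]
  s <- fit@model@samples[1L]
  expect_length(predictiveDraws(fit, s, g, 0L), 0L)
  d1 <- predictiveDraws(fit, s, g, 500L, seed = 4)
  d2 <- predictiveDraws(fit, s, g, 500L, seed = 4)
  expect_identical(d1, d2)
  # Monte-Carlo oracle on the degenerate posterior
  xs <- predictiveDraws(fit, s, g, 1e5, seed = 9)
  se <- sd(xs) / sqrt(length(xs))
  expect_lt(abs(mean(xs) - 10), 3 * se)
  expect_error(predictiveDraws(fit, "nope", g), "unknown \\(sample")
})

test_that("sampled intervals match analytic NB quantiles for a degenerate posterior", {
  fit <- fix_degenerate_fit(mu = 10, sigma = 2)
  g <- fit@model@transcripts[1L]; s <- fit@model@samples[1L]
  iv <- intervalSampled(fit, s, g, 0.95, nDraws = 2e5, seed = 31)
  expect_lte(abs(iv$lower - qnbinom(0.025, size = exp(2), mu = 10)), 1)
  expect_lte(abs(iv$upper - qnbinom(0.975, size = exp(2), mu = 10)), 1)
  # zero-coverage convention: a point interval at the predictive median
  iv0 <- intervalSampled(fit, s, g, 0, nDraws = 2e4, seed = 5)
  expect_identical(iv0$lower, iv0$upper)
  expect_warning(intervalSampled(fit, s, g, 0.999, nDraws = 100L),
                 "small for tail")
})

test_that("approximated intervals equal analytic quantiles for identical draws", {
  fit <- fix_degenerate_fit(mu = 25, sigma = 1)
  g <- fit@model@transcripts[1L]; s <- fit@model@samples[1L]
  iv <- intervalApproximated(fit, s, g, 0.95)
  expect_identical(iv$lower, qnbinom(0.025, size = exp(1), mu = 25))
  expect_identical(iv$upper, qnbinom(0.975, size = exp(1), mu = 25))
  # the mixture-CDF variant agrees on a degenerate posterior too
  ivm <- intervalApproximated(fit, s, g, 0.95, mixture = TRUE)
  expect_identical(ivm$lower, iv$lower)
  expect_identical(ivm$upper, iv$upper)
})

test_that("observation quantiles follow the mixture CDF", {
  fit <- fix_degenerate_fit(mu = 10, sigma = 2)
  g <- fit@model@transcripts[1L]; s <- fit@model@samples[1L]
  expect_equal(quantileOfObservation(fit, s, g, 7),
               pnbinom(7, size = exp(2), mu = 10))
  expect_gt(quantileOfObservation(fit, s, g, 1e6), 1 - 1e-6)
  expect_identical(quantileOfObservation(fit, s, g, 0, right = TRUE), 1)
})

test_that("widening the coverage never shrinks an interval", {
  fit <- fix_fit()
  g <- fit@model@transcripts[3L]; s <- fit@model@samples[2L]
  covs <- c(0.5, 0.8, 0.9, 0.95, 0.99, 0.999)
  ivs <- do.call(rbind, lapply(covs, function(cc) {
    intervalApproximated(fit, s, g, cc)
  }))
  expect_true(all(diff(ivs$lower) <= 0))
  expect_true(all(diff(ivs$upper) >= 0))
})

test_that("95% intervals cover model-generated observations", {
  fit <- fix_fit()
  cs <- fix_counts()
  checked <- checkedTranscripts(cs)
  ti <- theoreticalIntervals(fit, 0.95, "approximated",
                             transcripts = checked)
  y <- SummarizedExperiment::assay(cs, "counts")
  obs <- y[cbind(match(ti$transcript, rownames(y)),
                 match(ti$sample, colnames(y)))]
  inside <- mean(obs >= ti$lower & obs <= ti$upper)
  n <- length(obs)
  mc <- 3 * sqrt(0.05 * 0.95 / n)
  # nominal 0.95, allowing Monte-Carlo error at this sample size (the
  # posterior predictive is slightly conservative at small S)
  expect_gte(inside, 0.95 - mc)
  expect_lte(inside, 1)
})

test_that("the vectorized interval table matches the single-pair function", {
  fit <- fix_fit()
  checked <- checkedTranscripts(fix_counts())[1:4]
  ti <- theoreticalIntervals(fit, 0.9, "approximated", transcripts = checked)
  one <- intervalApproximated(fit, ti$sample[5L], ti$transcript[5L], 0.9)
  row <- ti[ti$sample == one$sample & ti$transcript == one$transcript, ]
  expect_equal(row$lower, one$lower)
  expect_equal(row$upper, one$upper)
})
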