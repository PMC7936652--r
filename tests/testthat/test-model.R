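test_that("model assembly keeps the expected dimensions", {
  cs <- fix_counts()
  g1 <- rownames(cs)[1L]
  # single transcript, intercept-only design: 1 coefficient, 1 sigma,
  # S exposures, 3 trend hyperparameters
  designSpec(cs) <- DesignSpec(~ 1, as.data.frame(colData(cs)),
                               factorOfInterest = NA)
  m <- buildModel(cs, transcripts = g1)
  obj <- ppcOutliers:::.makeObjective(m)
  S <- ncol(cs)
  expect_identical(obj$dims$p, 1L)
  expect_identical(obj$dims$G, 1L)
  u <- obj$unpack(obj$init())
  expect_length(u$e, S)
  expect_length(u$sigma, 1L)
  expect_length(c(u$a, u$b, u$ltau), 3L)
})

test_that("truncating one data point changes only its likelihood term", {
  cs <- fix_counts()
  tx <- checkedTranscripts(cs)[1:3]
  m0 <- buildModel(cs, transcripts = tx)
  y11 <- m0@counts[1L, 1L]
  tr <- data.frame(sample = m0@samples[1L], transcript = tx[1L],
                   lower = max(0, y11 - 5), upper = y11 + 20)
  m1 <- buildModel(cs, transcripts = tx, truncation = tr)
  o0 <- ppcOutliers:::.makeObjective(m0)
  o1 <- ppcOutliers:::.makeObjective(m1)
  th <- o0$init()
  u <- o0$unpack(th)
  mu11 <- exp((m0@design %*% u$beta)[1L, 1L] + u$e[1L])
  # independent renormalization oracle: brute-force pmf sum over the bounds
  z <- sum(dnbinom(tr$lower:tr$upper, size = exp(u$sigma[1L]), mu = mu11))
  expect_equal(o0$lp(th) - o1$lp(th), log(z), tolerance = 1e-8)
  expect_error(
    buildModel(cs, transcripts = tx,
               truncation = data.frame(sample = "nope", transcript = tx[1L],
                                       lower = 0, upper = 10)),
    "unknown \\(sample, transcript\\)")
})

test_that("exposure anchors prefer the most stable housekeeping transcripts", {
  # balanced totals: three constant transcripts are exactly the most stable
  set.seed(3)
  samples <- paste0("s", 1:4)
  const <- matrix(50L, 3, 4)
  noisy <- matrix(rpois(28, 50), 7, 4)
  # rebalance so library sizes are equal across samples
  y <- rbind(const, noisy)
  rownames(y) <- sprintf("hk%02d", 1:10)
  colnames(y) <- samples
  checked <- matrix(rpois(8, 100), 2, 4,
                    dimnames = list(c("gA", "gB"), samples))
  ymat <- rbind(checked, y)
  cs <- new("CountSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = ymat),
    rowData = S4Vectors::DataFrame(
      significance = c(0.01, 0.01, rep(NA, 10)),
      do_check = c(TRUE, TRUE, rep(FALSE, 10)),
      row.names = rownames(ymat)),
    colData = S4Vectors::DataFrame(condition = c("a", "a", "b", "b"),
                                   row.names = samples)))
  # equalize totals exactly by padding the last noisy transcript
  tot <- colSums(ymat)
  ymat["hk10", ] <- ymat["hk10", ] + max(tot) - tot
  SummarizedExperiment::assay(cs, "counts") <- ymat
  sel <- estimateExposureAnchors(cs, 3L)
  expect_setequal(sel, c("hk01", "hk02", "hk03"))
  expect_warning(all4 <- estimateExposureAnchors(cs[1:6, ], 5L),
                 "using all")
  expect_length(all4, 4L)
  allchecked <- cs
  SummarizedExperiment::rowData(allchecked)$do_check <- TRUE
  expect_error(estimateExposureAnchors(allchecked, 3L),
               "no anchor candidates")
})

test_that("the joint gradient matches finite differences", {
  cs <- fix_counts()
  tx <- rownames(cs)[c(1:4, 25:28)]
  tr <- data.frame(sample = rep(colnames(cs)[1:2], 2),
                   transcript = rep(tx[c(2, 4)], each = 2))
  y <- SummarizedExperiment::assay(cs, "counts")
  obs <- y[cbind(match(tr$transcript, rownames(y)),
                 match(tr$sample, colnames(y)))]
  tr$lower <- pmax(0, floor(obs * 0.5))
  tr$upper <- ceiling(obs * 2 + 10)
  ex <- data.frame(sample = colnames(cs)[3L], transcript = tx[1L])
  m <- buildModel(cs, transcripts = tx, truncation = tr, exclude = ex)
  obj <- ppcOutliers:::.makeObjective(m)
  set.seed(5)
  th <- obj$init() + rnorm(obj$npar, 0, 0.2)
  ga <- obj$gr(th)
  gn <- vapply(seq_len(obj$npar), function(i) {
    h <- 1e-5; tp <- th; tm <- th
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (obj$lp(tp) - obj$lp(tm)) / (2 * h)
  }, 0)
  expect_lt(max(abs(ga - gn)), 1e-4)
})

test_that("model descriptions serialize to JSON", {
  cs <- fix_counts()
  m <- buildModel(cs, transcripts = rownames(cs)[1:5])
  js <- serializeModel(m)
  parsed <- jsonlite::fromJSON(js)
  expect_identical(parsed$nTranscripts, 5L)
  expect_identical(parsed$nSamples, ncol(cs))
  expect_identical(parsed$priors$betaSd, 5L)
})
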