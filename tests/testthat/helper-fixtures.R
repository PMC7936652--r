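# Shared fixtures, built once per test run.  Everything is generated in code
# at small scale; the heavier objects are created lazily and cached.

fix_env <- new.env()

fix_scenario <- function() {
  simulationScenario(G = 30L, S = 10L, nAnchors = 12L, seed = 101L)
}

fix_counts <- function() {
  if (is.null(fix_env$cs)) fix_env$cs <- simulateCounts(fix_scenario())
  fix_env$cs
}

fix_fit <- function() {
  if (is.null(fix_env$fit)) {
    cs <- fix_counts()
    model <- buildModel(cs, transcripts = c(checkedTranscripts(cs),
                                            estimateExposureAnchors(cs, 10)))
    fix_env$fit <- fitModel(model, inferenceSettings("vb", seed = 7))
  }
  fix_env$fit
}

fix_injected <- function() {
  if (is.null(fix_env$csI)) {
    sc <- fix_scenario()
    fix_env$csI <- injectOutliers(simulateCounts(sc), sc)
  }
  fix_env$csI
}

fix_report <- function() {
  if (is.null(fix_env$report)) {
    fix_env$report <- suppressMessages(suppressWarnings(
      identifyOutliers(fix_injected(),
                       config = testConfig(seed = 11, nAnchors = 10))))
  }
  fix_env$report
}

# degenerate posterior: every draw identical, handy for analytic oracles
fix_degenerate_fit <- function(mu = 10, sigma = 2, D = 50L) {
  cs <- fix_counts()
  model <- buildModel(cs, transcripts = rownames(cs)[1:2])
  p <- ncol(model@design); S <- nrow(model@counts)
  beta <- array(0, c(D, p, 2L))
  beta[, 1L, ] <- log(mu)   # intercept only; effect 0
  new("PosteriorFit", model = model, backend = "vb",
      beta = beta,
      sigma = matrix(sigma, D, 2L,
                     dimnames = list(NULL, model@transcripts)),
      exposure = matrix(0, D, S, dimnames = list(NULL, model@samples)),
      trend = matrix(c(0, 0, 1), D, 3L, byrow = TRUE,
                     dimnames = list(NULL, c("a", "b", "tau"))),
      diagnostics = list(converged = TRUE), seed = 1L)
}

# tiny tidy table for ingest tests; balanced totals so constant-count
# transcripts really are the most stable anchors
tiny_long_table <- function() {
  grid <- expand.grid(sample = c("s1", "s2"), transcript = c("tA", "tB"),
                      stringsAsFactors = FALSE)
  grid$count <- c(5L, 7L, 9L, 7L)
  grid$condition <- ifelse(grid$sample == "s1", "ctrl", "case")
  grid$pval <- ifelse(grid$transcript == "tA", 0.001, 0.8)
  grid$sig <- grid$transcript == "tA"
  grid
}
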