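#' Inference settings
#'
#' Defaults follow common practice for this model family: 300 warmup
#' iterations for HMC with target acceptance 0.8, and for the variational
#' backend at most 50000 iterations with stopping tolerance 0.01 on the
#' relative change of the smoothed evidence lower bound.
#'
#' @param backend `"vb"` (mean-field Gaussian variational approximation,
#'   default) or `"hmc"` (adaptive Hamiltonian Monte Carlo).
#' @param chains number of HMC chains.
#' @param warmup HMC warmup iterations (step size and diagonal mass
#'   adaptation); at least 100.
#' @param iter posterior draws per HMC chain after warmup.
#' @param targetAccept dual-averaging target acceptance probability.
#' @param vbMaxIter maximum stochastic-gradient iterations.
#' @param vbTol relative ELBO-change stopping tolerance (> 0).
#' @param vbDraws posterior draws sampled from the fitted approximation.
#' @param vbSamplesPerIter Monte Carlo gradient samples per iteration.
#' @param vbLearningRate Adam step size.
#' @param seed integer seed; identical seed and settings give identical
#'   draws.
#' @return a named list of class `ppc_inference_settings`.
#' @export
inferenceSettings <- function(backend = c("vb", "hmc"), chains = 2L,
                              warmup = 300L, iter = 500L,
                              targetAccept = 0.8,
                              vbMaxIter = 50000L, vbTol = 0.01,
                              vbDraws = 500L, vbSamplesPerIter = 2L,
                              vbLearningRate = 0.01, seed = 1L) {
  backend <- match.arg(backend)
  if (backend == "hmc" && warmup < 100L) stop("warmup must be >= 100 for hmc")
  if (vbTol <= 0) stop("vbTol must be > 0")
  out <- list(backend = backend, chains = as.integer(chains),
              warmup = as.integer(warmup), iter = as.integer(iter),
              targetAccept = targetAccept,
              vbMaxIter = as.integer(vbMaxIter), vbTol = vbTol,
              vbDraws = as.integer(vbDraws),
              vbSamplesPerIter = as.integer(vbSamplesPerIter),
              vbLearningRate = vbLearningRate, seed = as.integer(seed))
  class(out) <- "ppc_inference_settings"
  out
}

# Posterior mode on the unconstrained scale; starting point for both backends.
.mapEstimate <- function(obj, start = NULL, maxIter = 1500L) {
  if (is.null(start)) start <- obj$init()
  o <- stats::nlminb(start, function(th) -obj$lp(th),
                     function(th) -obj$gr(th),
                     control = list(iter.max = maxIter,
                                    eval.max = 2L * maxIter))
  list(par = o$par, objective = o$objective,
       converged = o$convergence %in% c(0L, 1L))
}

# Mean-field Gaussian variational fit by stochastic gradient ascent on the
# ELBO (reparameterization gradients, Adam updates, exponential iterate
# averaging).  Stopping follows the usual rule for this family of
# optimizers: the relative change of the smoothed ELBO, checked on a fixed
# cadence, must fall below `vbTol`.
.adviFit <- function(obj, map, settings) {
  d <- obj$npar
  m <- map$par
  ls <- rep(-2, d)
  lr <- settings$vbLearningRate
  nmc <- settings$vbSamplesPerIter
  maxIt <- settings$vbMaxIter
  checkEvery <- 50L
  minIt <- min(if (isTRUE(settings$warmStarted)) 300L else 600L, maxIt)
  am <- av <- numeric(2L * d)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  ema_m <- m; ema_ls <- ls; ema_a <- 0.02
  elbo <- function(mm, ll) {
    s <- exp(ll)
    mean(vapply(seq_len(10L), function(k) obj$lp(mm + s * stats::rnorm(d)),
                0)) + sum(ll)
  }
  hist_elbo <- c()
  converged <- FALSE
  itDone <- maxIt
  for (itn in seq_len(maxIt)) {
    s <- exp(ls)
    gm <- numeric(d); gl <- numeric(d)
    for (k in seq_len(nmc)) {
      z <- stats::rnorm(d)
      g <- obj$gr(m + s * z)
      gm <- gm + g / nmc
      gl <- gl + (g * s * z) / nmc
    }
    gl <- gl + 1  # entropy gradient on the log-sd scale
    gall <- c(gm, gl)
    am <- b1 * am + (1 - b1) * gall
    av <- b2 * av + (1 - b2) * gall^2
    ah <- am / (1 - b1^itn); vh <- av / (1 - b2^itn)
    step <- lr * ah / (sqrt(vh) + eps)
    m <- m + step[seq_len(d)]
    ls <- ls + step[d + seq_len(d)]
    ema_m <- (1 - ema_a) * ema_m + ema_a * m
    ema_ls <- (1 - ema_a) * ema_ls + ema_a * ls
    if (itn %% checkEvery == 0L && itn >= minIt) {
      hist_elbo <- c(hist_elbo, elbo(ema_m, ema_ls))
      nh <- length(hist_elbo)
      if (nh >= 2L) {
        rel <- abs(hist_elbo[nh] - hist_elbo[nh - 1L]) /
          (abs(hist_elbo[nh]) + 1e-12)
        if (rel < settings$vbTol) { converged <- TRUE; itDone <- itn; break }
      }
    }
  }
  if (!converged) {
    warning("variational fit did not reach the stopping tolerance within ",
            maxIt, " iterations")
  }
  D <- settings$vbDraws
  s <- exp(ema_ls)
  draws <- matrix(stats::rnorm(D * d), D, d)
  draws <- sweep(sweep(draws, 2L, s, "*"), 2L, ema_m, "+")
  list(draws = draws, iterations = itDone, converged = converged,
       elboHistory = hist_elbo)
}

# One HMC chain with dual-averaging step-size adaptation and diagonal mass
# estimated from the middle of warmup.
.hmcChain <- function(obj, map, settings, chainSeed) {
  set.seed(chainSeed)
  d <- obj$npar
  warmup <- settings$warmup; iter <- settings$iter
  q <- map$par
  invM <- rep(1, d)
  lpq <- obj$lp(q); grq <- obj$gr(q)

  leapfrog <- function(q, p, eps, L) {
    g <- obj$gr(q)
    for (l in seq_len(L)) {
      p <- p + 0.5 * eps * g
      q <- q + eps * (invM * p)
      g <- obj$gr(q)
      if (any(!is.finite(g))) return(list(q = q, p = p, ok = FALSE))
      p <- p + 0.5 * eps * g
    }
    list(q = q, p = p, ok = TRUE)
  }
  hamiltonian <- function(q, p) -obj$lp(q) + 0.5 * sum(p^2 * invM)

  # cheap reasonable initial step size
  eps <- 0.1 / d^0.25
  p0 <- stats::rnorm(d, 0, sqrt(1 / invM))
  h0 <- hamiltonian(q, p0)
  for (k in seq_len(20L)) {
    st <- leapfrog(q, p0, eps, 1L)
    dh <- if (st$ok) h0 - hamiltonian(st$q, st$p) else -Inf
    a <- exp(min(0, dh))
    if (is.finite(a) && a > 0.5) break
    eps <- eps / 2
  }

  # dual averaging (restarted when the mass matrix is updated)
  mu <- log(10 * eps); lebar <- 0; Hbar <- 0; m0 <- 0L
  gam <- 0.05; t0 <- 10; kap <- 0.75
  collect_from <- floor(warmup * 0.25); collect_to <- floor(warmup * 0.75)
  pos <- matrix(0, collect_to - collect_from + 1L, d)
  basis_len <- 1.2
  divergences <- 0L
  acc_sum <- 0
  total <- warmup + iter
  draws <- matrix(0, iter, d)
  for (itn in seq_len(total)) {
    p <- stats::rnorm(d, 0, sqrt(1 / invM))
    h0 <- hamiltonian(q, p)
    L <- max(1L, min(64L, round(stats::runif(1, 0.8, 1.2) * basis_len / eps)))
    st <- leapfrog(q, p, eps, L)
    h1 <- if (st$ok) hamiltonian(st$q, st$p) else Inf
    dh <- h0 - h1
    if (!is.finite(dh) || dh < -1000) {
      divergences <- divergences + (itn > warmup)
      aprob <- 0
    } else {
      aprob <- exp(min(0, dh))
      if (stats::runif(1) < aprob) q <- st$q
    }
    if (itn <= warmup) {
      mstep <- itn - m0
      Hbar <- (1 - 1 / (mstep + t0)) * Hbar +
        (settings$targetAccept - aprob) / (mstep + t0)
      leps <- mu - sqrt(mstep) / gam * Hbar
      lebar <- mstep^(-kap) * leps + (1 - mstep^(-kap)) * lebar
      eps <- exp(leps)
      if (itn >= collect_from && itn <= collect_to) {
        pos[itn - collect_from + 1L, ] <- q
      }
      if (itn == collect_to) {
        v <- apply(pos, 2L, stats::var)
        n0 <- nrow(pos)
        invM <- (n0 / (n0 + 5)) * v + (5 / (n0 + 5)) * 1e-3
        basis_len <- 2.8
        # geometry changed: restart step-size adaptation around a fresh guess
        eps <- 0.3
        mu <- log(10 * eps); lebar <- 0; Hbar <- 0; m0 <- itn
      }
      if (itn == warmup) eps <- exp(lebar)
    } else {
      acc_sum <- acc_sum + aprob
      draws[itn - warmup, ] <- q
    }
  }
  list(draws = draws, accept = acc_sum / iter, divergences = divergences,
       stepSize = eps)
}

# Classic split-Rhat over chains (each chain halved).
.splitRhat <- function(chainList) {
  halves <- list()
  for (ch in chainList) {
    n <- nrow(ch); h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(h + 1L):(2L * h), , drop = FALSE]))
  }
  m <- length(halves); n <- nrow(halves[[1L]])
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1L]])))
  vars <- vapply(halves, function(x) apply(x, 2L, stats::var),
                 numeric(ncol(halves[[1L]])))
  B <- n * apply(means, 1L, stats::var)
  Wv <- rowMeans(vars)
  sqrt(((n - 1) / n * Wv + B / n) / pmax(Wv, 1e-300))
}

#' Fit the joint model
#'
#' Runs the selected backend from a common posterior-mode starting point and
#' returns posterior draws with diagnostics.  HMC fits are flagged (with a
#' warning) when the maximum split-Rhat exceeds 1.01; variational fits when
#' the stopping tolerance was not reached.
#'
#' @param model an [NbModel-class].
#' @param settings an [inferenceSettings()] list.
#' @param init optional warm start: a [PosteriorFit-class] of a model with
#'   the same dimensions (e.g. the discovery fit when refitting at the test
#'   step); posterior means seed the mode search.
#' @return a [PosteriorFit-class].
#' @export
fitModel <- function(model, settings = inferenceSettings(), init = NULL) {
  obj <- .makeObjective(model)
  set.seed(settings$seed)
  start <- NULL
  if (!is.null(init)) {
    tm <- colMeans(init@trend)
    start <- obj$pack(apply(init@beta, c(2L, 3L), mean),
                      colMeans(init@sigma), colMeans(init@exposure),
                      tm[["a"]], tm[["b"]], tm[["tau"]])
    settings$warmStarted <- TRUE
  }
  map <- .mapEstimate(obj, start,
                      maxIter = if (is.null(start)) 1500L else 300L)
  diag <- list(backend = settings$backend, mapConverged = map$converged,
               maxRhat = NA_real_)
  if (settings$backend == "vb") {
    vb <- .adviFit(obj, map, settings)
    TH <- vb$draws
    diag$converged <- vb$converged
    diag$iterations <- vb$iterations
    diag$elboHistory <- vb$elboHistory
  } else {
    chains <- lapply(seq_len(settings$chains), function(ch) {
      .hmcChain(obj, map, settings, chainSeed = settings$seed + 1009L * ch)
    })
    TH <- do.call(rbind, lapply(chains, `[[`, "draws"))
    rh <- .splitRhat(lapply(chains, `[[`, "draws"))
    diag$maxRhat <- max(rh, na.rm = TRUE)
    diag$rhat <- rh
    diag$accept <- vapply(chains, `[[`, 0, "accept")
    diag$divergences <- sum(vapply(chains, `[[`, 0L, "divergences"))
    diag$stepSize <- vapply(chains, `[[`, 0, "stepSize")
    diag$converged <- diag$maxRhat <= 1.01 && diag$divergences == 0L
    if (diag$maxRhat > 1.01) {
      warning("HMC fit did not converge: max split-Rhat = ",
              round(diag$maxRhat, 3))
    }
  }
  .fitFromDraws(model, TH, obj, settings, diag)
}

.fitFromDraws <- function(model, TH, obj, settings, diag) {
  D <- nrow(TH)
  dm <- obj$dims
  u1 <- obj$unpack(TH[1L, ])
  beta <- array(0, c(D, dm$p, dm$G))
  sigma <- matrix(0, D, dm$G)
  expo <- matrix(0, D, dm$S)
  trend <- matrix(0, D, 3L, dimnames = list(NULL, c("a", "b", "tau")))
  for (dd in seq_len(D)) {
    u <- obj$unpack(TH[dd, ])
    beta[dd, , ] <- u$beta
    sigma[dd, ] <- u$sigma
    expo[dd, ] <- u$e
    trend[dd, ] <- c(u$a, u$b, u$tau)
  }
  dimnames(beta) <- list(NULL, colnames(model@design), model@transcripts)
  colnames(sigma) <- model@transcripts
  colnames(expo) <- model@samples
  new("PosteriorFit", model = model, backend = settings$backend,
      beta = beta, sigma = sigma, exposure = expo, trend = trend,
      diagnostics = diag, seed = settings$seed)
}

#' Write a diagnostics table
#'
#' @param fit a [PosteriorFit-class].
#' @param path TSV output path.
#' @return the diagnostics data.frame, invisibly.
#' @export
writeDiagnostics <- function(fit, path) {
  d <- fit@diagnostics
  df <- data.frame(
    backend = fit@backend,
    converged = isTRUE(d$converged),
    maxRhat = if (is.null(d$maxRhat)) NA_real_ else d$maxRhat,
    iterations = if (is.null(d$iterations)) NA_integer_ else d$iterations,
    divergences = if (is.null(d$divergences)) NA_integer_ else d$divergences,
    draws = nrow(fit@sigma)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Compare two fitted backends on predictive summaries
#'
#' For every modelled data point, computes the theoretical-distribution mean
#' and the central credible-interval endpoints under each fit (approximated
#' method) and returns their differences scaled by the predictive mean of
#' the reference fit — the same scaling for all three quantities, which is
#' why upper-endpoint discrepancies look much larger than lower-endpoint
#' ones for right-skewed count distributions.
#'
#' @param fit reference [PosteriorFit-class].
#' @param other comparison fit of the same model dimensions.
#' @param coverage central interval coverage (default 0.95).
#' @return data.frame with one row per (sample, transcript, quantity) and a
#'   `summary` attribute of mean absolute scaled differences.
#' @export
compareBackends <- function(fit, other, coverage = 0.95) {
  if (!identical(dim(fit@model@counts), dim(other@model@counts))) {
    stop("fits have different model dimensions")
  }
  a <- .predictiveSummaries(fit, coverage)
  b <- .predictiveSummaries(other, coverage)
  ref_mean <- pmax(a$mean, 1e-9)
  out <- data.frame(
    sample = rep(a$sample, 3L),
    transcript = rep(a$transcript, 3L),
    quantity = rep(c("mean", "lower", "upper"), each = nrow(a)),
    reference = c(a$mean, a$lower, a$upper),
    comparison = c(b$mean, b$lower, b$upper),
    scaledDiff = c((b$mean - a$mean) / ref_mean,
                   (b$lower - a$lower) / ref_mean,
                   (b$upper - a$upper) / ref_mean)
  )
  sm <- stats::aggregate(abs(out$scaledDiff),
                         by = list(quantity = out$quantity), FUN = mean)
  names(sm)[2L] <- "meanAbsScaledDiff"
  attr(out, "summary") <- sm
  out
}
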