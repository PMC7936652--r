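.defaultPriors <- function() {
  list(betaSd = 5, aSd = 2, bSd = 1, tauScale = 1, exposureSd = 1)
}

#' Select housekeeping anchor transcripts for the exposure term
#'
#' The per-sample exposure (sequencing-depth) parameters are only weakly
#' identified from differentially abundant transcripts alone, so a set of
#' stably expressed, non-checked transcripts is included in the fit.
#' Candidates are transcripts with `do_check = FALSE`; the `nAnchor` with the
#' smallest between-sample variance of log counts-per-total are selected
#' (ties broken by transcript id).
#'
#' @param x a [CountSet-class].
#' @param nAnchor how many anchors to select.
#' @return character vector of transcript ids.
#' @export
estimateExposureAnchors <- function(x, nAnchor = 20L) {
  rd <- rowData(x)
  cand <- rownames(x)[!rd$do_check]
  if (!length(cand)) stop("no anchor candidates: all transcripts are checked")
  y <- assay(x, "counts")
  tot <- colSums(y)
  v <- apply(log((y[cand, , drop = FALSE] + 0.5) /
                 rep(tot, each = length(cand))), 1L, stats::var)
  if (length(cand) < nAnchor) {
    warning("only ", length(cand), " anchor candidate(s) available (",
            nAnchor, " requested); using all")
    nAnchor <- length(cand)
  }
  cand[order(v, cand)][seq_len(nAnchor)]
}

#' Assemble the joint hierarchical NB model
#'
#' Encodes the model fitted at both workflow stages: per-transcript
#' regression coefficients, per-transcript log-size parameters shrunk toward
#' a linear trend on the log baseline abundance, and sum-to-zero per-sample
#' exposures.  Individual data points can be truncated (test-stage
#' compensation for quarantine) or excluded from the likelihood entirely.
#'
#' @param x a [CountSet-class] with a design attached (see [DesignSpec()]).
#' @param transcripts transcripts to model; default all in `x`.
#' @param truncation optional data.frame with columns
#'   `sample`, `transcript`, `lower`, `upper` of integer-inclusive bounds.
#' @param exclude optional data.frame with columns `sample`, `transcript` of
#'   data points removed from the likelihood.
#' @param priors optional overrides of the prior hyperparameters
#'   (`betaSd`, `aSd`, `bSd`, `tauScale`, `exposureSd`).
#' @return an [NbModel-class].
#' @export
buildModel <- function(x, transcripts = NULL, truncation = NULL,
                       exclude = NULL, priors = list()) {
  ds <- designSpec(x)
  if (is.null(ds)) stop("no design attached: use ingestCounts() or designSpec()<-")
  if (is.null(transcripts)) transcripts <- rownames(x)
  missing_t <- setdiff(transcripts, rownames(x))
  if (length(missing_t)) stop("unknown transcript(s): ",
                              paste(missing_t, collapse = ", "))
  y <- t(assay(x, "counts")[transcripts, , drop = FALSE])  # S x G
  if (anyNA(y)) stop("modelled transcripts must be observed in every sample")
  S <- nrow(y); G <- ncol(y)
  samples <- rownames(y)
  include <- matrix(1, S, G, dimnames = dimnames(y))
  tl <- matrix(NA_real_, S, G, dimnames = dimnames(y))
  tu <- matrix(NA_real_, S, G, dimnames = dimnames(y))

  lookup <- function(df, what) {
    i <- match(as.character(df$sample), samples)
    j <- match(as.character(df$transcript), transcripts)
    bad <- is.na(i) | is.na(j)
    if (any(bad)) {
      stop(what, " references unknown (sample, transcript) pair(s): ",
           paste0("(", df$sample[bad], ", ", df$transcript[bad], ")",
                  collapse = ", "))
    }
    cbind(i, j)
  }
  if (!is.null(truncation) && nrow(truncation)) {
    ij <- lookup(truncation, "truncation")
    tl[ij] <- truncation$lower
    tu[ij] <- truncation$upper
  }
  if (!is.null(exclude) && nrow(exclude)) {
    include[lookup(exclude, "exclude")] <- 0
  }
  inTrunc <- include == 1 & !is.na(tl)
  if (any(inTrunc & (y < tl | y > tu))) {
    stop("a retained observation lies outside its truncation bounds; ",
         "widen the bounds or exclude the point")
  }
  pr <- utils::modifyList(.defaultPriors(), priors)
  rd <- rowData(x)[transcripts, , drop = FALSE]
  new("NbModel", counts = y, design = ds@design, transcripts = transcripts,
      samples = samples, checked = rd$do_check, include = include,
      truncLower = tl, truncUpper = tu, priors = pr,
      interceptIndex = as.integer(
        if ("(Intercept)" %in% colnames(ds@design)) {
          which(colnames(ds@design) == "(Intercept)")
        } else 0L),
      coefIndex = ds@coefIndex)
}

# Log-posterior and analytic gradient of the joint model on the unconstrained
# scale.  The per-transcript log-size is non-centered
# (sigma = a + b * lambda + tau * z) to avoid the funnel between tau and the
# transcript-level deviations.  Truncated likelihood terms subtract the log
# normalizing constant over [lower, upper]; its derivative in the mean
# direction is exact (through the regularized incomplete beta) and in the
# log-size direction a forward difference off the cached constant.
.makeObjective <- function(model) {
  y <- model@counts; X <- model@design; W <- model@include
  S <- nrow(y); G <- ncol(y); p <- ncol(X)
  pr <- model@priors
  icpt <- model@interceptIndex
  xbar <- colMeans(X)
  # anchor (non-checked, housekeeping) transcripts are modelled
  # intercept-only: their assumed stability is what identifies the
  # sequencing-depth exposures against the covariate effects
  mask <- matrix(1, p, G)
  if (icpt > 0L && p > 1L) mask[-icpt, !model@checked] <- 0
  bidx <- which(mask == 1)  # free beta entries only
  nb <- length(bidx)
  tidx <- which(W == 1 & !is.na(model@truncLower))
  tL <- model@truncLower[tidx]; tU <- model@truncUpper[tidx]
  ib <- seq_len(nb)
  iz <- nb + seq_len(G)
  ie <- nb + G + seq_len(S - 1L)
  ia <- nb + G + S
  ibb <- ia + 1L
  it <- ia + 2L
  npar <- it

  unpack <- function(th) {
    beta <- matrix(0, p, G)
    beta[bidx] <- th[ib]
    ef <- th[ie]
    e <- c(ef, -sum(ef))
    a <- th[ia]; b <- th[ibb]; tau <- exp(th[it])
    lambda <- if (icpt > 0L) beta[icpt, ] else as.vector(xbar %*% beta)
    sigma <- a + b * lambda + tau * th[iz]
    list(beta = beta, z = th[iz], e = e, a = a, b = b, ltau = th[it],
         tau = tau, lambda = lambda, sigma = sigma)
  }

  lp <- function(th) {
    u <- unpack(th)
    eta <- X %*% u$beta + u$e
    mu <- exp(eta)
    # clamp the log-size: beyond ~e^30 the NB is numerically Poisson, and at
    # e^-30 numerically degenerate; either extreme overflows digamma/dnbinom
    PHI <- matrix(exp(pmin(pmax(u$sigma, -30), 30)), S, G, byrow = TRUE)
    ll <- sum(W * stats::dnbinom(y, size = PHI, mu = mu, log = TRUE))
    if (length(tidx)) {
      ll <- ll - sum(.nbTruncLogZ(mu[tidx], log(PHI[tidx]), tL, tU))
    }
    ll +
      sum(stats::dnorm(u$beta[bidx], 0, pr$betaSd, log = TRUE)) +
      sum(stats::dnorm(u$z, log = TRUE)) +
      stats::dnorm(u$a, 0, pr$aSd, log = TRUE) +
      stats::dnorm(u$b, 0, pr$bSd, log = TRUE) +
      (-u$tau^2 / (2 * pr$tauScale^2)) + u$ltau +
      sum(stats::dnorm(u$e, 0, pr$exposureSd, log = TRUE))
  }

  gr <- function(th) {
    u <- unpack(th)
    eta <- X %*% u$beta + u$e
    mu <- exp(eta)
    phi_m <- matrix(exp(pmin(pmax(u$sigma, -30), 30)), S, G, byrow = TRUE)
    deta <- W * (y - (y + phi_m) * mu / (phi_m + mu))
    dsig <- W * phi_m * (digamma(y + phi_m) - digamma(phi_m) +
                         log(phi_m) - log(phi_m + mu) + 1 -
                         (y + phi_m) / (phi_m + mu))
    if (length(tidx)) {
      mu0 <- mu[tidx]
      sg0 <- matrix(pmin(pmax(u$sigma, -30), 30), S, G, byrow = TRUE)[tidx]
      phi0 <- exp(sg0)
      lz0 <- .nbTruncLogZ(mu0, sg0, tL, tU)
      # d pnbinom(k)/d eta is available in closed form through the
      # regularized incomplete beta: F(k) = I_p(phi, k+1), p = phi/(phi+mu)
      pb <- phi0 / (phi0 + mu0)
      dFu <- -stats::dbeta(pb, phi0, tU + 1) * pb * mu0 / (phi0 + mu0)
      dFu[!is.finite(tU)] <- 0
      dFl <- ifelse(tL > 0,
                    -stats::dbeta(pb, phi0, tL) * pb * mu0 / (phi0 + mu0),
                    0)
      deta[tidx] <- deta[tidx] - (dFu - dFl) * exp(-lz0)
      h <- 1e-6  # sigma direction: forward difference off the cached base
      dsig[tidx] <- dsig[tidx] -
        (.nbTruncLogZ(mu0, sg0 + h, tL, tU) - lz0) / h
    }
    Dsig <- colSums(dsig)
    gbeta <- crossprod(X, deta) * mask - u$beta / pr$betaSd^2
    if (icpt > 0L) {
      gbeta[icpt, ] <- gbeta[icpt, ] + u$b * Dsig
    } else {
      gbeta <- gbeta + outer(xbar, u$b * Dsig)
    }
    gz <- u$tau * Dsig - u$z
    ge <- rowSums(deta) - u$e / pr$exposureSd^2
    gef <- ge[seq_len(S - 1L)] - ge[S]
    ga <- sum(Dsig) - u$a / pr$aSd^2
    gb <- sum(Dsig * u$lambda) - u$b / pr$bSd^2
    gt <- u$tau * sum(Dsig * u$z) - u$tau^2 / pr$tauScale^2 + 1
    out <- numeric(npar)
    out[ib] <- gbeta[bidx]
    out[iz] <- gz
    out[ie] <- gef
    out[ia] <- ga; out[ibb] <- gb; out[it] <- gt
    out
  }

  init <- function() {
    th <- numeric(npar)
    cm <- log(pmax(colMeans(y), 0.5))
    bm <- matrix(0, p, G)
    if (icpt > 0L) {
      bm[icpt, ] <- cm
    } else {
      # put the baseline on the first column
      bm[1L, ] <- cm / max(xbar[1L], 0.1)
    }
    th[ib] <- bm[bidx]
    th[it] <- log(0.5)
    th
  }

  pack <- function(beta, sigma, e, a, b, tau) {
    th <- numeric(npar)
    th[ib] <- beta[bidx]
    lambda <- if (icpt > 0L) beta[icpt, ] else as.vector(xbar %*% beta)
    th[iz] <- (sigma - a - b * lambda) / max(tau, 1e-6)
    th[ie] <- e[seq_len(S - 1L)]
    th[ia] <- a; th[ibb] <- b; th[it] <- log(max(tau, 1e-6))
    th
  }

  list(lp = lp, gr = gr, unpack = unpack, pack = pack, init = init,
       npar = npar,
       dims = list(S = S, G = G, p = p),
       idx = list(beta = ib, z = iz, e = ie, a = ia, b = ibb, ltau = it))
}

#' Serialize a model description
#'
#' Writes a plain JSON description (dimensions, priors, truncation and
#' exclusion tables) for reproducibility logs.
#'
#' @param model an [NbModel-class].
#' @param path output path; `NULL` returns the JSON string.
#' @return path or JSON string, invisibly.
#' @export
serializeModel <- function(model, path = NULL) {
  tr <- which(!is.na(model@truncLower), arr.ind = TRUE)
  ex <- which(model@include == 0, arr.ind = TRUE)
  desc <- list(
    nTranscripts = ncol(model@counts),
    nSamples = nrow(model@counts),
    nCoefficients = ncol(model@design),
    coefficients = colnames(model@design),
    checked = sum(model@checked),
    priors = model@priors,
    truncation = if (nrow(tr)) data.frame(
      sample = model@samples[tr[, 1L]],
      transcript = model@transcripts[tr[, 2L]],
      lower = model@truncLower[tr],
      upper = model@truncUpper[tr]) else NULL,
    excluded = if (nrow(ex)) data.frame(
      sample = model@samples[ex[, 1L]],
      transcript = model@transcripts[ex[, 2L]]) else NULL
  )
  js <- jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
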