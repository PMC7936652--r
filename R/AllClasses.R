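#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Design specification for the count regression
#'
#' Couples the model formula with the encoded design matrix and the name of
#' the factor of interest, whose coefficient sign defines whether a transcript
#' is estimated to have increased or decreased.
#'
#' Categorical covariates are encoded with treatment (reference-level)
#' contrasts, the reference being the lexicographically first level.  The
#' direction of change reported downstream depends on this choice.
#'
#' @slot formula the Wilkinson formula over sample covariates.
#' @slot design numeric design matrix, one row per sample.
#' @slot factorOfInterest name of the model term defining direction.
#' @slot coefIndex column of `design` carrying the factor-of-interest
#'   coefficient.
#' @export
setClass("DesignSpec",
  representation(
    formula = "formula",
    design = "matrix",
    factorOfInterest = "character",
    coefIndex = "integer"
  )
)

setValidity("DesignSpec", function(object) {
  d <- object@design
  if (!is.numeric(d)) return("design matrix must be numeric")
  if (qr(d)$rank < ncol(d)) return("design matrix is rank deficient")
  if (length(object@coefIndex) != 1L || object@coefIndex < 1L ||
      object@coefIndex > ncol(d)) {
    return("coefIndex must index one design column")
  }
  TRUE
})

#' Validated container of observed counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `counts` assay
#' (transcripts in rows, samples in columns), per-transcript `significance`
#' and `do_check` columns in `rowData`, sample covariates in `colData`, and
#' (optionally) a [DesignSpec-class] stored under `metadata()$design`.
#'
#' Counts must be non-negative integers; transcripts flagged for checking must
#' be observed in every sample (a missing cell is an ingest error, not an
#' implicit zero).
#'
#' @export
setClass("CountSet", contains = "SummarizedExperiment")

setValidity("CountSet", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("a 'counts' assay is required")
  }
  y <- assay(object, "counts")
  if (any(!is.finite(y))) return("counts must be finite")
  if (any(y < 0)) return("counts must be non-negative")
  if (any(abs(y - round(y)) > 1e-8)) return("non-integer count")
  rd <- rowData(object)
  if (!all(c("significance", "do_check") %in% colnames(rd))) {
    return("rowData must contain 'significance' and 'do_check'")
  }
  if (!is.logical(rd$do_check) || anyNA(rd$do_check)) {
    return("'do_check' must be logical without NA")
  }
  TRUE
})

#' Joint hierarchical negative binomial model specification
#'
#' Encodes the data, design and priors of the joint model
#' \deqn{y_{sg} \sim \mathrm{NB}(\mu_{sg}, e^{\sigma_g}), \quad
#'       \log \mu_{sg} = x_s^\top \beta_g + e_s, \quad
#'       \sigma_g \sim \mathrm{N}(a + b\,\lambda_g, \tau)}
#' where \eqn{e^{\sigma_g}} is the NB size (see [nbLogPmf()]), \eqn{e_s} are
#' sum-to-zero sequencing-depth exposures and \eqn{\lambda_g} is the model's
#' own log baseline abundance (the intercept coefficient).  Individual
#' likelihood terms may be truncated to integer-inclusive bounds or excluded
#' altogether (the test-step quarantine).
#'
#' @slot counts samples x transcripts count matrix.
#' @slot design samples x p design matrix.
#' @slot transcripts,samples dimension names.
#' @slot checked logical, per transcript: is it under outlier check.
#' @slot include 0/1 matrix of likelihood weights (0 = quarantined).
#' @slot truncLower,truncUpper per-cell truncation bounds (NA = untruncated).
#' @slot priors list of prior hyperparameters.
#' @slot interceptIndex design column of the intercept (0 if absent).
#' @export
setClass("NbModel",
  representation(
    counts = "matrix",
    design = "matrix",
    transcripts = "character",
    samples = "character",
    checked = "logical",
    include = "matrix",
    truncLower = "matrix",
    truncUpper = "matrix",
    priors = "list",
    interceptIndex = "integer",
    coefIndex = "integer"
  )
)

setValidity("NbModel", function(object) {
  S <- nrow(object@counts); G <- ncol(object@counts)
  if (nrow(object@design) != S) return("design rows must equal samples")
  for (nm in c("include", "truncLower", "truncUpper")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(S, G))) return(sprintf("%s has wrong dimensions", nm))
  }
  tr <- !is.na(object@truncLower)
  if (!identical(tr, !is.na(object@truncUpper))) {
    return("truncation bounds must be set in pairs")
  }
  if (any(tr)) {
    lo <- object@truncLower[tr]; up <- object@truncUpper[tr]
    if (any(lo > up)) return("truncation bounds must satisfy lower <= upper")
    if (any(lo < 0) || any(lo != floor(lo)) ||
        any(is.finite(up) & up != floor(up))) {
      return("truncation bounds must be attainable counts")
    }
  }
  TRUE
})

#' Posterior draws of the joint model
#'
#' @slot model the fitted [NbModel-class].
#' @slot backend `"hmc"` or `"vb"`.
#' @slot beta draws x p x transcripts array of regression coefficients.
#' @slot sigma draws x transcripts matrix of log-size parameters.
#' @slot exposure draws x samples matrix; every draw sums to zero.
#' @slot trend draws x 3 matrix (columns `a`, `b`, `tau`).
#' @slot diagnostics list: convergence flag, Rhat table (HMC), iteration
#'   counts, divergences, ELBO history (VB).
#' @slot seed integer seed the fit was run under.
#' @export
setClass("PosteriorFit",
  representation(
    model = "NbModel",
    backend = "character",
    beta = "array",
    sigma = "matrix",
    exposure = "matrix",
    trend = "matrix",
    diagnostics = "list",
    seed = "integer"
  )
)

setValidity("PosteriorFit", function(object) {
  D <- nrow(object@sigma)
  if (D < 1) return("at least one posterior draw is required")
  if (dim(object@beta)[1] != D || nrow(object@exposure) != D ||
      nrow(object@trend) != D) {
    return("draw dimensions disagree")
  }
  if (max(abs(rowSums(object@exposure))) > 1e-6) {
    return("exposures must sum to zero in every draw")
  }
  TRUE
})

#' Result of the two-step outlier identification
#'
#' @slot transcriptSummary one row per checked transcript: significance, rank,
#'   whether it contains a finally flagged outlier, number of outliers.
#' @slot calls one row per (sample, checked transcript) data point with
#'   discovery/test intervals, deleterious status and the final flag.
#' @slot discovery discovery-stage [PosteriorFit-class].
#' @slot test test-stage [PosteriorFit-class], or NULL when nothing was
#'   quarantined.
#' @slot config the [testConfig()] the run used.
#' @export
setClass("OutlierReport",
  representation(
    transcriptSummary = "data.frame",
    calls = "data.frame",
    discovery = "ANY",
    test = "ANY",
    config = "list"
  )
)
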