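#' @rdname CountSet-accessors
#' @export
setGeneric("designSpec", function(x) standardGeneric("designSpec"))

#' @rdname CountSet-accessors
#' @export
setGeneric("designSpec<-", function(x, value) standardGeneric("designSpec<-"))

#' @rdname CountSet-accessors
#' @export
setGeneric("checkedTranscripts", function(x) standardGeneric("checkedTranscripts"))

#' @rdname PosteriorFit-accessors
#' @export
setGeneric("posteriorDraws", function(x, parameter = c("beta", "sigma",
  "exposure", "trend")) standardGeneric("posteriorDraws"))

#' @rdname PosteriorFit-accessors
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))

#' @rdname OutlierReport-accessors
#' @export
setGeneric("transcriptSummary", function(x) standardGeneric("transcriptSummary"))

#' @rdname OutlierReport-accessors
#' @export
setGeneric("outlierCalls", function(x) standardGeneric("outlierCalls"))

#' Accessors for CountSet
#'
#' `designSpec()` returns the [DesignSpec-class] attached to the dataset;
#' `checkedTranscripts()` the ids of transcripts with `do_check = TRUE`.
#'
#' @param x a `CountSet`.
#' @param value a `DesignSpec`.
#' @name CountSet-accessors
NULL

#' @rdname CountSet-accessors
#' @export
setMethod("designSpec", "CountSet", function(x) metadata(x)$design)

#' @rdname CountSet-accessors
#' @export
setReplaceMethod("designSpec", "CountSet", function(x, value) {
  stopifnot(is(value, "DesignSpec"))
  if (nrow(value@design) != ncol(x)) {
    stop("design matrix rows must equal the number of samples")
  }
  metadata(x)$design <- value
  x
})

#' @rdname CountSet-accessors
#' @export
setMethod("checkedTranscripts", "CountSet", function(x) {
  rownames(x)[rowData(x)$do_check]
})

#' Accessors for PosteriorFit
#'
#' `posteriorDraws()` extracts one draw array; `diagnostics()` the
#' convergence information.
#'
#' @param x a `PosteriorFit`.
#' @param parameter which parameter block to return.
#' @name PosteriorFit-accessors
NULL

#' @rdname PosteriorFit-accessors
#' @export
setMethod("posteriorDraws", "PosteriorFit", function(x,
    parameter = c("beta", "sigma", "exposure", "trend")) {
  slot(x, match.arg(parameter))
})

#' @rdname PosteriorFit-accessors
#' @export
setMethod("diagnostics", "PosteriorFit", function(x) x@diagnostics)

#' Accessors for OutlierReport
#'
#' @param x an `OutlierReport`.
#' @name OutlierReport-accessors
NULL

#' @rdname OutlierReport-accessors
#' @export
setMethod("transcriptSummary", "OutlierReport", function(x) x@transcriptSummary)

#' @rdname OutlierReport-accessors
#' @export
setMethod("outlierCalls", "OutlierReport", function(x) x@calls)

setMethod("show", "DesignSpec", function(object) {
  cat("DesignSpec:", deparse(object@formula), "\n")
  cat("  ", nrow(object@design), "samples x", ncol(object@design),
      "coefficients; factor of interest:", object@factorOfInterest,
      sprintf("(column %d)\n", object@coefIndex))
})

setMethod("show", "CountSet", function(object) {
  callNextMethod()
  cat("checked transcripts:", sum(rowData(object)$do_check), "of",
      nrow(object), "\n")
})

setMethod("show", "NbModel", function(object) {
  S <- nrow(object@counts); G <- ncol(object@counts)
  cat("NbModel:", G, "transcripts x", S, "samples,",
      ncol(object@design), "coefficients\n")
  cat("  checked:", sum(object@checked),
      "| truncated cells:", sum(!is.na(object@truncLower)),
      "| excluded cells:", sum(object@include == 0), "\n")
})

setMethod("show", "PosteriorFit", function(object) {
  d <- object@diagnostics
  cat("PosteriorFit (", object@backend, "): ",
      nrow(object@sigma), " draws\n", sep = "")
  show(object@model)
  if (!is.null(d$maxRhat) && is.finite(d$maxRhat)) {
    cat("  max Rhat:", round(d$maxRhat, 4), "\n")
  }
  cat("  converged:", isTRUE(d$converged), "\n")
})

setMethod("show", "OutlierReport", function(object) {
  ts <- object@transcriptSummary
  cat("OutlierReport:", nrow(ts), "checked transcripts,",
      sum(ts$contains_outlier), "with outliers;",
      nrow(object@calls), "data-point inferences\n")
  cat("  fpr discovery/test:", object@config$fprDiscovery, "/",
      object@config$fprTest, "| backend:", object@config$backend, "\n")
})
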