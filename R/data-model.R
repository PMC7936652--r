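#' Read a delimited count or results table
#'
#' Reads CSV/TSV (optionally gzip-compressed) with the delimiter taken from
#' the file extension or sniffed from the header line.
#'
#' @param path file path (`.csv`, `.tsv`, `.txt`, optionally `.gz`).
#' @param sep field delimiter; `NULL` (default) to infer.
#' @return a `data.frame`, strings kept as character.
#' @export
readCountTable <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  base <- sub("\\.gz$", "", path)
  if (is.null(sep)) {
    sep <- switch(tools::file_ext(base), csv = ",", tsv = "\t", "")
    if (identical(sep, "")) {
      con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
      hdr <- readLines(con, n = 1L); close(con)
      sep <- if (lengths(regmatches(hdr, gregexpr(",", hdr))) >
                 lengths(regmatches(hdr, gregexpr("\t", hdr)))) "," else "\t"
    }
  }
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.encodeCovariates <- function(df) {
  # treatment contrasts, lexicographically first level as reference
  for (nm in colnames(df)) {
    v <- df[[nm]]
    if (is.character(v) || is.logical(v)) {
      df[[nm]] <- factor(v, levels = sort(unique(as.character(v))))
    } else if (is.factor(v)) {
      df[[nm]] <- factor(as.character(v),
                         levels = sort(unique(as.character(v))))
    }
  }
  df
}

#' Build a design specification from a formula and sample covariates
#'
#' Encodes categorical covariates with treatment contrasts (reference =
#' lexicographically first level) so that the design matrix, and hence the
#' reported direction of change, is deterministic across runs.
#'
#' @param formula model formula over sample covariates (e.g. `~ condition`).
#' @param covariates data.frame of per-sample covariates, one row per sample.
#' @param factorOfInterest name of the term whose coefficient sign defines
#'   "increased"/"decreased"; defaults to the first term of the formula.
#' @return a [DesignSpec-class].
#' @export
DesignSpec <- function(formula, covariates, factorOfInterest = NULL) {
  stopifnot(inherits(formula, "formula"))
  tt <- stats::terms(formula)
  labs <- attr(tt, "term.labels")
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, colnames(covariates))
  if (length(missing_vars)) {
    stop("covariate(s) named in the formula are missing: ",
         paste(missing_vars, collapse = ", "))
  }
  covariates <- .encodeCovariates(covariates)
  X <- stats::model.matrix(formula, data = covariates)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (is.null(factorOfInterest)) {
    if (!length(labs)) stop("intercept-only formula needs an explicit factorOfInterest = NA")
    factorOfInterest <- labs[1L]
  }
  if (is.na(factorOfInterest)) {
    coefIndex <- 1L
    factorOfInterest <- colnames(X)[1L]
  } else {
    term_id <- match(factorOfInterest, labs)
    if (is.na(term_id)) stop("factorOfInterest is not a term of the formula")
    coefIndex <- which(attr(X, "assign") == term_id)[1L]
  }
  new("DesignSpec", formula = formula, design = X,
      factorOfInterest = factorOfInterest, coefIndex = as.integer(coefIndex))
}

#' Ingest a tidy table of raw counts
#'
#' Validates and pivots a long-format table (one row per sample/transcript
#' pair) into a [CountSet-class], and attaches the [DesignSpec-class] built
#' from `formula`.  Column roles are given explicitly through `columnMap`
#' rather than positionally.
#'
#' Counts must be non-negative integers.  The sample-by-transcript grid must
#' be complete for every transcript with `do_check = TRUE`: an absent row is
#' treated as a pivoting error and reported, never imputed as zero.
#' Transcripts without a `do_check` flag default to `FALSE` (reference /
#' housekeeping candidates).
#'
#' @param table a data.frame or path accepted by [readCountTable()].
#' @param formula model formula over sample covariates.
#' @param columnMap named character vector mapping roles
#'   (`sample`, `transcript`, `count`, and optionally `significance`,
#'   `do_check`) to column names of `table`.
#' @param factorOfInterest passed to [DesignSpec()].
#' @return a [CountSet-class] with the design attached.
#' @export
ingestCounts <- function(table, formula,
                         columnMap = c(sample = "sample",
                                       transcript = "transcript",
                                       count = "count"),
                         factorOfInterest = NULL) {
  if (is.character(table)) table <- readCountTable(table)
  stopifnot(is.data.frame(table))
  table <- as.data.frame(table)
  need <- c("sample", "transcript", "count")
  if (!all(need %in% names(columnMap))) {
    stop("columnMap must name at least: ", paste(need, collapse = ", "))
  }
  for (role in names(columnMap)) {
    if (!columnMap[[role]] %in% colnames(table)) {
      stop("missing column: '", columnMap[[role]], "' (role: ", role, ")")
    }
  }
  smp <- as.character(table[[columnMap[["sample"]]]])
  trx <- as.character(table[[columnMap[["transcript"]]]])
  cnt <- table[[columnMap[["count"]]]]
  if (!is.numeric(cnt) || any(!is.finite(cnt))) stop("non-integer count")
  if (any(abs(cnt - round(cnt)) > 1e-8)) stop("non-integer count")
  if (any(cnt < 0)) stop("counts must be non-negative")

  samples <- sort(unique(smp))
  transcripts <- sort(unique(trx))
  if (anyDuplicated(paste(smp, trx, sep = "\r"))) {
    stop("duplicated (sample, transcript) rows in the input table")
  }

  y <- matrix(NA_real_, length(transcripts), length(samples),
              dimnames = list(transcripts, samples))
  y[cbind(match(trx, transcripts), match(smp, samples))] <- round(cnt)

  do_check <- if ("do_check" %in% names(columnMap)) {
    v <- tapply(as.logical(table[[columnMap[["do_check"]]]]), trx,
                function(z) z[1L])
    dc <- as.logical(v[transcripts]); dc[is.na(dc)] <- FALSE; dc
  } else rep(FALSE, length(transcripts))
  significance <- if ("significance" %in% names(columnMap)) {
    v <- tapply(as.numeric(table[[columnMap[["significance"]]]]), trx,
                function(z) z[1L])
    as.numeric(v[transcripts])
  } else rep(NA_real_, length(transcripts))

  missing_cells <- which(is.na(y), arr.ind = TRUE)
  if (nrow(missing_cells)) {
    bad <- missing_cells[do_check[missing_cells[, 1L]], , drop = FALSE]
    if (nrow(bad)) {
      cells <- paste0("(", colnames(y)[bad[, 2L]], ", ",
                      rownames(y)[bad[, 1L]], ")")
      stop("incomplete sample x transcript grid for checked transcript(s); ",
           "missing cells: ", paste(cells, collapse = ", "))
    }
    drop_g <- unique(missing_cells[, 1L])
    warning("dropping ", length(drop_g),
            " unchecked transcript(s) with missing cells")
    keep <- setdiff(seq_along(transcripts), drop_g)
    y <- y[keep, , drop = FALSE]
    transcripts <- transcripts[keep]
    do_check <- do_check[keep]
    significance <- significance[keep]
  }

  covar_names <- all.vars(formula)
  cov_df <- data.frame(row.names = samples)
  for (nm in covar_names) {
    if (!nm %in% colnames(table)) {
      stop("covariate(s) named in the formula are missing: ", nm)
    }
    v <- tapply(as.character(table[[nm]]), smp, function(z) {
      u <- unique(z)
      if (length(u) > 1L) stop("covariate '", nm,
                               "' is not constant within a sample")
      u
    })
    v <- unname(v[samples])
    vn <- suppressWarnings(as.numeric(v))
    cov_df[[nm]] <- if (is.numeric(table[[nm]]) && !anyNA(vn)) vn else v
  }
  ds <- DesignSpec(formula, cov_df, factorOfInterest)

  cs <- new("CountSet", SummarizedExperiment(
    assays = list(counts = y),
    rowData = DataFrame(significance = significance, do_check = do_check,
                        row.names = transcripts),
    colData = DataFrame(.encodeCovariates(cov_df), row.names = samples)
  ))
  metadata(cs)$design <- ds
  cs
}

#' Join upstream differential-expression results onto raw counts
#'
#' Annotates a long count table with per-transcript significance and a
#' `do_check` flag taken from an upstream DE result table (edgeR/DESeq2
#' style), then ingests the annotated table.  Transcripts with no DE match
#' get `do_check = FALSE`.
#'
#' @param counts long count table (data.frame or path).
#' @param deResults DE result table with one row per transcript.
#' @param formula,columnMap,factorOfInterest passed to [ingestCounts()].
#' @param keys named character vector: the transcript key column of `counts`
#'   named by the transcript key column of `deResults`,
#'   e.g. `c(gene = "transcript")`.
#' @param significance column of `deResults` holding the significance value.
#' @param significant column of `deResults` holding the logical check flag
#'   (e.g. `FDR < 0.05` computed upstream).
#' @return a [CountSet-class].
#' @export
joinUpstreamResults <- function(counts, deResults, formula,
                                columnMap = c(sample = "sample",
                                              transcript = "transcript",
                                              count = "count"),
                                keys = c(transcript = "transcript"),
                                significance = "PValue",
                                significant = "significant",
                                factorOfInterest = NULL) {
  if (is.character(counts)) counts <- readCountTable(counts)
  if (is.character(deResults)) deResults <- readCountTable(deResults)
  de_key <- names(keys)[1L]
  cnt_key <- unname(keys[1L])
  for (cc in c(de_key, significance, significant)) {
    if (nrow(deResults) > 0 && !cc %in% colnames(deResults)) {
      stop("missing column in deResults: '", cc, "'")
    }
  }
  if (!cnt_key %in% colnames(counts)) {
    stop("missing column in counts: '", cnt_key, "'")
  }
  if (anyDuplicated(deResults[[de_key]])) {
    stop("duplicate transcript keys in deResults: ambiguous join")
  }
  idx <- match(as.character(counts[[cnt_key]]),
               as.character(deResults[[de_key]]))
  counts$.significance <- if (nrow(deResults)) {
    as.numeric(deResults[[significance]])[idx]
  } else NA_real_
  counts$.do_check <- if (nrow(deResults)) {
    v <- as.logical(deResults[[significant]])[idx]
    v[is.na(v)] <- FALSE
    v
  } else FALSE
  if (!any(counts$.do_check)) {
    warning("no transcript selected for checking (empty or non-significant ",
            "DE results)")
  }
  columnMap <- columnMap[setdiff(names(columnMap),
                                 c("significance", "do_check"))]
  columnMap["transcript"] <- cnt_key
  columnMap <- c(columnMap, significance = ".significance",
                 do_check = ".do_check")
  ingestCounts(counts, formula, columnMap, factorOfInterest)
}

#' Configuration of the two-step outlier test
#'
#' @param fprDiscovery discovery-stage false positive rate across all
#'   biological-replicate/transcript pairs; data points outside the central
#'   `1 - fprDiscovery` posterior predictive interval become candidates.
#' @param fprTest user-selected (test-stage) false positive rate; allocated
#'   over the quarantined candidates as a per-test one-sided tail width
#'   `fprTest / (2 * nOutliers)` (see [allocateTestIntervalWidth()]).
#' @param nTheoreticalDraws predictive draws per data point for the sampled
#'   interval method.
#' @param intervalMethod `"approximated"` (mean of per-draw analytic NB
#'   quantiles; supports arbitrarily extreme tails) or `"sampled"`.
#' @param backend inference backend, `"vb"` (default) or `"hmc"`.
#' @param seed integer seed controlling every stochastic step.
#' @param nAnchors number of housekeeping anchor transcripts included to pin
#'   the exposures (see [estimateExposureAnchors()]).
#' @param truncateAllChecked logical; if `FALSE` (default) the test-stage
#'   truncated likelihood is applied only to transcripts that actually lost
#'   observations to the quarantine — where the censoring correction is
#'   real.  `TRUE` truncates every retained observation of every checked
#'   transcript; because the fitted bounds then sit far outside the bulk of
#'   untouched transcripts' data, the normalizing term rewards dispersion
#'   inflation and biases the refit (kept as a sensitivity option).
#' @param testScope `"all"` (default): every checked data point is tested
#'   against the test-stage theoretical distribution, quarantined or not;
#'   `"quarantined"`: only the quarantined candidates are re-tested.
#' @param allocation how the user FPR is divided into per-test tail widths
#'   `fpr / (2 n)`: `"perGene"` (default) takes `n` as the number of
#'   quarantined candidate points of the transcript under test;
#'   `"replicates"` takes `n` as half the biological replicates;
#'   `"quarantined"` divides over the total number of quarantined points.
#' @param settings optional [inferenceSettings()] overriding the backend
#'   defaults.
#' @return a named list of class `ppc_config`.
#' @export
testConfig <- function(fprDiscovery = 0.05, fprTest = 0.01,
                       nTheoreticalDraws = 20000L,
                       intervalMethod = c("approximated", "sampled"),
                       backend = c("vb", "hmc"), seed = 1L,
                       nAnchors = 20L, truncateAllChecked = FALSE,
                       testScope = c("all", "quarantined"),
                       allocation = c("perGene", "replicates", "quarantined"),
                       settings = NULL) {
  stopifnot(fprDiscovery > 0, fprDiscovery < 1, fprTest > 0, fprTest < 1,
            nTheoreticalDraws >= 0)
  if (fprTest > fprDiscovery) {
    warning("fprTest > fprDiscovery: the test step is less stringent than ",
            "discovery; recommended 0 < fprTest <= fprDiscovery < 1")
  }
  backend <- match.arg(backend)
  cfg <- list(
    fprDiscovery = fprDiscovery,
    fprTest = fprTest,
    nTheoreticalDraws = as.integer(nTheoreticalDraws),
    intervalMethod = match.arg(intervalMethod),
    backend = backend,
    seed = as.integer(seed),
    nAnchors = as.integer(nAnchors),
    truncateAllChecked = isTRUE(truncateAllChecked),
    testScope = match.arg(testScope),
    allocation = match.arg(allocation),
    settings = settings
  )
  class(cfg) <- "ppc_config"
  cfg
}

#' Serialize an annotated dataset back to TSV
#'
#' Long-format output mirroring the ingested table; the round trip through
#' [ingestCounts()] is integer-exact.
#'
#' @param x a [CountSet-class].
#' @param path output file (TSV).
#' @return `path`, invisibly.
#' @export
writeCountSet <- function(x, path) {
  y <- assay(x, "counts")
  rd <- rowData(x)
  cd <- as.data.frame(colData(x))
  long <- data.frame(
    sample = rep(colnames(y), each = nrow(y)),
    transcript = rep(rownames(y), times = ncol(y)),
    count = as.integer(y),
    significance = rep(rd$significance, times = ncol(y)),
    do_check = rep(rd$do_check, times = ncol(y)),
    stringsAsFactors = FALSE
  )
  for (nm in colnames(cd)) {
    long[[nm]] <- rep(as.character(cd[[nm]]), each = nrow(y))
  }
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
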