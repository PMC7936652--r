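test_that("ingest builds a validated count set with a deterministic design", {
  tab <- tiny_long_table()
  cs <- ingestCounts(tab, ~ condition,
                     columnMap = c(sample = "sample",
                                   transcript = "transcript",
                                   count = "count",
                                   significance = "pval",
                                   do_check = "sig"))
  expect_s4_class(cs, "CountSet")
  expect_identical(dim(cs), c(2L, 2L))
  expect_identical(checkedTranscripts(cs), "tA")
  ds <- designSpec(cs)
  expect_identical(nrow(ds@design), 2L)
  expect_identical(ncol(ds@design), 2L)
  # treatment contrasts, lexicographically first level is the reference
  expect_identical(colnames(ds@design)[2], "conditionctrl")
  cs2 <- ingestCounts(tab, ~ condition,
                      columnMap = c(sample = "sample",
                                    transcript = "transcript",
                                    count = "count",
                                    significance = "pval",
                                    do_check = "sig"))
  expect_identical(designSpec(cs2)@design, ds@design)
})

test_that("ingest errors name the offending column, cell and count", {
  tab <- tiny_long_table()
  expect_error(
    ingestCounts(tab, ~ condition,
                 columnMap = c(sample = "sample", transcript = "transcript",
                               count = "reads")),
    "missing column: 'reads'")
  bad <- tab[-2L, ]  # drop (s2, tA): tA is checked
  expect_error(
    ingestCounts(bad, ~ condition,
                 columnMap = c(sample = "sample", transcript = "transcript",
                               count = "count", do_check = "sig")),
    "missing cells.*s2, tA")
  tab2 <- tab; tab2$count[1L] <- 3.5
  expect_error(
    ingestCounts(tab2, ~ condition,
                 columnMap = c(sample = "sample", transcript = "transcript",
                               count = "count")),
    "non-integer count")
  tab3 <- rbind(tab, tab[1L, ])
  expect_error(
    ingestCounts(tab3, ~ condition,
                 columnMap = c(sample = "sample", transcript = "transcript",
                               count = "count")),
    "duplicated")
  expect_error(
    ingestCounts(tab, ~ batch,
                 columnMap = c(sample = "sample", transcript = "transcript",
                               count = "count")),
    "covariate.*batch")
})

test_that("serialization round-trips counts and covariates exactly", {
  cs <- fix_counts()
  path <- tempfile(fileext = ".tsv")
  writeCountSet(cs, path)
  back <- ingestCounts(path, ~ condition,
                       columnMap = c(sample = "sample",
                                     transcript = "transcript",
                                     count = "count",
                                     significance = "significance",
                                     do_check = "do_check"))
  y0 <- SummarizedExperiment::assay(cs, "counts")
  y1 <- SummarizedExperiment::assay(back, "counts")
  expect_identical(y1[rownames(y0), colnames(y0)], y0)
  expect_identical(sort(checkedTranscripts(back)),
                   sort(checkedTranscripts(cs)))
})

test_that("joining upstream DE results sets the check flags", {
  counts <- tiny_long_table()
  counts <- rbind(counts,
                  data.frame(sample = c("s1", "s2"), transcript = "tC",
                             count = c(2L, 3L),
                             condition = c("ctrl", "case"),
                             pval = NA, sig = NA))
  de <- data.frame(transcript = c("tA", "tB"),
                   PValue = c(0.001, 0.2),
                   significant = c(TRUE, FALSE))
  cs <- joinUpstreamResults(counts, de, ~ condition)
  expect_identical(checkedTranscripts(cs), "tA")
  expect_false(rowData(cs)["tC", "do_check"])

  de_dup <- rbind(de, de[1L, ])
  expect_error(joinUpstreamResults(counts, de_dup, ~ condition),
               "ambiguous join")
  expect_warning(
    cs0 <- joinUpstreamResults(counts, de[0, ], ~ condition),
    "no transcript selected")
  expect_length(checkedTranscripts(cs0), 0L)
})

test_that("test configuration validates and warns on inverted rates", {
  cfg <- testConfig()
  expect_identical(cfg$fprDiscovery, 0.05)
  expect_identical(cfg$fprTest, 0.01)
  expect_warning(testConfig(fprDiscovery = 0.01, fprTest = 0.05),
                 "less stringent")
  expect_error(testConfig(fprTest = 0))
})

test_that("delimited readers sniff separators and accept gzip", {
  df <- data.frame(a = 1:3, b = c("x", "y", "z"))
  p1 <- tempfile(fileext = ".csv")
  utils::write.csv(df, p1, row.names = FALSE)
  expect_identical(readCountTable(p1)$a, 1:3)
  p2 <- tempfile(fileext = ".txt.gz")
  con <- gzfile(p2, "w")
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  expect_identical(readCountTable(p2)$b, c("x", "y", "z"))
})
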