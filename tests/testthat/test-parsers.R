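# The five caller dialects share one contract: every syntactically valid
# data row yields exactly one standardized call, nothing is filtered at
# parse time, and caller-specific extras land in `annotations`.

test_that("all five parsers are total: record count equals data-row count", {
  withr::with_seed(11, {
    n <- 17L
    genes <- sprintf("G%02d", 1:40)
    calls <- make_call(
      caller = "arriba", sample_id = "S1",
      gene5 = sample(genes, n), gene3 = sample(genes, n),
      chrom5 = as.character(sample(1:22, n, TRUE)), pos5 = sample(1e6, n),
      chrom3 = as.character(sample(1:22, n, TRUE)), pos3 = sample(1e6, n),
      split_reads = sample(0:50, n, TRUE), spanning_reads = sample(0:50, n, TRUE),
      confidence = sample(c("high", "medium", "low"), n, TRUE)
    )
    for (cl in fusion_callers()) {
      path <- withr::local_tempfile(fileext = ".tsv")
      calls$caller <- cl
      if (cl == "cicero") calls$confidence <- "HQ"
      write_caller_file(calls, cl, path)
      parsed <- parse_caller(path, cl, sample_id = "S1")
      # independent oracle: physical line count minus header
      expect_identical(nrow(parsed), length(readLines(path)) - 1L,
        info = cl)
      expect_identical(nrow(parsed), n, info = cl)
      expect_setequal(parsed$caller, cl)
    }
  })
})

test_that("header-only files parse to empty call tables for every caller", {
  for (cl in fusion_callers()) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_caller_file(empty_fusion_calls(), cl, path)
    parsed <- parse_caller(path, cl, sample_id = "S1")
    expect_identical(nrow(parsed), 0L, info = cl)
    expect_identical(names(parsed), names(empty_fusion_calls()))
  }
})

test_that("Arriba: confidence passes through verbatim and split-read columns sum", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("#gene1", "gene2", "strand1(gene/fusion)", "strand2(gene/fusion)",
      "breakpoint1", "breakpoint2", "site1", "site2", "type",
      "split_reads1", "split_reads2", "discordant_mates", "confidence",
      "reading_frame", sep = "\t"),
    paste("KMT2A", "AFF1", "+/+", "+/+", "chr11:118436492", "chr4:87061055",
      "splice-site", "splice-site", "translocation", "2", "3", "4", "high",
      "in-frame", sep = "\t"),
    paste("BCR", "ABL1", "+/+", "+/+", "chr22:23290413", "chr9:130854064",
      "splice-site", "splice-site", "translocation", "1", "0", "2", "medium",
      "out-of-frame", sep = "\t"),
    paste("ETV6", "RUNX1", "+/+", "+/+", "12:11869969", "21:34859473",
      "splice-site", "splice-site", "translocation", "0", "1", "1", "low",
      ".", sep = "\t")
  ), path)
  calls <- parse_arriba(path, sample_id = "S1")
  expect_identical(calls$confidence, c("high", "medium", "low"))
  expect_identical(calls$split_reads, c(5, 1, 1)) # split_reads1 + split_reads2
  expect_identical(calls$spanning_reads, c(4, 2, 1))
  expect_identical(calls$frame, c("in-frame", "out-of-frame", "unknown"))
  # both chromosome dialects normalized to the bare token
  expect_identical(calls$chrom5, c("11", "22", "12"))
})

test_that("a 584-row Arriba file yields 584 records", {
  withr::with_seed(584, {
    n <- 584
    calls <- make_call(
      gene5 = sprintf("GA%03d", sample(500, n, TRUE)),
      gene3 = sprintf("GB%03d", sample(500, n, TRUE)),
      chrom5 = as.character(sample(1:22, n, TRUE)), pos5 = sample(1e8, n),
      chrom3 = as.character(sample(1:22, n, TRUE)), pos3 = sample(1e8, n),
      split_reads = sample(0:100, n, TRUE),
      spanning_reads = sample(0:100, n, TRUE),
      confidence = sample(c("high", "medium", "low"), n, TRUE)
    )
    path <- withr::local_tempfile(fileext = ".tsv")
    write_arriba(calls, path)
    expect_identical(length(readLines(path)), 585L)
    expect_identical(nrow(parse_arriba(path, "S1")), 584L)
  })
})

test_that("STAR-Fusion: read-count mapping and fusion-name splitting", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("#FusionName", "JunctionReadCount", "SpanningFragCount", "SpliceType",
      "LeftGene", "LeftBreakpoint", "RightGene", "RightBreakpoint", sep = "\t"),
    paste("KMT2A--AFF1", "5", "2", "ONLY_REF_SPLICE", "KMT2A",
      "chr11:118436492:+", "AFF1", "chr4:87061055:+", sep = "\t")
  ), path)
  calls <- parse_starfusion(path, "S1")
  expect_identical(calls$split_reads, 5)
  expect_identical(calls$spanning_reads, 2)
  expect_identical(calls$gene5, "KMT2A")
  expect_identical(calls$gene3, "AFF1")
  expect_identical(calls$strand5, "+")
})

test_that("FusionCatcher: description flags and common-mapping counts retained", {
  calls <- make_call(caller = "fusioncatcher", gene5 = "MTAP",
    gene3 = "CDKN2B-AS1")
  calls$annotations <- list(c(fusion_description = "readthrough",
    counts_of_common_mapping_reads = "7"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fusioncatcher(calls, path)
  parsed <- parse_fusioncatcher(path, "S1")
  expect_identical(parsed$annotations[[1]][["Fusion_description"]], "readthrough")
  expect_identical(parsed$annotations[[1]][["Counts_of_common_mapping_reads"]], "7")
})

test_that("deFuse: probability kept as confidence, splitr/span counts mapped", {
  calls <- make_call(caller = "defuse", split_reads = 9, spanning_reads = 4,
    confidence = "0.93")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_defuse(calls, path)
  parsed <- parse_defuse(path, "S1")
  expect_identical(parsed$confidence, "0.93")
  expect_identical(parsed$split_reads, 9)
  expect_identical(parsed$spanning_reads, 4)
})

test_that("CICERO: rating kept as confidence, readsA/readsB mapped, sample column used", {
  calls <- make_call(caller = "cicero", sample_id = "PTX",
    split_reads = 12, spanning_reads = 6, confidence = "HQ")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cicero(calls, path)
  parsed <- parse_cicero(path)
  expect_identical(parsed$sample_id, "PTX")
  expect_identical(parsed$confidence, "HQ")
  expect_identical(parsed$split_reads, 12)
  expect_identical(parsed$spanning_reads, 6)
})

test_that("missing mandatory columns are named in the error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene1\tgene2", path)
  expect_error(parse_arriba(path, "S1"), "breakpoint1")
  writeLines("FusionName\tJunctionReadCount", path)
  expect_error(parse_starfusion(path, "S1"), "SpanningFragCount")
})

test_that("unparseable numeric fields fail fast with the offending row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("#FusionName", "JunctionReadCount", "SpanningFragCount", "SpliceType",
      "LeftGene", "LeftBreakpoint", "RightGene", "RightBreakpoint", sep = "\t"),
    paste("A--B", "5", "2", "x", "A", "1:100:+", "B", "2:200:+", sep = "\t"),
    paste("C--D", "oops", "2", "x", "C", "1:100:+", "D", "2:200:+", sep = "\t")
  ), path)
  expect_error(parse_starfusion(path, "S1"), "row 2")
})
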