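cfg_plain <- function(...) {
  filter_config(blacklist = c("HLA-A", "GAPDH"), whitelist = c("KMT2A", "TAL1"), ...)
}

# events with evidence, as run_filter_cascade expects
event_of <- function(calls, ...) {
  merge_calls(calls, ...)
}

test_that("evidence filter: support and confidence thresholds with boundary semantics", {
  cfg <- cfg_plain()
  out <- evidence_filter(make_call(caller = "arriba", confidence = "low"), cfg)
  expect_false(out$pass)
  expect_identical(out$reason, "low_confidence")
  out <- evidence_filter(make_call(split_reads = 0, spanning_reads = 0,
    confidence = "high"), cfg)
  expect_false(out$pass)
  expect_identical(out$reason, "low_support")
  # thresholds are minima: exactly at threshold passes
  out <- evidence_filter(make_call(split_reads = 2, spanning_reads = 1,
    confidence = "high"), cfg)
  expect_true(out$pass)
  # absent confidence passes (benefit of the doubt)
  out <- evidence_filter(make_call(caller = "starfusion"), cfg)
  expect_true(out$pass)
  # deFuse probability floor
  out <- evidence_filter(make_call(caller = "defuse", confidence = "0.3"), cfg)
  expect_identical(out$reason, "low_confidence")
  expect_true(evidence_filter(make_call(caller = "defuse", confidence = "0.9"),
    cfg)$pass)
  # unknown caller section is a contract error
  cc <- cfg
  cc$callers$arriba <- NULL
  expect_error(evidence_filter(make_call(caller = "arriba"), cc),
    "no filter configuration")
})

test_that("read-through geometry matches an exhaustive enumeration oracle", {
  ann <- toy_annotation()
  md <- 1000
  pairs <- expand.grid(g5 = ann$genes$gene, g3 = ann$genes$gene,
    stringsAsFactors = FALSE)
  pairs <- pairs[pairs$g5 != pairs$g3, ]
  got <- is_read_through(
    tibble::tibble(gene5 = pairs$g5, gene3 = pairs$g3), ann, md)
  want <- mapply(oracle_read_through, pairs$g5, pairs$g3,
    MoreArgs = list(genes = ann$genes, max_distance = md))
  expect_identical(got, unname(want))
  # the one true geometry in the toy set
  expect_true(is_read_through(tibble::tibble(gene5 = "A", gene3 = "B"), ann, md))
  # different chromosomes / opposite strands are never read-throughs
  expect_false(is_read_through(tibble::tibble(gene5 = "A", gene3 = "F"), ann, md))
  expect_false(is_read_through(tibble::tibble(gene5 = "B", gene3 = "C"), ann, md))
  # unannotated partner: never TRUE
  expect_false(is_read_through(tibble::tibble(gene5 = "A", gene3 = "ZZZ"), ann, md))
  # the generated annotation places the canonical read-through neighbours
  gen <- generate_annotation()
  expect_true(is_read_through(
    tibble::tibble(gene5 = "MTAP", gene3 = "CDKN2B-AS1"), gen, 1e6))
})

test_that("breakpoint classification agrees with a linear-scan oracle", {
  ann <- toy_annotation()
  # boundary definitions
  expect_identical(breakpoint_site_class("1", 1199, ann), "splice_site") # exon end
  expect_identical(breakpoint_site_class("1", 1100, ann), "exonic")
  expect_identical(breakpoint_site_class("1", 1300, ann), "intronic")
  expect_identical(breakpoint_site_class("1", 2100, ann), "intergenic")
  withr::with_seed(5, {
    pos <- sample(500:7000, 120, replace = TRUE)
    chrom <- sample(c("1", "2"), 120, replace = TRUE)
    got <- breakpoint_site_class(chrom, pos, ann)
    want <- mapply(oracle_site_class, chrom, pos, MoreArgs = list(ann = ann))
    expect_identical(got, unname(want))
  })
})

test_that("promiscuous genes are flagged side-agnostically within a sample", {
  ev <- harmonize_calls(dplyr::bind_rows(
    make_call(gene5 = "G", gene3 = "A"),
    make_call(gene5 = "G", gene3 = "B", caller = "cicero")
  ))
  expect_identical(flag_promiscuous(ev, 2), "G")
  ev1 <- harmonize_calls(make_call(gene5 = "G", gene3 = "A"))
  expect_identical(flag_promiscuous(ev1, 2), character())
  ev2 <- harmonize_calls(dplyr::bind_rows(
    make_call(gene5 = "A", gene3 = "G"),
    make_call(gene5 = "B", gene3 = "G", caller = "defuse")
  ))
  expect_identical(flag_promiscuous(ev2, 2), "G")
})

test_that("cascade verdicts partition the input and reasons explain discards", {
  ann <- generate_annotation()
  cfg <- filter_config()
  ev <- dplyr::bind_rows(
    # clean event at splice sites, different chromosomes
    event_of(make_call(gene5 = "SYNFP01", gene3 = "SYNFP03",
      chrom5 = "7", pos5 = ann$exons$end[ann$exons$gene == "SYNFP01"][2],
      chrom3 = "7", pos3 = ann$exons$start[ann$exons$gene == "SYNFP03"][2],
      confidence = "high")),
    # read-through, not whitelisted
    event_of(make_call(gene5 = "MTAP", gene3 = "CDKN2B-AS1",
      chrom5 = "9", pos5 = ann$exons$end[ann$exons$gene == "MTAP"][2],
      chrom3 = "9", pos3 = ann$exons$start[ann$exons$gene == "CDKN2B-AS1"][2],
      confidence = "high")),
    # out-of-frame but whitelisted partner: rescued
    event_of(make_call(gene5 = "KMT2A", gene3 = "AFF1",
      chrom5 = "11", pos5 = ann$exons$end[ann$exons$gene == "KMT2A"][2],
      chrom3 = "4", pos3 = ann$exons$start[ann$exons$gene == "AFF1"][2],
      confidence = "high", frame = "out-of-frame")),
    # no read support at all
    event_of(make_call(gene5 = "SYNFP05", gene3 = "SYNFP07",
      chrom5 = "7", pos5 = ann$exons$end[ann$exons$gene == "SYNFP05"][2],
      chrom3 = "7", pos3 = ann$exons$start[ann$exons$gene == "SYNFP07"][2],
      split_reads = 0, spanning_reads = 0, confidence = "high"))
  )
  res <- run_filter_cascade(ev, ann, cfg)
  expect_identical(nrow(res$retained) + nrow(res$discarded), nrow(ev))
  expect_identical(nrow(res$verdicts), nrow(ev))
  v <- res$verdicts
  expect_identical(v$status[v$gene5 == "SYNFP01"], "retained")
  expect_identical(v$reasons[v$gene5 == "MTAP"], "read_through")
  expect_identical(v$status[v$gene5 == "KMT2A"], "retained")
  expect_identical(v$reasons[v$gene5 == "KMT2A"], "whitelist_rescue")
  expect_identical(v$reasons[v$gene5 == "SYNFP05"], "low_support")
  # discarded implies non-empty reasons
  expect_true(all(nzchar(v$reasons[v$status == "discarded"])))
  # whitelist_rescue appears only on retained events
  expect_true(all(v$status[grepl("whitelist_rescue", v$reasons)] == "retained"))
})

test_that("retained set is stable under input reordering", {
  withr::with_seed(9, {
    d <- withr::local_tempdir()
    co <- write_tiny_cohort(d)
    ev <- harmonize_calls(parse_cohort(d))
    ref <- run_filter_cascade(ev, co$annotation, filter_config())$retained
    for (i in 1:5) {
      shuf <- ev[sample(nrow(ev)), ]
      out <- run_filter_cascade(shuf, co$annotation, filter_config())$retained
      expect_identical(out, ref)
    }
  })
})

test_that("whitelisted events never fall to structural filters, but evidence still counts", {
  ann <- generate_annotation()
  cfg <- filter_config()
  # whitelisted event failing every structural rule: intronic breakpoints,
  # out-of-frame, promiscuous partner pattern
  ev <- harmonize_calls(dplyr::bind_rows(
    make_call(gene5 = "STIL", gene3 = "TAL1",
      chrom5 = "1", pos5 = ann$exons$end[ann$exons$gene == "STIL"][1] + 50,
      chrom3 = "1", pos3 = ann$exons$start[ann$exons$gene == "TAL1"][1] + 400,
      confidence = "high", frame = "out-of-frame"),
    make_call(gene5 = "STIL", gene3 = "ERG", caller = "cicero",
      chrom5 = "1", pos5 = ann$exons$end[ann$exons$gene == "STIL"][2],
      chrom3 = "21", pos3 = ann$exons$start[ann$exons$gene == "ERG"][2],
      confidence = "HQ")
  ))
  res <- run_filter_cascade(ev, ann, cfg)
  expect_identical(unique(res$events$status), "retained")
  # but a whitelisted event with no read evidence is still discarded
  weak <- harmonize_calls(make_call(gene5 = "KMT2A", gene3 = "AFF1",
    split_reads = 0, spanning_reads = 0, confidence = "high"))
  res <- run_filter_cascade(weak, ann, cfg)
  expect_identical(res$events$status, "discarded")
  expect_identical(res$events$reasons[[1]], "low_support")
})

test_that("relaxing thresholds never shrinks the retained set", {
  withr::with_seed(13, {
    d <- withr::local_tempdir()
    co <- write_tiny_cohort(d)
    ev <- harmonize_calls(parse_cohort(d))
    strict <- filter_config()
    lax <- filter_config(
      callers = lapply(strict$callers, function(x) { x$min_reads <- 0; x }),
      discard_out_of_frame = FALSE, require_splice_site = FALSE
    )
    r_strict <- run_filter_cascade(ev, co$annotation, strict)$retained
    r_lax <- run_filter_cascade(ev, co$annotation, lax)$retained
    key <- function(x) paste(x$sample_id, x$gene5, x$gene3)
    expect_true(all(key(r_strict) %in% key(r_lax)))
  })
})

test_that("events with unannotated genes pass structural checks with a warning tag", {
  ann <- toy_annotation()
  ev <- harmonize_calls(make_call(gene5 = "NOTINGTF", gene3 = "ALSONOT",
    confidence = "high"))
  res <- run_filter_cascade(ev, ann, filter_config(whitelist = "X",
    blacklist = "Y"))
  expect_identical(res$events$status, "retained")
  expect_identical(res$events$reasons[[1]], "unannotated_gene")
})
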