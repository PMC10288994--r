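test_that("canonical_pair resolves aliases, identities and chains", {
  al <- alias_table(c(MLL = "KMT2A"))
  out <- canonical_pair(tibble::tibble(gene5 = "MLL", gene3 = "AFF1"), al)
  expect_identical(out, tibble::tibble(gene5 = "KMT2A", gene3 = "AFF1"))
  # empty alias table is the identity
  out <- canonical_pair(tibble::tibble(gene5 = "KMT2A", gene3 = "AFF1"),
    alias_table())
  expect_identical(out$gene5, "KMT2A")
  # chains resolve to the terminal symbol and the closure is idempotent
  al <- alias_table(c(A = "B", B = "B"))
  expect_identical(canonical_symbols("A", al), "B")
  expect_identical(canonical_symbols(canonical_symbols("A", al), al), "B")
  al <- alias_table(c(A = "B", B = "C"))
  expect_identical(canonical_symbols("A", al), "C")
  expect_error(canonical_symbols("", al), "empty")
})

test_that("calls with one gene pair merge into one event whatever the breakpoints", {
  calls <- dplyr::bind_rows(
    make_call(caller = "arriba", pos5 = 1000, pos3 = 2000),
    make_call(caller = "starfusion", pos5 = 1012, pos3 = 2000)
  )
  ev <- merge_calls(calls)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$caller_count, 2L)
  expect_identical(ev$callers[[1]], c("arriba", "starfusion"))

  # same caller twice: one event, caller_count 1, both calls in evidence
  calls <- dplyr::bind_rows(
    make_call(caller = "arriba", pos5 = 1000),
    make_call(caller = "arriba", pos5 = 90000)
  )
  ev <- merge_calls(calls)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$caller_count, 1L)
  expect_identical(nrow(ev$evidence[[1]]), 2L)

  # one call per caller: caller_count 5
  calls <- dplyr::bind_rows(lapply(fusion_callers(), function(cl) {
    make_call(caller = cl)
  }))
  ev <- merge_calls(calls)
  expect_identical(ev$caller_count, 5L)
})

test_that("merging is invariant under every permutation of the input", {
  calls <- dplyr::bind_rows(
    make_call(caller = "arriba", pos5 = 1000, split_reads = 4),
    make_call(caller = "cicero", pos5 = 1030, split_reads = 9),
    make_call(caller = "defuse", gene5 = "BCR", gene3 = "ABL1", pos5 = 500),
    make_call(caller = "starfusion", pos5 = 1001, split_reads = 20)
  )
  ref <- merge_calls(calls)
  # brute force over all 24 orderings
  idx <- 1:4
  all_perms <- do.call(rbind, lapply(1:4, function(a) {
    do.call(rbind, lapply(setdiff(idx, a), function(b) {
      do.call(rbind, lapply(setdiff(idx, c(a, b)), function(c) {
        cbind(a, b, c, setdiff(idx, c(a, b, c)))
      }))
    }))
  }))
  for (r in seq_len(nrow(all_perms))) {
    out <- merge_calls(calls[all_perms[r, ], ])
    expect_identical(out, ref)
  }
})

test_that("merging conserves every call exactly once", {
  withr::with_seed(42, {
    pairs <- list(c("A", "B"), c("B", "A"), c("C", "D"), c("E", "F"))
    calls <- dplyr::bind_rows(lapply(1:40, function(i) {
      p <- pairs[[sample(4, 1)]]
      make_call(caller = sample(fusion_callers(), 1), gene5 = p[1], gene3 = p[2],
        pos5 = sample(1e5, 1), pos3 = sample(1e5, 1))
    }))
    ev <- merge_calls(calls)
    expect_identical(sum(ev$n_calls), 40L)
    recovered <- dplyr::bind_rows(ev$evidence) |>
      dplyr::arrange(caller, gene5, gene3, pos5, pos3, split_reads)
    original <- calls |>
      dplyr::arrange(caller, gene5, gene3, pos5, pos3, split_reads)
    expect_identical(recovered, original)
    # caller_count always equals the distinct callers in evidence
    for (i in seq_len(nrow(ev))) {
      expect_identical(ev$caller_count[i],
        dplyr::n_distinct(ev$evidence[[i]]$caller))
    }
  })
})

test_that("merge refuses mixed samples but harmonize_calls partitions them", {
  calls <- dplyr::bind_rows(
    make_call(sample_id = "S1"),
    make_call(sample_id = "S2", caller = "cicero")
  )
  expect_error(merge_calls(calls), "mixed sample")
  ev <- harmonize_calls(calls)
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$sample_id, c("S1", "S2"))
})

test_that("representative breakpoint: caller majority, then support, then coordinate", {
  # junction 1000/2000 seen by two callers; 5000/6000 by one with more reads
  calls <- dplyr::bind_rows(
    make_call(caller = "arriba", pos5 = 1000, pos3 = 2000, split_reads = 3),
    make_call(caller = "cicero", pos5 = 1004, pos3 = 2001, split_reads = 4),
    make_call(caller = "defuse", pos5 = 5000, pos3 = 6000, split_reads = 90)
  )
  ev <- merge_calls(calls)
  expect_identical(ev$pos5, 1004) # best-supported call of the majority cluster
  # support tie-break when each junction has one caller
  calls <- dplyr::bind_rows(
    make_call(caller = "arriba", pos5 = 1000, pos3 = 2000, split_reads = 3,
      spanning_reads = 0),
    make_call(caller = "defuse", pos5 = 5000, pos3 = 6000, split_reads = 80,
      spanning_reads = 0)
  )
  expect_identical(merge_calls(calls)$pos5, 5000)
  # full tie falls back to the lowest coordinate
  calls <- dplyr::bind_rows(
    make_call(caller = "arriba", pos5 = 5000, pos3 = 6000, split_reads = 3),
    make_call(caller = "defuse", pos5 = 1000, pos3 = 2000, split_reads = 3)
  )
  expect_identical(merge_calls(calls)$pos5, 1000)
})

test_that("reciprocal orientations stay distinct unless collapsed by config", {
  calls <- dplyr::bind_rows(
    make_call(caller = "arriba", gene5 = "KMT2A", gene3 = "AFF1"),
    make_call(caller = "cicero", gene5 = "AFF1", gene3 = "KMT2A"),
    make_call(caller = "defuse", gene5 = "KMT2A", gene3 = "AFF1")
  )
  expect_identical(nrow(merge_calls(calls)), 2L)
  collapsed <- merge_calls(calls, collapse_reciprocal = TRUE)
  expect_identical(nrow(collapsed), 1L)
  expect_identical(collapsed$gene5, "KMT2A") # majority orientation wins
  expect_identical(collapsed$caller_count, 3L)
})

test_that("consensus selection is a caller_count threshold with nested results", {
  ev <- harmonize_calls(dplyr::bind_rows(
    lapply(fusion_callers()[1:3], function(cl) make_call(caller = cl)),
    lapply(fusion_callers(), function(cl) {
      make_call(caller = cl, gene5 = "BCR", gene3 = "ABL1")
    }),
    make_call(caller = "arriba", gene5 = "ETV6", gene3 = "RUNX1")
  ))
  expect_identical(nrow(consensus_select(ev, 3)), 2L) # boundary: count 3 at k 3
  expect_identical(nrow(consensus_select(ev, 4)), 1L) # count 3 excluded at k 4
  expect_error(consensus_select(ev, 0), "between 1 and 5")
  expect_error(consensus_select(ev, 6), "between 1 and 5")
  sizes <- vapply(1:5, function(k) nrow(consensus_select(ev, k)), integer(1))
  expect_true(all(diff(sizes) <= 0)) # monotone in k
  for (k in 4:5) {
    hi <- consensus_select(ev, k)[, c("sample_id", "gene5", "gene3")]
    lo <- consensus_select(ev, k - 1)[, c("sample_id", "gene5", "gene3")]
    expect_identical(nrow(dplyr::anti_join(hi, lo,
      by = c("sample_id", "gene5", "gene3"))), 0L)
  }
})
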