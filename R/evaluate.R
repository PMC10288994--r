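#' Read a truth set of expected rearrangements
#'
#' The truth set lists gene fusions previously confirmed by orthogonal
#' clinical methods (karyotype, FISH, RT-qPCR, targeted panel); it is the
#' reference for true-positive / false-negative accounting.
#'
#' @param path TSV with columns `sample_id`, `gene5`, `gene3` and optionally
#'   `method` (the confirming methodology).
#' @return A tibble.
#' @export
read_truth <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
    progress = FALSE)
  require_columns(df, c("sample_id", "gene5", "gene3"), path)
  if (!"method" %in% names(df)) df$method <- NA_character_
  df[, c("sample_id", "gene5", "gene3", "method")]
}

truth_key <- function(df, ignore_orientation) {
  if (ignore_orientation) {
    paste(df$sample_id, pmin(df$gene5, df$gene3), pmax(df$gene5, df$gene3))
  } else {
    paste(df$sample_id, df$gene5, df$gene3)
  }
}

#' Match a call set against a truth set
#'
#' A call is a true positive iff its (sample, canonical gene pair) matches a
#' truth entry; each truth entry counts at most once toward TP however many
#' calls match it (and extra matching calls are not false positives — they
#' report the same true fusion). Unmatched truth entries are false
#' negatives; unmatched calls are false positives.
#'
#' @param events Event tibble (typically the retained set) with `sample_id`,
#'   `gene5`, `gene3`.
#' @param truth Truth tibble from [read_truth()].
#' @param aliases Optional [alias_table()] applied to both sides before
#'   matching.
#' @param ignore_orientation If `TRUE`, A::B matches a truth entry B::A.
#' @return A list of class `fusemble_truth_match` with `tp` (matched truth
#'   entries), `fp` (unmatched events), `fn` (unmatched truth entries) and a
#'   `counts` row.
#' @export
match_truth <- function(events, truth, aliases = NULL, ignore_orientation = FALSE) {
  truth <- as_tibble(truth)
  truth[, c("gene5", "gene3")] <- canonical_pair(truth, aliases)
  tkey <- truth_key(truth, ignore_orientation)
  if (anyDuplicated(tkey)) {
    abort("duplicate truth entries after canonicalization")
  }
  ev <- as_tibble(events)
  if (nrow(ev) > 0) {
    ev[, c("gene5", "gene3")] <- canonical_pair(ev, aliases)
    ekey <- truth_key(ev, ignore_orientation)
  } else {
    ekey <- character()
  }
  tp <- truth[tkey %in% ekey, ]
  fn <- truth[!tkey %in% ekey, ]
  fp <- ev[!ekey %in% tkey, ]
  n_tp <- nrow(tp)
  n_fp <- nrow(fp)
  n_fn <- nrow(fn)
  structure(list(
    tp = tp, fp = fp, fn = fn,
    counts = tibble(tp = n_tp, fp = n_fp, fn = n_fn,
      total_identified = n_tp + n_fp)
  ), class = "fusemble_truth_match")
}

#' @export
print.fusemble_truth_match <- function(x, ...) {
  cat(sprintf("<fusemble_truth_match> TP %d, FP %d, FN %d\n",
    nrow(x$tp), nrow(x$fp), nrow(x$fn)))
  invisible(x)
}

#' Detection accuracy metrics
#'
#' Sensitivity is `100 * TP / (TP + FN)` and precision `100 * TP / (TP + FP)`,
#' reported as percentages to one decimal; the F1 score is the harmonic mean
#' of the two, `2 * S * P / (S + P)`, reported on the 0-1 scale to two
#' decimals. Rounding is half away from zero. A metric whose denominator is
#' zero is undefined and raises an error.
#'
#' @param tp,fn,fp Non-negative counts.
#' @return A single number.
#' @export
sensitivity <- function(tp, fn) {
  if (tp + fn <= 0) abort("sensitivity undefined: TP + FN = 0")
  round_half_up(100 * tp / (tp + fn), 1)
}

#' @rdname sensitivity
#' @export
precision <- function(tp, fp) {
  if (tp + fp <= 0) abort("precision undefined: TP + FP = 0")
  round_half_up(100 * tp / (tp + fp), 1)
}

#' @rdname sensitivity
#' @param sens,prec Sensitivity and precision, both in percent.
#' @export
f1_score <- function(sens, prec) {
  if (sens + prec <= 0) abort("F1 undefined: sensitivity + precision = 0")
  round_half_up(2 * sens * prec / (sens + prec) / 100, 2)
}

benchmark_row <- function(method, dataset, tp, fp, fn) {
  s <- sensitivity(tp, fn)
  p <- precision(tp, fp)
  tibble(
    method = method, dataset = dataset,
    total_identified = tp + fp, tp = tp, fp = fp, fn = fn,
    sensitivity = s, precision = p, f1 = f1_score(s, p)
  )
}

#' Benchmark call sets against truth sets
#'
#' Computes one row of TP/FP/FN counts and sensitivity/precision/F1 per
#' method and dataset, plus, when several datasets are supplied, a pooled
#' `global` row per method (TP, FP and FN sum across datasets; the global
#' truth denominator is the sum of the per-dataset truth sizes). Also builds
#' the detection matrix: truth entries in rows, methods in columns, `TRUE`
#' where the method's call set contains a match.
#'
#' @param call_sets A named list `method -> event tibble`, or a nested named
#'   list `method -> dataset -> event tibble` for multi-dataset runs.
#' @param truth A truth tibble ([read_truth()]), or a named list
#'   `dataset -> truth tibble` matching the nesting of `call_sets`.
#' @inheritParams match_truth
#' @return An object of class `fusemble_benchmark` with `results` (the
#'   metric table), `detection` (the detection matrix in long form) and the
#'   canonicalized truth. Use [generics::tidy()], [generics::glance()],
#'   [detection_matrix()] and `autoplot()` on it.
#' @export
benchmark_methods <- function(call_sets, truth, aliases = NULL,
                              ignore_orientation = FALSE) {
  if (is.null(names(call_sets)) || any(!nzchar(names(call_sets)))) {
    abort("call_sets must be a named list of methods")
  }
  if (anyDuplicated(names(call_sets))) {
    abort("method label collision in call_sets")
  }
  multi <- is.data.frame(truth) == FALSE
  datasets <- if (multi) names(truth) else "all"
  if (multi && (is.null(datasets) || anyDuplicated(datasets))) {
    abort("truth must be a uniquely named list of datasets")
  }
  results <- list()
  detection <- list()
  for (m in names(call_sets)) {
    per_ds <- list()
    for (ds in datasets) {
      tr <- if (multi) truth[[ds]] else truth
      if (nrow(tr) == 0) abort(sprintf("empty truth set for dataset '%s'", ds))
      calls <- if (multi) {
        if (!ds %in% names(call_sets[[m]])) {
          abort(sprintf("method '%s' has no call set for dataset '%s'", m, ds))
        }
        call_sets[[m]][[ds]]
      } else {
        call_sets[[m]]
      }
      mt <- match_truth(calls, tr, aliases, ignore_orientation)
      per_ds[[ds]] <- mt$counts
      results[[length(results) + 1]] <-
        benchmark_row(m, ds, mt$counts$tp, mt$counts$fp, mt$counts$fn)
      trc <- tr
      trc[, c("gene5", "gene3")] <- canonical_pair(trc, aliases)
      detection[[length(detection) + 1]] <- tibble(
        dataset = ds, sample_id = trc$sample_id,
        gene5 = trc$gene5, gene3 = trc$gene3, method = m,
        detected = truth_key(trc, ignore_orientation) %in%
          truth_key(mt$tp, ignore_orientation)
      )
    }
    if (length(datasets) > 1) {
      pooled <- bind_rows(per_ds)
      results[[length(results) + 1]] <- benchmark_row(
        m, "global", sum(pooled$tp), sum(pooled$fp), sum(pooled$fn)
      )
    }
  }
  structure(list(
    results = bind_rows(results),
    detection = bind_rows(detection)
  ), class = "fusemble_benchmark")
}

#' @export
print.fusemble_benchmark <- function(x, ...) {
  cat("<fusemble_benchmark>\n")
  print(as.data.frame(x$results), row.names = FALSE)
  invisible(x)
}

#' Detection matrix in wide form
#'
#' Truth entries in rows, one 0/1 column per method.
#'
#' @param x A `fusemble_benchmark`.
#' @return A tibble.
#' @export
detection_matrix <- function(x) {
  x$detection |>
    mutate(detected = as.integer(.data$detected)) |>
    tidyr::pivot_wider(names_from = "method", values_from = "detected")
}

#' Write the benchmark report and detection matrix
#'
#' @param x A `fusemble_benchmark`.
#' @param report_path,matrix_path Output TSV paths (either may be `NULL`).
#' @return `x`, invisibly.
#' @export
write_benchmark <- function(x, report_path = NULL, matrix_path = NULL) {
  if (!is.null(report_path)) write_tsv_unix(x$results, report_path)
  if (!is.null(matrix_path)) write_tsv_unix(detection_matrix(x), matrix_path)
  invisible(x)
}

#' Tidy a benchmark
#'
#' @param x A `fusemble_benchmark`.
#' @param ... Unused.
#' @return The per-method, per-dataset metric tibble.
#' @method tidy fusemble_benchmark
#' @export
tidy.fusemble_benchmark <- function(x, ...) {
  x$results
}

#' Glance at a benchmark
#'
#' @param x A `fusemble_benchmark`.
#' @param ... Unused.
#' @return A one-row tibble naming the best-F1 method on the pooled (or
#'   only) dataset.
#' @method glance fusemble_benchmark
#' @export
glance.fusemble_benchmark <- function(x, ...) {
  pool <- if ("global" %in% x$results$dataset) {
    filter(x$results, .data$dataset == "global")
  } else {
    x$results
  }
  best <- pool[which.max(pool$f1), ]
  tibble(
    n_methods = n_distinct(x$results$method),
    n_datasets = n_distinct(setdiff(x$results$dataset, "global")),
    best_method = best$method,
    best_f1 = best$f1,
    max_sensitivity = max(pool$sensitivity),
    max_precision = max(pool$precision)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
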