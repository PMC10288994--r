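#' Parse every caller file of a cohort directory
#'
#' Expects the layout `dir/<sample>/<native caller file>` (the layout
#' [generate_cohort()] writes and caller runs produce). A sample directory
#' missing a caller's file raises a warning and proceeds with the remaining
#' callers — k-of-n agreement is still counted against all five callers, so
#' consensus denominators do not change. A malformed file is an error.
#'
#' @param dir Cohort directory.
#' @param samples Optional subset of sample directories; defaults to every
#'   subdirectory.
#' @return A standardized call tibble across all samples and callers.
#' @export
parse_cohort <- function(dir, samples = NULL) {
  if (is.null(samples)) {
    samples <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  }
  if (length(samples) == 0) abort(sprintf("no sample directories under %s", dir))
  out <- list()
  for (s in samples) {
    for (cl in fusion_callers()) {
      path <- file.path(dir, s, caller_file_name(cl))
      if (!file.exists(path)) {
        warn(sprintf("missing %s output for sample %s; proceeding without it (agreement still counted out of 5)", cl, s))
        next
      }
      out[[length(out) + 1]] <- parse_caller(path, cl, sample_id = s)
    }
  }
  bind_rows(out)
}

#' Run the integration pipeline: parse, merge, vote, filter
#'
#' The three-stage flow over already-generated caller outputs: standardize
#' the five callers' files into one call table, merge equivalent calls into
#' fusion events per sample, keep the k-of-5 consensus set, and run the
#' artifact filter cascade. The returned object records the call funnel
#' (raw calls, merged events, consensus events, retained events).
#'
#' @param dir Cohort directory (`dir/<sample>/<caller file>` layout).
#' @param annotation A [gene_annotation()] or a path to a GTF.
#' @param config A [filter_config()].
#' @param k Consensus threshold, 1-5 (default 3 — the agreement level with
#'   the best sensitivity/precision balance).
#' @param aliases An [alias_table()]; defaults to the bundled table.
#' @inheritParams merge_calls
#' @param samples Optional subset of samples.
#' @return An object of class `fusemble_integration`: `calls`, `events`
#'   (all merged events), `consensus`, `filter` (the
#'   `fusemble_filter_result`), `retained`, and a `funnel` tibble.
#' @export
integrate_cohort <- function(dir, annotation, config = filter_config(), k = 3,
                             aliases = read_alias_table(),
                             bp_tolerance = 100, collapse_reciprocal = FALSE,
                             samples = NULL) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  calls <- parse_cohort(dir, samples)
  events <- harmonize_calls(calls, aliases = aliases,
    bp_tolerance = bp_tolerance, collapse_reciprocal = collapse_reciprocal)
  consensus <- consensus_select(events, k)
  filt <- run_filter_cascade(consensus, annotation, config)
  funnel <- tibble(
    stage = c("raw_calls", "merged_events", sprintf("consensus_k%d", k), "retained"),
    n = c(nrow(calls), nrow(events), nrow(consensus), nrow(filt$retained))
  )
  structure(list(
    calls = calls, events = events, consensus = consensus,
    filter = filt, retained = filt$retained, funnel = funnel,
    k = k, config = config
  ), class = "fusemble_integration")
}

#' @export
print.fusemble_integration <- function(x, ...) {
  cat(sprintf("<fusemble_integration> k = %d\n", x$k))
  print(as.data.frame(x$funnel), row.names = FALSE)
  invisible(x)
}

#' Write the integration outputs
#'
#' Emits the three integration files: the standardized fusion table (every
#' merged event from every caller, one row per event), the caller summary
#' (how many and which callers detected each event), and the filter audit
#' TSV.
#'
#' @param x A `fusemble_integration`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_integration <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    standard = file.path(dir, "fusions_standard.tsv"),
    summary = file.path(dir, "fusions_summary.tsv"),
    audit = file.path(dir, "filter_audit.tsv")
  )
  write_standard_table(x$events, paths[["standard"]])
  write_summary(x$events, paths[["summary"]])
  write_audit(x$filter, paths[["audit"]])
  invisible(paths)
}
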