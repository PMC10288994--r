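standard_table_columns <- function() {
  c("sample", "gene5", "gene3", "chrom5", "pos5", "strand5",
    "chrom3", "pos3", "strand3", "caller_count", "callers",
    "max_split", "max_spanning", "frame", "status")
}

#' Write the standardized fusion table
#'
#' One tab-separated row per merged fusion event with a fixed column order
#' (sample, partner symbols, representative breakpoints, caller agreement,
#' maximum read support, frame, lifecycle status). The caller list is
#' comma-joined in alphabetical order. [read_standard_table()] re-parses the
#' file into an equal event table (round-trip, minus the per-call evidence).
#'
#' @param events An event tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_standard_table <- function(events, path) {
  df <- tibble(
    sample = events$sample_id,
    gene5 = events$gene5, gene3 = events$gene3,
    chrom5 = events$chrom5, pos5 = events$pos5, strand5 = events$strand5,
    chrom3 = events$chrom3, pos3 = events$pos3, strand3 = events$strand3,
    caller_count = events$caller_count,
    callers = vapply(events$callers, paste, character(1), collapse = ","),
    max_split = events$max_split, max_spanning = events$max_spanning,
    frame = events$frame, status = events$status
  )
  write_tsv_unix(df, path)
  invisible(path)
}

#' Read a standardized fusion table
#'
#' @param path A TSV written by [write_standard_table()].
#' @return An event tibble (without the `evidence` and `n_calls` columns).
#' @export
read_standard_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample = "c", gene5 = "c", gene3 = "c",
    chrom5 = "c", pos5 = "d", strand5 = "c",
    chrom3 = "c", pos3 = "d", strand3 = "c",
    caller_count = "i", callers = "c",
    max_split = "d", max_spanning = "d", frame = "c", status = "c"
  ), progress = FALSE)
  require_columns(df, standard_table_columns(), path)
  tibble(
    sample_id = df$sample,
    gene5 = df$gene5, gene3 = df$gene3,
    chrom5 = df$chrom5, pos5 = df$pos5, strand5 = df$strand5,
    chrom3 = df$chrom3, pos3 = df$pos3, strand3 = df$strand3,
    caller_count = df$caller_count,
    callers = stringr::str_split(df$callers, ","),
    max_split = df$max_split, max_spanning = df$max_spanning,
    frame = df$frame, status = df$status
  )
}

#' Write the caller summary file
#'
#' One row per fusion event with the number and names of the callers that
#' detected it, caller names comma-joined alphabetically.
#'
#' @inheritParams write_standard_table
#' @return `path`, invisibly.
#' @export
write_summary <- function(events, path) {
  df <- tibble(
    sample = events$sample_id,
    gene5 = events$gene5, gene3 = events$gene3,
    caller_count = events$caller_count,
    callers = vapply(events$callers, function(x) paste(sort(x), collapse = ","),
      character(1))
  )
  write_tsv_unix(df, path)
  invisible(path)
}
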