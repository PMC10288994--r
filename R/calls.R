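#' Supported fusion callers
#'
#' Identifiers of the five callers whose native output the package reads.
#'
#' @return A character vector of caller identifiers.
#' @export
fusion_callers <- function() {
  c("arriba", "cicero", "defuse", "fusioncatcher", "starfusion")
}

call_columns <- function() {
  c(
    "caller", "sample_id", "gene5", "gene3",
    "chrom5", "pos5", "strand5", "chrom3", "pos3", "strand3",
    "split_reads", "spanning_reads", "confidence", "frame", "annotations"
  )
}

#' An empty standardized call table
#'
#' Returns a zero-row tibble with the standardized call schema: one row per
#' fusion prediction by one caller in one sample, with both breakpoints,
#' read support, the caller's native confidence label and reading-frame
#' annotation, plus an `annotations` list-column holding caller-specific
#' extras.
#'
#' @return A zero-row tibble with the standardized call columns.
#' @export
empty_fusion_calls <- function() {
  tibble(
    caller = character(), sample_id = character(),
    gene5 = character(), gene3 = character(),
    chrom5 = character(), pos5 = double(), strand5 = character(),
    chrom3 = character(), pos3 = double(), strand3 = character(),
    split_reads = double(), spanning_reads = double(),
    confidence = character(), frame = character(),
    annotations = list()
  )
}

# Validate and finish a parsed call table. All parsers funnel through here so
# the invariants (non-negative read counts, known caller ids, positive
# coordinates, frame vocabulary) hold package-wide.
new_fusion_calls <- function(df, path = "<calls>") {
  df <- as_tibble(df)
  if (nrow(df) == 0) {
    return(empty_fusion_calls())
  }
  df$chrom5 <- normalize_chrom(df$chrom5)
  df$chrom3 <- normalize_chrom(df$chrom3)
  df$strand5 <- ifelse(df$strand5 %in% c("+", "-"), df$strand5, "unknown")
  df$strand3 <- ifelse(df$strand3 %in% c("+", "-"), df$strand3, "unknown")
  df$frame <- ifelse(df$frame %in% c("in-frame", "out-of-frame"), df$frame, "unknown")
  bad_caller <- setdiff(unique(df$caller), fusion_callers())
  if (length(bad_caller) > 0) {
    abort(sprintf("%s: unknown caller id: %s", path, paste(bad_caller, collapse = ", ")))
  }
  if (any(df$split_reads < 0, na.rm = TRUE) || any(df$spanning_reads < 0, na.rm = TRUE)) {
    abort(sprintf("%s: negative read counts", path))
  }
  if (any(df$pos5 < 1, na.rm = TRUE) || any(df$pos3 < 1, na.rm = TRUE)) {
    abort(sprintf("%s: breakpoint positions must be >= 1", path))
  }
  if (any(!nzchar(df$gene5)) || any(!nzchar(df$gene3))) {
    abort(sprintf("%s: empty gene symbol", path))
  }
  if (!"annotations" %in% names(df)) {
    df$annotations <- rep(list(character()), nrow(df))
  }
  df[call_columns()]
}

# Pull leftover native columns into the annotations list-column, one named
# character vector per row.
collect_annotations <- function(df, used) {
  extra <- setdiff(names(df), used)
  if (length(extra) == 0) {
    return(rep(list(character()), nrow(df)))
  }
  extras <- df[extra]
  lapply(seq_len(nrow(df)), function(i) {
    vals <- vapply(extras[i, ], function(v) as.character(v)[1], character(1))
    vals[!is.na(vals)]
  })
}
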