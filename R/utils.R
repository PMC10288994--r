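#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join anti_join semi_join distinct n n_distinct row_number
#' @importFrom tibble tibble as_tibble
NULL

# Round half away from zero (printed tables use 73.7 = 100*14/19, which
# plain round() would sometimes turn into the even neighbour).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Strip a leading "chr" prefix so both dialects ("chr9" and "9") compare equal.
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x))
}

# Strict numeric coercion: any value that does not parse is an error, never a
# silent zero. `what` and `path` give the user a usable message.
parse_count <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "")
  if (length(bad) > 0) {
    abort(sprintf(
      "unparseable value '%s' in column '%s' (data row %d) of %s",
      x[bad[1]], what, bad[1], path
    ))
  }
  out[is.na(out)] <- NA_real_
  out
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s: missing mandatory column%s: %s",
      path, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Default sample id: name of the directory that holds the caller file, the
# layout both real caller runs and generate_cohort() use.
infer_sample_id <- function(path) {
  basename(dirname(normalizePath(path, mustWork = FALSE)))
}
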