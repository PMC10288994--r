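read_caller_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  )
  names(df) <- sub("^#", "", names(df))
  df
}

split_breakpoint <- function(x, what, path) {
  m <- stringr::str_match(x, "^([^:]+):([0-9]+)(?::([+-]))?$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed breakpoint '%s' in column '%s' (data row %d) of %s",
      x[bad[1]], what, bad[1], path
    ))
  }
  tibble(chrom = m[, 2], pos = as.numeric(m[, 3]), strand = m[, 4])
}

# Arriba emits strands as "gene/fusion" (e.g. "+/+"); the fusion strand is the
# one that locates the breakpoint.
arriba_strand <- function(x) {
  out <- sub("^.*/", "", x)
  ifelse(out %in% c("+", "-"), out, "unknown")
}

#' Read an Arriba `fusions.tsv` file
#'
#' Parses Arriba's tab-separated prediction file into the standardized call
#' table. Arriba's two split-read columns (one per breakpoint) are summed into
#' a single `split_reads` value so read support is one comparable scalar
#' across callers; `discordant_mates` maps to `spanning_reads`. The native
#' `confidence` label (high/medium/low) and `reading_frame` are preserved.
#' No filtering is applied: every data row yields exactly one call.
#'
#' @param path Path to an Arriba `fusions.tsv`.
#' @param sample_id Sample identifier; defaults to the name of the directory
#'   containing `path`.
#' @return A standardized call tibble (see [empty_fusion_calls()]).
#' @export
parse_arriba <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% infer_sample_id(path)
  df <- read_caller_tsv(path)
  mandatory <- c(
    "gene1", "gene2", "breakpoint1", "breakpoint2",
    "split_reads1", "split_reads2", "discordant_mates", "confidence"
  )
  require_columns(df, mandatory, path)
  if (nrow(df) == 0) return(empty_fusion_calls())
  bp1 <- split_breakpoint(df$breakpoint1, "breakpoint1", path)
  bp2 <- split_breakpoint(df$breakpoint2, "breakpoint2", path)
  s1 <- if ("strand1(gene/fusion)" %in% names(df)) arriba_strand(df$`strand1(gene/fusion)`) else "unknown"
  s2 <- if ("strand2(gene/fusion)" %in% names(df)) arriba_strand(df$`strand2(gene/fusion)`) else "unknown"
  frame <- if ("reading_frame" %in% names(df)) {
    ifelse(df$reading_frame == "in-frame", "in-frame",
      ifelse(df$reading_frame == "out-of-frame", "out-of-frame", "unknown")
    )
  } else "unknown"
  used <- c(
    mandatory, "strand1(gene/fusion)", "strand2(gene/fusion)", "reading_frame"
  )
  new_fusion_calls(tibble(
    caller = "arriba", sample_id = sample_id,
    gene5 = df$gene1, gene3 = df$gene2,
    chrom5 = bp1$chrom, pos5 = bp1$pos, strand5 = s1,
    chrom3 = bp2$chrom, pos3 = bp2$pos, strand3 = s2,
    split_reads = parse_count(df$split_reads1, "split_reads1", path) +
      parse_count(df$split_reads2, "split_reads2", path),
    spanning_reads = parse_count(df$discordant_mates, "discordant_mates", path),
    confidence = df$confidence,
    frame = frame,
    annotations = collect_annotations(df, used)
  ), path)
}

#' Read a STAR-Fusion prediction file
#'
#' Parses `star-fusion.fusion_predictions.tsv`. The `#FusionName` column
#' ("GENE5--GENE3") is split into the partner symbols; `JunctionReadCount`
#' maps to `split_reads` and `SpanningFragCount` to `spanning_reads`.
#' STAR-Fusion reports no confidence label, so `confidence` is `NA`.
#'
#' @inheritParams parse_arriba
#' @return A standardized call tibble.
#' @export
parse_starfusion <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% infer_sample_id(path)
  df <- read_caller_tsv(path)
  mandatory <- c(
    "FusionName", "JunctionReadCount", "SpanningFragCount",
    "LeftBreakpoint", "RightBreakpoint"
  )
  require_columns(df, mandatory, path)
  if (nrow(df) == 0) return(empty_fusion_calls())
  genes <- stringr::str_split_fixed(df$FusionName, "--", 2)
  bad <- which(!nzchar(genes[, 2]))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed FusionName '%s' (data row %d) of %s",
      df$FusionName[bad[1]], bad[1], path
    ))
  }
  bp1 <- split_breakpoint(df$LeftBreakpoint, "LeftBreakpoint", path)
  bp2 <- split_breakpoint(df$RightBreakpoint, "RightBreakpoint", path)
  used <- c(mandatory, "LeftGene", "RightGene")
  new_fusion_calls(tibble(
    caller = "starfusion", sample_id = sample_id,
    gene5 = genes[, 1], gene3 = genes[, 2],
    chrom5 = bp1$chrom, pos5 = bp1$pos, strand5 = bp1$strand %||% "unknown",
    chrom3 = bp2$chrom, pos3 = bp2$pos, strand3 = bp2$strand,
    split_reads = parse_count(df$JunctionReadCount, "JunctionReadCount", path),
    spanning_reads = parse_count(df$SpanningFragCount, "SpanningFragCount", path),
    confidence = NA_character_,
    frame = "unknown",
    annotations = collect_annotations(df, used)
  ), path)
}

#' Read a FusionCatcher candidate list
#'
#' Parses `final-list_candidate-fusion-genes.txt`. `Spanning_unique_reads`
#' maps to `split_reads` (reads crossing the junction) and `Spanning_pairs`
#' to `spanning_reads`. The `Fusion_description` tags (e.g. "readthrough",
#' "known") and `Counts_of_common_mapping_reads` are retained in
#' `annotations` for downstream filtering; `Predicted_effect` feeds `frame`.
#'
#' @inheritParams parse_arriba
#' @return A standardized call tibble.
#' @export
parse_fusioncatcher <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% infer_sample_id(path)
  df <- read_caller_tsv(path)
  g5 <- "Gene_1_symbol(5end_fusion_partner)"
  g3 <- "Gene_2_symbol(3end_fusion_partner)"
  p5 <- "Fusion_point_for_gene_1(5end_fusion_partner)"
  p3 <- "Fusion_point_for_gene_2(3end_fusion_partner)"
  mandatory <- c(g5, g3, "Spanning_pairs", "Spanning_unique_reads", p5, p3)
  require_columns(df, mandatory, path)
  if (nrow(df) == 0) return(empty_fusion_calls())
  bp1 <- split_breakpoint(df[[p5]], p5, path)
  bp2 <- split_breakpoint(df[[p3]], p3, path)
  frame <- if ("Predicted_effect" %in% names(df)) {
    ifelse(df$Predicted_effect == "in-frame", "in-frame",
      ifelse(df$Predicted_effect == "out-of-frame", "out-of-frame", "unknown")
    )
  } else "unknown"
  used <- c(mandatory, "Predicted_effect")
  new_fusion_calls(tibble(
    caller = "fusioncatcher", sample_id = sample_id,
    gene5 = df[[g5]], gene3 = df[[g3]],
    chrom5 = bp1$chrom, pos5 = bp1$pos, strand5 = bp1$strand,
    chrom3 = bp2$chrom, pos3 = bp2$pos, strand3 = bp2$strand,
    split_reads = parse_count(df$Spanning_unique_reads, "Spanning_unique_reads", path),
    spanning_reads = parse_count(df$Spanning_pairs, "Spanning_pairs", path),
    confidence = NA_character_,
    frame = frame,
    annotations = collect_annotations(df, used)
  ), path)
}

#' Read a deFuse filtered results file
#'
#' Parses `results.filtered.tsv`. `splitr_count` maps to `split_reads`,
#' `span_count` to `spanning_reads`, and the classifier `probability` is kept
#' as the caller's confidence value. The `orf` flag (Y/N) feeds `frame`.
#'
#' @inheritParams parse_arriba
#' @return A standardized call tibble.
#' @export
parse_defuse <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% infer_sample_id(path)
  df <- read_caller_tsv(path)
  mandatory <- c(
    "gene_name1", "gene_name2", "gene_chromosome1", "gene_chromosome2",
    "genomic_break_pos1", "genomic_break_pos2",
    "splitr_count", "span_count", "probability"
  )
  require_columns(df, mandatory, path)
  if (nrow(df) == 0) return(empty_fusion_calls())
  s1 <- if ("gene_strand1" %in% names(df)) df$gene_strand1 else "unknown"
  s2 <- if ("gene_strand2" %in% names(df)) df$gene_strand2 else "unknown"
  frame <- if ("orf" %in% names(df)) {
    ifelse(df$orf == "Y", "in-frame", ifelse(df$orf == "N", "out-of-frame", "unknown"))
  } else "unknown"
  used <- c(mandatory, "gene_strand1", "gene_strand2", "orf")
  new_fusion_calls(tibble(
    caller = "defuse", sample_id = sample_id,
    gene5 = df$gene_name1, gene3 = df$gene_name2,
    chrom5 = df$gene_chromosome1,
    pos5 = parse_count(df$genomic_break_pos1, "genomic_break_pos1", path),
    strand5 = s1,
    chrom3 = df$gene_chromosome2,
    pos3 = parse_count(df$genomic_break_pos2, "genomic_break_pos2", path),
    strand3 = s2,
    split_reads = parse_count(df$splitr_count, "splitr_count", path),
    spanning_reads = parse_count(df$span_count, "span_count", path),
    confidence = df$probability,
    frame = frame,
    annotations = collect_annotations(df, used)
  ), path)
}

#' Read a CICERO `final_fusions.txt` file
#'
#' Parses CICERO's final fusion table. CICERO reports per-side read evidence
#' (`readsA`/`readsB`); these map to `split_reads`/`spanning_reads`
#' respectively as an approximation — CICERO does not separate junction from
#' bridging reads the way the other callers do. The `rating` label (HQ/LQ/RT)
#' is kept as `confidence` and `score` lands in `annotations`.
#'
#' @inheritParams parse_arriba
#' @return A standardized call tibble.
#' @export
parse_cicero <- function(path, sample_id = NULL) {
  df <- read_caller_tsv(path)
  mandatory <- c(
    "geneA", "chrA", "posA", "geneB", "chrB", "posB", "readsA", "readsB", "rating"
  )
  require_columns(df, mandatory, path)
  if (nrow(df) == 0) return(empty_fusion_calls())
  sample_col <- if ("sample" %in% names(df)) df$sample else NA_character_
  sid <- sample_id %||% infer_sample_id(path)
  sample_ids <- ifelse(!is.na(sample_col) & nzchar(sample_col) & is.null(sample_id),
    sample_col, sid
  )
  s1 <- if ("ortA" %in% names(df)) df$ortA else "unknown"
  s2 <- if ("ortB" %in% names(df)) df$ortB else "unknown"
  frame <- if ("frame" %in% names(df)) {
    ifelse(df$frame %in% c("1", "in-frame"), "in-frame",
      ifelse(df$frame %in% c("0", "out-of-frame"), "out-of-frame", "unknown")
    )
  } else "unknown"
  used <- c(mandatory, "sample", "ortA", "ortB", "frame")
  new_fusion_calls(tibble(
    caller = "cicero", sample_id = sample_ids,
    gene5 = df$geneA, gene3 = df$geneB,
    chrom5 = df$chrA, pos5 = parse_count(df$posA, "posA", path), strand5 = s1,
    chrom3 = df$chrB, pos3 = parse_count(df$posB, "posB", path), strand3 = s2,
    split_reads = parse_count(df$readsA, "readsA", path),
    spanning_reads = parse_count(df$readsB, "readsB", path),
    confidence = df$rating,
    frame = frame,
    annotations = collect_annotations(df, used)
  ), path)
}

#' Read any supported caller's native output
#'
#' Dispatches to the caller-specific parser.
#'
#' @param path Path to the caller's native output file.
#' @param caller One of `fusion_callers()`.
#' @inheritParams parse_arriba
#' @return A standardized call tibble.
#' @export
parse_caller <- function(path, caller, sample_id = NULL) {
  caller <- match.arg(caller, fusion_callers())
  switch(caller,
    arriba = parse_arriba(path, sample_id),
    cicero = parse_cicero(path, sample_id),
    defuse = parse_defuse(path, sample_id),
    fusioncatcher = parse_fusioncatcher(path, sample_id),
    starfusion = parse_starfusion(path, sample_id)
  )
}

# Native file name each caller's run directory is expected to contain.
caller_file_name <- function(caller) {
  switch(caller,
    arriba = "fusions.tsv",
    starfusion = "star-fusion.fusion_predictions.tsv",
    fusioncatcher = "final-list_candidate-fusion-genes.txt",
    defuse = "results.filtered.tsv",
    cicero = "final_fusions.txt",
    abort(sprintf("unknown caller id: %s", caller))
  )
}
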