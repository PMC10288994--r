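# Emit caller-native files from standardized call tables. These writers are
# the inverse of the parsers and back the cohort simulator: the files they
# produce are valid input to every parser. Column sets are the mandatory
# subset of each caller's published layout.

ann_field <- function(annotations, key, default) {
  vapply(annotations, function(a) {
    if (!is.null(a) && key %in% names(a)) a[[key]] else default
  }, character(1))
}

write_tsv_unix <- function(df, path) {
  readr::write_tsv(df, path, na = "", eol = "\n", progress = FALSE)
}

frame_label <- function(frame, inf, outf, unk) {
  ifelse(frame == "in-frame", inf, ifelse(frame == "out-of-frame", outf, unk))
}

strand_or <- function(x, default) ifelse(x %in% c("+", "-"), x, default)

#' Write calls as an Arriba `fusions.tsv`
#'
#' @param calls A standardized call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @rdname caller_writers
#' @export
write_arriba <- function(calls, path) {
  df <- tibble(
    `#gene1` = calls$gene5, gene2 = calls$gene3,
    `strand1(gene/fusion)` = paste0(strand_or(calls$strand5, "."), "/", strand_or(calls$strand5, ".")),
    `strand2(gene/fusion)` = paste0(strand_or(calls$strand3, "."), "/", strand_or(calls$strand3, ".")),
    breakpoint1 = paste0("chr", calls$chrom5, ":", calls$pos5),
    breakpoint2 = paste0("chr", calls$chrom3, ":", calls$pos3),
    site1 = "splice-site", site2 = "splice-site", type = "translocation",
    split_reads1 = calls$split_reads, split_reads2 = 0,
    discordant_mates = calls$spanning_reads,
    confidence = ifelse(is.na(calls$confidence), ".", calls$confidence),
    reading_frame = frame_label(calls$frame, "in-frame", "out-of-frame", ".")
  )
  write_tsv_unix(df, path)
  invisible(path)
}

#' @rdname caller_writers
#' @export
write_starfusion <- function(calls, path) {
  strand5 <- strand_or(calls$strand5, "")
  strand3 <- strand_or(calls$strand3, "")
  df <- tibble(
    `#FusionName` = paste0(calls$gene5, "--", calls$gene3),
    JunctionReadCount = calls$split_reads,
    SpanningFragCount = calls$spanning_reads,
    SpliceType = "ONLY_REF_SPLICE",
    LeftGene = calls$gene5,
    LeftBreakpoint = paste0("chr", calls$chrom5, ":", calls$pos5,
      ifelse(nzchar(strand5), paste0(":", strand5), "")),
    RightGene = calls$gene3,
    RightBreakpoint = paste0("chr", calls$chrom3, ":", calls$pos3,
      ifelse(nzchar(strand3), paste0(":", strand3), ""))
  )
  write_tsv_unix(df, path)
  invisible(path)
}

#' @rdname caller_writers
#' @export
write_fusioncatcher <- function(calls, path) {
  df <- tibble(
    `Gene_1_symbol(5end_fusion_partner)` = calls$gene5,
    `Gene_2_symbol(3end_fusion_partner)` = calls$gene3,
    Fusion_description = ann_field(calls$annotations, "fusion_description", ""),
    Counts_of_common_mapping_reads = ann_field(calls$annotations, "counts_of_common_mapping_reads", "0"),
    Spanning_pairs = calls$spanning_reads,
    Spanning_unique_reads = calls$split_reads,
    `Fusion_point_for_gene_1(5end_fusion_partner)` =
      paste0(calls$chrom5, ":", calls$pos5, ":", strand_or(calls$strand5, "+")),
    `Fusion_point_for_gene_2(3end_fusion_partner)` =
      paste0(calls$chrom3, ":", calls$pos3, ":", strand_or(calls$strand3, "+")),
    Predicted_effect = frame_label(calls$frame, "in-frame", "out-of-frame", "unknown")
  )
  write_tsv_unix(df, path)
  invisible(path)
}

#' @rdname caller_writers
#' @export
write_defuse <- function(calls, path) {
  df <- tibble(
    cluster_id = seq_len(nrow(calls)),
    splitr_count = calls$split_reads,
    span_count = calls$spanning_reads,
    gene_name1 = calls$gene5, gene_name2 = calls$gene3,
    gene_chromosome1 = calls$chrom5, gene_chromosome2 = calls$chrom3,
    gene_strand1 = strand_or(calls$strand5, "."),
    gene_strand2 = strand_or(calls$strand3, "."),
    genomic_break_pos1 = calls$pos5, genomic_break_pos2 = calls$pos3,
    probability = ifelse(is.na(calls$confidence), "0.5", calls$confidence),
    orf = frame_label(calls$frame, "Y", "N", "-")
  )
  if (nrow(calls) == 0) df <- df[0, ]
  write_tsv_unix(df, path)
  invisible(path)
}

#' @rdname caller_writers
#' @export
write_cicero <- function(calls, path) {
  df <- tibble(
    sample = calls$sample_id,
    geneA = calls$gene5, chrA = paste0("chr", calls$chrom5), posA = calls$pos5,
    ortA = strand_or(calls$strand5, "."),
    geneB = calls$gene3, chrB = paste0("chr", calls$chrom3), posB = calls$pos3,
    ortB = strand_or(calls$strand3, "."),
    readsA = calls$split_reads, readsB = calls$spanning_reads,
    type = "CTX",
    score = ann_field(calls$annotations, "score", "100"),
    rating = ifelse(is.na(calls$confidence), "HQ", calls$confidence),
    frame = frame_label(calls$frame, "1", "0", "NA")
  )
  write_tsv_unix(df, path)
  invisible(path)
}

#' @rdname caller_writers
#' @param caller One of `fusion_callers()`.
#' @export
write_caller_file <- function(calls, caller, path) {
  caller <- match.arg(caller, fusion_callers())
  switch(caller,
    arriba = write_arriba(calls, path),
    cicero = write_cicero(calls, path),
    defuse = write_defuse(calls, path),
    fusioncatcher = write_fusioncatcher(calls, path),
    starfusion = write_starfusion(calls, path)
  )
}
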