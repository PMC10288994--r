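# Shared in-code fixtures: a call-row builder, a 6-gene toy annotation with
# known geometry, and a tiny cohort writer.

make_call <- function(caller = "arriba", sample_id = "S1",
                      gene5 = "KMT2A", gene3 = "AFF1",
                      chrom5 = "11", pos5 = 1500, strand5 = "+",
                      chrom3 = "4", pos3 = 2500, strand3 = "+",
                      split_reads = 10, spanning_reads = 5,
                      confidence = NA_character_, frame = "in-frame") {
  tibble::tibble(
    caller = caller, sample_id = sample_id, gene5 = gene5, gene3 = gene3,
    chrom5 = chrom5, pos5 = pos5, strand5 = strand5,
    chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
    split_reads = split_reads, spanning_reads = spanning_reads,
    confidence = confidence, frame = frame,
    annotations = rep(list(character()), length(caller))
  )
}

# Six genes with every read-through-relevant geometry:
#   A -> B   : chr1 "+", adjacent, gap 500  (read-through)
#   B -> C   : chr1, C on "-"              (strand mismatch)
#   C -> D   : chr1 "-" , D downstream-in-transcription of C? D is "+"
#   E        : chr1 "+", 5 Mb away         (gap too large)
#   F        : chr2                        (different chromosome)
# Exons: two per gene, with an intron between, so splice/exonic/intronic/
# intergenic positions all exist.
toy_annotation <- function() {
  genes <- tibble::tribble(
    ~gene, ~chrom, ~start, ~end, ~strand, ~biotype,
    "A", "1", 1000, 2000, "+", "protein_coding",
    "B", "1", 2500, 3500, "+", "protein_coding",
    "C", "1", 4000, 5000, "-", "protein_coding",
    "D", "1", 5600, 6600, "-", "protein_coding",
    "E", "1", 9000000, 9001000, "+", "protein_coding",
    "F", "2", 1000, 2000, "+", "protein_coding"
  )
  exons <- dplyr::bind_rows(lapply(seq_len(nrow(genes)), function(i) {
    s <- genes$start[i]
    tibble::tibble(gene = genes$gene[i],
      start = c(s, s + 600), end = c(s + 199, s + 1000))
  }))
  gene_annotation(genes, exons)
}

# Independent brute-force oracle for the read-through geometry, written from
# the definition: same chromosome and strand, 5' partner immediately
# upstream in transcriptional orientation, non-negative gap within limit.
oracle_read_through <- function(g5, g3, genes, max_distance) {
  a <- genes[genes$gene == g5, ]
  b <- genes[genes$gene == g3, ]
  if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
  if (a$chrom != b$chrom || a$strand != b$strand) return(FALSE)
  gap <- if (a$strand == "+") b$start - a$end else a$start - b$end
  !is.na(gap) && gap >= 0 && gap <= max_distance
}

# Linear-scan oracle for breakpoint classification.
oracle_site_class <- function(chrom, pos, ann, gene = NULL) {
  g <- ann$genes
  covering <- g[g$chrom == chrom & g$start <= pos & g$end >= pos, ]
  if (!is.null(gene)) covering <- covering[covering$gene == gene, ]
  if (nrow(covering) == 0) return("intergenic")
  cls <- "intronic"
  for (gn in covering$gene) {
    ex <- ann$exons[ann$exons$gene == gn, ]
    for (j in seq_len(nrow(ex))) {
      if (pos == ex$start[j] || pos == ex$end[j]) return("splice_site")
      if (pos > ex$start[j] && pos < ex$end[j]) cls <- "exonic"
    }
  }
  cls
}

# A minimal two-sample cohort on disk for pipeline tests.
write_tiny_cohort <- function(dir, seed = 7) {
  truth <- tibble::tibble(
    sample_id = c("S1", "S1", "S2"),
    gene5 = c("KMT2A", "ETV6", "BCR"),
    gene3 = c("AFF1", "RUNX1", "ABL1"),
    callers = list(fusion_callers(), c("arriba", "cicero", "defuse"), fusion_callers())
  )
  spec <- cohort_spec("tiny", c("S1", "S2"), truth,
    noise_per_caller = 1, seed = seed)
  generate_cohort(spec, dir)
}
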