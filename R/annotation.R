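#' Construct a gene annotation object
#'
#' Holds per-gene intervals (chromosome, span, strand, biotype) and exon
#' intervals whose boundary coordinates define the splice sites used by the
#' breakpoint classifier and the read-through test.
#'
#' @param genes Tibble with columns `gene`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`.
#' @param exons Tibble with columns `gene`, `start`, `end`.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  require_columns(genes, c("gene", "chrom", "start", "end", "strand", "biotype"),
    "<genes>")
  require_columns(exons, c("gene", "start", "end"), "<exons>")
  if (any(genes$start > genes$end)) abort("gene start > end")
  if (any(duplicated(genes$gene))) abort("duplicated gene symbols in annotation")
  ex <- left_join(exons, genes[, c("gene", "start", "end")],
    by = "gene", suffix = c("", ".gene"))
  if (any(is.na(ex$start.gene))) {
    abort("exon refers to a gene absent from the gene table")
  }
  if (any(ex$start < ex$start.gene | ex$end > ex$end.gene | ex$start > ex$end)) {
    abort("exon boundaries must lie within the gene body")
  }
  genes$chrom <- normalize_chrom(genes$chrom)
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf(
    "<gene_annotation> %d genes, %d exons on %d chromosomes\n",
    nrow(x$genes), nrow(x$exons), n_distinct(x$genes$chrom)
  ))
  invisible(x)
}

annotation_has <- function(ann, genes) {
  genes %in% ann$genes$gene
}

#' Read a gene annotation from GTF/GFF
#'
#' Ingests `gene` and `exon` records via `rtracklayer` and builds a
#' [gene_annotation()] object keyed by gene symbol (`gene_name`, falling back
#' to `gene_id`).
#'
#' @param path Path to a GTF or GFF3 file.
#' @return A `gene_annotation` object.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as_tibble(as.data.frame(gr))
  nm <- if ("gene_name" %in% names(df)) df$gene_name else df$gene_id
  nm[is.na(nm)] <- df$gene_id[is.na(nm)]
  df$gene <- nm
  genes <- df |>
    filter(.data$type == "gene") |>
    mutate(
      chrom = as.character(.data$seqnames),
      strand = as.character(.data$strand),
      biotype = if ("gene_biotype" %in% names(df)) .data$gene_biotype else "protein_coding"
    ) |>
    select("gene", "chrom", "start", "end", "strand", "biotype")
  exons <- df |>
    filter(.data$type == "exon") |>
    select("gene", "start", "end")
  gene_annotation(genes, exons)
}

#' Write a gene annotation as GTF
#'
#' @param ann A `gene_annotation` object.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  genes <- ann$genes
  exons <- left_join(ann$exons, genes[, c("gene", "chrom", "strand")], by = "gene")
  exons <- exons |>
    group_by(.data$gene) |>
    mutate(exon_number = as.character(row_number())) |>
    ungroup()
  rows <- bind_rows(
    tibble(
      chrom = genes$chrom, start = genes$start, end = genes$end,
      strand = genes$strand, type = "gene", gene = genes$gene,
      biotype = genes$biotype, exon_number = NA_character_
    ),
    tibble(
      chrom = exons$chrom, start = exons$start, end = exons$end,
      strand = exons$strand, type = "exon", gene = exons$gene,
      biotype = genes$biotype[match(exons$gene, genes$gene)],
      exon_number = exons$exon_number
    )
  )
  # GTF convention: each gene record followed by its exons
  rows <- rows[order(rows$chrom, match(rows$gene, genes$gene),
    rows$type != "gene", rows$start), ]
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand,
    source = "fusemble", type = rows$type,
    gene_id = rows$gene, gene_name = rows$gene, gene_biotype = rows$biotype,
    exon_number = rows$exon_number
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
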