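# Synthetic cohort simulator. Generates a toy GRCh38-labelled annotation,
# truth sets and caller-native output files with planted true fusions and an
# artifact taxonomy (read-through products, weakly supported calls,
# low-confidence calls, out-of-frame junctions, non-splice-site breakpoints,
# blacklisted partners, promiscuous hub genes), so every pipeline stage runs
# without sequencing data or caller execution. No read or sequence data is
# simulated — only caller output tables.

artifact_classes <- function() {
  c("read_through", "low_support", "out_of_frame", "non_splice",
    "blacklisted", "promiscuous", "low_confidence")
}

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Chromosomes of the real leukemia genes in the toy annotation (coordinates
# are synthetic; only chromosome identity and neighbourhood geometry matter).
real_gene_chroms <- function() {
  c(
    BCR = "22", ABL1 = "9", ETV6 = "12", RUNX1 = "21", KMT2A = "11",
    AFF1 = "4", TCF3 = "19", PBX1 = "1", MLLT3 = "9", MLLT1 = "19",
    ELL = "19", CBFB = "16", MYH11 = "16", RUNX1T1 = "8", PML = "15",
    RARA = "17", NUP214 = "9", SET = "9", FUS = "16", ERG = "21",
    PICALM = "11", MLLT10 = "10", `NKX2-5` = "5", TLX3 = "5",
    BCL11B = "14", LMO1 = "11", TRD = "14", CBFA2T3 = "16", GLIS2 = "16",
    NUP98 = "11", KDM5A = "12", MEF2D = "1", BCL9 = "1", EP300 = "22",
    ZNF384 = "12", KAT6A = "8", CREBBP = "16", DDX3X = "X",
    `HLA-A` = "6", `HLA-B` = "6", `HLA-DRB1` = "6", GAPDH = "12",
    ACTB = "7", RPL10 = "X", `MT-CO1` = "MT", `MT-ND4` = "MT"
  )
}

synthetic_gene_sets <- function() {
  list(
    generic = sprintf("SYNART%03d", 1:100), # artifact partners, chr2
    blk_partner = sprintf("SYNBLK%02d", 1:12), # partners of blacklisted genes, chr3
    prom_hub = sprintf("SYNPRO%d", 1:6), # promiscuous hubs, chr6
    prom_partner = sprintf("SYNPP%02d", 1:12), # their partners, chr6
    passenger = sprintf("SYNFP%02d", 1:10), # clean false-positive pairs, chr7
    noise = as.vector(vapply(c("AR", "CI", "DF", "FC", "SF"),
      function(p) sprintf("NZ%s%02d", p, 1:8), character(8)))
  )
}

noise_pool <- function(caller) {
  prefix <- c(arriba = "NZAR", cicero = "NZCI", defuse = "NZDF",
    fusioncatcher = "NZFC", starfusion = "NZSF")[[caller]]
  sprintf("%s%02d", prefix, 1:8)
}

# Adjacent same-strand gene groups: the read-through geometry pool plus the
# two intrachromosomal-deletion fusions that pipelines tend to mistake for
# read-throughs. Each entry: genes in coordinate order, gaps between them,
# strand.
adjacency_groups <- function() {
  list(
    list(chrom = "9", genes = c("MTAP", "CDKN2B-AS1"), gap = 5000, strand = "+"),
    list(chrom = "11", genes = c("RAG1", "IFTAP"), gap = 40000, strand = "+"),
    list(chrom = "2", genes = c("SYNRT1A", "SYNRT1B"), gap = 8000, strand = "+"),
    list(chrom = "3", genes = c("SYNRT2A", "SYNRT2B"), gap = 8000, strand = "+"),
    # minus-strand pair: transcription runs right-to-left, so the downstream
    # partner (SYNRT3B) sits at lower coordinates
    list(chrom = "4", genes = c("SYNRT3B", "SYNRT3A"), gap = 8000, strand = "-"),
    list(chrom = "1", genes = c("STIL", "TAL1"), gap = 16000, strand = "+"),
    list(chrom = "X", genes = c("P2RY8", "CRLF2"), gap = 300000, strand = "+")
  )
}

read_through_pairs <- function() {
  list(
    c("MTAP", "CDKN2B-AS1"), c("RAG1", "IFTAP"),
    c("SYNRT1A", "SYNRT1B"), c("SYNRT2A", "SYNRT2B"), c("SYNRT3A", "SYNRT3B")
  )
}

#' Generate the deterministic toy annotation
#'
#' Builds a GRCh38-labelled synthetic annotation containing every gene the
#' simulator can plant: the bundled whitelist and blacklist genes, adjacent
#' same-strand pairs for read-through geometry (including MTAP/CDKN2B-AS1
#' and RAG1/IFTAP), the STIL/TAL1 and P2RY8/CRLF2 neighbourhoods, and pools
#' of clearly synthetic (`SYN*`/`NZ*`) artifact, passenger and noise genes.
#' Every gene gets three exons, so each has known splice-site, exonic,
#' intronic and flanking intergenic coordinates. Generation is fully
#' deterministic: repeated calls (and GTF exports) are identical.
#'
#' @return A [gene_annotation()].
#' @export
generate_annotation <- function() {
  adj <- adjacency_groups()
  adj_genes <- unlist(lapply(adj, `[[`, "genes"))
  singles <- real_gene_chroms()
  singles <- singles[!names(singles) %in% adj_genes]
  syn <- synthetic_gene_sets()
  placements <- c(
    purrr::imap(singles, function(chrom, gene) {
      list(chrom = chrom, genes = gene, gap = NA, strand = "+")
    }),
    list(
      list(chrom = "2", genes = syn$generic, gap = NA, strand = "+"),
      list(chrom = "3", genes = syn$blk_partner, gap = NA, strand = "+"),
      list(chrom = "6", genes = c(syn$prom_hub, syn$prom_partner), gap = NA, strand = "+"),
      list(chrom = "7", genes = syn$passenger, gap = NA, strand = "+"),
      list(chrom = "8", genes = syn$noise, gap = NA, strand = "+")
    ),
    adj
  )
  base_gap <- 3e6 # far beyond the read-through distance
  gene_len <- 2600
  cursor <- list()
  rows <- list()
  for (pl in placements) {
    chrom <- pl$chrom
    at <- cursor[[chrom]] %||% 1e6
    for (j in seq_along(pl$genes)) {
      gap <- if (j == 1 || is.na(pl$gap)) base_gap else pl$gap
      start <- if (is.null(cursor[[chrom]])) at else cursor[[chrom]] + gap
      rows[[length(rows) + 1]] <- tibble(
        gene = pl$genes[j], chrom = chrom, start = start,
        end = start + gene_len - 1, strand = pl$strand
      )
      cursor[[chrom]] <- start + gene_len - 1
    }
  }
  genes <- bind_rows(rows) |> mutate(biotype = "protein_coding")
  exons <- genes |>
    select("gene", "start") |>
    tidyr::crossing(tibble(off_start = c(0, 1100, 2200),
      off_end = c(299, 1299, 2599))) |>
    mutate(exon_start = .data$start + .data$off_start,
      exon_end = .data$start + .data$off_end) |>
    select("gene", start = "exon_start", end = "exon_end") |>
    arrange(match(.data$gene, genes$gene), .data$start)
  gene_annotation(genes[, c("gene", "chrom", "start", "end", "strand", "biotype")],
    exons)
}

#' Specify a synthetic cohort
#'
#' A cohort spec pins down everything the generator needs: the samples, the
#' truth fusions (each either with an explicit detecting-caller set or
#' detected per caller with probability `detection_prob`), clean passenger
#' false positives, an artifact mix, and per-sample caller-specific noise
#' calls. Planted true calls always carry splice-site breakpoints and read
#' support above the default evidence thresholds; artifacts carry the
#' defining defect of their class.
#'
#' @param name Cohort label.
#' @param samples Character vector of sample ids.
#' @param truth Tibble with `sample_id`, `gene5`, `gene3`, optional `method`
#'   and optional `callers` list-column (explicit detecting callers; `NULL`
#'   entries fall back to sampled detection).
#' @param fp_events Tibble like `truth` (with `callers`) of clean passenger
#'   fusions that survive every filter but match no truth entry.
#' @param artifacts Tibble with `sample_id`, `gene5`, `gene3`, `class`
#'   (one of `artifact_classes()`) and `callers`.
#' @param noise_per_caller Number of caller-private singleton calls planted
#'   per caller per sample (default 2).
#' @param detection_prob Named per-caller detection probability for truth
#'   rows without an explicit caller set (default 0.9 each).
#' @param seed Integer seed; the same seed yields byte-identical output files.
#' @return A list of class `fusemble_cohort_spec`.
#' @export
cohort_spec <- function(name, samples, truth,
                        fp_events = NULL, artifacts = NULL,
                        noise_per_caller = 2,
                        detection_prob = NULL, seed = 1L) {
  detection_prob <- detection_prob %||%
    stats::setNames(rep(0.9, 5), fusion_callers())
  if (any(detection_prob < 0 | detection_prob > 1)) {
    abort("detection probabilities must lie in [0, 1]")
  }
  if (noise_per_caller < 0) abort("noise_per_caller must be >= 0")
  truth <- as_tibble(truth)
  if (!"method" %in% names(truth)) truth$method <- "karyotype/FISH"
  if (!"callers" %in% names(truth)) truth$callers <- list(NULL)
  if (!is.null(artifacts)) {
    bad <- setdiff(unique(artifacts$class), artifact_classes())
    if (length(bad) > 0) {
      abort(sprintf("unknown artifact class: %s", paste(bad, collapse = ", ")))
    }
  }
  structure(list(
    name = name, samples = samples, truth = truth,
    fp_events = fp_events %||% tibble(sample_id = character(),
      gene5 = character(), gene3 = character(), callers = list()),
    artifacts = artifacts %||% tibble(sample_id = character(),
      gene5 = character(), gene3 = character(), class = character(),
      callers = list()),
    noise_per_caller = noise_per_caller,
    detection_prob = detection_prob,
    seed = as.integer(seed)
  ), class = "fusemble_cohort_spec")
}

#' @export
print.fusemble_cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<fusemble_cohort_spec> '%s': %d samples, %d truth fusions, %d passengers, %d artifacts (seed %d)\n",
    x$name, length(x$samples), nrow(x$truth), nrow(x$fp_events),
    nrow(x$artifacts), x$seed
  ))
  invisible(x)
}

# Splice-site breakpoints for a planted fusion: the donor side uses an exon
# end of the 5' gene, the acceptor side an exon start of the 3' gene. The
# non_splice artifact class shifts both into introns instead.
plant_breakpoints <- function(gene5, gene3, ann, splice = TRUE) {
  ex5 <- ann$exons[ann$exons$gene == gene5, ]
  ex3 <- ann$exons[ann$exons$gene == gene3, ]
  g <- ann$genes
  i5 <- match(gene5, g$gene)
  i3 <- match(gene3, g$gene)
  off <- if (splice) 0 else 100
  list(
    chrom5 = g$chrom[i5], pos5 = ex5$end[2] + off, strand5 = g$strand[i5],
    chrom3 = g$chrom[i3], pos3 = ex3$start[2] - off, strand3 = g$strand[i3]
  )
}

# FusionCatcher writes legacy symbols for a few genes; the bundled alias
# table maps them back. Exercises symbol harmonization end to end.
fc_legacy_symbol <- function(x) {
  legacy <- c(KMT2A = "MLL", AFF1 = "AF4", MLLT3 = "AF9", ETV6 = "TEL",
    RUNX1 = "AML1")
  hit <- legacy[x]
  ifelse(is.na(hit), x, unname(hit))
}

# One standardized call for caller `cl` supporting a planted event of class
# `class` ("true"/"fp" or an artifact class). Read counts are sampled, but
# always on the intended side of the default evidence thresholds.
planted_call <- function(cl, sample_id, gene5, gene3, class, frame, ann) {
  bp <- plant_breakpoints(gene5, gene3, ann, splice = class != "non_splice")
  weak_conf <- class == "low_confidence" && cl %in% c("fusioncatcher", "starfusion")
  weak <- class == "low_support" || weak_conf
  split <- if (weak) sample(0:1, 1) else sample(8:40, 1)
  spanning <- if (weak) sample(0:1, 1) else sample(4:20, 1)
  confidence <- switch(cl,
    arriba = if (class == "low_confidence") "low" else "high",
    cicero = if (class == "low_confidence") "LQ" else "HQ",
    defuse = if (class == "low_confidence") "0.30" else sample(c("0.85", "0.92", "0.98"), 1),
    NA_character_
  )
  frame <- if (class == "out_of_frame") "out-of-frame" else frame
  annotations <- if (cl == "fusioncatcher") {
    desc <- if (class == "read_through") "readthrough" else if (class == "true") "known" else ""
    list(c(fusion_description = desc, counts_of_common_mapping_reads = "0"))
  } else {
    list(character())
  }
  g5 <- if (cl == "fusioncatcher") fc_legacy_symbol(gene5) else gene5
  g3 <- if (cl == "fusioncatcher") fc_legacy_symbol(gene3) else gene3
  tibble(
    caller = cl, sample_id = sample_id, gene5 = g5, gene3 = g3,
    chrom5 = bp$chrom5, pos5 = bp$pos5, strand5 = bp$strand5,
    chrom3 = bp$chrom3, pos3 = bp$pos3, strand3 = bp$strand3,
    split_reads = split, spanning_reads = spanning,
    confidence = confidence,
    frame = if (cl == "starfusion") "unknown" else frame,
    annotations = annotations
  )
}

#' Generate a cohort on disk
#'
#' Materializes a [cohort_spec()]: writes the toy annotation (GTF), the truth
#' set (TSV), a YAML copy of the spec parameters, and per sample one native
#' output file per caller under `dir/<sample>/`. Output is reproducible: the
#' same spec and seed give byte-identical files.
#'
#' @param spec A `fusemble_cohort_spec`.
#' @param dir Output directory (created if needed).
#' @param annotation Optional [gene_annotation()]; defaults to
#'   [generate_annotation()].
#' @return A list with `dir`, `annotation_path`, `truth_path`, `config_path`,
#'   `samples`, and the annotation object, invisibly classed
#'   `fusemble_cohort`.
#' @export
generate_cohort <- function(spec, dir, annotation = NULL) {
  ann <- annotation %||% generate_annotation()
  planted <- bind_rows(
    spec$truth |> mutate(class = "true") |>
      select("sample_id", "gene5", "gene3", "class", "callers"),
    spec$fp_events |> mutate(class = "fp") |>
      select("sample_id", "gene5", "gene3", "class", "callers"),
    spec$artifacts |>
      select("sample_id", "gene5", "gene3", "class", "callers")
  )
  missing <- setdiff(unique(c(planted$gene5, planted$gene3)), ann$genes$gene)
  if (length(missing) > 0) {
    abort(sprintf("gene pair absent from annotation: %s",
      paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(planted[, c("sample_id", "gene5", "gene3")])) {
    abort("duplicate planted (sample, gene pair): events would merge")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  annotation_path <- file.path(dir, "annotation.gtf")
  write_annotation(ann, annotation_path)
  truth_path <- file.path(dir, "truth.tsv")
  write_tsv_unix(spec$truth[, c("sample_id", "gene5", "gene3", "method")],
    truth_path)
  config_path <- file.path(dir, "cohort.yaml")
  yaml::write_yaml(list(
    name = spec$name, seed = spec$seed, samples = spec$samples,
    noise_per_caller = spec$noise_per_caller,
    detection_prob = as.list(spec$detection_prob)
  ), config_path)

  with_seed(spec$seed, {
    for (s in spec$samples) {
      sdir <- file.path(dir, s)
      dir.create(sdir, showWarnings = FALSE)
      rows <- planted[planted$sample_id == s, ]
      calls_by_caller <- stats::setNames(
        vector("list", length(fusion_callers())), fusion_callers())
      for (i in seq_len(nrow(rows))) {
        callers <- rows$callers[[i]]
        if (is.null(callers)) {
          keep <- stats::runif(5) < spec$detection_prob[fusion_callers()]
          callers <- fusion_callers()[keep]
        }
        for (cl in callers) {
          calls_by_caller[[cl]] <- c(calls_by_caller[[cl]], list(planted_call(
            cl, s, rows$gene5[i], rows$gene3[i], rows$class[i], "in-frame", ann
          )))
        }
      }
      # caller-private singleton noise from per-caller gene pools
      for (cl in fusion_callers()) {
        pool <- noise_pool(cl)
        if (spec$noise_per_caller > 0) {
          for (j in seq_len(spec$noise_per_caller)) {
            pair <- sample(pool, 2)
            calls_by_caller[[cl]] <- c(calls_by_caller[[cl]], list(planted_call(
              cl, s, pair[1], pair[2], "fp", "unknown", ann
            )))
          }
        }
        calls <- if (length(calls_by_caller[[cl]]) > 0) {
          new_fusion_calls(bind_rows(calls_by_caller[[cl]]))
        } else {
          empty_fusion_calls()
        }
        write_caller_file(calls, cl, file.path(sdir, caller_file_name(cl)))
      }
    }
  })
  invisible(structure(list(
    dir = dir, annotation_path = annotation_path, truth_path = truth_path,
    config_path = config_path, samples = spec$samples, annotation = ann,
    spec = spec
  ), class = "fusemble_cohort"))
}

# ---- canned benchmark scenarios --------------------------------------------

all5 <- function() fusion_callers()
but <- function(drop) setdiff(fusion_callers(), drop)

# Deterministic artifact plan: `quota` maps caller-agreement level ("5", "4",
# "3") to the number of consensus-level artifacts to plant. Classes, samples,
# caller subsets and gene pairs all cycle deterministically; the promiscuous
# class plants two events sharing a hub gene and so consumes two slots.
plan_artifacts <- function(samples, quota) {
  classes <- artifact_classes()
  blacklist <- c("HLA-A", "HLA-B", "HLA-DRB1", "GAPDH", "ACTB", "RPL10")
  rt <- read_through_pairs()
  triples <- utils::combn(fusion_callers(), 3, simplify = FALSE)
  ctr <- list(class = 0L, generic = 0L, rt = 0L, blk = 0L,
    prom = 0L, drop = 0L, tri = 0L)
  # per-class sample cycling keeps every class spread over all samples,
  # so no sample exhausts a small pair pool
  samp_ctr <- stats::setNames(rep(0L, length(classes)), classes)
  rows <- list()
  used <- character()
  for (lvl in names(quota)) {
    left <- quota[[lvl]]
    while (left > 0) {
      cls <- classes[ctr$class %% length(classes) + 1L]
      ctr$class <- ctr$class + 1L
      if (cls == "promiscuous" && left < 2) cls <- "low_support"
      s <- samples[samp_ctr[[cls]] %% length(samples) + 1L]
      samp_ctr[[cls]] <- samp_ctr[[cls]] + 1L
      callers <- switch(lvl,
        "5" = all5(),
        "4" = {
          ctr$drop <- ctr$drop + 1L
          but(fusion_callers()[(ctr$drop - 1L) %% 5L + 1L])
        },
        "3" = {
          ctr$tri <- ctr$tri + 1L
          triples[[(ctr$tri - 1L) %% length(triples) + 1L]]
        }
      )
      # advance the class-specific pool counter until the (sample, pair)
      # combination is unused, so cycling never plants the same pair twice
      # in one sample
      repeat {
        if (cls == "read_through") {
          ctr$rt <- ctr$rt + 1L
          pair <- rt[[(ctr$rt - 1L) %% length(rt) + 1L]]
          add <- tibble(sample_id = s, gene5 = pair[1], gene3 = pair[2],
            class = cls, callers = list(callers))
        } else if (cls == "blacklisted") {
          ctr$blk <- ctr$blk + 1L
          g5 <- blacklist[(ctr$blk - 1L) %% length(blacklist) + 1L]
          g3 <- sprintf("SYNBLK%02d", (ctr$blk - 1L) %% 12L + 1L)
          add <- tibble(sample_id = s, gene5 = g5, gene3 = g3,
            class = cls, callers = list(callers))
        } else if (cls == "promiscuous") {
          ctr$prom <- ctr$prom + 1L
          hub <- sprintf("SYNPRO%d", (ctr$prom - 1L) %% 6L + 1L)
          p1 <- sprintf("SYNPP%02d", ((ctr$prom - 1L) * 2L) %% 12L + 1L)
          p2 <- sprintf("SYNPP%02d", ((ctr$prom - 1L) * 2L + 1L) %% 12L + 1L)
          add <- tibble(sample_id = s, gene5 = hub, gene3 = c(p1, p2),
            class = cls, callers = list(callers, callers))
        } else {
          ctr$generic <- ctr$generic + 1L
          j <- (ctr$generic - 1L) %% 50L + 1L
          add <- tibble(sample_id = s,
            gene5 = sprintf("SYNART%03d", 2L * j - 1L),
            gene3 = sprintf("SYNART%03d", 2L * j),
            class = cls, callers = list(callers))
        }
        keys <- paste(add$sample_id, add$gene5, add$gene3)
        if (!any(keys %in% used)) break
      }
      used <- c(used, keys)
      rows[[length(rows) + 1]] <- add
      left <- left - nrow(add)
    }
  }
  bind_rows(rows)
}

#' Canned benchmark scenarios
#'
#' `scenario_cell_lines()` emulates a 14-sample leukemia cell-line cohort
#' with a 19-entry truth set: 13 fusions detected by all five callers, one by
#' four, two by three, and three (NKX2-5::BCL11B, TLX3::BCL11B, LMO1::TRD)
#' by none — FusionCatcher alone detects all 16 detectable fusions. Four
#' clean passenger false positives (one at 5-caller agreement, one at four,
#' two at three) survive the filter cascade, and 80 consensus-level
#' artifacts (14 at five-caller agreement, 19 at four, 47 at three) are
#' planted to be removed by it.
#'
#' `scenario_patients()` emulates a 15-patient cohort with a 22-entry truth
#' set: 12 fusions at five-caller agreement, six at four, four at three —
#' among them STIL::TAL1 and P2RY8::CRLF2, detected by exactly three
#' callers — plus one surviving passenger at three-caller agreement and 51
#' consensus-level artifacts (11/14/26 at agreement 5/4/3).
#'
#' Detection patterns are deterministic 0/1 flags, so downstream metrics are
#' exact and seed-independent; read supports are still sampled under the
#' spec seed.
#'
#' @param seed Seed stored in the spec (default 20230609).
#' @return A `fusemble_cohort_spec`.
#' @export
scenario_cell_lines <- function(seed = 20230609) {
  samples <- sprintf("CL%02d", 1:14)
  truth <- dplyr::tribble(
    ~sample_id, ~gene5, ~gene3, ~callers,
    "CL01", "BCR", "ABL1", all5(),
    "CL02", "ETV6", "RUNX1", all5(),
    "CL03", "KMT2A", "AFF1", all5(),
    "CL04", "TCF3", "PBX1", all5(),
    "CL05", "KMT2A", "MLLT3", all5(),
    "CL06", "RUNX1", "RUNX1T1", all5(),
    "CL07", "CBFB", "MYH11", all5(),
    "CL08", "PML", "RARA", all5(),
    "CL09", "NUP214", "ABL1", all5(),
    "CL10", "KMT2A", "MLLT1", all5(),
    "CL11", "STIL", "TAL1", all5(),
    "CL12", "P2RY8", "CRLF2", all5(),
    "CL13", "KMT2A", "ELL", all5(),
    "CL14", "CBFA2T3", "GLIS2", but("defuse"),
    "CL11", "SET", "NUP214", c("arriba", "defuse", "fusioncatcher"),
    "CL12", "PICALM", "MLLT10", c("cicero", "fusioncatcher", "starfusion"),
    "CL09", "NKX2-5", "BCL11B", character(),
    "CL10", "TLX3", "BCL11B", character(),
    "CL11", "LMO1", "TRD", character()
  )
  truth$method <- "karyotype/FISH/RT-qPCR"
  fp <- dplyr::tribble(
    ~sample_id, ~gene5, ~gene3, ~callers,
    "CL01", "SYNFP01", "SYNFP02", all5(),
    "CL02", "SYNFP03", "SYNFP04", but("cicero"),
    "CL03", "SYNFP05", "SYNFP06", c("arriba", "cicero", "defuse"),
    "CL04", "SYNFP07", "SYNFP08", c("arriba", "fusioncatcher", "starfusion")
  )
  artifacts <- plan_artifacts(samples, list("5" = 14, "4" = 19, "3" = 47))
  cohort_spec("cell_lines", samples, truth, fp, artifacts, seed = seed)
}

#' @rdname scenario_cell_lines
#' @export
scenario_patients <- function(seed = 20230609) {
  samples <- sprintf("PT%02d", 1:15)
  truth <- dplyr::tribble(
    ~sample_id, ~gene5, ~gene3, ~callers,
    "PT01", "ETV6", "RUNX1", all5(),
    "PT02", "BCR", "ABL1", all5(),
    "PT03", "KMT2A", "AFF1", all5(),
    "PT04", "TCF3", "PBX1", all5(),
    "PT05", "KMT2A", "MLLT3", all5(),
    "PT06", "CBFB", "MYH11", all5(),
    "PT07", "RUNX1", "RUNX1T1", all5(),
    "PT08", "PML", "RARA", all5(),
    "PT09", "KMT2A", "MLLT1", all5(),
    "PT10", "NUP214", "ABL1", all5(),
    "PT11", "KMT2A", "ELL", all5(),
    "PT12", "ETV6", "ABL1", all5(),
    "PT13", "PICALM", "MLLT10", but("defuse"),
    "PT14", "SET", "NUP214", but("cicero"),
    "PT15", "FUS", "ERG", but("starfusion"),
    "PT02", "NUP98", "KDM5A", but("arriba"),
    "PT05", "MEF2D", "BCL9", but("fusioncatcher"),
    "PT07", "EP300", "ZNF384", but("cicero"),
    "PT13", "STIL", "TAL1", c("arriba", "cicero", "fusioncatcher"),
    "PT14", "P2RY8", "CRLF2", c("arriba", "fusioncatcher", "starfusion"),
    "PT10", "KAT6A", "CREBBP", c("cicero", "defuse", "fusioncatcher"),
    "PT11", "DDX3X", "MLLT10", c("defuse", "fusioncatcher", "starfusion")
  )
  truth$method <- "karyotype/FISH/RT-qPCR/panel"
  fp <- dplyr::tribble(
    ~sample_id, ~gene5, ~gene3, ~callers,
    "PT01", "SYNFP01", "SYNFP02", c("arriba", "fusioncatcher", "starfusion")
  )
  artifacts <- plan_artifacts(samples, list("5" = 11, "4" = 14, "3" = 26))
  cohort_spec("patients", samples, truth, fp, artifacts, seed = seed)
}
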