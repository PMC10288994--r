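#' Build a gene-symbol alias table
#'
#' Callers emit differing symbol vocabularies (e.g. the legacy "MLL" versus
#' the current "KMT2A"). An alias table maps every alias to its canonical
#' symbol. Chains (A -> B, B -> C) are resolved at construction so lookup is
#' a single substitution, and canonical symbols map to themselves
#' (idempotent closure).
#'
#' @param x A named character vector (`c(alias = "canonical")`) or a data
#'   frame with columns `alias` and `canonical`.
#' @return A named character vector of class `fusemble_aliases`.
#' @export
alias_table <- function(x = character()) {
  if (is.data.frame(x)) {
    map <- stats::setNames(as.character(x$canonical), as.character(x$alias))
  } else {
    map <- x
  }
  if (length(map) > 0 && (is.null(names(map)) || any(!nzchar(names(map))))) {
    abort("alias table entries must be named: c(alias = 'canonical')")
  }
  # resolve chains; a cycle would never terminate, so cap at table size
  for (i in seq_len(length(map) + 1)) {
    hit <- map[map] # follow one link where the target is itself an alias
    step <- !is.na(hit) & hit != map
    if (!any(step)) break
    map[step] <- hit[step]
    if (i > length(map)) abort("alias table contains a cycle")
  }
  canon <- setdiff(unique(map), names(map))
  map <- c(map, stats::setNames(canon, canon))
  structure(map, class = c("fusemble_aliases", class(map)))
}

#' Read an alias table from a two-column TSV
#'
#' @param path TSV with columns `alias` and `canonical`. Defaults to the
#'   bundled table seeded with leukemia-relevant synonyms.
#' @return A `fusemble_aliases` table.
#' @export
read_alias_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gene_aliases.tsv", package = "fusemble")
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  require_columns(df, c("alias", "canonical"), path)
  alias_table(df)
}

#' Canonicalize gene symbols
#'
#' @param symbols Character vector of gene symbols.
#' @param aliases An alias table from [alias_table()], or `NULL` for identity.
#' @return Character vector of canonical symbols.
#' @export
canonical_symbols <- function(symbols, aliases = NULL) {
  if (any(is.na(symbols)) || any(!nzchar(symbols))) {
    abort("empty gene symbol cannot be canonicalized")
  }
  if (is.null(aliases) || length(aliases) == 0) {
    return(symbols)
  }
  hit <- unname(unclass(aliases)[symbols])
  ifelse(is.na(hit), symbols, hit)
}

#' Canonical ordered gene pair for each call
#'
#' Replaces both partner symbols by their canonical form while preserving the
#' 5' to 3' order — fusion direction is biologically meaningful
#' (KMT2A::AFF1 is not AFF1::KMT2A).
#'
#' @param calls A data frame with `gene5` and `gene3` columns.
#' @inheritParams canonical_symbols
#' @return A tibble with canonicalized `gene5`, `gene3`.
#' @export
canonical_pair <- function(calls, aliases = NULL) {
  tibble(
    gene5 = canonical_symbols(calls$gene5, aliases),
    gene3 = canonical_symbols(calls$gene3, aliases)
  )
}

# Group junction coordinates of same-pair calls: two calls describe the same
# junction when both breakpoints agree within `tol` bp on the same
# chromosomes. Greedy single-pass over junctions sorted by coordinate, so the
# result does not depend on input order.
junction_clusters <- function(calls, tol) {
  ord <- order(calls$chrom5, calls$pos5, calls$chrom3, calls$pos3)
  cluster <- integer(nrow(calls))
  seeds <- list()
  nxt <- 0L
  for (i in ord) {
    assigned <- FALSE
    for (j in seq_along(seeds)) {
      s <- seeds[[j]]
      if (calls$chrom5[i] == s$chrom5 && calls$chrom3[i] == s$chrom3 &&
        abs(calls$pos5[i] - s$pos5) <= tol && abs(calls$pos3[i] - s$pos3) <= tol) {
        cluster[i] <- j
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      nxt <- nxt + 1L
      seeds[[nxt]] <- list(
        chrom5 = calls$chrom5[i], pos5 = calls$pos5[i],
        chrom3 = calls$chrom3[i], pos3 = calls$pos3[i]
      )
      cluster[i] <- nxt
    }
  }
  cluster
}

# Deterministic representative breakpoint for one event: the junction cluster
# backed by the most callers wins; ties break by total read support, then by
# lowest coordinate. Within the winning cluster the best-supported call
# provides the coordinates.
representative_call <- function(calls, tol) {
  cl <- junction_clusters(calls, tol)
  support <- calls$split_reads + calls$spanning_reads
  stats_df <- tibble(cluster = cl, caller = calls$caller, support = support,
    pos5 = calls$pos5, pos3 = calls$pos3) |>
    group_by(.data$cluster) |>
    summarise(
      n_callers = n_distinct(.data$caller),
      total_support = sum(.data$support),
      min5 = min(.data$pos5), min3 = min(.data$pos3),
      .groups = "drop"
    ) |>
    arrange(dplyr::desc(.data$n_callers), dplyr::desc(.data$total_support),
      .data$min5, .data$min3)
  win <- stats_df$cluster[1]
  idx <- which(cl == win)
  idx <- idx[order(-support[idx], calls$pos5[idx], calls$pos3[idx], calls$caller[idx])]
  calls[idx[1], ]
}

#' Merge one sample's calls into fusion events
#'
#' Calls sharing the same canonical ordered gene pair within a sample merge
#' into a single event, whatever their exact breakpoints — callers disagree
#' on coordinates (different aligners and conventions), and fusions are
#' counted at gene-pair granularity. `bp_tolerance` only decides which calls
#' describe the same junction when picking the representative breakpoint; it
#' never splits an event. Merging is deterministic and independent of input
#' order, and every input call lands in exactly one event's evidence.
#'
#' @param calls A standardized call tibble for a single sample.
#' @inheritParams canonical_symbols
#' @param bp_tolerance Maximum distance in bp for two breakpoints to count as
#'   the same junction (default 100).
#' @param collapse_reciprocal If `TRUE`, A::B and B::A calls in the same
#'   sample are folded into one event under the majority orientation; by
#'   default reciprocal orientations stay distinct events.
#' @return An event tibble: one row per (sample, canonical gene pair) with a
#'   representative breakpoint, `caller_count`, sorted `callers` list-column,
#'   maximum read support, a consensus `frame` label ("in-frame" if any
#'   caller reports it, else "out-of-frame" if any, else "unknown"), lifecycle
#'   `status`, and the supporting calls in the `evidence` list-column.
#' @export
merge_calls <- function(calls, aliases = NULL, bp_tolerance = 100,
                        collapse_reciprocal = FALSE) {
  calls <- new_fusion_calls(calls)
  if (nrow(calls) == 0) {
    return(empty_fusion_events())
  }
  if (n_distinct(calls$sample_id) > 1) {
    abort("merge_calls() merges one sample at a time; got mixed sample_ids")
  }
  pair <- canonical_pair(calls, aliases)
  calls$gene5 <- pair$gene5
  calls$gene3 <- pair$gene3
  if (collapse_reciprocal) {
    lo <- pmin(calls$gene5, calls$gene3)
    hi <- pmax(calls$gene5, calls$gene3)
    ukey <- paste(lo, hi, sep = "\r")
    for (k in unique(ukey)) {
      i <- which(ukey == k)
      oris <- paste(calls$gene5[i], calls$gene3[i], sep = "\r")
      if (n_distinct(oris) < 2) next
      tab <- sort(table(oris), decreasing = TRUE)
      major <- if (tab[1] > tab[2]) names(tab)[1] else sort(names(tab))[1]
      flip <- i[oris != major]
      calls[flip, c("gene5", "gene3", "chrom5", "chrom3", "pos5", "pos3",
        "strand5", "strand3")] <-
        calls[flip, c("gene3", "gene5", "chrom3", "chrom5", "pos3", "pos5",
          "strand3", "strand5")]
    }
  }
  # deterministic internal order before grouping
  calls <- arrange(calls, .data$gene5, .data$gene3, .data$chrom5, .data$pos5,
    .data$chrom3, .data$pos3, .data$caller,
    dplyr::desc(.data$split_reads + .data$spanning_reads))
  keys <- distinct(calls, .data$gene5, .data$gene3)
  events <- purrr::pmap(keys, function(gene5, gene3) {
    sub <- calls[calls$gene5 == gene5 & calls$gene3 == gene3, ]
    rep <- representative_call(sub, bp_tolerance)
    tibble(
      sample_id = sub$sample_id[1],
      gene5 = gene5, gene3 = gene3,
      chrom5 = rep$chrom5, pos5 = rep$pos5, strand5 = rep$strand5,
      chrom3 = rep$chrom3, pos3 = rep$pos3, strand3 = rep$strand3,
      caller_count = n_distinct(sub$caller),
      callers = list(sort(unique(sub$caller))),
      n_calls = nrow(sub),
      max_split = max(sub$split_reads),
      max_spanning = max(sub$spanning_reads),
      frame = if (any(sub$frame == "in-frame")) "in-frame"
        else if (any(sub$frame == "out-of-frame")) "out-of-frame"
        else "unknown",
      status = "raw",
      evidence = list(sub)
    )
  })
  bind_rows(events) |> arrange(.data$sample_id, .data$gene5, .data$gene3)
}

#' A zero-row fusion event table
#'
#' @return A zero-row tibble with the event schema produced by [merge_calls()].
#' @export
empty_fusion_events <- function() {
  tibble(
    sample_id = character(), gene5 = character(), gene3 = character(),
    chrom5 = character(), pos5 = double(), strand5 = character(),
    chrom3 = character(), pos3 = double(), strand3 = character(),
    caller_count = integer(), callers = list(), n_calls = integer(),
    max_split = double(), max_spanning = double(),
    frame = character(), status = character(), evidence = list()
  )
}

#' Merge a multi-sample call table into fusion events
#'
#' Partitions the calls by sample and applies [merge_calls()] to each
#' partition, so merging never crosses sample boundaries.
#'
#' @inheritParams merge_calls
#' @param calls A standardized call tibble covering one or more samples.
#' @return An event tibble (see [merge_calls()]).
#' @export
harmonize_calls <- function(calls, aliases = NULL, bp_tolerance = 100,
                            collapse_reciprocal = FALSE) {
  calls <- new_fusion_calls(calls)
  if (nrow(calls) == 0) {
    return(empty_fusion_events())
  }
  split(calls, calls$sample_id) |>
    purrr::map(merge_calls, aliases = aliases, bp_tolerance = bp_tolerance,
      collapse_reciprocal = collapse_reciprocal) |>
    bind_rows() |>
    arrange(.data$sample_id, .data$gene5, .data$gene3)
}

#' Select the k-of-n caller consensus call set
#'
#' Keeps exactly the events reported by at least `k` of the five callers.
#' Because the predicate is a threshold on `caller_count`, the call sets nest:
#' the 5-of-5 set is contained in the 4-of-5 set, which is contained in the
#' 3-of-5 set.
#'
#' @param events An event tibble from [harmonize_calls()].
#' @param k Minimum number of agreeing callers, between 1 and 5.
#' @return The selected events, with `status` set to `"consensus"`.
#' @export
consensus_select <- function(events, k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k > 5 || k != floor(k)) {
    abort("k must be a single integer between 1 and 5")
  }
  events |>
    filter(.data$caller_count >= k) |>
    mutate(status = "consensus")
}
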