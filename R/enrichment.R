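# EASE-score over-representation of biological processes in the up- and
# down-regulated AD gene lists, cluster enrichment scores, retention
# filtering, and per-stage counts of aberrant genes per process.

#' EASE over-representation score
#'
#' One-sided hypergeometric upper-tail probability with the observed overlap
#' penalized by one (the EASE "conservative" convention): the reported
#' p-value is P(X >= overlap - 1) for X hypergeometric with `set_size`
#' successes in a universe of `background` genes and `list_size` draws.
#' Overlaps of 0 or 1 give p = 1.
#'
#' All arguments are vectorized.
#'
#' @param overlap genes shared by the query list and the annotation set.
#' @param list_size size of the query gene list (within the background).
#' @param set_size size of the annotation set (within the background).
#' @param background size of the gene universe.
#' @return EASE p-value(s) in \[0, 1\].
#' @export
ease_score <- function(overlap, list_size, set_size, background) {
  n <- max(length(overlap), length(list_size), length(set_size),
           length(background))
  overlap <- rep_len(overlap, n); list_size <- rep_len(list_size, n)
  set_size <- rep_len(set_size, n); background <- rep_len(background, n)
  bad <- overlap < 0 | overlap > pmin(list_size, set_size) |
    list_size > background | set_size > background
  if (any(bad))
    stop("inconsistent counts: need 0 <= overlap <= min(list_size, set_size)",
         " <= background", call. = FALSE)
  p <- rep(1, n)
  idx <- overlap >= 2
  p[idx] <- phyper(overlap[idx] - 2, set_size[idx],
                   background[idx] - set_size[idx], list_size[idx],
                   lower.tail = FALSE)
  pmin(p, 1)
}

#' Cluster Enrichment Score
#'
#' The enrichment score of a cluster of annotation terms: the arithmetic
#' mean of -log10(EASE p) over the member terms, i.e. -log10 of their
#' geometric mean.  A single-term "cluster" reduces to -log10 of its own
#' EASE p.
#'
#' @param member_ps EASE p-values of the cluster's terms, in (0, 1].
#' @return the enrichment score (>= 0).
#' @export
cluster_enrichment_score <- function(member_ps) {
  if (!length(member_ps)) stop("empty cluster", call. = FALSE)
  if (any(is.na(member_ps)) || any(member_ps < 0 | member_ps > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(member_ps == 0)) {
    warning("p-value of 0 clamped to smallest positive double")
    member_ps[member_ps == 0] <- .Machine$double.xmin
  }
  mean(-log10(member_ps))
}

#' Score over-representation of a gene list in annotation sets
#'
#' Computes, for each annotation set, the overlap with the query list and
#' its EASE p-value against the given background universe, plus the
#' degenerate one-term enrichment score -log10(ease_p).  Term clusters, when
#' available, can be rescored with [cluster_enrichment_score()].
#'
#' @param genes character vector of query genes (e.g. up-regulated AD
#'   genes).
#' @param sets a `gene_set_collection` (named list of gene vectors).
#' @param background character vector: the gene universe (e.g. all screened
#'   genes that carry annotations).
#' @return data frame: `name`, `overlap`, `set_size`, `list_size`,
#'   `background`, `ease_p`, `es`, and `members` (list column of
#'   overlapping genes).
#' @export
enrich_processes <- function(genes, sets, background) {
  background <- unique(trimws(background))
  genes <- intersect(unique(trimws(genes)), background)
  rows <- lapply(names(sets), function(nm) {
    members_bg <- intersect(unique(trimws(sets[[nm]])), background)
    ov <- intersect(genes, members_bg)
    data.frame(name = nm, overlap = length(ov),
               set_size = length(members_bg),
               list_size = length(genes),
               background = length(background),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ease_p <- ease_score(out$overlap, out$list_size, out$set_size,
                           out$background)
  out$es <- -log10(pmax(out$ease_p, .Machine$double.xmin))
  out$members <- lapply(names(sets), function(nm)
    intersect(genes, intersect(unique(trimws(sets[[nm]])), background)))
  out
}

#' Retain significantly over-represented processes
#'
#' Keeps processes with enrichment score strictly above `es_min`, EASE
#' p-value strictly below `ease_max`, and member-gene count strictly above
#' `min_genes` ("more than ten").
#'
#' @param candidates data frame with columns `es`, `ease_p`, and a gene
#'   count column `n_genes` (or `overlap`, used as fallback).
#' @param es_min enrichment-score threshold (default 2.0, strict).
#' @param ease_max EASE p threshold (default 0.05, strict).
#' @param min_genes gene-count threshold (default 10, strict).
#' @return the retained subset, in input order.
#' @export
filter_processes <- function(candidates, es_min = 2.0, ease_max = 0.05,
                             min_genes = 10) {
  ng <- candidates$n_genes %||% candidates$overlap
  if (is.null(ng))
    stop("candidates need an `n_genes` or `overlap` column", call. = FALSE)
  keep <- candidates$es > es_min & candidates$ease_p < ease_max &
    ng > min_genes
  candidates[keep, , drop = FALSE]
}

#' Count aberrantly expressed process genes per disease stage
#'
#' For each retained process, counts its member genes that are flagged as
#' AD-related at each stage (a gene flagged at several stages counts at each
#' of them), and appends per-stage totals over all retained processes.
#'
#' @param processes a named list of member-gene vectors (e.g. a
#'   `gene_set_collection` restricted to retained processes), or a data
#'   frame with `name` and list column `members`.
#' @param ad_table an `ad_gene_table` from [call_ad_genes()].
#' @param direction optional named character vector (process -> `"up"` /
#'   `"down"`) carried into the output.
#' @return a data frame of class `stage_count_table`: `process`, `early`,
#'   `medium`, `late` (plus `direction` when given), with per-stage totals
#'   in `attr(, "totals")`.
#' @export
count_stage_genes <- function(processes, ad_table, direction = NULL) {
  stopifnot(inherits(ad_table, "ad_gene_table"))
  if (is.data.frame(processes)) {
    members <- processes$members
    names(members) <- processes$name
    processes <- members
  }
  flagged_by_stage <- lapply(STAGE_LABELS, function(st)
    stage_flagged_genes(ad_table, st))
  names(flagged_by_stage) <- STAGE_LABELS
  counts <- t(vapply(names(processes), function(nm) {
    mem <- unique(processes[[nm]])
    cnt <- vapply(STAGE_LABELS, function(st)
      length(intersect(mem, flagged_by_stage[[st]])), integer(1))
    if (all(cnt == 0) &&
        !length(intersect(mem, unique(ad_table$records$gene_id))))
      warning("process '", nm, "' contains no screened gene", call. = FALSE)
    cnt
  }, integer(3)))
  out <- data.frame(process = names(processes), counts,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:4] <- STAGE_LABELS
  if (!is.null(direction)) out$direction <- direction[out$process]
  totals <- colSums(out[STAGE_LABELS])
  stopifnot(all(totals == colSums(out[STAGE_LABELS])))  # conservation
  attr(out, "totals") <- totals
  class(out) <- c("stage_count_table", class(out))
  out
}
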