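# Stage-wise correlation screening: detection filtering, log2 median
# normalization, per-stage Pearson correlation of each gene with MMSE or
# sqrt(NFT), Benjamini-Hochberg adjustment restricted to high-R2 records, and
# the AD-gene call table.

SCORE_TYPES <- c("MMSE", "sqrtNFT")

#' Filter genes by detection calls
#'
#' Keeps the genes whose expression was detected (call `P` or `M`) on at
#' least `min_detected` chips; absent (`A`) and missing calls do not count.
#' The sample set is unchanged.
#'
#' @param ds an [expression_dataset] with a detection-call matrix.
#' @param min_detected minimum number of present/marginal calls per gene.
#' @return the filtered [expression_dataset].
#' @export
filter_by_detection <- function(ds, min_detected = 16) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$calls))
    stop("dataset has no detection-call matrix; either supply calls or skip ",
         "the detection filter explicitly", call. = FALSE)
  if (min_detected > ncol(ds$values))
    stop("min_detected (", min_detected, ") exceeds the number of samples (",
         ncol(ds$values), ")", call. = FALSE)
  n_det <- rowSums(ds$calls == "P" | ds$calls == "M", na.rm = TRUE)
  keep <- n_det >= min_detected
  out <- expression_dataset(ds$values[keep, , drop = FALSE],
                            calls = ds$calls[keep, , drop = FALSE],
                            log2_scale = ds$log2_scale)
  attr(out, "normalized") <- attr(ds, "normalized")
  out
}

#' Log2 transform and per-gene median centering
#'
#' Linear-scale values are log2-transformed first (they must then be strictly
#' positive); each gene's median across samples is subtracted, so every
#' output row has median zero.  Pearson correlations are invariant under this
#' per-gene affine transformation; centering only fixes the scale on which
#' expression profiles are reported.
#'
#' @param ds an [expression_dataset].
#' @return the normalized [expression_dataset] (log2 scale, median-centered).
#' @export
normalize_log2_median <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  v <- ds$values
  if (!ds$log2_scale) {
    bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("non-positive linear-scale value for gene '",
           rownames(v)[bad[1, 1]], "', sample '", colnames(v)[bad[1, 2]],
           "'; cannot log2-transform", call. = FALSE)
    v <- log2(v)
  }
  med <- apply(v, 1, median, na.rm = TRUE)
  v <- v - med
  out <- expression_dataset(v, calls = ds$calls, log2_scale = TRUE)
  attr(out, "normalized") <- TRUE
  out
}

#' Square-root transform of NFT scores
#'
#' @param x numeric vector of non-negative NFT burden scores.
#' @return element-wise square roots.
#' @export
sqrt_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE))
    stop("NFT scores must be non-negative for the square-root transform",
         call. = FALSE)
  sqrt(x)
}

# fast per-row Pearson r of a genes x samples matrix against one score
# vector; returns r, per-gene n, and a zero-variance flag.  Missing
# expression values are dropped pairwise (score NAs are removed upstream).
row_pearson <- function(mat, score) {
  if (anyNA(mat)) {
    res <- t(vapply(seq_len(nrow(mat)), function(i) {
      xi <- mat[i, ]
      ok <- !is.na(xi)
      ni <- sum(ok)
      if (ni < 3) return(c(NA_real_, ni, 1))
      xs <- xi[ok] - mean(xi[ok])
      ys <- score[ok] - mean(score[ok])
      sx <- sum(xs^2); sy <- sum(ys^2)
      if (sx == 0 || sy == 0) return(c(NA_real_, ni, 1))
      c(sum(xs * ys) / sqrt(sx * sy), ni, 0)
    }, numeric(3)))
    list(r = res[, 1], n = res[, 2], undefined = res[, 3] == 1)
  } else {
    n <- length(score)
    xc <- mat - rowMeans(mat)
    yc <- score - mean(score)
    sx <- rowSums(xc^2)
    sy <- sum(yc^2)
    r <- as.vector(xc %*% yc) / sqrt(sx * sy)
    und <- sx == 0 | sy == 0
    r[und] <- NA_real_
    list(r = r, n = rep(n, nrow(mat)), undefined = und)
  }
}

#' Stage-wise Pearson correlation of expression with a clinical score
#'
#' For each gene and each disease stage, computes the Pearson correlation of
#' the gene's (median-normalized log2) expression with the MMSE score or the
#' square root of the NFT score over that stage's samples only, together with
#' the two-sided p-value from the t-transform with n - 2 degrees of freedom.
#' Genes with zero expression variance within a stage yield an
#' undefined-correlation record (`undefined = TRUE`, `r = NA`), which is
#' excluded from multiple testing downstream.
#'
#' @param ds an [expression_dataset] (normally after
#'   [normalize_log2_median()]).
#' @param samples sample metadata data frame (see [read_sample_metadata()]).
#' @param score `"MMSE"` or `"sqrtNFT"` (square root of the NFT score).
#' @param stages stage labels to screen; each must have at least 3 usable
#'   samples.
#' @return a data frame of correlation records: `gene_id`, `stage`,
#'   `score_type`, `n`, `r`, `r2`, `p`, `undefined`.
#' @export
stagewise_pearson <- function(ds, samples, score = c("MMSE", "sqrtNFT"),
                              stages = STAGE_LABELS) {
  stopifnot(inherits(ds, "expression_dataset"))
  score <- match.arg(score)
  samples <- validate_sample_metadata(samples)
  vals <- if (score == "MMSE") samples$mmse else sqrt_transform(samples$nft)
  names(vals) <- samples$sample_id
  out <- vector("list", length(stages))
  for (si in seq_along(stages)) {
    st <- stages[si]
    ids <- samples$sample_id[samples$group == st & !is.na(vals)]
    ids <- intersect(ids, colnames(ds$values))
    if (length(ids) < 3)
      stop("stage '", st, "' has fewer than 3 usable samples (",
           length(ids), ")", call. = FALSE)
    pr <- row_pearson(ds$values[, ids, drop = FALSE], vals[ids])
    r <- pr$r
    tt <- r * sqrt((pr$n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = pr$n - 2)
    p[!is.na(r) & abs(r) >= 1] <- 0
    out[[si]] <- data.frame(
      gene_id = rownames(ds$values), stage = st, score_type = score,
      n = pr$n, r = r, r2 = r^2, p = p, undefined = pr$undefined,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order, each >= its input, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1] and be non-missing", call. = FALSE)
  p.adjust(pvals, method = "BH")
}

#' Call AD-related genes from stage-wise correlation records
#'
#' Implements the two-step calling rule: Benjamini-Hochberg adjustment is
#' applied only to the records whose squared correlation exceeds `r2_min`
#' (strictly), and a record is flagged when additionally its adjusted p-value
#' is below `alpha`.  By default the BH family is each (stage, score-type)
#' cell of the prefiltered records; `family = "global"` adjusts all
#' prefiltered records together.
#'
#' Direction of regulation: because MMSE falls and NFT rises as disease
#' worsens, a flagged gene is called `down` when it correlates positively
#' with MMSE or negatively with sqrt(NFT), and `up` otherwise
#' (`direction_policy = "clinical"`).  `direction_policy = "sign"` reports
#' the raw correlation sign (`up` for r > 0) instead.
#'
#' @param records data frame from [stagewise_pearson()] (both score types may
#'   be row-bound together).
#' @param r2_min squared-correlation prefilter (strict; default 0.30).
#' @param alpha adjusted-p significance level (default 0.05).
#' @param family `"per_stage_score"` or `"global"` BH family.
#' @param direction_policy `"clinical"` or `"sign"`.
#' @return an object of class `ad_gene_table`: list with `records` (input
#'   plus `p_adj`, `flagged`, `direction`), `genes` (one row per flagged
#'   gene with its overall direction), `counts` (flag counts per stage and
#'   score type) and `n_genes`.
#' @export
call_ad_genes <- function(records, r2_min = 0.30, alpha = 0.05,
                          family = c("per_stage_score", "global"),
                          direction_policy = c("clinical", "sign")) {
  family <- match.arg(family)
  direction_policy <- match.arg(direction_policy)
  if (is.null(records) || nrow(records) == 0)
    stop("empty correlation record table", call. = FALSE)
  stopifnot(r2_min > 0, r2_min < 1, alpha > 0, alpha < 1)

  eligible <- !records$undefined & !is.na(records$r2) & records$r2 > r2_min
  p_adj <- rep(NA_real_, nrow(records))
  if (any(eligible)) {
    if (family == "global") {
      p_adj[eligible] <- bh_adjust(records$p[eligible])
    } else {
      grp <- interaction(records$stage, records$score_type, drop = TRUE)
      for (g in levels(grp)) {
        idx <- which(eligible & grp == g)
        if (length(idx)) p_adj[idx] <- bh_adjust(records$p[idx])
      }
    }
  }
  flagged <- eligible & !is.na(p_adj) & p_adj < alpha

  direction <- rep(NA_character_, nrow(records))
  pos <- records$r > 0
  if (direction_policy == "clinical") {
    down <- ifelse(records$score_type == "MMSE", pos, !pos)
  } else {
    down <- !pos
  }
  direction[flagged] <- ifelse(down[flagged], "down", "up")

  rec <- records
  rec$p_adj <- p_adj
  rec$flagged <- flagged
  rec$direction <- direction

  fl <- rec[rec$flagged, , drop = FALSE]
  genes <- data.frame(gene_id = character(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(fl)) {
    dir_by_gene <- tapply(fl$direction, fl$gene_id, function(d) {
      u <- unique(d)
      if (length(u) == 1) u else "mixed"
    })
    genes <- data.frame(gene_id = names(dir_by_gene),
                        direction = as.character(dir_by_gene),
                        stringsAsFactors = FALSE)
    rownames(genes) <- NULL
  }
  counts <- table(stage = factor(fl$stage, levels = unique(records$stage)),
                  score_type = factor(fl$score_type, levels = SCORE_TYPES))

  structure(
    list(records = rec, genes = genes, counts = counts,
         n_genes = nrow(genes), r2_min = r2_min, alpha = alpha),
    class = "ad_gene_table"
  )
}

#' @export
print.ad_gene_table <- function(x, ...) {
  cat("ad_gene_table:", x$n_genes, "AD-related genes",
      sprintf("(R2 > %.2g, BH-adjusted p < %.2g)\n", x$r2_min, x$alpha))
  print(x$counts)
  invisible(x)
}

#' Genes flagged at a given stage
#'
#' @param ad_table an `ad_gene_table`.
#' @param stage stage label.
#' @param direction optional `"up"` or `"down"` restriction.
#' @return character vector of gene ids flagged at that stage (either score).
#' @export
stage_flagged_genes <- function(ad_table, stage, direction = NULL) {
  stopifnot(inherits(ad_table, "ad_gene_table"))
  rec <- ad_table$records
  sel <- rec$flagged & rec$stage == stage
  if (!is.null(direction)) sel <- sel & rec$direction == direction
  unique(rec$gene_id[sel])
}

#' Run the full correlation screen
#'
#' Convenience wrapper: detection filter (optional), log2 median
#' normalization, stage-wise Pearson correlation against both scores, and
#' AD-gene calling.
#'
#' @param ds an [expression_dataset].
#' @param samples sample metadata data frame.
#' @param min_detected detection-filter threshold, or `NULL` to skip.
#' @param stages stage labels to screen.
#' @inheritParams call_ad_genes
#' @return an `ad_gene_table` (see [call_ad_genes()]).
#' @export
screen_ad_genes <- function(ds, samples, min_detected = 16,
                            stages = STAGE_LABELS,
                            r2_min = 0.30, alpha = 0.05,
                            family = c("per_stage_score", "global"),
                            direction_policy = c("clinical", "sign")) {
  if (!is.null(min_detected)) ds <- filter_by_detection(ds, min_detected)
  ds <- normalize_log2_median(ds)
  records <- rbind(
    stagewise_pearson(ds, samples, "MMSE", stages = stages),
    stagewise_pearson(ds, samples, "sqrtNFT", stages = stages)
  )
  call_ad_genes(records, r2_min = r2_min, alpha = alpha,
                family = match.arg(family),
                direction_policy = match.arg(direction_policy))
}
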