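#' Expression dataset container
#'
#' A light container for a genes x samples expression matrix with optional
#' per-cell detection calls (the `P`/`M`/`A` flags of expression microarrays).
#' Gene and sample identifiers live in the matrix dimnames.  Duplicate gene
#' identifiers are tolerated (probe-level data before collapsing); duplicate
#' sample identifiers are not.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param calls optional character matrix of the same dimensions with entries
#'   in `P` (present), `M` (marginal), `A` (absent), or `NA`.
#' @param log2_scale logical; `TRUE` if `values` are already log2, `FALSE`
#'   for linear-scale intensities.
#'
#' @return an object of class `expression_dataset`: a list with elements
#'   `values`, `calls`, `log2_scale`.
#' @export
expression_dataset <- function(values, calls = NULL, log2_scale = TRUE) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "),
         call. = FALSE)
  if (!is.null(calls)) {
    calls <- as.matrix(calls)
    if (!identical(dim(calls), dim(values)))
      stop("`calls` must have the same dimensions as `values`", call. = FALSE)
    bad <- !(calls %in% c("P", "M", "A") | is.na(calls))
    if (any(bad))
      stop("detection calls must be 'P', 'M' or 'A'; found: ",
           paste(unique(calls[bad]), collapse = ", "), call. = FALSE)
    dimnames(calls) <- dimnames(values)
  }
  structure(
    list(values = values, calls = calls, log2_scale = isTRUE(log2_scale)),
    class = "expression_dataset"
  )
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d genes x %d samples (%s scale%s%s)\n",
    nrow(x$values), ncol(x$values),
    if (x$log2_scale) "log2" else "linear",
    if (!is.null(x$calls)) ", with detection calls" else "",
    if (isTRUE(attr(x, "normalized"))) ", median-centered" else ""
  ))
  invisible(x)
}

#' Gene and sample identifiers of a dataset
#'
#' @param ds an [expression_dataset].
#' @return character vector of identifiers.
#' @export
gene_ids <- function(ds) rownames(ds$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(ds) colnames(ds$values)
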