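# Readers and writers for the plain-text formats the pipeline touches:
# tab-separated expression matrices (optionally in the GEO series-matrix
# dialect), sample metadata tables, two-column / SIF edge lists, GMT gene-set
# collections, and GraphML export of result graphs.

STAGE_LABELS <- c("early", "medium", "late")
GROUP_LABELS <- c("control", STAGE_LABELS)

strip_quotes <- function(x) gsub('^"|"$', "", x)

# extract the data lines of a possibly series-matrix-dialect file:
# "!"-prefixed lines are metadata; if begin/end table markers are present the
# table is the block strictly between them.
extract_table_lines <- function(lines) {
  begin <- grep("^!\\S*table_begin", lines)
  end <- grep("^!\\S*table_end", lines)
  if (length(begin) >= 1) {
    stop_line <- if (length(end) >= 1) end[1] - 1L else length(lines)
    lines <- lines[seq.int(begin[1] + 1L, stop_line)]
  } else {
    lines <- lines[!startsWith(lines, "!")]
  }
  lines[nzchar(lines)]
}

parse_matrix_lines <- function(lines, what, path) {
  if (length(lines) < 2)
    stop("no data rows found in ", what, " file '", path, "'", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- strip_quotes(fields[[1]])
  ncol_exp <- length(header)
  widths <- lengths(fields[-1])
  if (any(widths != ncol_exp)) {
    bad <- which(widths != ncol_exp)[1] + 1L
    stop("ragged row in ", what, " file '", path, "' at line ", bad,
         ": expected ", ncol_exp, " fields, found ", widths[bad - 1L],
         call. = FALSE)
  }
  body <- do.call(rbind, fields[-1])
  list(
    sample_ids = trimws(header[-1]),
    gene_ids = trimws(strip_quotes(body[, 1])),
    cells = body[, -1, drop = FALSE]
  )
}

#' Read a genes x samples expression table
#'
#' Reads a tab-separated expression matrix whose first column holds gene
#' identifiers and whose header row holds sample identifiers.  The
#' `series_matrix` dialect additionally skips `!`-prefixed metadata lines and,
#' when table begin/end marker lines are present, reads only the block between
#' them.  Blank cells become missing values.
#'
#' @param path path to the table.
#' @param dialect `"plain_tsv"` or `"series_matrix"`.
#' @param calls_path optional path to a detection-call table of identical
#'   shape (same dialect), cells in `P`/`M`/`A`.
#' @param log2_scale logical flag recorded on the returned dataset.
#' @return an [expression_dataset].
#' @export
read_expression_table <- function(path,
                                  dialect = c("plain_tsv", "series_matrix"),
                                  calls_path = NULL,
                                  log2_scale = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (dialect == "series_matrix") lines <- extract_table_lines(lines)
  lines <- lines[nzchar(lines)]
  tab <- parse_matrix_lines(lines, "expression", path)
  if (anyDuplicated(tab$sample_ids))
    stop("duplicate sample ids in header of '", path, "': ",
         paste(unique(tab$sample_ids[duplicated(tab$sample_ids)]),
               collapse = ", "),
         call. = FALSE)
  cells <- tab$cells
  cells[!nzchar(trimws(cells))] <- NA_character_
  values <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  dimnames(values) <- list(tab$gene_ids, tab$sample_ids)

  calls <- NULL
  if (!is.null(calls_path)) {
    clines <- readLines(calls_path)
    if (dialect == "series_matrix") clines <- extract_table_lines(clines)
    ctab <- parse_matrix_lines(clines[nzchar(clines)], "detection-call",
                               calls_path)
    if (!identical(ctab$sample_ids, tab$sample_ids) ||
        !identical(ctab$gene_ids, tab$gene_ids))
      stop("detection-call table does not match the expression table ",
           "(gene/sample identifiers differ)", call. = FALSE)
    calls <- ctab$cells
    calls[!nzchar(trimws(calls))] <- NA_character_
    calls <- trimws(calls)
  }
  expression_dataset(values, calls = calls, log2_scale = log2_scale)
}

#' Write an expression dataset as a tab-separated table
#'
#' Values are written at full double precision so that a write/read round
#' trip is exact.
#'
#' @param ds an [expression_dataset].
#' @param path output path for the value matrix.
#' @param calls_path optional output path for the detection-call matrix.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(ds, path, calls_path = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  fmt <- function(m) {
    ch <- matrix(formatC(m, format = "g", digits = 17), nrow = nrow(m))
    ch[is.na(m)] <- ""
    ch
  }
  write_mat <- function(cells, p) {
    header <- paste(c("gene_id", colnames(ds$values)), collapse = "\t")
    rows <- apply(cbind(rownames(ds$values), cells), 1, paste,
                  collapse = "\t")
    writeLines(c(header, rows), p)
  }
  write_mat(fmt(ds$values), path)
  if (!is.null(calls_path)) {
    if (is.null(ds$calls)) stop("dataset has no detection calls", call. = FALSE)
    cc <- ds$calls
    cc[is.na(cc)] <- ""
    write_mat(cc, calls_path)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a tab-separated file with columns `sample_id`, `group`, `mmse`,
#' `nft`.  Groups must be one of `control`, `early`, `medium`, `late`; MMSE
#' must lie in \[0, 30\] and NFT scores must be non-negative.
#'
#' @param path path to the TSV file.
#' @return a data frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "mmse", "nft")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("metadata file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$sample_id <- trimws(as.character(df$sample_id))
  df$group <- trimws(as.character(df$group))
  validate_sample_metadata(df)
}

validate_sample_metadata <- function(df) {
  bad_group <- setdiff(unique(df$group), GROUP_LABELS)
  if (length(bad_group))
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         "; accepted labels are: ", paste(GROUP_LABELS, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  mm <- df$mmse[!is.na(df$mmse)]
  if (any(mm < 0 | mm > 30))
    stop("MMSE scores must lie in [0, 30]", call. = FALSE)
  nf <- df$nft[!is.na(df$nft)]
  if (any(nf < 0))
    stop("NFT scores must be non-negative", call. = FALSE)
  df
}

#' Read an undirected edge list
#'
#' Supports a plain two-column tab/whitespace-separated format and the
#' Cytoscape SIF format (`nodeA relation nodeB [nodeC ...]`, which expands to
#' one edge per target).  Pairs are returned in file order, not deduplicated;
#' pruning happens in [build_giant_component()].
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"sif"`.
#' @return a data frame with character columns `from` and `to`.
#' @export
read_edge_list <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  toks <- strsplit(trimws(lines), "[\t ]+")
  from <- character(0); to <- character(0)
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (format == "tsv") {
      if (length(tk) < 2)
        stop("edge-list parse error at line ", line_no[i],
             ": fewer than 2 node identifiers", call. = FALSE)
      from <- c(from, tk[1]); to <- c(to, tk[2])
    } else {
      if (length(tk) < 3)
        stop("SIF parse error at line ", line_no[i],
             ": expected 'nodeA relation nodeB'", call. = FALSE)
      targets <- tk[-(1:2)]
      from <- c(from, rep(tk[1], length(targets)))
      to <- c(to, targets)
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#'
#' @param path path to the `.gmt` file.
#' @return a named list of character vectors (class `gene_set_collection`),
#'   with per-set descriptions in `attr(, "descriptions")`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set file: ", path, call. = FALSE)
  toks <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(toks, function(t) trimws(t[1]), character(1))
  if (anyDuplicated(names_))
    stop("duplicate gene-set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "),
         call. = FALSE)
  sets <- lapply(toks, function(t) {
    members <- trimws(t[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop("gene set '", trimws(t[1]), "' has no member genes", call. = FALSE)
    members
  })
  names(sets) <- names_
  descr <- vapply(toks, function(t) if (length(t) >= 2) t[2] else "",
                  character(1))
  names(descr) <- names_
  structure(sets, descriptions = descr, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param sets a named list of character vectors (or `gene_set_collection`).
#' @param path output path.
#' @param descriptions optional named character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a graph to GraphML
#'
#' Writes an igraph object (a pruned interaction network or a process link
#' graph) with whatever node and edge attributes it carries, so that degree,
#' betweenness, hub flags and edge types survive into generic network tools.
#'
#' @param graph an `igraph` object with at least one node.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  if (!igraph::is_igraph(graph))
    stop("`graph` must be an igraph object", call. = FALSE)
  if (igraph::vcount(graph) == 0)
    stop("refusing to export an empty graph", call. = FALSE)
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
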