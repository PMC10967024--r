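#' Read a count table from TSV
#'
#' Canonical orientation is taxa-as-rows (first column `taxon_id`, one
#' column per sample); `orientation = "samples"` accepts the transpose.
#' Every cell must be a non-negative integer.
#'
#' @param path TSV file path.
#' @param marker marker label attached to the table.
#' @param orientation `"taxa"` (rows are taxa, default) or `"samples"`.
#' @return a [count_table].
#' @export
read_counts <- function(path, marker, orientation = c("taxa", "samples")) {
  orientation <- match.arg(orientation)
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  raw <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("no samples (empty or unreadable file)",
                             call. = FALSE))
  abort_if(nrow(raw) == 0 || ncol(raw) < 2, "no samples")
  ids <- raw[[1]]
  num <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(vals <- matrix(as.numeric(num), nrow = nrow(num),
                                  dimnames = dimnames(num)))
  abort_if(any(is.na(vals)), "non-integer count (non-numeric cell)")
  abort_if(any(vals != round(vals)), "non-integer count")
  rownames(vals) <- ids
  m <- if (orientation == "taxa") t(vals) else vals
  count_table(m, marker)
}

#' Write a count table to TSV (taxa-as-rows canonical orientation)
#'
#' @param table a [count_table].
#' @param path output path.
#' @export
write_counts <- function(table, path) {
  m <- t(ct_counts(table))  # taxa x samples
  df <- data.frame(taxon_id = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  write_tsv_plain(df, path)
}

#' Read / write sample metadata
#'
#' TSV with `sample_id`, `location`, `treatment`, `timepoint` and numeric
#' measurement columns; missing measurements are the literal `NA`.
#'
#' @param path TSV path.
#' @return a [sample_frame].
#' @export
read_metadata <- function(path) {
  df <- read_tsv_plain(path)
  num_re <- "^[+-]?([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?|NaN|Inf)$"
  for (nm in setdiff(names(df), c("sample_id", "location", "treatment",
                                  "timepoint", "plot"))) {
    v <- df[[nm]]
    if (is.character(v) && all(grepl(num_re, v[!is.na(v)]))) {
      df[[nm]] <- as.numeric(v)
    }
  }
  sample_frame(df)
}

#' @rdname read_metadata
#' @param frame a [sample_frame].
#' @export
write_metadata <- function(frame, path) {
  write_tsv_plain(as.data.frame(frame), path)
}

#' Read / write a taxonomy table
#'
#' @param path TSV path with `taxon_id` plus rank columns.
#' @param marker marker label.
#' @return a [taxonomy_table].
#' @export
read_taxonomy <- function(path, marker) {
  df <- read_tsv_plain(path)
  taxonomy_table(df, marker)
}

#' @rdname read_taxonomy
#' @param tax a [taxonomy_table].
#' @export
write_taxonomy <- function(tax, path) {
  write_tsv_plain(as.data.frame(tax), path)
}

#' Aggregate ASV counts to genus level
#'
#' Counts of ASVs sharing a genus are summed; ASVs whose genus is
#' `"unassigned"` are pooled under the reserved label `g__unassigned`.
#' Per-sample totals are preserved exactly.
#'
#' @param table a [count_table] of ASV counts.
#' @param tax a [taxonomy_table] with a `genus` column covering every taxon
#'   in `table`.
#' @return a [count_table] with genera as taxa.
#' @export
aggregate_to_genus <- function(table, tax) {
  abort_if(!"genus" %in% names(tax), "taxonomy lacks a genus column")
  idx <- match(ct_taxa(table), tax$taxon_id)
  abort_if(any(is.na(idx)),
           paste("taxon missing from taxonomy:",
                 paste(utils::head(ct_taxa(table)[is.na(idx)], 3),
                       collapse = ", ")))
  genus <- tax$genus[idx]
  genus[genus == "unassigned"] <- "g__unassigned"
  m <- ct_counts(table)
  agg <- t(rowsum(t(m), group = genus))
  # rowsum sorts groups; keep first-appearance order for stability
  ord <- unique(genus)
  agg <- agg[, ord, drop = FALSE]
  count_table(agg, table$marker)
}

#' Write / read a signed weighted edge list
#'
#' Columns `node_a`, `node_b`, `sign` (`+`/`-`), `weight`, `p`, `q` in a
#' fixed order; numeric values survive a write/read round trip exactly.
#' Self-loops and duplicate undirected edges are rejected on read.
#'
#' @param edges data.frame with the six canonical columns (extra columns
#'   are preserved after them).
#' @param path TSV path.
#' @export
write_edges <- function(edges, path) {
  need <- c("node_a", "node_b", "sign", "weight", "p", "q")
  miss <- setdiff(need, names(edges))
  abort_if(length(miss) > 0,
           paste("edge list missing column(s):", paste(miss, collapse = ", ")))
  extra <- setdiff(names(edges), need)
  write_tsv_plain(edges[, c(need, extra), drop = FALSE], path)
}

#' @rdname write_edges
#' @return `read_edges` returns the validated edge data.frame.
#' @export
read_edges <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("node_a", "node_b", "sign", "weight", "p", "q")
  miss <- setdiff(need, names(df))
  abort_if(length(miss) > 0,
           paste("edge list missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(df)) {
    df$node_a <- as.character(df$node_a)
    df$node_b <- as.character(df$node_b)
    abort_if(any(df$node_a == df$node_b), "self-loop in edge list")
    key <- paste(pmin(df$node_a, df$node_b), pmax(df$node_a, df$node_b))
    abort_if(anyDuplicated(key) > 0, "duplicate undirected edge")
    abort_if(!all(df$sign %in% c("+", "-")), "edge sign must be '+' or '-'")
    for (nm in c("weight", "p", "q")) df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}

#' Export an edge list as GraphML
#'
#' @param edges edge data.frame as accepted by [write_edges()].
#' @param path output `.graphml` path.
#' @param nodes optional character vector of node names to include even if
#'   isolated.
#' @export
write_graphml <- function(edges, path, nodes = NULL) {
  g <- edges_to_igraph(edges, nodes = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# Internal: build an igraph graph from a canonical edge list.
edges_to_igraph <- function(edges, nodes = NULL, sign = NULL) {
  if (!is.null(sign) && nrow(edges)) {
    edges <- edges[edges$sign == sign, , drop = FALSE]
  }
  verts <- unique(c(nodes, edges$node_a, edges$node_b))
  if (length(verts) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b",
              setdiff(names(edges), c("node_a", "node_b"))), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = verts))
  g
}

#' Write / read a flat key=value truth record
#'
#' Serializes the planted-effect truth record of the synthetic generator
#' (named list of atomic vectors) as `key=value` lines; vector values are
#' comma-joined.
#'
#' @param record named list.
#' @param path output path.
#' @export
write_truth <- function(record, path) {
  abort_if(is.null(names(record)) || any(!nzchar(names(record))),
           "truth record entries must be named")
  lines <- vapply(names(record), function(k) {
    v <- record[[k]]
    val <- if (is.numeric(v)) paste(fmt_num(v), collapse = ",")
           else paste(as.character(v), collapse = ",")
    paste0(k, "=", val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth` returns the named list (values as character
#'   vectors; coerce as needed).
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, function(x) strsplit(x[2], ",", fixed = TRUE)[[1]])
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}
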