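#' Count table constructor
#'
#' A `count_table` holds a samples x taxa matrix of non-negative integer
#' marker-gene counts (ASVs or genera) together with the marker label
#' ("16S" or "ITS"). Sample and taxon identifiers are carried as dimnames
#' and must be unique.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   dimnames; all entries must be non-negative integers.
#' @param marker marker label, e.g. `"16S"` or `"ITS"`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, marker) {
  abort_if(!is.matrix(counts), "counts must be a matrix")
  abort_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "counts must have sample rownames and taxon colnames")
  abort_if(anyDuplicated(rownames(counts)) > 0, "duplicate sample id")
  abort_if(anyDuplicated(colnames(counts)) > 0, "duplicate taxon id")
  abort_if(nrow(counts) == 0, "no samples")
  abort_if(ncol(counts) == 0, "empty taxon set")
  abort_if(any(is.na(counts)), "missing count")
  abort_if(any(counts < 0), "negative count")
  abort_if(any(counts != round(counts)), "non-integer count")
  abort_if(!is.character(marker) || length(marker) != 1L,
           "marker must be a single string")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, marker = marker), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> marker=%s: %d samples x %d taxa, total reads %s\n",
              x$marker, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
ct_samples <- function(x) rownames(x$counts)

#' @rdname count_table
#' @export
ct_taxa <- function(x) colnames(x$counts)

#' @rdname count_table
#' @export
ct_counts <- function(x) x$counts

#' Sample metadata frame
#'
#' Validates a per-sample design/measurement table: mandatory `sample_id`,
#' `location`, `treatment` (control/treated) and `timepoint` (T0/T1)
#' columns, plus any number of numeric measurement columns (yield,
#' soil/petiole/peel nutrients, environmental covariates). Missing
#' measurements are allowed and encoded as `NA`.
#'
#' @param df a data.frame with at least the four design columns.
#' @return The validated data.frame with class `sample_frame` prepended.
#' @export
sample_frame <- function(df) {
  abort_if(!is.data.frame(df), "metadata must be a data.frame")
  need <- c("sample_id", "location", "treatment", "timepoint")
  miss <- setdiff(need, names(df))
  abort_if(length(miss) > 0,
           paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  abort_if(anyDuplicated(df$sample_id) > 0, "duplicate sample id")
  abort_if(anyDuplicated(names(df)) > 0, "duplicate measurement name")
  abort_if(any(is.na(df$location)) || any(is.na(df$treatment)) ||
             any(is.na(df$timepoint)), "design columns may not be missing")
  abort_if(!all(df$treatment %in% c("control", "treated")),
           "treatment must be 'control' or 'treated'")
  abort_if(!all(df$timepoint %in% c("T0", "T1")),
           "timepoint must be 'T0' or 'T1'")
  class(df) <- unique(c("sample_frame", class(df)))
  df
}

#' Taxonomy table
#'
#' Maps taxon identifiers to taxonomic ranks for one marker. Rank values
#' that could not be assigned are the literal string `"unassigned"`.
#'
#' @param df data.frame with a `taxon_id` column and one or more rank
#'   columns among kingdom, phylum, class, order, family, genus, species.
#' @param marker marker label.
#' @return data.frame with class `taxonomy_table` and a `marker` attribute.
#' @export
taxonomy_table <- function(df, marker) {
  abort_if(!is.data.frame(df), "taxonomy must be a data.frame")
  abort_if(!"taxon_id" %in% names(df), "taxonomy needs a taxon_id column")
  abort_if(anyDuplicated(df$taxon_id) > 0, "duplicate taxon id")
  ranks <- intersect(c("kingdom", "phylum", "class", "order", "family",
                       "genus", "species"), names(df))
  abort_if(length(ranks) == 0, "taxonomy needs at least one rank column")
  for (r in ranks) {
    v <- df[[r]]
    abort_if(any(is.na(v) | !nzchar(v)),
             sprintf("rank '%s' has empty values; use 'unassigned'", r))
  }
  attr(df, "marker") <- marker
  class(df) <- unique(c("taxonomy_table", class(df)))
  df
}
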