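#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# funnel through this so a seed argument fully determines their output.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stage label, keeping the
# result inside the 32-bit signed integer range R requires.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
}

# Dirichlet sampler (one draw) via normalized gammas; alpha entries of 0 map
# to exact structural zeros.
rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  x[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  s <- sum(x)
  if (s == 0) {
    # degenerate: fall back to uniform over positive-alpha support
    x[pos] <- 1
    s <- sum(x)
  }
  x / s
}

# Format numerics for TSV output losslessly ("." decimal, no scientific
# locale surprises); integers are printed without a decimal point.
fmt_num <- function(x) {
  out <- character(length(x))
  na <- is.na(x)
  out[na] <- "NA"
  ints <- !na & x == round(x) & abs(x) < 2^53
  out[ints] <- sprintf("%.0f", x[ints])
  rest <- !na & !ints
  out[rest] <- sprintf("%.17g", x[rest])
  out
}

write_tsv_plain <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else {
      out <- as.character(col)
      out[is.na(out)] <- "NA"
      out
    }
  })
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df)) do.call(paste, c(cols, sep = "\t")) else character(0)
  )
  writeLines(lines, path)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    colClasses = NA)
}
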