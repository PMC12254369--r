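# Internal helpers shared across modules.

# Classed error for malformed user input; the CLI maps this class to exit 2.
stop_input <- function(..., call. = FALSE) {
  msg <- paste0(...)
  stop(structure(
    class = c("cmaflux_input_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Run `expr` under set.seed(seed), restoring the caller's RNG state afterwards
# so library code never perturbs user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_input("'seed' must be a single finite number")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

read_tsv_checked <- function(path, what = "file", ...) {
  if (!is.character(path) || length(path) != 1L) {
    stop_input(what, " path must be a single string")
  }
  if (!file.exists(path)) stop_input(what, " not found: ", path)
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, ...)
}

write_tsv <- function(x, path, row_label = NULL) {
  if (!is.null(row_label)) {
    x <- data.frame(setNames(list(rownames(x)), row_label), x,
                    check.names = FALSE, stringsAsFactors = FALSE)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# First column of a TSV becomes rownames of a numeric matrix.
read_matrix_tsv <- function(path, what = "matrix") {
  df <- read_tsv_checked(path, what = what)
  if (ncol(df) < 2L) stop_input(what, " must have an id column plus >=1 sample column: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
  }
  rownames(m) <- ids
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
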