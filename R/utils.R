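# Internal helpers shared across modules.

# Condition classes map onto the CLI exit codes:
#   seedcoex_config_error -> 2, seedcoex_format_error -> 3,
#   seedcoex_empty_error  -> 4, seedcoex_domain_error -> 2.
abort_config <- function(msg, ...) abort(msg, class = "seedcoex_config_error", ...)
abort_format <- function(msg, ...) abort(msg, class = "seedcoex_format_error", ...)
abort_empty  <- function(msg, ...) abort(msg, class = "seedcoex_empty_error", ...)
abort_domain <- function(msg, ...) abort(msg, class = "seedcoex_domain_error", ...)

# An expression table is a tibble whose first column (`gene_id`) holds unique
# gene identifiers and whose remaining columns are numeric sample columns.
check_expression_tbl <- function(x, arg = "x") {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort_format(sprintf("`%s` must be a data frame with a gene id column and >= 1 sample column.", arg))
  }
  if (names(x)[1L] != "gene_id") {
    abort_format(sprintf("`%s` must have `gene_id` as its first column.", arg))
  }
  if (anyDuplicated(x$gene_id)) {
    dups <- unique(x$gene_id[duplicated(x$gene_id)])
    abort_format(sprintf("duplicate gene ids: %s", paste(head(dups, 5L), collapse = ", ")))
  }
  if (anyDuplicated(names(x)[-1L])) {
    abort_format(sprintf("`%s` has duplicate sample ids.", arg))
  }
  vals <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(vals)) abort_format(sprintf("`%s` has non-numeric sample columns.", arg))
  if (any(!is.finite(vals))) {
    abort_format(sprintf("`%s` contains missing or non-finite values; resolve them before use (see read_expression_matrix()).", arg))
  }
  invisible(x)
}

expr_to_matrix <- function(x) {
  m <- as.matrix(x[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

matrix_to_expr <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene_id = rownames(m)), out)
}

# Evaluate `expr` under a fixed RNG seed, leaving the caller's RNG state
# untouched.
with_rng_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    abort_config(sprintf("`%s` must be a single integer >= %d (got %s).", name, min, deparse(x)))
  }
  as.integer(x)
}

scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                          lower_open = FALSE, upper_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lower_open) x > lower else x >= lower) &&
    (if (upper_open) x < upper else x <= upper)
  if (!ok) {
    lo <- if (lower_open) "(" else "["
    hi <- if (upper_open) ")" else "]"
    abort_config(sprintf("`%s` must be a single number in %s%s, %s%s (got %s).",
                         name, lo, format(lower), format(upper), hi, deparse(x)))
  }
  as.numeric(x)
}
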