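#' @keywords internal
"_PACKAGE"

# Internal input-checking helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) stopf("`%s` = %g is outside its valid range", name, x)
  as.numeric(x)
}

check_expression_matrix <- function(expr, name = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr))
    stopf("`%s` must be a numeric matrix (genes x samples)", name)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stopf("`%s` must carry gene ids as rownames and sample ids as colnames", name)
  if (anyDuplicated(rownames(expr))) stopf("`%s` has duplicated gene ids", name)
  if (anyDuplicated(colnames(expr))) stopf("`%s` has duplicated sample ids", name)
  if (any(!is.finite(expr))) stopf("`%s` contains non-finite values", name)
  invisible(expr)
}

# Memoised combn index matrices (exact rank-test enumeration reuses the
# same split set many times).
.combn_cache <- new.env(parent = emptyenv())

combn_cached <- function(n, k) {
  key <- paste(n, k, sep = "_")
  if (is.null(.combn_cache[[key]]))
    .combn_cache[[key]] <- utils::combn(n, k)
  .combn_cache[[key]]
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded helpers do not perturb analyses.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
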