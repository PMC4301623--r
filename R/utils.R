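#' @keywords internal
#' @import stats
#' @importFrom utils head packageVersion write.table read.table
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stopf("`%s` must be a single number", name)
  if (x < min || x > max || (strict_min && x <= min))
    stopf("`%s` must be in %s%g, %g]", name, if (strict_min) "(" else "[", min, max)
  as.numeric(x)
}

#' Deterministic 31-bit string hash
#'
#' FNV-1a hash reduced to a non-negative 31-bit integer. Used to derive
#' independent, reproducible seed streams keyed by scenario labels rather
#' than by evaluation order, so that re-ordering a simulation grid does not
#' change any cell's random stream.
#'
#' @param key character scalar to hash.
#' @return a non-negative integer below 2^31.
#' @keywords internal
hash31 <- function(key) {
  bytes <- utf8ToInt(enc2utf8(as.character(key)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

# Derive a child seed below 2^31 from a base seed and a key.
derive_seed <- function(seed, key) {
  as.integer((as.double(seed) * 2654435761 + hash31(key)) %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix),
# for integrals of the form \int f(u) exp(-u^2) du.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  w <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = w[ord])
}

# log(sum(exp(x))) stable
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_plogis <- function(q) plogis(q, log.p = TRUE)
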