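# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= 0
}

# Symmetric positive-definiteness check via Cholesky; tol guards asymmetry.
is_pd <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) return(FALSE)
  ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
  ok
}

as_cov_matrix <- function(x, t, what = "covariance") {
  if (is.null(dim(x))) {
    if (length(x) == 1L && t == 1L) x <- matrix(x, 1L, 1L)
    else if (length(x) == t) x <- diag(x, t)
    else stopf("cannot interpret %s of length %d for %d trait(s)", what, length(x), t)
  }
  x <- as.matrix(x)
  if (!all(dim(x) == c(t, t))) stopf("%s must be %dx%d", what, t, t)
  if (!is_pd(x)) stopf("%s matrix is not symmetric positive definite", what)
  x
}

# Deterministic per-stage seed derivation from a master seed; keeps results
# below 2^31 - 1 so set.seed() accepts them.
derive_seed <- function(master, stage) {
  master <- as.integer(master)
  as.integer((as.double(master) * 48271 + 7919 * as.integer(stage)) %% 2147483647)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             na.strings = "NA", check.names = FALSE, comment.char = "")
}
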