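# Internal helpers: seeded evaluation, array slabs, softmax, parameter-tree ops.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state so exported functions taking a
# `seed` argument do not clobber the caller's RNG stream.
with_seed_ <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# n x k x d array -> the n x d matrix at group j (robust to n == 1 or d == 1)
slab <- function(A, j) {
  d <- dim(A)
  matrix(A[, j, ], nrow = d[1L], ncol = d[3L])
}

set_slab <- function(A, j, M) {
  A[, j, ] <- M
  A
}

softmax_rows <- function(L) {
  m <- apply(L, 1L, max)
  E <- exp(L - m)
  E / rowSums(E)
}

# Backward of row-wise softmax: given A = softmax(L) and dA, return dL.
softmax_rows_backward <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

one_hot <- function(y, C) {
  Y <- matrix(0, length(y), C)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

sign0 <- function(x) ifelse(x >= 0, 1, -1)

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# ---- parameter trees: nested lists with numeric leaves ----

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else {
    f(x, y)
  }
}

tree_zeros_like <- function(x) tree_map(function(v) v * 0, x)

tree_sum <- function(x) sum(vapply(
  rapply(x, function(v) sum(v), how = "unlist"),
  identity, numeric(1)
))

# Cheap content fingerprint used for the phase-2 freeze assertion.
params_checksum <- function(x) {
  v <- unlist(x, use.names = FALSE)
  c(n = length(v), sum = sum(v), sumsq = sum(v^2))
}

abort_ <- function(..., class = "fuseomics_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
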