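# Small numeric helpers shared across the network modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(x) {
  x <- as.matrix(x)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Row-wise maxima of a matrix (no apply() overhead in hot paths).
row_max <- function(x) {
  do.call(pmax, as.data.frame(x))
}

# Uniform fan-in initialisation, the convention used for every weight
# array in the network: U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
init_weights <- function(dims, fan_in) {
  b <- 1 / sqrt(max(fan_in, 1))
  array(stats::runif(prod(dims), -b, b), dim = dims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dynspec <- function(...) stop(..., call. = FALSE)

is_odd <- function(k) k %% 2L == 1L

# Recursively apply f elementwise over two parallel nested lists of arrays.
map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) map2_params(a[[i]], b[[i]], f))
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

map_params <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, map_params, f = f)
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

# Flatten a nested parameter list into a single named numeric vector
# (used by the parameter-count report and the gradient checker).
flatten_params <- function(p, prefix = "") {
  if (is.list(p)) {
    nms <- names(p) %||% as.character(seq_along(p))
    nms[nms == ""] <- as.character(which(nms == ""))
    parts <- lapply(seq_along(p), function(i) {
      flatten_params(p[[i]], paste0(prefix, nms[i], "."))
    })
    unlist(parts)
  } else {
    v <- as.numeric(p)
    names(v) <- paste0(prefix, seq_along(v))
    v
  }
}

n_params <- function(p) length(flatten_params(p))
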