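# internal helpers

check_pos_int <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      x < 1 || x != floor(x))
    stop("'", name, "' must be a single positive integer")
  as.integer(x)
}

vec_recycle <- function(a, b) {
  n <- max(length(a), length(b))
  if (n %% length(a) != 0L || n %% length(b) != 0L)
    stop("incompatible lengths")
  list(rep_len(a, n), rep_len(b, n))
}

# discrete inner product on the unit-spaced index grid
inner_prod <- function(f, g) sum(f * g)

# |cosine| similarity between two vectors, NA-safe
cosine_sim <- function(f, g) {
  nf <- sqrt(sum(f^2)); ng <- sqrt(sum(g^2))
  if (nf == 0 || ng == 0) return(NA_real_)
  sum(f * g) / (nf * ng)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_posix <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC")
}
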