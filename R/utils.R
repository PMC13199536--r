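#' @useDynLib vertebraFE, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats lm coef rnorm runif sd shapiro.test t.test var.test integrate
#' @importFrom utils write.csv head modifyList
#' @importFrom graphics hist
#' @importFrom methods as
NULL

# Deterministic seed splitting: every stochastic stage draws from a sub-seed
# derived from the master seed and a small label vector, so any single
# artefact (one mask, one scan) is regenerable in isolation.
split_seed <- function(seed, ...) {
  labels <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in labels) {
    s <- (s * 69069 + 1234567 + 97 * as.double(k)) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Voxel-centre world coordinates along one axis: centre of voxel i is
# (i - 0.5) * spacing + origin.
axis_coords <- function(n, spacing, origin = 0) {
  origin + (seq_len(n) - 0.5) * spacing
}

# Expand mask/image grid coordinates as three vectors (memory-light meshgrid).
grid_coords <- function(dim, spacing, origin = c(0, 0, 0)) {
  list(
    x = axis_coords(dim[1], spacing, origin[1]),
    y = axis_coords(dim[2], spacing, origin[2]),
    z = axis_coords(dim[3], spacing, origin[3])
  )
}

mask_digest <- function(mask) {
  # cheap content hash for memoising FE solves on identical masks
  v <- which(mask)
  paste(length(v), sum(as.double(v)), sum(as.double(v)^2) %% 1e15, sep = "-")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
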