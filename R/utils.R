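# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so simulator calls are pure in (inputs, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

vnorm <- function(x) sqrt(sum(x^2))

row_norms <- function(m) sqrt(rowSums(m^2))

cross3 <- function(u, v) {
  # u, v: n x 3 matrices (or length-3 vectors)
  if (is.null(dim(u))) u <- matrix(u, ncol = 3L)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

as_point_matrix <- function(x, arg = "points") {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop(sprintf("'%s' must be a 3-vector or an n x 3 matrix", arg))
    x <- matrix(x, ncol = 3L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("'%s' must have 3 columns (x, y, z in mm)", arg))
  if (!all(is.finite(x))) stop(sprintf("'%s' contains non-finite coordinates", arg))
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

stop_stage <- function(stage, msg, class = "scalafit_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf("[%s] %s", stage, msg), call = sys.call(-1))))
}
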