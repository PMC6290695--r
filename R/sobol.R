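#' Sobol' low-discrepancy sequence
#'
#' Generates the first `n_points` points of the Sobol' sequence in
#' `n_dims` dimensions using standard (Joe-Kuo) direction numbers and
#' Gray-code ordering. The initial all-zeros point is skipped, so the
#' first 1-D points are 0.5, 0.75, 0.25, ...
#'
#' @param n_dims number of dimensions (1 to 10).
#' @param n_points number of points.
#' @return a `n_points` x `n_dims` matrix with entries in [0, 1).
#' @export
#' @examples
#' sobol_sequence(1, 3)  # 0.5 0.75 0.25
sobol_sequence <- function(n_dims, n_points) {
  stopifnot(n_dims >= 1, n_points >= 1)
  sobol_points_cpp(as.integer(n_points), as.integer(n_dims))
}

#' Uncertain-parameter space with uniform marginals
#'
#' @param names character vector of parameter names.
#' @param min,max numeric vectors of lower and upper bounds.
#' @return an object of class `isr_space`.
#' @export
#' @examples
#' parameter_space(c("flow_velocity", "deployment_depth", "regen_time"),
#'                 min = c(0.432, 0.09, 15), max = c(0.528, 0.13, 23))
parameter_space <- function(names, min, max) {
  stopifnot(length(names) == length(min), length(min) == length(max))
  if (any(min >= max)) stop("every parameter needs min < max")
  structure(list(names = as.character(names), min = as.numeric(min),
                 max = as.numeric(max), n = length(names)),
            class = "isr_space")
}

#' Default uncertain inputs of the restenosis model
#'
#' Flow velocity 0.432-0.528 m/s, stent deployment depth 0.09-0.13 mm,
#' endothelium regeneration time 15-23 days, each uniform.
#' @return an `isr_space` with the three model inputs.
#' @export
default_parameter_space <- function() {
  parameter_space(c("flow_velocity", "deployment_depth", "regen_time"),
                  min = c(0.432, 0.09, 15),
                  max = c(0.528, 0.13, 23))
}

#' Map unit-cube points to parameter bounds
#'
#' @param u matrix (or vector) of points in [0,1)^n.
#' @param space an `isr_space`.
#' @return matrix of scaled input vectors, columns named by parameter.
#' @export
scale_to_bounds <- function(u, space) {
  stopifnot(inherits(space, "isr_space"))
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  if (ncol(u) != space$n)
    stop("dimension mismatch: ", ncol(u), " columns for ", space$n,
         " parameters")
  x <- sweep(u, 2, space$max - space$min, `*`)
  x <- sweep(x, 2, space$min, `+`)
  colnames(x) <- space$names
  x
}

# Deterministic seed below 2^31 from (seed_root, block, i, j); polynomial
# string hash modulo a prime (exact in doubles: h*31 + ch < 2^36 < 2^53).
derive_seed <- function(seed_root, block, i, j) {
  s <- paste(seed_root, block, i, j, sep = "/")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h) + 1L
}

#' Build the Saltelli evaluation design
#'
#' Draws M Sobol' points in the 2n-dimensional unit cube and splits the
#' columns: the first n columns form block A, the last n the
#' complementary block B (the standard dimension-doubling construction —
#' with a quasi-random sequence, consecutive row blocks are strongly
#' correlated and must not be used as A and B). The blocks expand into
#' the M(2n+2) runs needed for the aleatory-variance, first-order and
#' total sensitivity estimators:
#' \itemize{
#'  \item `A`: inputs A, base seeds;
#'  \item `A_RESEED`: inputs A, fresh seeds (aleatory-variance pairs);
#'  \item `FO_i`: inputs B with column i copied from A (first-order pairs);
#'  \item `TO_i`: inputs A with column i from B, fresh seeds (total-effect
#'    pairs, which therefore also resample the stochastic seed).
#' }
#' Every run receives a distinct seed derived deterministically from
#' `seed_root` by a stable hash of (block, i, j).
#'
#' @param space an `isr_space`.
#' @param M base sample size; the design has M(2n+2) runs.
#' @param seed_root integer root for per-run seed derivation.
#' @return an `isr_design`: data frame `runs` (run_id, block, i, j, one
#'   column per input, seed) plus `space`, `M`, `n`.
#' @export
#' @examples
#' d <- build_design(default_parameter_space(), M = 120, seed_root = 42)
#' nrow(d$runs)  # 960
build_design <- function(space, M, seed_root) {
  stopifnot(inherits(space, "isr_space"), M >= 1)
  n <- space$n
  u <- sobol_sequence(2 * n, M)
  xa <- scale_to_bounds(u[, seq_len(n), drop = FALSE], space)
  xb <- scale_to_bounds(u[, n + seq_len(n), drop = FALSE], space)
  blocks <- list(list(block = "A", x = xa, i = 0L))
  blocks <- c(blocks, list(list(block = "A_RESEED", x = xa, i = 0L)))
  for (i in seq_len(n)) {
    xf <- xb; xf[, i] <- xa[, i]
    blocks <- c(blocks, list(list(block = paste0("FO_", i), x = xf, i = i)))
  }
  for (i in seq_len(n)) {
    xt <- xa; xt[, i] <- xb[, i]
    blocks <- c(blocks, list(list(block = paste0("TO_", i), x = xt, i = i)))
  }
  rows <- do.call(rbind, lapply(blocks, function(b) {
    df <- as.data.frame(b$x)
    df$block <- b$block
    df$i <- b$i
    df$j <- seq_len(M)
    df
  }))
  rows$seed <- mapply(derive_seed, seed_root, rows$block, rows$i, rows$j)
  # hash collisions are ~2e-4 likely at 960 runs; bump until all distinct
  while (anyDuplicated(rows$seed)) {
    d <- duplicated(rows$seed)
    rows$seed[d] <- (rows$seed[d] %% 2147483629L) + 1L
  }
  rows$run_id <- sprintf("run_%04d", seq_len(nrow(rows)))
  runs <- rows[, c("run_id", "block", "i", "j", space$names, "seed")]
  structure(list(runs = runs, space = space, M = as.integer(M),
                 n = as.integer(n), seed_root = as.integer(seed_root)),
            class = "isr_design")
}

#' @export
print.isr_design <- function(x, ...) {
  cat("Saltelli design: M =", x$M, ", n =", x$n,
      "inputs ->", nrow(x$runs), "runs\n")
  cat("inputs:", paste(x$space$names, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a function over a Saltelli design
#'
#' Runs `f(x, seed)` for every design row, where `x` is the named input
#' vector. Used for analytic validation models and by the campaign layer.
#'
#' @param design an `isr_design`.
#' @param f function of (x, seed) returning a numeric scalar or vector
#'   (vectors must share length across runs).
#' @return matrix of outputs, one row per design run.
#' @export
evaluate_design <- function(design, f) {
  stopifnot(inherits(design, "isr_design"))
  X <- as.matrix(design$runs[, design$space$names, drop = FALSE])
  seeds <- design$runs$seed
  out <- lapply(seq_len(nrow(X)), function(k) as.numeric(f(X[k, ], seeds[k])))
  len <- unique(vapply(out, length, 1L))
  if (length(len) != 1) stop("f returned outputs of differing lengths")
  matrix(unlist(out), nrow = nrow(X), byrow = TRUE)
}

# Split a per-run output vector/matrix into aligned estimator blocks.
# Returns list(A, A_RESEED, FO = list per input, TO = list per input),
# each an M x n_outputs matrix ordered by j.
split_blocks <- function(design, y) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  runs <- design$runs
  pick <- function(block) {
    idx <- which(runs$block == block)
    idx <- idx[order(runs$j[idx])]
    y[idx, , drop = FALSE]
  }
  list(A = pick("A"), A_RESEED = pick("A_RESEED"),
       FO = lapply(seq_len(design$n), function(i) pick(paste0("FO_", i))),
       TO = lapply(seq_len(design$n), function(i) pick(paste0("TO_", i))))
}
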