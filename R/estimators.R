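#' Sample moments and coefficient of variation
#'
#' Mean, unbiased variance, standard deviation and the coefficient of
#' variation CV = sd/|mean| * 100%.
#'
#' @param samples numeric vector (>= 2 values).
#' @return list(mean, variance, sd, cv); `cv` is `NA` (flagged via the
#'   `cv_defined` field) when the mean is zero.
#' @export
#' @examples
#' estimate_moments(c(1, 2, 3))  # mean 2, variance 1, cv 50
estimate_moments <- function(samples) {
  stopifnot(length(samples) >= 2)
  m <- mean(samples)
  v <- var(samples)
  cv_defined <- m != 0
  list(mean = m, variance = v, sd = sqrt(v),
       cv = if (cv_defined) sqrt(v) / abs(m) * 100 else NA_real_,
       cv_defined = cv_defined)
}

#' Aleatory (stochastic) variance and its standard-deviation bound
#'
#' Estimates the variance that would remain if all uncertain inputs were
#' known exactly, from paired runs sharing inputs but not seeds:
#' VarT_xi = 1/(2M) * sum_j (fA_j - fA'_j)^2. Jensen's inequality bounds
#' the mean conditional standard deviation by sqrt(VarT_xi).
#'
#' @param fA outputs of the base block.
#' @param fA_reseed outputs with identical inputs, fresh seeds.
#' @return list(variance, sd_bound).
#' @export
aleatory_variance <- function(fA, fA_reseed) {
  if (length(fA) != length(fA_reseed))
    stop("block length mismatch: ", length(fA), " vs ", length(fA_reseed))
  v <- mean((fA - fA_reseed)^2) / 2
  list(variance = v, sd_bound = sqrt(v))
}

#' First-order Sobol index of one input
#'
#' Saltelli estimator Var_xi = 1/M * sum_j (fA_j - f0)(fFO_j - f0) with
#' f0 the base-block mean, normalised by the base-block sample variance
#' and expressed in percent. Negative estimates are reported as-is.
#'
#' @param fA base-block outputs.
#' @param fFO_i outputs of the block sharing only column i with the base.
#' @return list(partial_variance, index, defined); `defined` is FALSE when
#'   the total variance is zero.
#' @export
first_order_index <- function(fA, fFO_i) {
  if (length(fA) != length(fFO_i))
    stop("block length mismatch: ", length(fA), " vs ", length(fFO_i))
  f0 <- mean(fA)
  pv <- mean((fA - f0) * (fFO_i - f0))
  tv <- var(fA)
  defined <- is.finite(tv) && tv > 0
  list(partial_variance = pv,
       index = if (defined) pv / tv * 100 else NA_real_,
       defined = defined)
}

#' Total sensitivity index of one input (including seed interactions)
#'
#' VarT = 1/(2M) * sum_j (fA_j - fTO_j)^2 where the TO block differs from
#' the base block in input i and in the stochastic seed, so the total
#' index includes all combined effects of x_i with other inputs and with
#' the model's internal stochasticity.
#'
#' @param fA base-block outputs.
#' @param fTO_i outputs of the block differing from the base in column i
#'   (and seed).
#' @return list(partial_variance, index, defined).
#' @export
total_index <- function(fA, fTO_i) {
  if (length(fA) != length(fTO_i))
    stop("block length mismatch: ", length(fA), " vs ", length(fTO_i))
  pv <- mean((fA - fTO_i)^2) / 2
  tv <- var(fA)
  defined <- is.finite(tv) && tv > 0
  list(partial_variance = pv,
       index = if (defined) pv / tv * 100 else NA_real_,
       defined = defined)
}

#' Bootstrap mean and error bar of a design-based estimator
#'
#' Resamples design rows j = 1..M with replacement, keeping every block's
#' row j together so that the pairing required by the aleatory and Sobol
#' estimators is preserved, recomputes the estimator K times, and returns
#' the bootstrap mean and standard deviation.
#'
#' @param samples_by_block named list of equal-length numeric vectors
#'   (one per design block), aligned by row index j.
#' @param estimator function taking a resampled list of the same shape and
#'   returning a numeric scalar.
#' @param K number of bootstrap replicates (the study default is 10000).
#' @return list(mean, sd, K).
#' @export
#' @examples
#' blocks <- list(A = rnorm(100))
#' bootstrap_estimate(blocks, function(b) mean(b$A), K = 200)
bootstrap_estimate <- function(samples_by_block, estimator, K = 10000) {
  stopifnot(K >= 2, length(samples_by_block) >= 1)
  M <- unique(vapply(samples_by_block, length, 1L))
  if (length(M) != 1) stop("blocks must share length M")
  vals <- vapply(seq_len(K), function(k) {
    idx <- sample.int(M, M, replace = TRUE)
    estimator(lapply(samples_by_block, function(b) b[idx]))
  }, numeric(1))
  list(mean = mean(vals), sd = sd(vals), K = K)
}

# Vectorised bootstrap used by the campaign analysis: draws one K x M index
# matrix and evaluates all standard estimators on it via row means.
# Returns per-estimator c(mean, sd). `blocks` is the split_blocks() output
# restricted to a single scalar output (column vectors).
bootstrap_report <- function(blocks, K, n_inputs) {
  a <- as.numeric(blocks$A)
  r <- as.numeric(blocks$A_RESEED)
  M <- length(a)
  idx <- matrix(sample.int(M, K * M, replace = TRUE), K, M)
  A <- matrix(a[idx], K, M)
  Rr <- matrix(r[idx], K, M)
  mA <- rowMeans(A)
  vA <- (rowMeans(A^2) - mA^2) * M / (M - 1)
  stat <- function(v) c(mean = mean(v), sd = sd(v))
  out <- list(
    mean = stat(mA),
    variance = stat(vA),
    sd = stat(sqrt(pmax(vA, 0))),
    cv = stat(ifelse(mA != 0, sqrt(pmax(vA, 0)) / abs(mA) * 100, NA_real_)),
    aleatory_variance = stat(rowMeans((A - Rr)^2) / 2)
  )
  fo <- to <- vector("list", n_inputs)
  for (i in seq_len(n_inputs)) {
    Fi <- matrix(as.numeric(blocks$FO[[i]])[idx], K, M)
    Ti <- matrix(as.numeric(blocks$TO[[i]])[idx], K, M)
    pv_fo <- rowMeans(A * Fi) - mA * rowMeans(Fi)
    pv_to <- rowMeans((A - Ti)^2) / 2
    fo[[i]] <- stat(ifelse(vA > 0, pv_fo / vA * 100, NA_real_))
    to[[i]] <- stat(ifelse(vA > 0, pv_to / vA * 100, NA_real_))
  }
  out$first_order <- fo
  out$total <- to
  out
}
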