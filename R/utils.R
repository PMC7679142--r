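#' @keywords internal
"_PACKAGE"

# Canonical region labels used throughout
REGIONS <- c("aIC", "pIC", "CE_SST", "CE_PKCd", "CEm")
STAGES <- c("habituation", "C_early", "C_late", "FC", "recall")

#' Derive a stage seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed from a single master
#' seed through this counter scheme, so any stage can be re-run in isolation
#' and still reproduce the full-pipeline result.
#'
#' @param master master seed (integer).
#' @param k stage counter (small non-negative integer).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(master, k) {
  as.integer((abs(as.numeric(master)) %% 1e6) * 1000 + (k %% 1000))
}

# z-score columns of a matrix using supplied (or own) means/sds.
# Zero-variance columns map to all zeros, never NaN.
zscore_cols <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- Inf
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

# Largest-remainder allocation of n_total into parts proportional to pool
# sizes. Returns integer vector summing to n_total, each entry <= pool.
largest_remainder <- function(pool, n_total) {
  pool <- as.numeric(pool)
  if (sum(pool) < n_total) stop("pool smaller than requested total")
  quota <- n_total * pool / sum(pool)
  alloc <- floor(quota)
  rem <- quota - alloc
  short <- n_total - sum(alloc)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    take <- ord[seq_len(short)]
    alloc[take] <- alloc[take] + 1
  }
  # respect pool caps (can only matter with tiny pools)
  over <- which(alloc > pool)
  while (length(over) > 0) {
    excess <- sum(alloc[over] - pool[over])
    alloc[over] <- pool[over]
    room <- which(alloc < pool)
    ord <- room[order(quota[room] - alloc[room], decreasing = TRUE)]
    for (i in ord) {
      if (excess == 0) break
      alloc[i] <- alloc[i] + 1
      excess <- excess - 1
    }
    over <- which(alloc > pool)
  }
  as.integer(alloc)
}

# Stratified fold assignment: within each class, cycle fold ids over a
# random permutation of the class members.
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

# Sample from a von Mises distribution (Best & Fisher rejection scheme).
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  atan2(sin(out), cos(out))
}

# Hann taper of length n
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}
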