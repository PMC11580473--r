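#' Lilliefors (Kolmogorov-Smirnov) normality test with Monte-Carlo p-value
#'
#' Computes the Lilliefors statistic `D = sup |F_n(x) - Phi((x - mean)/sd)|`
#' with mean and standard deviation estimated from the sample, and obtains
#' its p-value from a seeded Monte-Carlo reference distribution of `D`
#' under normality at the same sample size (the distribution is not the
#' plain Kolmogorov-Smirnov one because the parameters are estimated).
#'
#' @param x Numeric vector, `n >= 4`, non-constant.
#' @param mc_reps Number of Monte-Carlo null replicates.
#' @param seed Seed for the Monte-Carlo draw (`NULL` = current RNG stream).
#' @param null_d Optional precomputed null statistics from
#'   [lilliefors_null()] at the same `n`; overrides `mc_reps`/`seed`.
#' @return List with `statistic` (D), `p.value`, `n` and `mc_reps`.
#' @export
#' @examples
#' lilliefors_test(rexp(50), mc_reps = 500, seed = 1)
lilliefors_test <- function(x, mc_reps = 10000L, seed = NULL,
                            null_d = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("x must not contain NA")
  n <- length(x)
  if (n < 4L) stop("need n >= 4")
  if (stats::sd(x) == 0) stop("x is constant; Lilliefors D is undefined")
  D <- .lilliefors_stat(x)
  if (is.null(null_d)) {
    null_d <- lilliefors_null(n, mc_reps, seed)
  }
  p <- (1 + sum(null_d >= D)) / (length(null_d) + 1)
  list(statistic = D, p.value = p, n = n, mc_reps = length(null_d))
}

.lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Monte-Carlo null distribution of the Lilliefors statistic
#'
#' @param n Sample size.
#' @param reps Number of replicates.
#' @param seed RNG seed (`NULL` = current stream).
#' @return Numeric vector of `reps` null D statistics.
#' @export
lilliefors_null <- function(n, reps = 10000L, seed = NULL) {
  n <- as.integer(n); reps <- as.integer(reps)
  if (is.na(n) || n < 4L) stop("need n >= 4")
  if (is.na(reps) || reps < 1L) stop("reps must be >= 1")
  .with_seed(seed, {
    vapply(seq_len(reps),
           function(i) .lilliefors_stat(stats::rnorm(n)), numeric(1))
  })
}

# Within-block ranks (ties averaged) for an n x k matrix.
.block_ranks <- function(m) {
  t(apply(m, 1L, rank))
}

#' Friedman rank-sum test
#'
#' Nonparametric test for differences among `k` treatments observed on `n`
#' blocks (here: distance bins observed on species). The statistic is
#' `chi^2_F = [12 / (n k (k+1))] * sum_j R_j^2 - 3 n (k+1)`, where `R_j`
#' is the rank sum of treatment `j` from within-block ranks with average
#' ties, divided by the tie-correction factor
#' `1 - sum(t^3 - t) / (n k (k^2 - 1))`; df = `k - 1` and the p-value is
#' the upper chi-squared tail.
#'
#' @param m Complete numeric matrix, `n >= 2` blocks (rows) by `k >= 2`
#'   treatments (columns).
#' @return List with `statistic`, `df` and `p.value`.
#' @export
#' @examples
#' friedman_test(rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
friedman_test <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("matrix must be complete (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 blocks and 2 treatments")
  r <- .block_ranks(m)
  Rj <- colSums(r)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  tie_sum <- sum(apply(m, 1L, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  corr <- 1 - tie_sum / (n * k * (k^2 - 1))
  if (corr <= 0) {
    # every block fully tied: no information, statistic defined as 0
    stat <- 0
  } else {
    stat <- stat / corr
  }
  df <- k - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Nemenyi all-pairs comparisons after a Friedman test
#'
#' For treatments `i, j` with mean ranks `Rbar`, computes
#' `q_obs = |Rbar_i - Rbar_j| / sqrt(k (k+1) / (12 n))` and refers it to
#' the studentized range distribution with infinite degrees of freedom:
#' `p = P(Q_{k,Inf} >= q_obs)`.
#'
#' @inheritParams friedman_test
#' @return Symmetric `k x k` matrix of pairwise p-values with unit
#'   diagonal; dimnames from the input columns.
#' @export
nemenyi_allpairs <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("matrix must be complete (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 blocks and 2 treatments")
  rbar <- colMeans(.block_ranks(m))
  se <- sqrt(k * (k + 1) / (12 * n))
  q <- abs(outer(rbar, rbar, "-")) / se
  p <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
  diag(p) <- 1
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("bin", seq_len(k))
  dimnames(p) <- list(cn, cn)
  p
}
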