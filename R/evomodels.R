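#' Brownian-motion covariance structure of a tree
#'
#' Returns the `n x n` matrix `C` with `C[i, j]` the root-to-MRCA depth of
#' tips `i` and `j` (shared path length) and `C[i, i]` the depth of tip
#' `i`. Under Brownian motion trait covariances are `sigma^2 * C`.
#'
#' @param tree An ape `phylo` tree with non-negative branch lengths.
#' @return Symmetric positive semidefinite matrix with tip-label dimnames.
#' @export
#' @examples
#' bm_covariance(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
bm_covariance <- function(tree) {
  .check_tree(tree)
  .mrca_depth_matrix(tree)
}

#' Trait covariance under an evolutionary model
#'
#' Builds the (unit-rate) covariance matrix `V` for one of four trait
#' evolution models; likelihood code scales it by `sigma^2`.
#'
#' * `BM`: `V = C`, the Brownian-motion structure.
#' * `lambda` (Pagel): off-diagonals scaled, `V[i,j] = lambda * C[i,j]`,
#'   diagonal unchanged; `lambda` in `[0, 1]`.
#' * `OU` (fixed root, attraction `alpha > 0`, ultrametric tree):
#'   `V[i,j] = exp(-alpha (t_i + t_j - 2 t_a)) (1 - exp(-2 alpha t_a)) /
#'   (2 alpha)` with `t_a` the MRCA depth.
#' * `EB` (early burst, rate decaying as `exp(r t)`, `r <= 0`):
#'   `V[i,j] = (exp(r t_a) - 1) / r`, converging to `t_a` as `r -> 0`.
#'
#' @param tree An ape `phylo` tree.
#' @param model One of `"BM"`, `"OU"`, `"EB"`, `"lambda"`.
#' @param shape_param `lambda`, `alpha` or `r` as appropriate; ignored for
#'   BM.
#' @return Covariance matrix with tip-label dimnames.
#' @export
model_covariance <- function(tree, model = c("BM", "OU", "EB", "lambda"),
                             shape_param = NULL) {
  model <- match.arg(model)
  .check_tree(tree)
  depths <- .node_depths(tree)
  C <- .mrca_depth_matrix(tree, depths)
  .model_covariance_from_C(C, depths[seq_along(tree$tip.label)], model,
                           shape_param,
                           ultrametric = is_ultrametric_tree(tree))
}

# Core transform working from precomputed pieces (used in fitting loops).
.model_covariance_from_C <- function(C, tip_depths, model, shape_param,
                                     ultrametric = TRUE) {
  switch(model,
    BM = C,
    lambda = {
      lam <- shape_param
      if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
          lam < 0 || lam > 1)
        stop("lambda must lie in [0, 1]")
      V <- lam * C
      diag(V) <- diag(C)
      V
    },
    OU = {
      alpha <- shape_param
      if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
          alpha <= 0)
        stop("alpha must be > 0")
      if (!ultrametric)
        stop("the OU covariance requires an ultrametric tree")
      ti <- tip_depths
      # -expm1(-2 a t) / (2 a) is (1 - e^{-2 a t}) / (2 a), stable as a -> 0
      exp(-alpha * (outer(ti, ti, "+") - 2 * C)) *
        (-expm1(-2 * alpha * C)) / (2 * alpha)
    },
    EB = {
      r <- shape_param
      if (!is.numeric(r) || length(r) != 1L || is.na(r) || r > 0)
        stop("r must be <= 0")
      if (!ultrametric)
        stop("the EB covariance requires an ultrametric tree")
      if (r == 0) C else expm1(r * C) / r
    }
  )
}

# Profiled Gaussian likelihood on a fixed covariance structure V:
# mu and sigma2 have closed-form ML estimates. Returns NULL if V is not
# positive definite.
.profile_mvn <- function(V, x) {
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) return(NULL)
  n <- length(x)
  logdet <- 2 * sum(log(diag(U)))
  ones <- rep(1, n)
  w1 <- backsolve(U, ones, transpose = TRUE)
  wx <- backsolve(U, x, transpose = TRUE)
  mu <- sum(w1 * wx) / sum(w1 * w1)
  r <- wx - mu * w1
  Q <- sum(r * r)
  sigma2 <- Q / n
  logLik <- if (sigma2 <= 0) Inf else
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  list(mu = mu, sigma2 = sigma2, logLik = logLik, logdet = logdet, Q = Q)
}

# Maximize f over [lo, hi] with optimize() restarted on n_starts equal
# subintervals (optionally on log scale). Returns list(par, value).
.multistart_optimize <- function(f, lo, hi, n_starts = 5L,
                                 log_scale = FALSE, tol = 1e-9) {
  tf <- if (log_scale) function(u) f(exp(u)) else f
  a <- if (log_scale) log(lo) else lo
  b <- if (log_scale) log(hi) else hi
  cuts <- seq(a, b, length.out = n_starts + 1L)
  best <- list(par = a, value = tf(a))
  ends <- c(a, b)
  for (u in ends) {
    v <- tf(u)
    if (v > best$value) best <- list(par = u, value = v)
  }
  for (i in seq_len(n_starts)) {
    o <- stats::optimize(tf, c(cuts[i], cuts[i + 1L]), maximum = TRUE,
                         tol = tol)
    if (o$objective > best$value)
      best <- list(par = o$maximum, value = o$objective)
  }
  if (log_scale) best$par <- exp(best$par)
  best
}

# Shape-parameter search bounds, following common comparative-methods
# practice; T is tree height.
.shape_bounds <- function(model, height) {
  switch(model,
    lambda = c(0, 1),
    OU = c(1e-8 / height, 50 / height),
    EB = c(log(1e-5) / height, 0)
  )
}
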