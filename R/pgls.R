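#' Phylogenetic generalized least squares regression
#'
#' Fits `y = X beta + e` with residual covariance `sigma^2 V(theta)` given
#' by a trait-evolution model on the tree (BM, OU with attraction `alpha`,
#' or Pagel's `lambda`). For a candidate shape parameter `theta`,
#' `beta(theta) = (X' V^-1 X)^-1 X' V^-1 y` and the profile (ML)
#' log-likelihood is maximized over `theta` by bounded multi-start search.
#' Standard errors use the unbiased error variance
#' `RSS_gls / (n - p - 1)` (`p` = predictors excluding the intercept) with
#' t-tests on `n - p - 1` df, while `logLik`/AICc use the ML divisor `n`.
#' `R^2 = 1 - RSS_gls(full) / RSS_gls(intercept-only at the same theta)`,
#' and `adj R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)` (it may be negative).
#' With `model = "auto"` the BM, OU and lambda fits are compared by AICc
#' (ties toward fewer parameters) before reporting.
#'
#' The reported `correlation_call` applies the decision rule
#' `p_slope < 0.05 AND adj R^2 > 0.1` (see [correlation_call()]), where the
#' slope is the first non-intercept coefficient.
#'
#' @param tree An ape `phylo` tree.
#' @param y Named response vector (names = tip labels).
#' @param X Design matrix including an intercept column; rownames = tip
#'   labels (or rows in tip order).
#' @param model `"auto"` (AICc selection), `"BM"`, `"OU"` or `"lambda"`.
#' @param n_starts Multi-start subintervals for the shape search.
#' @param shape Optional fixed shape parameter; skips the profile search
#'   and evaluates the GLS fit at this value (not available with
#'   `model = "auto"`).
#' @return Object of class `pgls_fit`: coefficient table (estimate, se, t,
#'   p), `sigma2_ml`, `sigma2_e`, `shape_param`, `logLik`, `AICc`,
#'   `r_squared`, `adj_r_squared`, `model`, `correlation_call`, `n`, `p`.
#' @export
pgls_fit <- function(tree, y, X, model = c("auto", "BM", "OU", "lambda"),
                     n_starts = 5L, shape = NULL) {
  model <- match.arg(model)
  .check_tree(tree)
  y <- .align_trait(tree, y)
  n <- length(y)
  X <- .align_design(tree, X, n)
  p <- ncol(X) - 1L
  if (qr(X)$rank < ncol(X)) stop("design matrix X is rank deficient")
  if (n <= p + 2L) stop("need n > p + 2 observations")
  if (!any(apply(X, 2L, function(col) all(col == col[[1L]]))))
    stop("X must include an intercept column")
  if (model == "auto" && !is.null(shape))
    stop("a fixed shape requires a specific model")
  if (model == "auto") {
    fits <- lapply(c("BM", "OU", "lambda"), function(mm)
      tryCatch(pgls_fit(tree, y, X, mm, n_starts), error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0L) stop("no PGLS model could be fitted")
    aicc <- vapply(fits, function(f) f$AICc, numeric(1))
    k <- vapply(fits, function(f) f$k_params, numeric(1))
    cand <- which(aicc - min(aicc) < 1e-6)
    return(fits[[cand[which.min(k[cand])]]])
  }

  ultra <- is_ultrametric_tree(tree)
  if (model == "OU" && !ultra)
    stop("the OU model requires an ultrametric tree")
  depths <- .node_depths(tree)
  C <- .mrca_depth_matrix(tree, depths)
  td <- depths[seq_len(n)]
  height <- max(td)

  gls_at <- function(theta) {
    V <- .model_covariance_from_C(C, td, model, theta, ultrametric = ultra)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    ty <- backsolve(U, y, transpose = TRUE)
    tX <- backsolve(U, X, transpose = TRUE)
    qx <- qr(tX)
    beta <- qr.coef(qx, ty)
    res <- ty - tX %*% beta
    rss <- sum(res^2)
    logdet <- 2 * sum(log(diag(U)))
    ll <- -0.5 * (n * log(2 * pi) + n * log(rss / n) + logdet + n)
    list(beta = beta, rss = rss, logLik = ll, tX = tX, ty = ty, U = U)
  }

  if (model == "BM") {
    theta <- NA_real_
    g <- gls_at(NA_real_)
    if (is.null(g)) stop("singular BM covariance")
  } else if (!is.null(shape)) {
    theta <- shape
    g <- gls_at(theta)
    if (is.null(g)) stop("singular covariance at the fixed shape parameter")
  } else {
    b <- .shape_bounds(model, height)
    opt <- .multistart_optimize(function(th) {
      g <- gls_at(th)
      if (is.null(g)) -Inf else g$logLik
    }, b[1L], b[2L], n_starts = as.integer(n_starts),
       log_scale = model == "OU")
    theta <- opt$par
    g <- gls_at(theta)
    if (is.null(g)) stop("singular covariance at fitted shape parameter")
  }

  df_resid <- n - p - 1L
  sigma2_e <- g$rss / df_resid
  xtx_inv <- chol2inv(qr.R(qr(g$tX)))
  se <- sqrt(sigma2_e * diag(xtx_inv))
  beta <- drop(g$beta)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = df_resid)
  # intercept-only RSS at the same theta for R^2
  ic <- which(apply(X, 2L, function(col) all(col == col[[1L]])))[[1L]]
  t1 <- g$U; t0X <- backsolve(t1, X[, ic, drop = FALSE], transpose = TRUE)
  ty <- g$ty
  q0 <- qr(t0X)
  rss0 <- sum((ty - t0X %*% qr.coef(q0, ty))^2)
  r2 <- 1 - g$rss / rss0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  k_params <- ncol(X) + 1L + (model != "BM")
  aicc <- if (n - k_params - 1L > 0L)
    -2 * g$logLik + 2 * k_params +
      2 * k_params * (k_params + 1) / (n - k_params - 1)
  else Inf
  slope_idx <- setdiff(seq_len(ncol(X)), ic)[1L]
  call_val <- if (is.na(slope_idx)) NA else
    correlation_call(pval[[slope_idx]], adj_r2)
  coef_tab <- data.frame(
    term = colnames(X), estimate = beta, std_error = se, t_value = tval,
    p_value = pval, stringsAsFactors = FALSE
  )
  rownames(coef_tab) <- NULL
  structure(list(
    model = model, coefficients = coef_tab, sigma2_ml = g$rss / n,
    sigma2_e = sigma2_e, shape_param = theta, logLik = g$logLik,
    k_params = k_params, AICc = aicc, r_squared = r2,
    adj_r_squared = adj_r2, correlation_call = call_val,
    slope_index = slope_idx, n = n, p = p
  ), class = "pgls_fit")
}

.align_design <- function(tree, X, n) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X)) X <- matrix(X, ncol = 1L, dimnames = list(names(X), "x"))
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  if (nrow(X) != n) stop("X must have one row per tip")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.null(rownames(X))) {
    if (!setequal(rownames(X), tree$tip.label))
      stop("X rownames do not match tree tip labels")
    X <- X[tree$tip.label, , drop = FALSE]
  }
  if (anyNA(X)) stop("X must not contain NA")
  X
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (%s model), n = %d, predictors = %d\n",
              x$model, x$n, x$p))
  if (!is.na(x$shape_param))
    cat(sprintf("  shape parameter = %.6g\n", x$shape_param))
  print(x$coefficients, digits = 5)
  cat(sprintf("  R2 = %.5f, adj R2 = %.5f, logLik = %.4f, AICc = %.4f\n",
              x$r_squared, x$adj_r_squared, x$logLik, x$AICc))
  cat(sprintf("  correlated (p < 0.05 & adj R2 > 0.1): %s\n",
              x$correlation_call))
  if (!is.null(x$bootstrap)) {
    q <- x$bootstrap$quantiles
    cat(sprintf("  bootstrap slope (B = %d): 2.5%% %.5g, 50%% %.5g, 97.5%% %.5g\n",
                x$bootstrap$B, q[[1L]], q[[2L]], q[[3L]]))
  }
  invisible(x)
}

#' Parametric bootstrap of the PGLS slope
#'
#' Simulates `B` response vectors from the fitted model (`X beta_hat` plus
#' multivariate-normal noise with covariance `sigma2_ml * V(theta_hat)`),
#' refits the same PGLS model to each, and summarizes the slope estimates.
#'
#' @param fit A [pgls_fit()] result.
#' @param tree,y,X The data used for `fit`.
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed RNG seed (`NULL` = current stream).
#' @param n_starts Multi-start subintervals for the shape search in each
#'   refit; the default is coarser than in [pgls_fit()] because bootstrap
#'   replicates only feed quantile summaries.
#' @return List with `estimates` (length `B`), `quantiles`
#'   (2.5/50/97.5 percent), `B` and `seed`.
#' @export
pgls_bootstrap <- function(fit, tree, y, X, B = 1000L, seed = NULL,
                           n_starts = 2L) {
  if (!inherits(fit, "pgls_fit")) stop("fit must be a pgls_fit object")
  B <- as.integer(B)
  if (is.na(B) || B < 2L) stop("B must be >= 2")
  .check_tree(tree)
  y <- .align_trait(tree, y)
  n <- length(y)
  X <- .align_design(tree, X, n)
  ultra <- is_ultrametric_tree(tree)
  depths <- .node_depths(tree)
  C <- .mrca_depth_matrix(tree, depths)
  td <- depths[seq_len(n)]
  V <- .model_covariance_from_C(C, td, fit$model, fit$shape_param,
                                ultrametric = ultra)
  U <- chol(fit$sigma2_ml * V)
  mu <- drop(X %*% fit$coefficients$estimate)
  est <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ystar <- mu + drop(crossprod(U, stats::rnorm(n)))
      names(ystar) <- names(y)
      f <- pgls_fit(tree, ystar, X, fit$model, n_starts = n_starts)
      f$coefficients$estimate[[f$slope_index]]
    }, numeric(1))
  })
  list(estimates = est,
       quantiles = stats::quantile(est, c(0.025, 0.5, 0.975)),
       B = B, seed = seed)
}

#' The density-trait correlation decision rule
#'
#' Two traits are called correlated when the slope p-value is below 0.05
#' and the adjusted R-squared exceeds 0.1.
#'
#' @param p_slope Slope p-value (finite).
#' @param adj_r2 Adjusted R-squared (finite; may be negative).
#' @return Logical scalar.
#' @export
#' @examples
#' correlation_call(0.01, 0.20)  # TRUE
#' correlation_call(0.01, 0.05)  # FALSE
correlation_call <- function(p_slope, adj_r2) {
  if (!is.numeric(p_slope) || !is.numeric(adj_r2) ||
      length(p_slope) != 1L || length(adj_r2) != 1L ||
      !is.finite(p_slope) || !is.finite(adj_r2))
    stop("p_slope and adj_r2 must be finite numbers")
  p_slope < 0.05 && adj_r2 > 0.1
}

#' Mass-adjust a duration trait
#'
#' Returns the residuals of an ordinary least squares regression of
#' `log10(duration)` on `log10(mass)`, a standard allometric adjustment.
#' Precomputed adjusted traits can be supplied to downstream analyses
#' directly, bypassing this helper.
#'
#' @param duration,mass Strictly positive numeric vectors over the same
#'   species (aligned; equal names if named).
#' @return Numeric vector of residuals (named like the input).
#' @export
adjust_trait <- function(duration, mass) {
  if (length(duration) != length(mass))
    stop("duration and mass must be aligned (equal length)")
  if (!is.null(names(duration)) && !is.null(names(mass)) &&
      !identical(names(duration), names(mass)))
    stop("duration and mass names disagree")
  if (any(!is.finite(duration)) || any(!is.finite(mass)) ||
      any(duration <= 0) || any(mass <= 0))
    stop("duration and mass must be strictly positive")
  ld <- log10(duration)
  lm_ <- stats::lm(ld ~ log10(mass))
  r <- stats::residuals(lm_)
  names(r) <- names(duration)
  r
}
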