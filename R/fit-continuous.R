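#' Fit a continuous-trait evolution model by maximum likelihood
#'
#' Maximizes the multivariate-normal log-likelihood
#' `lnL = -0.5 [n ln 2pi + ln det(sigma^2 V) + (x - mu 1)' (sigma^2 V)^-1
#' (x - mu 1)]` over root state `mu`, rate `sigma^2` and (for OU, EB and
#' lambda) one shape parameter. `mu` and `sigma^2` are profiled
#' analytically; the shape parameter is found by bounded scalar search with
#' multi-start (5 grid intervals; log scale for `alpha`). Search bounds:
#' `lambda` in `[0, 1]`, `alpha` in `(1e-8/T, 50/T]`, `r` in
#' `[ln(1e-5)/T, 0]`, with `T` the tree height. AICc uses
#' `k = 2` parameters for BM and `k = 3` otherwise.
#'
#' @param tree An ape `phylo` tree (ultrametric for OU/EB).
#' @param x Named numeric trait vector; names must match the tip labels.
#' @param model One of `"BM"`, `"OU"`, `"EB"`, `"lambda"`.
#' @param n_starts Number of multi-start subintervals for the shape search.
#' @return Object of class `evo_model_fit`: list with `model`, `sigma2`,
#'   `root_state`, `shape_param` (`NA` for BM), `logLik`, `k_params`,
#'   `AICc`, `n` and the (tip-ordered) `data`. A constant trait yields the
#'   degenerate boundary fit `sigma2 = 0`, `logLik = Inf` with a warning
#'   and `degenerate = TRUE`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
#' fit_continuous(tr, c(A = 1, B = 1.4, C = 3, D = 2.6), "BM")
fit_continuous <- function(tree, x, model = c("BM", "OU", "EB", "lambda"),
                           n_starts = 5L) {
  model <- match.arg(model)
  .check_tree(tree)
  x <- .align_trait(tree, x)
  n <- length(x)
  k <- if (model == "BM") 2L else 3L
  if (n < 2L) stop("need at least 2 tips")
  if (k == 3L && n < 4L) stop("need at least 4 tips for 3-parameter models")
  ultra <- is_ultrametric_tree(tree)
  if (model %in% c("OU", "EB") && !ultra)
    stop("the ", model, " model requires an ultrametric tree")
  depths <- .node_depths(tree)
  C <- .mrca_depth_matrix(tree, depths)
  td <- depths[seq_len(n)]
  height <- max(td)

  if (stats::var(x) < .Machine$double.eps * max(1, mean(x)^2)) {
    warning("trait is (numerically) constant: sigma2 = 0 boundary fit; ",
            "logLik and AICc are not finite")
    return(structure(list(
      model = model, sigma2 = 0, root_state = mean(x),
      shape_param = NA_real_, logLik = Inf, k_params = k, AICc = -Inf,
      n = n, data = x, degenerate = TRUE
    ), class = "evo_model_fit"))
  }

  obj <- function(theta) {
    V <- .model_covariance_from_C(C, td, model, theta, ultrametric = ultra)
    pr <- .profile_mvn(V, x)
    if (is.null(pr)) return(-Inf)
    pr$logLik
  }

  if (model == "BM") {
    theta <- NA_real_
    pr <- .profile_mvn(C, x)
    if (is.null(pr)) stop("singular BM covariance (zero-length tree?)")
  } else {
    b <- .shape_bounds(model, height)
    opt <- .multistart_optimize(obj, b[1L], b[2L],
                                n_starts = as.integer(n_starts),
                                log_scale = model == "OU")
    theta <- opt$par
    V <- .model_covariance_from_C(C, td, model, theta, ultrametric = ultra)
    pr <- .profile_mvn(V, x)
    if (is.null(pr)) stop("singular covariance at fitted shape parameter")
  }

  degenerate <- !is.finite(pr$logLik)
  if (degenerate)
    warning("trait is (numerically) constant: sigma2 = 0 boundary fit; ",
            "logLik and AICc are not finite")
  aicc <- if (n - k - 1L > 0L)
    -2 * pr$logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  else Inf
  structure(list(
    model = model, sigma2 = pr$sigma2, root_state = pr$mu,
    shape_param = theta, logLik = pr$logLik, k_params = k,
    AICc = if (degenerate) -Inf else aicc, n = n, data = x,
    degenerate = degenerate
  ), class = "evo_model_fit")
}

.align_trait <- function(tree, x) {
  if (!is.numeric(x)) stop("trait must be numeric")
  if (is.null(names(x))) {
    if (length(x) != length(tree$tip.label))
      stop("unnamed trait vector must have one value per tip")
    names(x) <- tree$tip.label
    return(x)
  }
  if (!setequal(names(x), tree$tip.label))
    stop("trait names do not match tree tip labels")
  if (anyNA(x)) stop("trait must not contain NA")
  x[tree$tip.label]
}

#' @export
print.evo_model_fit <- function(x, ...) {
  cat(sprintf("Trait-evolution fit: %s model, n = %d tips\n", x$model, x$n))
  cat(sprintf("  sigma2 = %.6g, root state = %.6g\n", x$sigma2,
              x$root_state))
  if (!is.na(x$shape_param))
    cat(sprintf("  shape parameter = %.6g\n", x$shape_param))
  cat(sprintf("  logLik = %.4f, k = %d, AICc = %.4f\n", x$logLik,
              x$k_params, x$AICc))
  invisible(x)
}

#' Select the best trait-evolution model by AICc
#'
#' Returns the fit with the smallest AICc; ties (difference below `1e-6`)
#' are broken toward the model with fewer parameters.
#'
#' @param fits List of [fit_continuous()] results on identical data.
#' @return The selected `evo_model_fit`.
#' @export
select_model <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L)
    stop("need at least 2 fits to select among")
  if (!all(vapply(fits, inherits, logical(1), "evo_model_fit")))
    stop("fits must be evo_model_fit objects")
  d0 <- fits[[1L]]$data
  same <- vapply(fits, function(f) {
    identical(names(f$data), names(d0)) &&
      isTRUE(all.equal(unname(f$data), unname(d0), tolerance = 1e-12))
  }, logical(1))
  if (!all(same)) stop("fits were computed on mismatched data")
  aicc <- vapply(fits, function(f) f$AICc, numeric(1))
  k <- vapply(fits, function(f) f$k_params, numeric(1))
  best <- min(aicc)
  cand <- which(aicc - best < 1e-6)
  fits[[cand[which.min(k[cand])]]]
}
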