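test_that("BM covariance equals MRCA depths (hand cases and ape oracle)", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(bm_covariance(t2),
               matrix(c(1, 0, 0, 1), 2, dimnames = list(c("A", "B"),
                                                        c("A", "B"))))
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- bm_covariance(t3)
  expect_equal(unname(diag(C)), c(2, 2, 2))
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  set.seed(81)
  for (i in 1:25) {
    tr <- rand_test_tree(sample(4:40, 1), ultrametric = i %% 2 == 0)
    C <- bm_covariance(tr)
    ref <- ape::vcv.phylo(tr)
    expect_equal(C, ref[rownames(C), colnames(C)], tolerance = 1e-12)
  }
  bad <- t3; bad$edge.length[2] <- -0.1
  expect_error(bm_covariance(bad), "negative")
})

test_that("model covariances transform C as documented", {
  tr <- sim_yule_tree(25, 1, seed = 82)
  C <- bm_covariance(tr)
  expect_equal(model_covariance(tr, "lambda", 1), C)
  V0 <- model_covariance(tr, "lambda", 0)
  expect_equal(V0, diag(diag(C)), ignore_attr = TRUE)
  expect_equal(diag(V0), diag(C))
  # OU flattens towards independence as alpha grows
  Vou <- model_covariance(tr, "OU", 50 / max(C))
  expect_lt(max(Vou[upper.tri(Vou)] / diag(Vou)[1]),
            max(C[upper.tri(C)] / diag(C)[1]))
  expect_error(model_covariance(tr, "lambda", 1.2), "lambda")
  expect_error(model_covariance(tr, "OU", -1), "alpha")
  expect_error(model_covariance(tr, "EB", 0.5), "r must be")
  nu <- ape::rtree(10)
  expect_error(model_covariance(nu, "OU", 1), "ultrametric")
})

test_that("OU and EB covariances converge to BM in the small-rate limit", {
  tr <- sim_yule_tree(20, 1, seed = 83)
  C <- bm_covariance(tr)
  expect_lt(max(abs(model_covariance(tr, "OU", 1e-8) - C)), 1e-5)
  expect_equal(model_covariance(tr, "EB", 0), C)
  expect_lt(max(abs(model_covariance(tr, "EB", -1e-9) - C)), 1e-5)
})

test_that("2-tip BM fit matches its closed form", {
  t2 <- ape::read.tree(text = "(A:1.5,B:1.5);")
  x <- c(A = 1, B = 4)
  f <- fit_continuous(t2, x, "BM")
  mu <- mean(x)
  expect_equal(f$root_state, mu, tolerance = 1e-10)
  expect_equal(f$sigma2, sum((x - mu)^2) / (2 * 1.5), tolerance = 1e-10)
})

test_that("fitted likelihoods satisfy AICc and dense-MVN consistency", {
  tr <- sim_yule_tree(30, 1, seed = 84)
  x <- sim_trait(tr, "lambda", sigma2 = 2, mu = 3, shape = 0.6, seed = 85)
  for (m in c("BM", "OU", "EB", "lambda")) {
    f <- fit_continuous(tr, x, m)
    k <- f$k_params
    expect_equal(f$AICc,
                 -2 * f$logLik + 2 * k + 2 * k * (k + 1) / (f$n - k - 1),
                 tolerance = 1e-10)
    V <- model_covariance(tr, m, f$shape_param)
    ll <- mvn_loglik_oracle(x[tr$tip.label], rep(f$root_state, f$n),
                            f$sigma2 * V)
    expect_equal(f$logLik, ll, tolerance = 1e-6)
  }
  # lambda nests BM at lambda = 1
  fb <- fit_continuous(tr, x, "BM")
  fl <- fit_continuous(tr, x, "lambda")
  expect_gte(fl$logLik, fb$logLik - 1e-6)
  # constant traits give the documented degenerate boundary fit
  expect_warning(fc <- fit_continuous(tr, stats::setNames(
    rep(2, 30), tr$tip.label), "BM"), "constant")
  expect_true(fc$degenerate)
  expect_equal(fc$sigma2, 0)
})

test_that("lambda and logLik agree with phytools on shared data", {
  skip_if_not_installed("phytools")
  tr <- sim_yule_tree(60, 1, seed = 86)
  x <- sim_trait(tr, "lambda", sigma2 = 1, shape = 0.5, seed = 87)
  f <- fit_continuous(tr, x, "lambda")
  ps <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(f$shape_param, ps$lambda, tolerance = 1e-4)
  expect_equal(f$logLik, ps$logL, tolerance = 1e-4)
})

test_that("model selection minimizes AICc with ties to fewer parameters", {
  tr <- sim_yule_tree(40, 1, seed = 88)
  x <- sim_trait(tr, "BM", sigma2 = 1, seed = 89)
  fits <- lapply(c("BM", "OU", "lambda"), function(m)
    fit_continuous(tr, x, m))
  best <- select_model(fits)
  expect_equal(best$AICc, min(vapply(fits, function(f) f$AICc, 1)))
  # exact tie between BM and a 3-parameter fit resolves to BM
  fake <- fits
  fake[[2L]]$AICc <- fake[[1L]]$AICc
  expect_equal(select_model(fake[1:2])$model, "BM")
  y <- x; y[1L] <- y[1L] + 1
  f2 <- fit_continuous(tr, y, "BM")
  expect_error(select_model(list(fits[[1L]], f2)), "mismatched")
  expect_error(select_model(fits[1L]), "at least 2")
})

test_that("ancestral states equal their closed forms and the GLS oracle", {
  # equal tip values propagate unchanged
  tr <- sim_yule_tree(12, 1, seed = 90)
  x <- stats::setNames(rep(4.2, 12), tr$tip.label)
  expect_equal(unname(ancestral_states_bm(tr, x)), rep(4.2, tr$Nnode))
  # 2-tip inverse-variance weighting
  t2 <- ape::read.tree(text = "(A:1,B:3);")
  a <- ancestral_states_bm(t2, c(A = 1, B = 3))
  expect_equal(unname(a), (1 / 1 + 3 / 3) / (1 / 1 + 1 / 3),
               tolerance = 1e-12)
  # dense conditional-mean oracle on random trees
  set.seed(91)
  for (i in 1:12) {
    tr <- rand_test_tree(sample(4:15, 1), ultrametric = i %% 2 == 0)
    x <- stats::setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    mine <- ancestral_states_bm(tr, x)
    oracle <- anc_oracle_dense(tr, x)
    expect_equal(mine, oracle[names(mine)], tolerance = 1e-8)
  }
})

test_that("ancestral states agree with phytools fastAnc", {
  skip_if_not_installed("phytools")
  tr <- sim_yule_tree(25, 1, seed = 92)
  x <- sim_trait(tr, "BM", sigma2 = 1.5, seed = 93)
  mine <- ancestral_states_bm(tr, x)
  ref <- phytools::fastAnc(tr, x)
  expect_equal(unname(mine), unname(ref[names(mine)]), tolerance = 1e-8)
})

test_that("PGLS equals OLS on a star tree and at lambda = 0", {
  st <- ape::stree(25, "star")
  st$edge.length <- rep(2, 25)
  set.seed(94)
  y <- rnorm(25); x <- rnorm(25)
  names(y) <- names(x) <- st$tip.label
  X <- cbind(intercept = 1, slope = x)
  rownames(X) <- names(x)
  f <- pgls_fit(st, y, X, "BM")
  ols <- summary(stats::lm(y ~ x))
  expect_equal(f$coefficients$estimate, unname(coef(ols)[, 1]),
               tolerance = 1e-8)
  expect_equal(f$coefficients$std_error, unname(coef(ols)[, 2]),
               tolerance = 1e-8)
  expect_equal(f$coefficients$p_value, unname(coef(ols)[, 4]),
               tolerance = 1e-8)
  expect_equal(f$r_squared, ols$r.squared, tolerance = 1e-8)
  expect_equal(f$adj_r_squared, ols$adj.r.squared, tolerance = 1e-8)

  # lambda fixed at 0 removes all phylogenetic structure
  tr <- sim_yule_tree(25, 1, seed = 95)
  y2 <- sim_trait(tr, "BM", 1, seed = 96)
  x2 <- sim_trait(tr, "BM", 1, seed = 97)
  X2 <- cbind(intercept = 1, slope = x2)
  rownames(X2) <- names(x2)
  f0 <- pgls_fit(tr, y2, X2, "lambda", shape = 0)
  ols2 <- summary(stats::lm(y2[tr$tip.label] ~ x2[tr$tip.label]))
  expect_equal(f0$coefficients$estimate, unname(coef(ols2)[, 1]),
               tolerance = 1e-8)
  expect_equal(f0$coefficients$std_error, unname(coef(ols2)[, 2]),
               tolerance = 1e-8)
  expect_equal(f0$adj_r_squared, ols2$adj.r.squared, tolerance = 1e-8)
})

test_that("BM PGLS coefficients match nlme::gls with a Brownian structure", {
  skip_if_not_installed("nlme")
  tr <- sim_yule_tree(30, 1, seed = 98)
  d <- sim_regression_dataset(tr, beta = c(1, 0.7), sigma2 = 0.5,
                              seed = 99)
  X <- cbind(intercept = 1, slope = d$x)
  rownames(X) <- names(d$x)
  f <- pgls_fit(tr, d$y, X, "BM")
  df <- data.frame(y = d$y, x = d$x, sp = names(d$y))
  g <- nlme::gls(y ~ x, data = df,
                 correlation = ape::corBrownian(phy = tr, form = ~sp),
                 method = "ML")
  expect_equal(f$coefficients$estimate, unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
})

test_that("PGLS validates its design matrix and sample size", {
  tr <- sim_yule_tree(10, 1, seed = 100)
  y <- sim_trait(tr, "BM", 1, seed = 101)
  X <- cbind(intercept = 1, a = 1:10, b = 2 * (1:10))
  rownames(X) <- tr$tip.label
  expect_error(pgls_fit(tr, y, X, "BM"), "rank deficient")
  tr4 <- sim_yule_tree(4, 1, seed = 102)
  y4 <- sim_trait(tr4, "BM", 1, seed = 103)
  X4 <- cbind(intercept = 1, a = rnorm(4), b = rnorm(4))
  rownames(X4) <- tr4$tip.label
  expect_error(pgls_fit(tr4, y4, X4, "BM"), "n > p \\+ 2")
  Xni <- cbind(a = rnorm(10), b = rnorm(10))
  rownames(Xni) <- tr$tip.label
  expect_error(pgls_fit(tr, y, Xni, "BM"), "intercept")
})

test_that("parametric bootstrap is reproducible and validated", {
  tr <- sim_yule_tree(20, 1, seed = 104)
  d <- sim_regression_dataset(tr, beta = c(0, 0.5), seed = 105)
  X <- cbind(intercept = 1, slope = d$x)
  rownames(X) <- names(d$x)
  f <- pgls_fit(tr, d$y, X, "BM")
  b1 <- pgls_bootstrap(f, tr, d$y, X, B = 30, seed = 7)
  b2 <- pgls_bootstrap(f, tr, d$y, X, B = 30, seed = 7)
  expect_identical(b1$estimates, b2$estimates)
  expect_length(b1$estimates, 30L)
  expect_true(all(diff(unname(b1$quantiles)) >= 0))
  expect_error(pgls_bootstrap(f, tr, d$y, X, B = 1), "B must be")
})

test_that("the correlation decision rule gates on p and adjusted R2", {
  expect_true(correlation_call(0.01, 0.20))
  expect_false(correlation_call(0.01, 0.05))
  expect_false(correlation_call(0.20, 0.30))
  expect_false(correlation_call(0.049, 0.1))
  expect_error(correlation_call(NA, 0.2), "finite")
})

test_that("trait adjustment regresses log durations on log mass", {
  # constant mass: residuals are centered log10 durations
  dur <- c(10, 20, 40, 80)
  r <- adjust_trait(dur, rep(5, 4))
  expect_equal(unname(r), log10(dur) - mean(log10(dur)), tolerance = 1e-10)
  # exact allometry leaves zero residuals
  mass <- c(1, 10, 100, 1000)
  expect_equal(unname(adjust_trait(2 * mass^0.75, mass)), rep(0, 4),
               tolerance = 1e-10)
  # matches an explicit OLS fit on a 5-species example
  dur5 <- c(12, 30, 22, 55, 80)
  mass5 <- c(100, 900, 350, 2500, 8000)
  ref <- unname(resid(stats::lm(log10(dur5) ~ log10(mass5))))
  expect_equal(unname(adjust_trait(dur5, mass5)), ref, tolerance = 1e-10)
  expect_error(adjust_trait(c(1, -2), c(1, 2)), "positive")
})

test_that("pruning to shared species preserves surviving depths", {
  tr <- sim_yule_tree(5, 1, seed = 106)
  tab <- data.frame(species = tr$tip.label[1:3], trait = c(1, 2, 3))
  pr <- prune_to_common(tr, tab)
  expect_setequal(pr$tree$tip.label, tab$species)
  expect_equal(pr$table$species, pr$tree$tip.label)
  # patristic distances among survivors are untouched; depths shift by
  # the constant root-path length collapsed away with the dropped clade
  D0 <- ape::cophenetic.phylo(tr)[pr$tree$tip.label, pr$tree$tip.label]
  D1 <- ape::cophenetic.phylo(pr$tree)[pr$tree$tip.label,
                                       pr$tree$tip.label]
  expect_equal(D1, D0, tolerance = 1e-10)
  d0 <- ape::node.depth.edgelength(tr)[1:5]
  names(d0) <- tr$tip.label
  d1 <- ape::node.depth.edgelength(pr$tree)[1:3]
  names(d1) <- pr$tree$tip.label
  offs <- d0[names(d1)] - d1
  expect_lt(max(offs) - min(offs), 1e-10)

  # full overlap leaves the tree untouched
  full <- data.frame(species = tr$tip.label, trait = 1:5)
  expect_identical(prune_to_common(tr, full)$tree, tr)

  expect_error(prune_to_common(tr, data.frame(species = c("x", "y", "z"),
                                              trait = 1:3)),
               "fewer than 3")
  expect_error(prune_to_common(tr, rbind(full, full[1L, ])), "duplicate")
  # NA traits drop species before the overlap check
  nas <- full; nas$trait[1:3] <- NA
  expect_error(prune_to_common(tr, nas), "fewer than 3")
})
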