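test_that("BM log-likelihood matches the two-tip closed form", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  sp <- model_spec("BM", list(z0 = 0, sig2 = 1))
  expect_equal(loglik_gaussian(tr, c(A = 0, B = 0), sp), -log(2 * pi),
               tolerance = 1e-10)
})

test_that("Gaussian likelihoods equal a direct MVN oracle on small trees", {
  set.seed(14)
  for (i in 1:6) {
    tr <- rand_fossil_tree(6)
    x <- setNames(rnorm(6, 1), tr$tip.label)
    o <- ou_moments_oracle(tr, z0 = 0.5, sig2 = 0.8, alpha = 0.7, theta = 1.5)
    l_pkg <- loglik_gaussian(tr, x, model_spec("OU",
      list(z0 = 0.5, sig2 = 0.8, alpha = 0.7, theta = 1.5)))
    l_ora <- dmvnorm_log_oracle(x[o$tips], o$mean, o$V)
    expect_equal(l_pkg, l_ora, tolerance = 1e-8)

    # BM and TREND against the same oracle machinery
    C <- cov_path_enumeration(tr)
    l_bm <- loglik_gaussian(tr, x, model_spec("BM", list(z0 = 0.2, sig2 = 1.3)))
    expect_equal(l_bm, dmvnorm_log_oracle(x[rownames(C)],
                                          rep(0.2, 6), 1.3 * C),
                 tolerance = 1e-8)
    l_tr <- loglik_gaussian(tr, x, model_spec("TREND",
      list(z0 = 0.2, sig2 = 1.3, mu_trend = 0.4)))
    expect_equal(l_tr, dmvnorm_log_oracle(x[rownames(C)],
                                          0.2 + 0.4 * diag(C), 1.3 * C),
                 tolerance = 1e-8)
  }
})

test_that("nesting identities hold on random data", {
  set.seed(21)
  for (i in 1:20) {
    tr <- rand_fossil_tree(7)
    x <- setNames(rnorm(7, 2), tr$tip.label)
    l_bm <- loglik_gaussian(tr, x, model_spec("BM", list(z0 = 1, sig2 = 0.7)))
    expect_equal(loglik_gaussian(tr, x, model_spec("KAPPA",
      list(z0 = 1, sig2 = 0.7, kappa = 1))), l_bm, tolerance = 1e-10)
    expect_equal(loglik_gaussian(tr, x, model_spec("EB",
      list(z0 = 1, sig2 = 0.7, r_eb = 0))), l_bm, tolerance = 1e-10)
    expect_equal(loglik_pulsed(tr, x, model_spec("PULSED",
      list(z0 = 1, sig2 = 0.7, lambda_j = 0, delta2 = 3))), l_bm,
      tolerance = 1e-9)
    l_ou_small <- loglik_gaussian(tr, x, model_spec("OU",
      list(z0 = 1, sig2 = 0.7, alpha = 1e-8, theta = 5)))
    expect_equal(l_ou_small, l_bm, tolerance = 1e-4)
  }
})

test_that("env-coupled OU collapses to OU and absorbs constant curves", {
  set.seed(8)
  tr <- rand_fossil_tree(6)
  x <- setNames(rnorm(6, 1), tr$tip.label)
  age <- seq(500, 240, by = -4)
  cv <- fit_smoothing_spline(age, 25 + 3 * sin(age / 20))
  l_ou <- loglik_gaussian(tr, x, model_spec("OU",
    list(z0 = 0.5, sig2 = 0.8, alpha = 0.7, theta = 1.5)))
  l_b0 <- loglik_env_ou(tr, x, model_spec("ENV_OU_TEMP",
    list(z0 = 0.5, sig2 = 0.8, alpha = 0.7, theta0 = 1.5, beta = 0),
    curve = cv, root_age_ma = 480))
  expect_equal(l_b0, l_ou, tolerance = 1e-8)

  const <- fit_smoothing_spline(seq(500, 240, -10), rep(10, 27), smoothing = 0)
  l_abs <- loglik_env_ou(tr, x, model_spec("ENV_OU_TEMP",
    list(z0 = 0.5, sig2 = 0.8, alpha = 0.7, theta0 = 0.5, beta = 0.1),
    curve = const, root_age_ma = 480))
  expect_equal(l_abs, l_ou, tolerance = 1e-8)

  # out-of-range placement errors
  expect_error(loglik_env_ou(tr, x, model_spec("ENV_OU_TEMP",
    list(z0 = 0, sig2 = 1, alpha = 0.1, theta0 = 0, beta = 1),
    curve = cv, root_age_ma = 600)), "range")
})

test_that("env-OU tip means match a fine-step ODE oracle on a ramp", {
  tr <- ape::read.tree(text = "(A:5,B:9);")
  age <- seq(500, 480, by = -1)
  ramp <- fit_smoothing_spline(age, 2 * (500 - age), smoothing = 0)
  z0 <- 1; alpha <- 0.4; theta0 <- 0.5; beta <- 0.05
  # package tip means via the design columns
  K <- palaeotrait:::.env_ou_design(tr, ramp, alpha, root_age_ma = 498)
  Tt <- diag(bm_covariance(tr))[tr$tip.label]
  m_pkg <- z0 * exp(-alpha * Tt) + theta0 * (1 - exp(-alpha * Tt)) +
    beta * setNames(K, tr$tip.label)
  for (tip in tr$tip.label) {
    m_ora <- env_ou_mean_ode_oracle(ramp, Tt[[tip]], z0, alpha, theta0, beta,
                                    root_age_ma = 498)
    expect_equal(m_pkg[[tip]], m_ora, tolerance = 1e-6)
  }
})

test_that("multi-peak OU matches a segment-recursion oracle and collapses", {
  set.seed(31)
  tr <- rand_fossil_tree(5)
  x <- setNames(rnorm(5, 2), tr$tip.label)
  # paint alternating regimes along each edge
  maps <- lapply(seq_len(nrow(tr$edge)), function(e) {
    l <- tr$edge.length[e]
    if (e %% 2 == 0) setNames(c(0.4 * l, 0.6 * l), c("R1", "R2"))
    else setNames(l, "R1")
  })
  rm <- regime_map(tr, maps)
  theta <- c(R1 = 1, R2 = 3.5)
  sp <- model_spec("OUM3_HABITAT", list(z0 = 0.5, sig2 = 0.6, alpha = 0.45,
                                        theta = theta))
  l_pkg <- loglik_oum(rm, x, sp)
  o <- oum_moments_oracle(rm, 0.5, theta, 0.45, 0.6)
  expect_equal(l_pkg, dmvnorm_log_oracle(x[o$tips], o$mean, o$V),
               tolerance = 1e-8)

  # equal regimes collapse to single-peak OU
  sp_eq <- model_spec("OUM3_HABITAT", list(z0 = 0.5, sig2 = 0.6, alpha = 0.45,
                                           theta = c(R1 = 2, R2 = 2)))
  l_ou <- loglik_gaussian(tr, x, model_spec("OU",
    list(z0 = 0.5, sig2 = 0.6, alpha = 0.45, theta = 2)))
  expect_equal(loglik_oum(rm, x, sp_eq), l_ou, tolerance = 1e-8)

  # strong pull sends regime-pure tip means to their optimum
  deep <- ape::read.tree(text = "(A:40,B:40);")
  dmap <- regime_map(deep, list(setNames(40, "R1"), setNames(40, "R2")))
  mom <- palaeotrait:::.oum_node_moments(dmap, c("R1", "R2"),
                                         c(1, 1), c(0.1, 0.1))
  mean_tips <- mom$coefs[1:2, ] %*% c(0, 1, 3.5)
  expect_equal(drop(mean_tips), c(1, 3.5), tolerance = 1e-4)

  # unpainted regime errors
  sp_bad <- model_spec("OUM3_HABITAT", list(z0 = 0, sig2 = 1, alpha = 0.1,
                                            theta = c(R1 = 1)))
  expect_error(loglik_oum(rm, x, sp_bad), "theta")
})

test_that("pulsed likelihood matches series and Monte-Carlo oracles", {
  # symmetric 2-tip series: two independent branches of length 1 from z0
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  l_pkg <- loglik_pulsed(tr2, c(A = 0, B = 0), model_spec("PULSED",
    list(z0 = 0, sig2 = 1, lambda_j = 1, delta2 = 1)))
  ser <- sum(vapply(0:80, function(k)
    exp(-1) / factorial(k) * dnorm(0, 0, sqrt(1 + k)), 0))
  expect_equal(as.numeric(l_pkg), 2 * log(ser), tolerance = 1e-8)

  # Monte-Carlo oracle on a random 4-tip tree
  set.seed(77)
  tr <- rand_fossil_tree(4)
  x <- simulate_continuous(tr, model_spec("PULSED",
    list(z0 = 0, sig2 = 0.5, lambda_j = 0.3, delta2 = 2)), seed = 3)
  l_pkg <- loglik_pulsed(tr, x, model_spec("PULSED",
    list(z0 = 0, sig2 = 0.5, lambda_j = 0.3, delta2 = 2)))
  mc <- pulsed_mc_oracle(tr, x, 0, 0.5, 0.3, 2, ndraw = 2e5, seed = 4)
  expect_lt(abs(as.numeric(l_pkg) - mc$loglik), 3 * mc$se_log + 1e-6)
})

test_that("log-likelihoods are invariant to tip ordering", {
  set.seed(41)
  tr <- rand_fossil_tree(8)
  x <- setNames(rnorm(8), tr$tip.label)
  perm <- sample(names(x))
  for (sp in list(model_spec("BM", list(z0 = 0, sig2 = 1)),
                  model_spec("OU", list(z0 = 0, sig2 = 1, alpha = 0.3, theta = 1)),
                  model_spec("PULSED", list(z0 = 0, sig2 = 1, lambda_j = 0.2,
                                            delta2 = 1)))) {
    expect_equal(trait_loglik(tr, x, sp), trait_loglik(tr, x[perm], sp),
                 tolerance = 1e-12)
  }
})

test_that("fitting honours preconditions and recovers simple truths", {
  ultra <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  x <- c(A = 1, B = 1.2, C = 0.8, D = 1.1)
  expect_error(fit_trait_model(ultra, x, "TREND"), "ultrametric")
  expect_error(fit_trait_model(ultra, x, "OUM3_HABITAT"), "regime_map")
  expect_error(fit_trait_model(ultra, x, "ENV_OU_TEMP"), "curve")
  small <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_error(
    fit_trait_model(small, c(A = 1, B = 2, C = 3), "OU"), "AICc")

  set.seed(5)
  tr <- rand_fossil_tree(60)
  xs <- simulate_continuous(tr, model_spec("BM", list(z0 = 0, sig2 = 2)),
                            seed = 6)
  f <- fit_trait_model(tr, xs, "BM")
  expect_true(f$converged)
  expect_lt(abs(f$params$sig2 - 2) / 2, 0.5)
  expect_equal(f$aicc, aicc(f$lnL, 2, 60))

  # determinism of the restarted optimizer
  f2 <- fit_trait_model(tr, xs, "KAPPA", options = list(seed = 3))
  f3 <- fit_trait_model(tr, xs, "KAPPA", options = list(seed = 3))
  expect_identical(f2$params, f3$params)
})
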