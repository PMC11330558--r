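test_that("pure-birth FBD trees are ultrametric with the requested tips", {
  tr <- simulate_fbd_tree(1, 0, 0, n_extant = 8, seed = 2)
  expect_equal(ape::Ntip(tr), 8)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  t1 <- simulate_fbd_tree(0.08, 0.05, 0.04, duration = 120, seed = 9)
  t2 <- simulate_fbd_tree(0.08, 0.05, 0.04, duration = 120, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(ape::is.ultrametric(t1, tol = 1e-6))
  expect_error(simulate_fbd_tree(0, 0, 0, duration = 10), "lambda")
  expect_error(simulate_fbd_tree(1, 0, 0), "stop condition")
})

test_that("FBD sampled-tip counts match a discrete-step forward oracle", {
  lambda <- 0.1; mu <- 0.05; psi <- 0.05; dur <- 100
  n_rep <- 1500
  pkg_counts <- vapply(seq_len(n_rep), function(s) {
    tr <- tryCatch(simulate_fbd_tree(lambda, mu, psi, duration = dur, rho = 0,
                                     seed = 5000 + s, min_tips = 2,
                                     max_retries = 1),
                   error = function(e) NULL)
    # failed runs are trees with < 2 samples; count them as their true size
    if (is.null(tr)) NA_real_ else ape::Ntip(tr)
  }, 0)
  set.seed(321)
  ora_counts <- vapply(seq_len(1000), function(s)
    fbd_forward_oracle_count(lambda, mu, psi, dur, dt = 0.05), 0)
  # compare conditional on >= 2 sampled tips (the simulator's support)
  m_pkg <- mean(pkg_counts[!is.na(pkg_counts)])
  m_ora <- mean(ora_counts[ora_counts >= 2])
  expect_lt(abs(m_pkg - m_ora) / m_ora, 0.10)
})

test_that("Gaussian trait simulation matches analytic moments", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  X <- simulate_continuous(tr, model_spec("BM", list(z0 = 0, sig2 = 1)),
                           nsim = 5000, seed = 9)
  S <- cov(t(X))
  expect_lt(max(abs(S - bm_covariance(tr)[rownames(S), colnames(S)])), 0.1)

  # OU stationary collapse under strong pull
  Xo <- simulate_continuous(tr, model_spec("OU", list(z0 = 0, sig2 = 1,
                                                      alpha = 60, theta = 3)),
                            nsim = 20, seed = 1)
  expect_lt(max(abs(Xo - 3)), 0.5)

  # TREND mean shift
  Xt <- simulate_continuous(tr, model_spec("TREND", list(z0 = 0, sig2 = 0.01,
                                                         mu_trend = 1)),
                            nsim = 2000, seed = 2)
  expect_equal(unname(rowMeans(Xt)[c("A", "B", "C")]), c(2, 2, 2),
               tolerance = 0.05)
})

test_that("pulsed simulation with no jumps is Brownian", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  Xp <- simulate_continuous(tr, model_spec("PULSED",
      list(z0 = 0, sig2 = 1, lambda_j = 0, delta2 = 1)), nsim = 2000, seed = 3)
  Xb <- simulate_continuous(tr, model_spec("BM", list(z0 = 0, sig2 = 1)),
                            nsim = 2000, seed = 4)
  for (tip in c("A", "C")) {
    expect_gt(stats::ks.test(Xp[tip, ], Xb[tip, ])$p.value, 0.01)
  }
  # jump history is returned and consistent with the tip values
  Xh <- simulate_continuous(tr, model_spec("PULSED",
      list(z0 = 0, sig2 = 0.001, lambda_j = 2, delta2 = 1)), nsim = 2,
      seed = 5, return_history = TRUE)
  expect_type(attr(Xh, "jumps"), "list")
})

test_that("discrete simulation matches the closed-form flip probability", {
  q <- 0.1; tlen <- 5
  Q <- matrix(c(-q, q, q, -q), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- ape::read.tree(text = "(A:5,B:0.001);")
  flips <- vapply(1:10000, function(s)
    simulate_discrete(tr, Q, root_state = "a", seed = s)$tip_states[["A"]] != "a",
    TRUE)
  p_hat <- mean(flips)
  p_true <- 0.5 * (1 - exp(-2 * q * tlen))
  se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(p_hat - p_true), 2 * se + 1e-9)
})

test_that("structural zeros are never crossed and Q = 0 is static", {
  Q0 <- matrix(0, 3, 3, dimnames = list(habitat_states(), habitat_states()))
  tr <- rand_fossil_tree(8, seed = 2)
  s <- simulate_discrete(tr, Q0, root_state = "marine", seed = 1)
  expect_true(all(s$tip_states == "marine"))
  expect_equal(s$n_events, 0L)

  # ordered evolution: marine <-> continental only through marginal
  Q <- make_q_matrix(c(0.3, 0, 0.3, 0.3, 0, 0.3))
  for (seed in 1:40) {
    s <- simulate_discrete(rand_fossil_tree(10, seed = seed), Q,
                           root_state = "marine", seed = seed)
    for (m in s$map$maps) {
      if (length(m) > 1) {
        pairs <- cbind(names(m)[-length(m)], names(m)[-1])
        direct <- (pairs[, 1] == "marine" & pairs[, 2] == "continental") |
                  (pairs[, 1] == "continental" & pairs[, 2] == "marine")
        expect_false(any(direct))
      }
    }
  }
})

test_that("per-branch event counts are Poisson under a symmetric rate", {
  q <- 0.25; tlen <- 4
  Q <- matrix(c(-q, q, q, -q), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- ape::read.tree(text = "(A:4,B:0.001);")
  counts <- vapply(1:10000, function(s) {
    m <- simulate_discrete(tr, Q, root_state = "a", seed = 20000 + s)$map$maps
    e <- which(tr$edge[, 2] == which(tr$tip.label == "A"))
    length(m[[e]]) - 1L
  }, 0L)
  lam <- q * tlen
  brk <- c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf)
  obs <- table(cut(counts, brk))
  pp <- diff(ppois(c(-1, 0, 1, 2, 3, Inf), lam))
  expect_gt(stats::chisq.test(as.numeric(obs), p = pp)$p.value, 0.001)
})

test_that("environmental curves are smooth, bounded and reproducible", {
  flat <- simulate_env_curve(c(460, 250), roughness = 0, mean = 25, seed = 1)
  expect_equal(nrow(flat), 211)
  expect_true(all(flat$value == 25))
  a <- simulate_env_curve(c(460, 250), roughness = 5, mean = 25,
                          bounds = c(20, 30), seed = 2)
  b <- simulate_env_curve(c(460, 250), roughness = 5, mean = 25,
                          bounds = c(20, 30), seed = 2)
  expect_identical(a, b)
  expect_true(all(a$value >= 20 & a$value <= 30))
  expect_error(simulate_env_curve(c(250, 460)), "t0 > t1")
})

test_that("community tables respect guild structure and the size law", {
  a <- simulate_community(50, seed = 5)
  b <- simulate_community(50, seed = 5)
  expect_identical(a, b)
  big <- simulate_community(2000, size_meanlog = 3, size_sdlog = 1, seed = 6)
  expect_lt(abs(median(big$max_length_cm) - exp(3)) / exp(3), 0.10)

  # sessile-only fauna yields zero prey for any focal eurypterid
  sess <- simulate_community(30, guild_probs = c(sessile = 1), seed = 7)
  sess$guild[1] <- "eurypterine"     # one focal predator
  sess$assemblage <- 1L
  rec <- classify_predators_prey(sess, sess$species[1])
  expect_equal(rec$n_prey, 0L)
})

test_that("the bundled scenario has the study-scale shape", {
  sc <- simulate_scenario(seed = 4, config = list(n_tips = 60L,
                                                  n_posterior_trees = 4L))
  expect_equal(ape::Ntip(sc$mcc), 60)
  expect_length(sc$trees, 4)
  expect_false(ape::is.ultrametric(sc$mcc, tol = 1e-6))
  expect_true(all(sc$traits$habitat %in% habitat_states()))
  expect_equal(sc$traits$log_size, log(sc$traits$max_length_cm))
  # same tip universe across the tree set
  for (tr in sc$trees) expect_setequal(tr$tip.label, sc$mcc$tip.label)
})
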