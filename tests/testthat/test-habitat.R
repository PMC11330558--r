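two_state_q <- function(q) {
  matrix(c(-q, q, q, -q), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
}

test_that("Mk likelihood matches closed forms and exhaustive enumeration", {
  # certain history under a zero rate matrix
  Q0 <- matrix(0, 3, 3, dimnames = list(habitat_states(), habitat_states()))
  tr <- rand_fossil_tree(5, seed = 1)
  ts <- setNames(rep("marine", 5), tr$tip.label)
  expect_equal(mk_loglik(tr, ts, Q0, root_prior = "marine"), 0)

  # single-branch transition probability: P(same) = 0.5 + 0.5 exp(-2qt)
  Q <- two_state_q(0.1)
  tr2 <- ape::read.tree(text = "(A:2.5,B:2.5);")
  ll <- mk_loglik(tr2, c(A = "a", B = "a"), Q, root_prior = "uniform")
  P <- as.matrix(Matrix::expm(Q * 2.5))
  expect_equal(exp(ll), sum(0.5 * P[, "a"]^2), tolerance = 1e-10)
  expect_equal(0.5 + 0.5 * exp(-2 * 0.1 * 5), P["a", "a"] * P["a", "a"] +
                 P["a", "b"] * P["b", "a"] + 0, tolerance = 1e-6)

  # random 6-tip, 3 states vs brute-force enumeration
  set.seed(13)
  states <- habitat_states()
  Q3 <- make_q_matrix(c(0.2, 0.1, 0.15, 0.2, 0.05, 0.1))
  for (i in 1:3) {
    tr6 <- rand_fossil_tree(6)
    ts6 <- setNames(sample(states, 6, replace = TRUE), tr6$tip.label)
    pri <- c(0.3, 0.3, 0.4)
    expect_equal(mk_loglik(tr6, ts6, Q3, root_prior = pri),
                 mk_brute_oracle(tr6, ts6, Q3, pri), tolerance = 1e-10)
  }

  # missing state is ambiguous, not an error
  ts_na <- ts6; ts_na[1] <- NA
  expect_silent(mk_loglik(tr6, ts_na, Q3))
})

test_that("rjMCMC is deterministic and samples its prior without data", {
  # two chains, same seed, identical streams
  tr <- rand_fossil_tree(12, seed = 4)
  Q <- two_state_q(0.2)
  ts <- simulate_discrete(tr, Q, root_state = "a", seed = 2)$tip_states
  r1 <- rjmcmc_mk(tr, ts, iterations = 400, burnin = 100, seed = 7,
                  states = c("a", "b"))
  r2 <- rjmcmc_mk(tr, ts, iterations = 400, burnin = 100, seed = 7,
                  states = c("a", "b"))
  expect_identical(r1$samples, r2$samples)

  # detailed balance: with a flat likelihood the chain must visit the five
  # two-entry structures (shared, split, two half-zero, all-zero) uniformly
  r0 <- rjmcmc_mk(NULL, NULL, iterations = 1e6, burnin = 1e5, thin = 5,
                  seed = 11, rate_mean = 1, states = c("a", "b"))
  freq <- r0$structure_freq
  expect_setequal(names(freq), c("aa", "ab", "0a", "a0", "00"))
  kl <- sum(freq * log(freq / 0.2))
  expect_lt(kl, 0.01)
})

test_that("stochastic maps agree with enumeration posteriors", {
  Q <- two_state_q(0.1)
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  ts <- c(A = "a", B = "b", C = "a")
  n_maps <- 4000
  maps <- stochastic_map(tr, ts, Q, n_maps = n_maps, seed = 1,
                         root_prior = "uniform")
  # marginal posteriors at both internal nodes by exhaustive enumeration
  for (node in 4:5) {
    marg <- mk_node_marginal_oracle(tr, ts, Q, c(0.5, 0.5), node)
    freq <- mean(vapply(maps, function(m) m$node_state[node] == "a", TRUE))
    expect_lt(abs(freq - marg[["a"]]), 0.03)
  }
  # transition counts never fall below the parsimony minimum (here 1)
  expect_gte(min(vapply(maps, n_transitions, 0L)), 1L)
  # maps are internally consistent with the data
  for (m in maps[1:50]) {
    expect_identical(m$node_state[1:3], unname(ts[tr$tip.label]))
  }
})

test_that("maps under near-zero rates have no transitions", {
  Q <- two_state_q(1e-9)
  tr <- rand_fossil_tree(6, seed = 3)
  ts <- setNames(rep("a", 6), tr$tip.label)
  maps <- stochastic_map(tr, ts, Q, n_maps = 50, seed = 2)
  expect_true(all(vapply(maps, n_transitions, 0L) == 0L))
})

test_that("map summaries conserve lineage counts and count transitions", {
  Q <- two_state_q(0.3)
  tr <- rand_fossil_tree(10, seed = 9)
  ts <- simulate_discrete(tr, Q, root_state = "a", seed = 5)$tip_states
  maps <- stochastic_map(tr, ts, Q, n_maps = 40, seed = 6)
  sm <- summarize_maps(maps)
  # per-state counts sum to the number of live branches at every grid time
  depth <- node_depths(tr)
  for (ti in seq(1, length(sm$time_grid), by = 20)) {
    tg <- sm$time_grid[ti]
    alive <- sum(depth[tr$edge[, 1]] <= tg & depth[tr$edge[, 2]] > tg)
    for (m in 1:5) {
      expect_equal(sum(sm$counts[m, , ti]), alive)
    }
  }
  expect_true(all(abs(rowSums(sm$node_freq) - 1) < 1e-12))
  # single map: bands collapse onto the map's own counts
  sm1 <- summarize_maps(maps[1])
  expect_equal(sm1$lineages_lo, sm1$lineages_hi)

  # hand-built 3-branch map with one marked transition
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  maps3 <- list(setNames(1, "a"), setNames(1, "a"),
                setNames(c(0.5, 0.5), c("a", "b")), setNames(2, "a"))
  # order must follow tr3$edge rows: (4,5), (5,A), (5,B), (4,C)
  rm3 <- regime_map(tr3, list(setNames(1, "a"), setNames(1, "a"),
                              setNames(c(0.5, 0.5), c("a", "b")),
                              setNames(2, "a")),
                    states = c("a", "b"))
  s3 <- summarize_maps(list(rm3), time_grid = c(1.2, 1.8))
  e_b <- which(tr3$edge[, 2] == which(tr3$tip.label == "B"))
  before <- s3$counts[1, , 1]
  after <- s3$counts[1, , 2]
  expect_equal(sum(before), sum(after))
  expect_equal(after[["b"]] - before[["b"]], 1)
  expect_equal(before[["a"]] - after[["a"]], 1)
})

test_that("colonization counting matches hand-built and simulated truths", {
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  rm_none <- regime_map(tr3, list(setNames(1, "marine"), setNames(1, "marine"),
                                  setNames(1, "marine"), setNames(2, "marine")))
  expect_equal(count_colonizations(list(rm_none), "continental")$counts, 0L)
  # three disjoint continental segments, each entered exactly once
  rm3 <- regime_map(tr3, list(
    setNames(c(0.3, 0.7), c("marine", "continental")),
    setNames(c(0.2, 0.8), c("marine", "continental")),
    setNames(c(0.5, 0.3, 0.2), c("marine", "continental", "marine")),
    setNames(2, "marine")))
  expect_equal(count_colonizations(list(rm3), "continental")$counts, 3L)

  # mapping-based counts agree with forward-simulation truth in expectation
  Q <- make_q_matrix(c(0.15, 0, 0.15, 0.1, 0, 0.05))
  tr <- rand_fossil_tree(12, seed = 21)
  truth <- integer(200); mapped <- integer(200)
  for (r in 1:200) {
    s <- simulate_discrete(tr, Q, root_state = "marine", seed = 300 + r)
    truth[r] <- sum(vapply(s$map$maps, function(m)
      sum(names(m)[-1] == "continental"), 0L))
    mp <- stochastic_map(tr, s$tip_states, Q, n_maps = 1, seed = 700 + r)
    mapped[r] <- count_colonizations(mp, "continental")$counts
  }
  se <- sqrt(var(truth) / 200 + var(mapped) / 200)
  expect_lt(abs(mean(truth) - mean(mapped)), 3 * se + 0.05)
})

test_that("habitat repainting merges states and conserves length", {
  tr <- rand_fossil_tree(8, seed = 2)
  Q <- make_q_matrix(c(0.2, 0, 0.2, 0.15, 0, 0.1))
  s <- simulate_discrete(tr, Q, root_state = "marine", seed = 8)
  two <- paint_habitat_regimes(s$map, "two_peak")
  expect_setequal(regime_states(two), intersect(c("marginal", "other"),
                                                regime_states(two)))
  expect_equal(sum(unlist(two$maps)), sum(tr$edge.length), tolerance = 1e-9)
  # merge rule: marine -> marginal -> continental becomes other/marginal/other
  tr1 <- ape::read.tree(text = "(A:3,B:0.1);")
  rm <- regime_map(tr1, list(
    setNames(c(1, 1, 1), c("marine", "marginal", "continental")),
    setNames(0.1, "marine")))
  t1 <- paint_habitat_regimes(rm, "two_peak")
  e <- which(tr1$edge[, 2] == which(tr1$tip.label == "A"))
  expect_equal(names(t1$maps[[e]]), c("other", "marginal", "other"))
  # a fully marginal map keeps a single regime
  rm_m <- regime_map(tr1, list(setNames(3, "marginal"), setNames(0.1, "marginal")))
  t2 <- paint_habitat_regimes(rm_m, "two_peak")
  expect_equal(unique(unlist(lapply(t2$maps, names))), "marginal")
})

test_that("crisis painting splits branches exactly at the crisis age", {
  tr <- ape::read.tree(text = "((A:10,B:10):10,(C:12,D:12):8);")
  # ages: root at 20, tips at 0
  cr <- paint_crisis_regimes(tr, 4, clade1 = c("A", "B"), clade2 = c("C", "D"))
  expect_equal(sum(unlist(cr$maps)), sum(tr$edge.length), tolerance = 1e-9)
  eA <- which(tr$edge[, 2] == which(tr$tip.label == "A"))
  expect_equal(unname(cr$maps[[eA]]), c(6, 4))
  expect_equal(names(cr$maps[[eA]]), c("PRE", "S1"))
  eC <- which(tr$edge[, 2] == which(tr$tip.label == "C"))
  expect_equal(unname(cr$maps[[eC]]), c(8, 4))
  expect_equal(names(cr$maps[[eC]]), c("PRE", "S2"))

  # crisis older than the root: membership only
  cr_old <- paint_crisis_regimes(tr, 25, c("A", "B"), c("C", "D"))
  expect_setequal(unique(unlist(lapply(cr_old$maps, names))),
                  c("S1", "S2"))
  # crisis younger than all tips: everything PRE
  cr_young <- paint_crisis_regimes(tr, -1, c("A", "B"), c("C", "D"))
  expect_equal(unique(unlist(lapply(cr_young$maps, names))), "PRE")
  expect_error(paint_crisis_regimes(tr, 4, c("A", "B"), c("B", "C")),
               "overlap")
})

test_that("stochastic mapping cross-checks against phytools", {
  Q <- two_state_q(0.15)
  tr <- ape::read.tree(text = "((A:2,B:2):1,(C:1,D:1):2);")
  ts <- c(A = "a", B = "b", C = "b", D = "b")
  maps <- stochastic_map(tr, ts, Q, n_maps = 3000, seed = 3,
                         root_prior = "uniform")
  mean_trans <- mean(vapply(maps, n_transitions, 0L))
  suppressWarnings({
    pt <- phytools::make.simmap(tr, ts, Q = Q, pi = "equal", nsim = 3000,
                                message = FALSE)
  })
  pt_trans <- mean(vapply(pt, function(m) sum(lengths(m$maps) - 1), 0))
  expect_lt(abs(mean_trans - pt_trans) / pt_trans, 0.1)
})
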