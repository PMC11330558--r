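test_that("pgls reduces to OLS without phylogenetic structure", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2,E:2,F:2);")
  set.seed(6)
  y <- setNames(rnorm(6), star$tip.label)
  x <- setNames(rnorm(6), star$tip.label)
  f <- pgls(star, y, x)
  ols <- lm(y ~ x)
  expect_equal(f$slope, unname(coef(ols)[2]), tolerance = 1e-8)
  expect_equal(f$r_squared, summary(ols)$r.squared, tolerance = 1e-8)

  # lambda = 0 equals OLS on trees with contemporaneous tips
  ultra <- ape::read.tree(text = "((A:1,B:1):1,((C:0.5,D:0.5):0.5,(E:0.7,F:0.7):0.3):1);")
  y2 <- setNames(rnorm(6), ultra$tip.label)
  x2 <- setNames(rnorm(6), ultra$tip.label)
  f0 <- pgls(ultra, y2, x2, lambda_policy = 0)
  ols2 <- lm(y2 ~ x2)
  expect_equal(f0$slope, unname(coef(ols2)[2]), tolerance = 1e-8)

  # perfectly linear data
  ylin <- setNames(2 + 0.3 * x, names(x))
  flin <- pgls(star, ylin, x)
  expect_equal(flin$slope, 0.3, tolerance = 1e-10)
  expect_equal(flin$r_squared, 1, tolerance = 1e-10)
})

test_that("pgls matches a brute-force GLS solution and nlme", {
  set.seed(9)
  tr <- rand_fossil_tree(5)
  y <- setNames(rnorm(5, 2), tr$tip.label)
  x <- setNames(rnorm(5), tr$tip.label)
  f <- pgls(tr, y, x)
  C <- cov_path_enumeration(tr)
  X <- cbind(1, x[rownames(C)])
  b <- solve(t(X) %*% solve(C, X), t(X) %*% solve(C, y[rownames(C)]))
  expect_equal(f$intercept, b[1], tolerance = 1e-8)
  expect_equal(f$slope, b[2], tolerance = 1e-8)

  # independent GLS engine on a larger ultrametric tree
  tr2 <- ape::rcoal(12)
  y2 <- setNames(rnorm(12, 1), tr2$tip.label)
  x2 <- setNames(rnorm(12), tr2$tip.label)
  f2 <- pgls(tr2, y2, x2)
  d <- data.frame(y = y2[tr2$tip.label], x = x2[tr2$tip.label],
                  sp = tr2$tip.label)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corBrownian(1, tr2, form = ~sp))
  expect_equal(f2$slope, unname(coef(g)[2]), tolerance = 1e-6)

  expect_error(pgls(tr, y[1:2], x), "3 tips")
})

test_that("predator and prey rules follow the size-ratio thresholds", {
  comm <- data.frame(
    assemblage = 1L,
    species = c("focal", "fish70", "styl140", "styl160", "nekto20",
                "sessile20", "hibb200", "eury75", "naut50"),
    max_length_cm = c(30, 70, 140, 160, 20, 20, 200, 75, 50),
    guild = c("eurypterine", "carnivorous_fish", "stylonurine", "stylonurine",
              "nektonic", "sessile", "hibbertopterid", "eurypterine",
              "nautiloid"))
  r <- classify_predators_prey(comm, "focal")
  # fish 70 > 2x30; eurypterine 75 > 60; stylonurine needs > 150: only 160;
  # nautiloid 50 fails 2x rule; hibbertopterid excluded
  expect_equal(r$n_predators, 3L)
  # prey < 15 cm among mobile benthic/nektonic: none (nekto20 too large)
  expect_equal(r$n_prey, 0L)
  expect_equal(r$n_co_eurypterids, 4L)
  expect_equal(r$size_group, "small")

  # the focal 50 cm predator: nektonic 20 < 25 counts; sessile never does
  comm2 <- data.frame(assemblage = 1L,
                      species = c("big", "nekto20", "sessile10"),
                      max_length_cm = c(50, 20, 10),
                      guild = c("eurypterine", "nektonic", "sessile"))
  r2 <- classify_predators_prey(comm2, "big")
  expect_equal(r2$n_prey, 1L)
  expect_equal(r2$size_group, "large")

  # scale consistency: multiplying every length leaves classifications fixed
  comm3 <- comm; comm3$max_length_cm <- comm3$max_length_cm * 7
  r3 <- classify_predators_prey(comm3, "focal")
  expect_equal(r3$n_predators, r$n_predators)
  expect_equal(r3$n_prey, r$n_prey)

  comm_bad <- comm; comm_bad$guild[2] <- "kraken"
  expect_error(classify_predators_prey(comm_bad, "focal"), "kraken")
})

test_that("permutational ANOVA behaves at the extremes", {
  set.seed(10)
  rec <- data.frame(n_predators = c(rnorm(20, 0), rnorm(20, 50)),
                    n_prey = c(rnorm(20, 0), rnorm(20, 50)),
                    n_co_eurypterids = rnorm(40),
                    richness = rnorm(40),
                    size_group = rep(c("small", "large"), each = 20))
  r <- permutational_anova(rec, n_perm = 1000, seed = 1)
  expect_equal(r$p_value, 1 / 1001)

  # duplicating every record: all sums of squares double, so the pseudo-F
  # changes only through its denominator degrees of freedom
  r2 <- permutational_anova(rbind(rec, rec), n_perm = 99, seed = 1)
  expect_equal(r2$F_observed * (40 - 2) / (2 * 40 - 2), r$F_observed,
               tolerance = 1e-6)

  rec_const <- rec; rec_const$richness <- 1
  expect_error(permutational_anova(rec_const), "constant")
  rec_one <- rec[rec$size_group == "small", ]
  expect_error(permutational_anova(rec_one), "two non-empty groups")
})

test_that("correlation screen flags exact and degenerate cases", {
  set.seed(11)
  rec <- data.frame(taxon = paste0("t", 1:30),
                    n_predators = rpois(30, 4),
                    n_prey = rpois(30, 6),
                    n_co_eurypterids = rpois(30, 3),
                    richness = rpois(30, 20))
  size <- setNames(rec$richness + 0.001 * rnorm(30), rec$taxon)
  out <- correlation_report(rec, size, n_perm = 199, seed = 2)
  expect_gt(out$rho[out$variable == "richness"], 0.99)

  rec$n_prey <- 5L
  expect_message(out2 <- correlation_report(rec, size, n_perm = 99, seed = 3),
                 "constant")
  expect_true(is.na(out2$rho[out2$variable == "n_prey"]))

  # independent columns rarely show strong rank correlation
  set.seed(12)
  hits <- 0
  for (r in 1:200) {
    v <- rnorm(100); w <- rnorm(100)
    if (abs(cor(v, w, method = "spearman")) < 0.3) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("pseudo-F agrees with vegan's PERMANOVA implementation", {
  set.seed(13)
  rec <- data.frame(n_predators = rpois(24, 4), n_prey = rpois(24, 6),
                    n_co_eurypterids = rpois(24, 3), richness = rpois(24, 15),
                    size_group = rep(c("small", "large"), each = 12))
  r <- permutational_anova(rec, n_perm = 99, seed = 1)
  M <- scale(as.matrix(rec[, 1:4]))
  ad <- vegan::adonis2(dist(M) ~ size_group, data = rec, permutations = 99)
  expect_equal(r$F_observed, ad$F[1], tolerance = 1e-10)
})
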