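#' Phylogenetic generalized least squares of size on a predictor
#'
#' GLS regression with residual correlation `lambda` times the off-diagonal
#' of the BM covariance (Pagel's lambda transform), a phylogenetic test of
#' Bergmann's rule when the predictor is palaeolatitude. `lambda_policy =
#' "fixed_1"` (default) uses the plain BM structure; `"ml"` profiles lambda
#' in \[0, 1\] by maximum likelihood. Taxa with missing predictor or
#' response are dropped (with a message).
#'
#' @param tree A `phylo`.
#' @param y Named response (log size, ln cm).
#' @param x Named predictor (palaeolatitude, degrees).
#' @param lambda_policy `"fixed_1"`, `"ml"`, or a numeric lambda in \[0, 1\].
#' @return List: `slope`, `intercept`, `r_squared`, `lambda_used`, `n`,
#'   `sigma2`.
#' @export
pgls <- function(tree, y, x, lambda_policy = "fixed_1") {
  common <- intersect(names(y)[is.finite(y)], names(x)[is.finite(x)])
  common <- intersect(common, tree$tip.label)
  dropped <- setdiff(tree$tip.label, common)
  if (length(dropped)) {
    message("pgls: dropping ", length(dropped), " taxa with missing data")
  }
  if (length(common) < 3) stop("fewer than 3 tips with complete data")
  tree <- prune_to_taxa(tree, common)
  y <- y[tree$tip.label]; x <- x[tree$tip.label]
  C <- bm_covariance(tree)
  fit_at <- function(lam) {
    V <- C * lam
    diag(V) <- diag(C)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    X <- cbind(intercept = 1, slope = x)
    Xw <- backsolve(R, X, transpose = TRUE)
    yw <- backsolve(R, y, transpose = TRUE)
    b <- stats::setNames(stats::lm.fit(Xw, yw)$coefficients,
                         c("intercept", "slope"))
    resid <- yw - Xw %*% b
    rss <- sum(resid^2)
    n <- length(y)
    sig2 <- rss / n
    lnL <- -0.5 * (n * log(2 * pi * sig2) + 2 * sum(log(diag(R))) + n)
    # GLS R^2 against the intercept-only GLS model
    mw <- backsolve(R, rep(1, n), transpose = TRUE)
    mu <- sum(mw * yw) / sum(mw^2)
    tss <- sum((yw - mw * mu)^2)
    list(b = b, rss = rss, tss = tss, lnL = lnL, sig2 = sig2)
  }
  lam <- if (identical(lambda_policy, "fixed_1")) 1
    else if (is.numeric(lambda_policy)) lambda_policy
    else if (identical(lambda_policy, "ml")) {
      stats::optimize(function(l) {
        f <- fit_at(l)
        if (is.null(f)) 1e10 else -f$lnL
      }, c(0, 1))$minimum
    } else stop("unknown lambda_policy")
  f <- fit_at(lam)
  if (is.null(f)) stop("singular correlation structure in pgls")
  list(slope = unname(f$b["slope"]), intercept = unname(f$b["intercept"]),
       r_squared = 1 - f$rss / f$tss, lambda_used = lam, n = length(y),
       sigma2 = f$sig2)
}

#' PGLS across a set of posterior trees
#'
#' @param trees `multiPhylo` or list of `phylo`.
#' @param y,x Named vectors as in [pgls()].
#' @param lambda_policy Passed to [pgls()].
#' @return List: `per_tree` data.frame (slope, intercept, r_squared,
#'   lambda), `median_slope`, `median_r_squared`.
#' @export
pgls_trees <- function(trees, y, x, lambda_policy = "fixed_1") {
  rows <- lapply(seq_along(trees), function(i) {
    f <- pgls(trees[[i]], y, x, lambda_policy)
    data.frame(tree = i, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, lambda = f$lambda_used)
  })
  tab <- do.call(rbind, rows)
  list(per_tree = tab, median_slope = stats::median(tab$slope),
       median_r_squared = stats::median(tab$r_squared))
}

#' Count potential predators and prey of a focal eurypterid
#'
#' Applies the community-composition rules: predators are carnivorous fish,
#' nautiloids or eurypterines longer than 2x the focal length, plus
#' stylonurines (sweep feeders) longer than 5x; hibbertopterids (suspension
#' feeders) are never predators. Prey — counted only when the focal taxon is
#' itself predatory, i.e. not a hibbertopterid — are mobile benthic or
#' nektonic species shorter than half the focal length; sessile taxa are
#' never prey.
#'
#' @param community Data.frame with columns `assemblage`, `species`,
#'   `max_length_cm`, `guild` (one of `carnivorous_fish`, `nautiloid`,
#'   `eurypterine`, `stylonurine`, `hibbertopterid`, `sessile`,
#'   `mobile_benthic`, `nektonic`).
#' @param focal_species Species name of the focal eurypterid (must be in the
#'   community table).
#' @return An ecospace record: list with `taxon`, `n_predators`, `n_prey`,
#'   `n_co_eurypterids`, `richness`, `size_group` (0.5 m threshold).
#' @export
classify_predators_prey <- function(community, focal_species) {
  guilds <- c("carnivorous_fish", "nautiloid", "eurypterine", "stylonurine",
              "hibbertopterid", "sessile", "mobile_benthic", "nektonic")
  bad <- setdiff(unique(community$guild), guilds)
  if (length(bad)) stop("unknown guild label(s): ", paste(bad, collapse = ", "))
  fi <- which(community$species == focal_species)
  if (length(fi) != 1) stop("focal species not found (or duplicated) in community")
  focal <- community[fi, ]
  eury_guilds <- c("eurypterine", "stylonurine", "hibbertopterid")
  if (!focal$guild %in% eury_guilds) stop("focal species is not a eurypterid")
  others <- community[community$assemblage == focal$assemblage &
                        community$species != focal_species, ]
  L <- focal$max_length_cm
  pred <- (others$guild %in% c("carnivorous_fish", "nautiloid", "eurypterine") &
             others$max_length_cm > 2 * L) |
          (others$guild == "stylonurine" & others$max_length_cm > 5 * L)
  focal_predatory <- focal$guild != "hibbertopterid"
  prey <- if (focal_predatory) {
    others$guild %in% c("mobile_benthic", "nektonic") &
      others$max_length_cm < 0.5 * L
  } else rep(FALSE, nrow(others))
  list(taxon = focal_species,
       n_predators = sum(pred),
       n_prey = sum(prey),
       n_co_eurypterids = sum(others$guild %in% eury_guilds),
       richness = nrow(others) + 1L,
       size_group = if (L >= 50) "large" else "small")
}

#' Ecospace records for every eurypterid in a community table
#'
#' @param community See [classify_predators_prey()].
#' @return Data.frame of ecospace records (one row per eurypterid).
#' @export
ecospace_records <- function(community) {
  eury <- community$species[community$guild %in%
                              c("eurypterine", "stylonurine", "hibbertopterid")]
  rows <- lapply(eury, function(sp) {
    as.data.frame(classify_predators_prey(community, sp),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Permutational ANOVA on ecospace occupancy
#'
#' Pseudo-F from between/within sums of squared Euclidean distances of the
#' standardized ecospace variables, with a permutation p-value
#' `p = (1 + #{F* >= F}) / (1 + n_perm)` obtained by shuffling the group
#' labels.
#'
#' @param records Data.frame of ecospace records (see [ecospace_records()]).
#' @param variables Columns used as ecospace axes (default the four counts).
#' @param group Column holding the two group labels (default `size_group`,
#'   the 0.5 m split).
#' @param n_perm Number of permutations (default 1000; minimum 99).
#' @param seed RNG seed.
#' @return List: `F_observed`, `p_value`, `n_perm`, `seed`.
#' @export
permutational_anova <- function(records,
                                variables = c("n_predators", "n_prey",
                                              "n_co_eurypterids", "richness"),
                                group = "size_group", n_perm = 1000L,
                                seed = 1L) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  g <- factor(records[[group]])
  if (nlevels(droplevels(g)) < 2) stop("need at least two non-empty groups")
  M <- as.matrix(records[, variables, drop = FALSE])
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant ecospace variable(s): ",
         paste(variables[sds == 0], collapse = ", "))
  }
  M <- scale(M)
  D2 <- as.matrix(stats::dist(M))^2
  n <- nrow(M)
  pseudo_F <- function(lab) {
    lab <- as.integer(lab)
    ss_w <- 0
    for (lv in unique(lab)) {
      idx <- which(lab == lv)
      ss_w <- ss_w + sum(D2[idx, idx]) / (2 * length(idx))
    }
    ss_t <- sum(D2) / (2 * n)
    a <- length(unique(lab))
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  F_obs <- pseudo_F(g)
  .with_seed(seed, {
    F_perm <- vapply(seq_len(n_perm), function(i) pseudo_F(sample(g)), 0)
    p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
    list(F_observed = F_obs, p_value = p, n_perm = n_perm, seed = seed)
  })
}

#' Rank correlations of size against community variables
#'
#' Spearman correlations of body size with co-occurring eurypterid count,
#' assemblage richness, predator count and prey count, each with a
#' permutation p-value. Deliberately non-phylogenetic (a preliminary
#' screen); constant covariates give NA with a message.
#'
#' @param records Ecospace records containing `taxon` plus count columns.
#' @param size Named vector of sizes (cm or ln cm) for `records$taxon`.
#' @param n_perm Permutations for the p-values.
#' @param seed RNG seed.
#' @return Data.frame: `variable`, `rho`, `p_value`, `n`.
#' @export
correlation_report <- function(records, size, n_perm = 999L, seed = 1L) {
  if (nrow(records) < 4) stop("need at least 4 records")
  s <- size[records$taxon]
  vars <- intersect(c("n_co_eurypterids", "richness", "n_predators", "n_prey"),
                    names(records))
  .with_seed(seed, {
    rows <- lapply(vars, function(v) {
      vv <- records[[v]]
      if (stats::sd(vv) == 0 || stats::sd(s) == 0) {
        message("correlation_report: '", v, "' is constant; correlation undefined")
        return(data.frame(variable = v, rho = NA_real_, p_value = NA_real_,
                          n = length(vv)))
      }
      rho <- stats::cor(s, vv, method = "spearman")
      perm <- vapply(seq_len(n_perm), function(i)
        stats::cor(s, sample(vv), method = "spearman"), 0)
      p <- (1 + sum(abs(perm) >= abs(rho))) / (1 + n_perm)
      data.frame(variable = v, rho = rho, p_value = p, n = length(vv))
    })
    do.call(rbind, rows)
  })
}
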