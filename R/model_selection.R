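#' Small-sample corrected Akaike information criterion
#'
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)`; requires `n - k - 1 > 0`.
#'
#' @param lnL Log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (tip count).
#' @return AICc value.
#' @export
aicc <- function(lnL, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n - k - 1 = ", n - k - 1)
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a set of models across a set of trees
#'
#' Runs [fit_trait_model()] for every (tree, model) pair. A fit that errors
#' is recorded as unconverged with `lnL = NA` rather than aborting the grid.
#'
#' @param trees A `multiPhylo` (or list of `phylo`).
#' @param x Named tip values.
#' @param models Character vector of model names (default all eleven).
#' @param curves Named list with elements `temp` and `oxy` (`env_curve`s) for
#'   the environment-coupled models.
#' @param regime_maps Named list with entries `OUM3_HABITAT`, `OUM2_HABITAT`,
#'   `OUM3_CRISIS`: for the habitat models a list (per tree) of
#'   `regime_map`s (one map per tree is used); for the crisis model a
#'   function `function(tree)` returning the painting, or a list per tree.
#' @param root_age_ma Absolute root age per tree (scalar or vector).
#' @param options Passed to [fit_trait_model()].
#' @return Data.frame with one row per (tree, model): `tree`, `model`,
#'   `lnL`, `k`, `n`, `AICc`, `converged`; fitted parameter lists in
#'   `attr(, "fits")`.
#' @export
fit_models_to_trees <- function(trees, x, models = trait_model_names(),
                                curves = NULL, regime_maps = NULL,
                                root_age_ma = NULL, options = list()) {
  bad <- setdiff(models, trait_model_names())
  if (length(bad)) stop("unknown model name(s): ", paste(bad, collapse = ", "))
  if (inherits(trees, "phylo")) trees <- list(trees)
  rows <- list(); fits <- list()
  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    ra <- if (is.null(root_age_ma)) NULL else
      if (length(root_age_ma) > 1) root_age_ma[ti] else root_age_ma
    for (mod in models) {
      curve <- switch(mod, ENV_OU_TEMP = curves$temp, ENV_OU_OXY = curves$oxy, NULL)
      regs <- if (mod %in% c("OUM3_HABITAT", "OUM2_HABITAT")) {
        regime_maps[[mod]][[ti]]
      } else if (mod == "OUM3_CRISIS") {
        rmc <- regime_maps$OUM3_CRISIS
        if (is.function(rmc)) rmc(tree) else rmc[[ti]]
      } else NULL
      fit <- tryCatch(
        fit_trait_model(tree, x, mod, curve = curve, regimes = regs,
                        root_age_ma = ra, options = options),
        error = function(e) NULL)
      key <- paste0("t", ti, ".", mod)
      if (is.null(fit)) {
        rows[[key]] <- data.frame(tree = ti, model = mod, lnL = NA_real_,
                                  k = NA_integer_, n = ape::Ntip(tree),
                                  AICc = NA_real_, converged = FALSE)
      } else {
        rows[[key]] <- data.frame(tree = ti, model = mod, lnL = fit$lnL,
                                  k = fit$k, n = fit$n, AICc = fit$aicc,
                                  converged = fit$converged)
        fits[[key]] <- fit
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Rank models by median AICc weight across trees
#'
#' Within each tree, AICc weights are computed over the converged fits
#' (`w_i = exp(-d_i/2) / sum_j exp(-d_j/2)`, `d` relative to the tree's best
#' model); models are then ranked by the median weight across trees (the
#' mean is reported alongside). A model that failed to converge on more than
#' half of the trees is excluded with a warning. Ties break toward fewer
#' parameters, then model name.
#'
#' @param fit_table Output of [fit_models_to_trees()] (or a data.frame with
#'   columns `tree`, `model`, `k`, `AICc`, `converged`).
#' @return Data.frame (one row per retained model) with `model`,
#'   `median_wAICc`, `mean_wAICc`, `wAICc_lo`, `wAICc_hi` (2.5/97.5%
#'   quantiles across trees), `median_AICc`, `k`, `rank`; per-tree weights
#'   in `attr(, "weights")`.
#' @export
rank_models <- function(fit_table) {
  stopifnot(all(c("tree", "model", "AICc", "converged") %in% names(fit_table)))
  models <- unique(fit_table$model)
  if (length(models) < 1) stop("no models to rank")
  trees <- unique(fit_table$tree)
  ok <- stats::aggregate(converged ~ model, fit_table, mean)
  drop <- ok$model[ok$converged < 0.5]
  if (length(drop)) {
    warning("excluded (unconverged on > 50% of trees): ",
            paste(drop, collapse = ", "))
    fit_table <- fit_table[!fit_table$model %in% drop, ]
    models <- setdiff(models, drop)
  }
  W <- matrix(NA_real_, length(trees), length(models),
              dimnames = list(trees, models))
  for (ti in seq_along(trees)) {
    sub <- fit_table[fit_table$tree == trees[ti] & fit_table$converged &
                       is.finite(fit_table$AICc), ]
    if (!nrow(sub)) next
    d <- sub$AICc - min(sub$AICc)
    w <- exp(-d / 2); w <- w / sum(w)
    W[ti, sub$model] <- w
  }
  med <- apply(W, 2, stats::median, na.rm = TRUE)
  mn <- colMeans(W, na.rm = TRUE)
  lo <- apply(W, 2, stats::quantile, 0.025, na.rm = TRUE)
  hi <- apply(W, 2, stats::quantile, 0.975, na.rm = TRUE)
  kk <- vapply(models, function(m)
    min(fit_table$k[fit_table$model == m], na.rm = TRUE), 0)
  medA <- vapply(models, function(m)
    stats::median(fit_table$AICc[fit_table$model == m], na.rm = TRUE), 0)
  out <- data.frame(model = models, median_wAICc = med[models],
                    mean_wAICc = mn[models], wAICc_lo = lo[models],
                    wAICc_hi = hi[models], median_AICc = medA,
                    k = kk, row.names = NULL)
  ord <- order(-out$median_wAICc, out$k, out$model)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "weights") <- W
  out
}

# GLS machinery under BM: root estimate and conditional node means
.bm_gls <- function(tree, x) {
  x <- .match_tips(tree, x)
  C <- bm_covariance(tree)
  n <- length(x)
  R <- chol(C)
  one <- rep(1, n)
  Ci1 <- backsolve(R, backsolve(R, one, transpose = TRUE))
  Cix <- backsolve(R, backsolve(R, x, transpose = TRUE))
  denom <- sum(one * Ci1)
  z0 <- sum(x * Ci1) / denom
  resid <- x - z0
  # REML-flavoured rate estimate for the sampling variance of the root
  sig2 <- sum(resid * backsolve(R, backsolve(R, resid, transpose = TRUE))) / (n - 1)
  list(z0 = z0, var_z0 = sig2 / denom, sig2 = sig2, C = C, R = R, x = x)
}

#' Ancestral state at the root under Brownian motion
#'
#' Generalized-least-squares estimate of the root trait value with its
#' sampling variance; the 95% CI is formed on the log scale and reported
#' back-transformed to cm.
#'
#' @param tree A `phylo`.
#' @param x Named log-size values (ln cm).
#' @return List: `estimate_ln`, `ci95_ln`, `estimate_cm`, `ci95_cm`,
#'   `se`, `sig2`.
#' @export
ancestral_root <- function(tree, x) {
  g <- .bm_gls(tree, x)
  se <- sqrt(g$var_z0)
  ci <- g$z0 + c(-1, 1) * stats::qnorm(0.975) * se
  list(estimate_ln = g$z0, ci95_ln = ci, estimate_cm = exp(g$z0),
       ci95_cm = exp(ci), se = se, sig2 = g$sig2)
}

#' Ancestral states at all internal nodes under Brownian motion
#'
#' Conditional expectations given the tips (GLS/BLUP with the root at its
#' GLS estimate): `a = z0 + S C^{-1} (x - z0)`, where `S` holds shared path
#' lengths between internal nodes and tips.
#'
#' @param tree A `phylo`.
#' @param x Named tip values.
#' @return Numeric vector over internal nodes (ape numbering, root first).
#' @export
ancestral_states_bm <- function(tree, x) {
  g <- .bm_gls(tree, x)
  nt <- ape::Ntip(tree)
  full <- ape::mrca(tree, full = TRUE)
  d <- node_depths(tree)
  S <- matrix(d[full[(nt + 1):(nt + tree$Nnode), seq_len(nt)]],
              tree$Nnode, nt)
  resid <- backsolve(g$R, backsolve(g$R, g$x - g$z0, transpose = TRUE))
  drop(g$z0 + S %*% resid)
}

#' Count independent origins of large size on a tree
#'
#' Ancestral values at internal nodes are reconstructed under BM
#' ([ancestral_states_bm()]); an origin is an edge whose parent value lies
#' below the threshold and whose child value (node or tip) reaches it.
#' Thresholds are on the log scale: `log(50)` for large (0.5 m) and
#' `log(100)` for giant (1 m).
#'
#' @param tree A `phylo`.
#' @param x Named log-size values.
#' @param threshold_ln Threshold in ln cm (default `log(50)`).
#' @return Integer count of threshold-crossing edges.
#' @export
count_size_origins <- function(tree, x, threshold_ln = log(50)) {
  x <- .match_tips(tree, x)
  anc <- ancestral_states_bm(tree, x)
  nt <- ape::Ntip(tree)
  val <- c(x, anc)                   # indexed by node id
  parent_v <- val[tree$edge[, 1]]
  child_v <- val[tree$edge[, 2]]
  sum(parent_v < threshold_ln & child_v >= threshold_ln)
}

#' Origin counts across a set of trees
#'
#' @param trees `multiPhylo` or list of `phylo`.
#' @param x Named log-size values (tips shared across trees).
#' @param threshold_ln Threshold in ln cm.
#' @return List: `counts` (per tree), `range`, `median`.
#' @export
count_size_origins_trees <- function(trees, x, threshold_ln = log(50)) {
  counts <- vapply(trees, function(tr)
    count_size_origins(tr, x[tr$tip.label], threshold_ln), 0)
  list(counts = counts, range = range(counts), median = stats::median(counts))
}
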