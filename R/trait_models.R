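#' @useDynLib palaeotrait, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- model registry ---------------------------------------------------------

#' Names of the eleven trait-evolution models
#'
#' Five gradual/punctuational models without extrinsic drivers (`BM`, `OU`,
#' `TREND`, `EB`, `KAPPA`), the Levy-type pulsed model (`PULSED`), two
#' environment-coupled OU models whose optimum tracks a curve
#' (`ENV_OU_TEMP`, `ENV_OU_OXY`), and three multi-peak OU models on painted
#' regime histories (`OUM3_HABITAT`, `OUM2_HABITAT`, `OUM3_CRISIS`).
#'
#' @return Character vector of model names.
#' @export
trait_model_names <- function() {
  c("BM", "OU", "TREND", "EB", "KAPPA", "PULSED",
    "ENV_OU_TEMP", "ENV_OU_OXY", "OUM3_HABITAT", "OUM2_HABITAT", "OUM3_CRISIS")
}

#' Free-parameter count of a trait model
#'
#' Counts are fixed so AICc values are reproducible: BM = 2 (z0, sig2);
#' TREND, EB, KAPPA = 3; OU, PULSED = 4; ENV_OU = 5; multi-peak OU with
#' shared alpha and sig2 = 3 + number of regimes; freeing per-regime rates
#' and pull strengths adds 2 per regime beyond the first.
#'
#' @param name Model name (see [trait_model_names()]).
#' @param n_regimes Number of regimes for multi-peak models.
#' @param free_rates Whether multi-peak fits free per-regime sig2 and alpha.
#' @return Integer parameter count.
#' @export
model_param_count <- function(name, n_regimes = NULL, free_rates = FALSE) {
  base <- switch(name,
    BM = 2L, TREND = 3L, EB = 3L, KAPPA = 3L, OU = 4L, PULSED = 4L,
    ENV_OU_TEMP = 5L, ENV_OU_OXY = 5L,
    OUM3_HABITAT = , OUM2_HABITAT = , OUM3_CRISIS = {
      if (is.null(n_regimes)) {
        n_regimes <- if (name == "OUM2_HABITAT") 2L else 3L
      }
      k <- 3L + n_regimes                      # z0, sig2, alpha, theta_k
      if (free_rates) k <- k + 2L * (n_regimes - 1L)
      k
    },
    stop("unknown model name: ", name, " (supported: ",
         paste(trait_model_names(), collapse = ", "), ")")
  )
  as.integer(base)
}

#' Construct a trait-model specification
#'
#' @param name Model name.
#' @param params Named list of parameters (`z0`, `sig2`, `alpha`, `theta`
#'   (scalar or per-regime vector), `mu_trend`, `r_eb`, `kappa`, `lambda_j`,
#'   `delta2`, `theta0`, `beta`, optionally per-regime `sig2_k`, `alpha_k`).
#' @param curve An `env_curve` for environment-coupled models.
#' @param regimes A `regime_map` for multi-peak models.
#' @param root_age_ma Absolute root age (Ma), required with a curve.
#' @return A `model_spec` list.
#' @export
model_spec <- function(name, params = list(), curve = NULL, regimes = NULL,
                       root_age_ma = NULL) {
  name <- match.arg(name, trait_model_names())
  chk <- function(p, ok, what) {
    if (!is.null(params[[p]]) && !all(ok(params[[p]])))
      stop("parameter ", p, " ", what)
  }
  chk("sig2", function(v) v >= 0, "must be >= 0")
  chk("delta2", function(v) v >= 0, "must be >= 0")
  chk("alpha", function(v) v >= 0, "must be >= 0")
  chk("lambda_j", function(v) v >= 0, "must be >= 0")
  chk("kappa", function(v) v >= 0, "must be >= 0")
  structure(list(name = name, params = params, curve = curve,
                 regimes = regimes, root_age_ma = root_age_ma),
            class = "model_spec")
}

# ---- shared numerics --------------------------------------------------------

# log density of x ~ MVN(mean, V) via Cholesky; errors on singular V
.dmvnorm_chol <- function(x, mean, V) {
  R <- tryCatch(chol(V), error = function(e)
    stop("singular covariance: ", conditionMessage(e),
         " (degenerate parameters or duplicated tips)", call. = FALSE))
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

# order a named trait vector to the tree's tips
.match_tips <- function(tree, x) {
  if (is.null(names(x))) {
    if (length(x) != ape::Ntip(tree)) stop("trait vector length != number of tips")
    return(x)
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop("tip(s) missing trait values: ", paste(miss, collapse = ", "))
  x[tree$tip.label]
}

# stable (1 - exp(-a)) helper
.omexp <- function(a) -expm1(-a)

# OU covariance (unit sig2) for shared alpha on a possibly non-ultrametric
# tree with fixed (non-stationary) root:
#   V_ij = exp(-alpha (T_i + T_j - 2 t_a)) * (1 - exp(-2 alpha t_a)) / (2 alpha)
.ou_cov_unit <- function(C, Tt, alpha) {
  if (alpha < 1e-12) return(C)
  E <- exp(-alpha * (outer(Tt, Tt, "+") - 2 * C))
  V <- E * .omexp(2 * alpha * C) / (2 * alpha)
  (V + t(V)) / 2
}

# ---- Gaussian model moments -------------------------------------------------

# unit-rate covariance V0 and mean design matrix X for the profiled models;
# mean = X %*% b where b are the linear parameters (z0 and friends)
.gaussian_structure <- function(tree, ctx, name, shape) {
  C <- ctx$C; Tt <- ctx$T
  switch(name,
    BM = list(V0 = C, X = matrix(1, ctx$n, 1), bnames = "z0"),
    TREND = list(V0 = C, X = cbind(z0 = 1, mu_trend = Tt),
                 bnames = c("z0", "mu_trend")),
    EB = {
      r <- shape
      V0 <- if (abs(r) < 1e-12) C else {
        V <- expm1(r * C) / r
        diag(V) <- expm1(r * Tt) / r
        V
      }
      list(V0 = V0, X = matrix(1, ctx$n, 1), bnames = "z0")
    },
    KAPPA = {
      tk <- tree
      tk$edge.length <- tree$edge.length^shape
      list(V0 = ape::vcv.phylo(tk), X = matrix(1, ctx$n, 1), bnames = "z0")
    },
    OU = {
      a <- shape
      ph <- exp(-a * Tt)
      list(V0 = .ou_cov_unit(C, Tt, a), X = cbind(z0 = ph, theta = 1 - ph),
           bnames = c("z0", "theta"))
    },
    stop("no Gaussian structure for model ", name)
  )
}

.shape_of <- function(name, params) {
  switch(name, EB = params$r_eb, KAPPA = params$kappa, OU = params$alpha, NULL)
}

.linear_of <- function(name, params) {
  switch(name,
    BM = , EB = , KAPPA = params$z0,
    TREND = c(params$z0, params$mu_trend),
    OU = c(params$z0, params$theta))
}

#' Log-likelihood of the simple Gaussian models (BM, OU, TREND, EB, KAPPA)
#'
#' Computes the exact multivariate-normal log-density of the tip values under
#' the model: BM has mean `z0` and covariance `sig2 * C` (C the shared
#' path-length matrix); TREND adds a drift `mu_trend` times root-to-tip time
#' to the mean; EB integrates an exponentially time-varying rate
#' `sig2 * exp(r_eb t)` along branches; KAPPA raises each branch length to
#' the power `kappa` before building C; OU uses the fixed-root
#' (non-stationary) covariance, valid on non-ultrametric trees.
#'
#' @param tree A `phylo`.
#' @param x Named numeric tip values (ln cm).
#' @param spec A [model_spec()] with complete parameters.
#' @return Log-likelihood (scalar).
#' @export
loglik_gaussian <- function(tree, x, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$name %in% c("BM", "OU", "TREND", "EB", "KAPPA")) {
    stop("loglik_gaussian handles BM/OU/TREND/EB/KAPPA, not ", spec$name)
  }
  x <- .match_tips(tree, x)
  ctx <- .model_ctx(tree)
  st <- .gaussian_structure(tree, ctx, spec$name, .shape_of(spec$name, spec$params))
  b <- .linear_of(spec$name, spec$params)
  .dmvnorm_chol(x, drop(st$X %*% b), spec$params$sig2 * st$V0)
}

.model_ctx <- function(tree) {
  C <- bm_covariance(tree)
  n <- ape::Ntip(tree)
  list(C = C, T = diag(C), n = n)
}

# ---- environment-coupled OU -------------------------------------------------

# per-tip design columns for ENV_OU: mean_i = z0 a_i + theta0 b_i + beta K_i,
# a = exp(-alpha T), b = 1 - a, K_i = int_0^Ti alpha e^{-alpha (Ti - s)} E(s) ds
# with E piecewise-linear at `step` Myr resolution along each branch
.env_ou_design <- function(tree, curve, alpha, root_age_ma, step = 0.25) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  depth <- node_depths(tree)
  if (root_age_ma - max(depth) < curve$range[1] - 1e-9 ||
      root_age_ma > curve$range[2] + 1e-9) {
    stop("tree placed at root_age_ma = ", root_age_ma,
         " extends outside the curve range [", curve$range[1], ", ",
         curve$range[2], "] Ma")
  }
  K <- numeric(nn)
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  elen <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; ch <- edges[e, 2]; s <- elen[e]
    m <- max(1L, ceiling(s / step)); h <- s / m
    d0 <- depth[par]
    ages <- root_age_ma - (d0 + h * (0:m))
    Ev <- env_value_at(curve, ages)
    one <- .omexp(alpha * h)
    ramp <- h - one / alpha            # int_0^h alpha e^{-a(h-u)} u du
    slopes <- diff(Ev) / h
    contrib <- Ev[seq_len(m)] * one + slopes * ramp
    # unroll the per-substep linear recursion K <- K e^{-a h} + contrib_j
    K[ch] <- K[par] * exp(-alpha * s) +
      sum(contrib * exp(-alpha * h * (m - seq_len(m))))
  }
  K[seq_len(nt)]
}

#' Log-likelihood of the environment-coupled OU model
#'
#' OU with a non-stationary optimum that tracks an environmental curve
#' linearly: theta(t) = theta0 + beta * E(t). The tip means integrate the OU
#' mean ODE along each root-to-tip path treating the curve as
#' piecewise-linear at 0.25 Myr resolution; the covariance is that of
#' fixed-root OU. `beta = 0` collapses exactly to standard OU.
#'
#' @param tree A `phylo`.
#' @param x Named tip values.
#' @param spec A [model_spec()] with params `z0, sig2, alpha, theta0, beta`,
#'   a `curve` and `root_age_ma`.
#' @return Log-likelihood.
#' @export
loglik_env_ou <- function(tree, x, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(spec$curve)) stop("ENV_OU model needs an attached env_curve")
  if (is.null(spec$root_age_ma)) stop("ENV_OU model needs root_age_ma")
  x <- .match_tips(tree, x)
  ctx <- .model_ctx(tree)
  p <- spec$params
  a <- max(p$alpha, 1e-10)
  ph <- exp(-a * ctx$T)
  K <- .env_ou_design(tree, spec$curve, a, spec$root_age_ma)
  mean <- p$z0 * ph + p$theta0 * (1 - ph) + p$beta * K
  .dmvnorm_chol(x, mean, p$sig2 * .ou_cov_unit(ctx$C, ctx$T, a))
}

# ---- multi-peak OU on a regime painting -------------------------------------

# Per-node quantities on a painted tree with per-regime alpha/sig2:
#   lphi  : log of exp(-int alpha dt) from root (mean/cov discount), kept in
#           log space so deep strong-pull paths do not underflow in ratios
#   coefs : mean = coefs %*% c(z0, theta_1..theta_m) per node
#   v     : variance accumulated from the (fixed) root
# Segment order in map entries is rootward -> tipward.
.oum_node_moments <- function(rmap, regimes, alpha_k, sig2_k) {
  tree <- rmap$tree
  nt <- ape::Ntip(tree); nn <- nt + tree$Nnode
  m <- length(regimes)
  lphi <- numeric(nn); v <- numeric(nn)
  coefs <- matrix(0, nn, m + 1)
  root <- nt + 1L
  coefs[root, 1] <- 1
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(po$edge)))
  edge_index <- .map_edge_index(rmap, po)
  for (e in ord) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    segs <- rmap$maps[[edge_index[e]]]
    lph <- lphi[par]; vv <- v[par]; cf <- coefs[par, ]
    for (j in seq_along(segs)) {
      reg <- names(segs)[j]; s <- segs[[j]]
      k <- match(reg, regimes)
      if (is.na(k)) stop("unpainted or unknown regime '", reg, "' on edge ",
                         par, "->", ch)
      a <- alpha_k[k]; s2 <- sig2_k[k]
      if (a < 1e-12) {
        # BM limit: no decay, the optimum does not pull
        vv <- vv + s2 * s
      } else {
        d <- exp(-a * s)
        vv <- vv * d^2 + s2 * .omexp(2 * a * s) / (2 * a)
        lph <- lph - a * s
        cf <- cf * d
        cf[k + 1] <- cf[k + 1] + .omexp(a * s)
      }
    }
    lphi[ch] <- lph; v[ch] <- vv; coefs[ch, ] <- cf
  }
  list(lphi = lphi, v = v, coefs = coefs)
}

# map entries are stored in the tree's own edge order; translate postorder
# edge rows back to that order
.map_edge_index <- function(rmap, po) {
  key <- paste(rmap$tree$edge[, 1], rmap$tree$edge[, 2])
  match(paste(po$edge[, 1], po$edge[, 2]), key)
}

#' Log-likelihood of a multi-peak OU model on a painted tree
#'
#' Regimes painted on the tree (from stochastic character maps or the
#' extinction-crisis painting) evolve toward distinct optima `theta_k`;
#' optionally the diffusion rate `sig2_k` and pull strength `alpha_k` also
#' differ among regimes. Means, variances and the between-tip covariance are
#' accumulated segment by segment along the painting, with the root value a
#' free parameter `z0` (not forced to the root regime's optimum).
#'
#' @param regimes A `regime_map` (see [stochastic_map()],
#'   [paint_crisis_regimes()]).
#' @param x Named tip values.
#' @param spec A [model_spec()] with `z0`, `theta` (vector named by regime),
#'   and either shared `sig2`, `alpha` or per-regime `sig2_k`, `alpha_k`.
#' @return Log-likelihood.
#' @export
loglik_oum <- function(regimes, x, spec) {
  stopifnot(inherits(regimes, "regime_map"), inherits(spec, "model_spec"))
  tree <- regimes$tree
  x <- .match_tips(tree, x)
  p <- spec$params
  regs <- regime_states(regimes)
  theta <- p$theta
  if (is.null(names(theta))) {
    if (length(theta) != length(regs)) stop("theta length != number of regimes")
    names(theta) <- regs
  }
  miss <- setdiff(regs, names(theta))
  if (length(miss)) stop("theta missing for regime(s): ", paste(miss, collapse = ", "))
  m <- length(regs)
  alpha_k <- if (!is.null(p$alpha_k)) p$alpha_k[regs] else rep(p$alpha, m)
  sig2_k <- if (!is.null(p$sig2_k)) p$sig2_k[regs] else rep(p$sig2, m)
  mom <- .oum_node_moments(regimes, regs, alpha_k, sig2_k)
  nt <- ape::Ntip(tree)
  b <- c(p$z0, theta[regs])
  mean <- drop(mom$coefs[seq_len(nt), , drop = FALSE] %*% b)
  M <- ape::mrca(tree, full = FALSE)
  Vm <- matrix(mom$v[M], nt, nt)
  Lm <- matrix(mom$lphi[M], nt, nt)
  lphit <- mom$lphi[seq_len(nt)]
  V <- Vm * exp(outer(lphit, lphit, "+") - 2 * Lm)
  diag(V) <- mom$v[seq_len(nt)]
  V <- (V + t(V)) / 2
  names(mean) <- tree$tip.label
  .dmvnorm_chol(x, mean, V)
}

# ---- pulsed (BM + compound-Poisson jumps) -----------------------------------

#' Log-likelihood of the pulsed (Levy jump-diffusion) model
#'
#' Brownian motion plus compound-Poisson normal jumps: along a branch of
#' length t the displacement is Gaussian with variance `sig2 * t + delta2 * k`
#' where `k ~ Poisson(lambda_j * t)` is the number of jumps. The likelihood
#' is computed by pruning with Gaussian-mixture messages: per-branch Poisson
#' counts are truncated at tail mass below `tail_tol`, components below a
#' relative weight of `weight_tol` are dropped, and near-identical components
#' merged. `lambda_j = 0` or `delta2 = 0` reduces exactly to BM.
#'
#' @param tree A `phylo`.
#' @param x Named tip values.
#' @param spec A [model_spec()] with params `z0, sig2, lambda_j, delta2`.
#' @param max_components Component cap per message; denser messages are
#'   reduced by moment-preserving collapse on a (mean, log-variance) grid,
#'   which conserves mixture mass (accuracy, not mass, improves with the
#'   cap).
#' @param tail_tol Poisson truncation tail mass (default 1e-10).
#' @param weight_tol Relative weight below which components are pruned.
#' @return Log-likelihood.
#' @export
loglik_pulsed <- function(tree, x, spec, max_components = 4096L,
                          tail_tol = 1e-10, weight_tol = 1e-12) {
  stopifnot(inherits(spec, "model_spec"))
  p <- spec$params
  if (p$lambda_j < 0 || p$delta2 < 0) stop("lambda_j and delta2 must be >= 0")
  x <- .match_tips(tree, x)
  po <- ape::reorder.phylo(tree, "postorder")
  res <- pulsed_prune(po$edge, po$edge.length, ape::Ntip(tree), tree$Nnode,
                      as.numeric(x), p$z0, p$sig2, p$lambda_j, p$delta2,
                      as.integer(max_components), tail_tol, weight_tol, FALSE)
  res[1]
}

# ---- dispatcher -------------------------------------------------------------

#' Log-likelihood of any of the eleven trait models
#'
#' Dispatches on `spec$name` to [loglik_gaussian()], [loglik_pulsed()],
#' [loglik_env_ou()] or [loglik_oum()].
#'
#' @param tree A `phylo` (ignored for multi-peak models, whose `spec$regimes`
#'   carries the painted tree).
#' @param x Named tip values.
#' @param spec A [model_spec()].
#' @return Log-likelihood.
#' @export
trait_loglik <- function(tree, x, spec) {
  switch(spec$name,
    BM = , OU = , TREND = , EB = , KAPPA = loglik_gaussian(tree, x, spec),
    PULSED = loglik_pulsed(tree, x, spec),
    ENV_OU_TEMP = , ENV_OU_OXY = loglik_env_ou(tree, x, spec),
    OUM3_HABITAT = , OUM2_HABITAT = , OUM3_CRISIS =
      loglik_oum(spec$regimes, x, spec))
}
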