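# run code under a local, seeded RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# profiled Gaussian ML: x ~ MVN(X b, sig2 * V0); returns ML b, sig2 and lnL
.profile_gaussian <- function(x, X, V0, sig2_bounds = c(1e-8, 1e4)) {
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  ld <- sum(log(diag(R)))
  if (!is.finite(ld)) return(NULL)
  Xw <- backsolve(R, X, transpose = TRUE)
  xw <- backsolve(R, x, transpose = TRUE)
  fit <- tryCatch(stats::lm.fit(Xw, xw), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  b <- fit$coefficients
  if (anyNA(b)) b[is.na(b)] <- 0
  rss <- sum((xw - Xw %*% b)^2)
  n <- length(x)
  sig2 <- min(max(rss / n, sig2_bounds[1]), sig2_bounds[2])
  lnL <- -0.5 * (n * log(2 * pi * sig2) + 2 * ld + rss / sig2)
  list(lnL = lnL, b = drop(b), sig2 = sig2)
}

# multi-start bounded local optimization; f is the objective (negative
# profile log-likelihood), box given by lower/upper; starts drawn by Latin
# hypercube plus caller-supplied warm starts
.multi_start <- function(f, lower, upper, n_restarts, warm = NULL,
                         control = list(iter.max = 500, eval.max = 1000)) {
  d <- length(lower)
  starts <- matrix(numeric(0), 0, d)
  if (!is.null(warm)) starts <- rbind(starts, matrix(warm, ncol = d, byrow = TRUE))
  if (n_restarts > 0) {
    u <- lhs::randomLHS(n_restarts, d)
    starts <- rbind(starts, sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+"))
  }
  best <- NULL
  n_used <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::nlminb(starts[i, ], f, lower = lower, upper = upper,
                    control = control),
      error = function(e) NULL)
    n_used <- n_used + 1L
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (!is.null(best)) {
    best$n_restarts_used <- n_used
    # nlminb's "false/singular convergence" flags a flat neighbourhood of
    # the optimum (common at parameter bounds); the point is still a
    # usable local maximum
    best$ok <- best$convergence == 0 ||
      grepl("false convergence|singular convergence", best$message)
  }
  best
}

.PENALTY <- 1e10

#' Fit a trait-evolution model by maximum likelihood
#'
#' Maximizes the model's log-likelihood over its parameters. Linear mean
#' parameters (root state `z0`, optima, drift, the environmental slope
#' `beta`) and the overall rate `sig2` are profiled out analytically by
#' generalized least squares, so only the shape parameters (`alpha`,
#' `kappa`, `r_eb`, jump parameters) are searched numerically, by bounded
#' multi-start local optimization seeded from Latin-hypercube draws.
#' Deterministic given `options$seed`.
#'
#' Search bounds: `sig2`, `delta2` in \[1e-8, 1e4\]; `alpha` in
#' \[1e-8, 1e2\]; `kappa` in \[0, 3\]; `lambda_j` in \[0, 10\];
#' `r_eb` in \[-2, 2\].
#'
#' @param tree A `phylo`.
#' @param x Named tip values (ln cm).
#' @param name Model name (see [trait_model_names()]).
#' @param curve `env_curve` for environment-coupled models.
#' @param regimes `regime_map` for multi-peak models.
#' @param root_age_ma Absolute root age, required with a curve.
#' @param options List: `n_restarts` (default 10), `seed` (default 1),
#'   `oum_free_rates` (default FALSE: multi-peak fits share `sig2` and
#'   `alpha` across regimes).
#' @return A `trait_fit`: list with `model`, `params`, `lnL`, `k`, `n`,
#'   `aicc`, `converged`, `n_restarts_used`, `seed`.
#' @export
fit_trait_model <- function(tree, x, name, curve = NULL, regimes = NULL,
                            root_age_ma = NULL, options = list()) {
  name <- match.arg(name, trait_model_names())
  opts <- utils::modifyList(list(n_restarts = 10L, seed = 1L,
                                 oum_free_rates = FALSE), options)
  if (name %in% c("OUM3_HABITAT", "OUM2_HABITAT", "OUM3_CRISIS")) {
    if (is.null(regimes)) stop(name, " requires a regime_map (regimes =)")
    tree <- regimes$tree
  }
  if (name %in% c("ENV_OU_TEMP", "ENV_OU_OXY")) {
    if (is.null(curve)) stop(name, " requires an environmental curve (curve =)")
    if (is.null(root_age_ma)) stop(name, " requires root_age_ma")
  }
  x <- .match_tips(tree, x)
  ctx <- .model_ctx(tree)
  n <- ctx$n
  nreg <- if (!is.null(regimes)) length(regime_states(regimes)) else NULL
  k <- model_param_count(name, n_regimes = nreg, free_rates = isTRUE(opts$oum_free_rates))
  if (name == "TREND" && diff(range(ctx$T)) < 1e-8 * max(ctx$T)) {
    stop("TREND is not identifiable on an ultrametric tree ",
         "(confounded with the root state); fit refused")
  }
  if (n - k - 1 <= 0) {
    stop("AICc undefined: n - k - 1 = ", n - k - 1, " for model ", name,
         " with n = ", n, " tips")
  }
  fit <- .with_seed(opts$seed, .fit_dispatch(tree, x, name, ctx, curve, regimes,
                                             root_age_ma, opts))
  structure(c(fit, list(model = name, k = k, n = n,
                        aicc = aicc(fit$lnL, k, n), seed = opts$seed)),
            class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat("<trait_fit> ", x$model, ": lnL = ", format(x$lnL, digits = 6),
      ", k = ", x$k, ", n = ", x$n, ", AICc = ", format(x$aicc, digits = 6),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  p <- unlist(x$params)
  cat("  ", paste(names(p), signif(p, 4), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

.fit_dispatch <- function(tree, x, name, ctx, curve, regimes, root_age_ma, opts) {
  switch(name,
    BM = , TREND = .fit_closed(tree, x, name, ctx),
    EB = .fit_shape1(tree, x, name, ctx, bounds = c(-2, 2), log_scale = FALSE, opts = opts),
    KAPPA = .fit_shape1(tree, x, name, ctx, bounds = c(0, 3), log_scale = FALSE, opts = opts),
    OU = .fit_shape1(tree, x, name, ctx, bounds = c(1e-8, 1e2), log_scale = TRUE, opts = opts),
    ENV_OU_TEMP = , ENV_OU_OXY = .fit_env_ou(tree, x, name, ctx, curve, root_age_ma, opts),
    OUM3_HABITAT = , OUM2_HABITAT = , OUM3_CRISIS =
      .fit_oum(tree, x, name, ctx, regimes, opts),
    PULSED = .fit_pulsed(tree, x, ctx, opts))
}

.fit_closed <- function(tree, x, name, ctx) {
  st <- .gaussian_structure(tree, ctx, name, NULL)
  pr <- .profile_gaussian(x, st$X, st$V0)
  if (is.null(pr)) stop("singular covariance in ", name, " fit")
  params <- as.list(stats::setNames(pr$b, st$bnames))
  params$sig2 <- pr$sig2
  list(params = params, lnL = pr$lnL, converged = TRUE, n_restarts_used = 0L)
}

.fit_shape1 <- function(tree, x, name, ctx, bounds, log_scale, opts) {
  obj <- function(s) {
    shape <- if (log_scale) exp(s) else s
    st <- .gaussian_structure(tree, ctx, name, shape)
    pr <- .profile_gaussian(x, st$X, st$V0)
    if (is.null(pr) || !is.finite(pr$lnL)) return(.PENALTY)
    -pr$lnL
  }
  b <- if (log_scale) log(bounds) else bounds
  warm <- if (log_scale) log(sqrt(prod(bounds))) else mean(bounds)
  best <- .multi_start(obj, b[1], b[2], opts$n_restarts, warm = warm)
  if (is.null(best)) stop("optimization failed for ", name)
  shape <- if (log_scale) exp(best$par) else best$par
  st <- .gaussian_structure(tree, ctx, name, shape)
  pr <- .profile_gaussian(x, st$X, st$V0)
  params <- as.list(stats::setNames(pr$b, st$bnames))
  params$sig2 <- pr$sig2
  params[[switch(name, EB = "r_eb", KAPPA = "kappa", OU = "alpha")]] <- shape
  list(params = params, lnL = pr$lnL, converged = isTRUE(best$ok),
       n_restarts_used = best$n_restarts_used)
}

.fit_env_ou <- function(tree, x, name, ctx, curve, root_age_ma, opts) {
  if (is.null(curve)) stop(name, " requires an environmental curve (curve =)")
  if (is.null(root_age_ma)) stop(name, " requires root_age_ma")
  # search on a piecewise-linear tabulation of the curve at the 0.25 Myr
  # interpolation step (the likelihood treats the curve piecewise-linearly
  # at that step anyway); the optimum is re-evaluated on the exact spline
  grid <- resample_curve(curve, 0.25)
  fast <- curve
  fast$fit <- stats::approxfun(grid$age_ma, grid$value, rule = 2)
  eval_at <- function(a, cv) {
    ph <- exp(-a * ctx$T)
    K <- .env_ou_design(tree, cv, a, root_age_ma)
    st <- list(V0 = .ou_cov_unit(ctx$C, ctx$T, a),
               X = cbind(z0 = ph, theta0 = 1 - ph, beta = K))
    pr <- .profile_gaussian(x, st$X, st$V0)
    list(pr = pr)
  }
  obj <- function(s) {
    pr <- eval_at(exp(s), fast)$pr
    if (is.null(pr) || !is.finite(pr$lnL)) return(.PENALTY)
    -pr$lnL
  }
  best <- .multi_start(obj, log(1e-8), log(1e2), opts$n_restarts, warm = log(1e-3))
  if (is.null(best)) stop("optimization failed for ", name)
  alpha <- exp(best$par)
  pr <- eval_at(alpha, curve)$pr
  params <- list(z0 = pr$b[[1]], theta0 = pr$b[[2]], beta = pr$b[[3]],
                 sig2 = pr$sig2, alpha = alpha)
  list(params = params, lnL = pr$lnL, converged = isTRUE(best$ok),
       n_restarts_used = best$n_restarts_used)
}

.fit_oum <- function(tree, x, name, ctx, regimes, opts) {
  regs <- regime_states(regimes)
  m <- length(regs)
  free <- isTRUE(opts$oum_free_rates)
  M <- ape::mrca(tree)
  eval_at <- function(shape) {
    alpha_k <- rep(exp(shape[1]), m)
    ratio <- rep(1, m)
    if (free) {
      alpha_k <- exp(shape[seq_len(m)])
      ratio <- c(1, exp(shape[m + seq_len(m - 1)]))
    }
    mom <- .oum_node_moments(regimes, regs, alpha_k, ratio)
    nt <- ctx$n
    Vm <- matrix(mom$v[M], nt, nt)
    Lm <- matrix(mom$lphi[M], nt, nt)
    lphit <- mom$lphi[seq_len(nt)]
    V0 <- Vm * exp(outer(lphit, lphit, "+") - 2 * Lm)
    diag(V0) <- mom$v[seq_len(nt)]
    X <- mom$coefs[seq_len(nt), , drop = FALSE]
    colnames(X) <- c("z0", regs)
    .profile_gaussian(x, X, (V0 + t(V0)) / 2)
  }
  d <- if (free) 2L * m - 1L else 1L
  lower <- c(rep(log(1e-8), if (free) m else 1), rep(log(1e-3), if (free) m - 1 else 0))
  upper <- c(rep(log(1e2), if (free) m else 1), rep(log(1e3), if (free) m - 1 else 0))
  obj <- function(s) {
    pr <- eval_at(s)
    if (is.null(pr) || !is.finite(pr$lnL)) return(.PENALTY)
    -pr$lnL
  }
  warm <- c(rep(log(1e-2), if (free) m else 1), rep(0, if (free) m - 1 else 0))
  best <- .multi_start(obj, lower, upper, opts$n_restarts, warm = warm)
  if (is.null(best)) stop("optimization failed for ", name)
  pr <- eval_at(best$par)
  theta <- stats::setNames(pr$b[-1], regs)
  params <- list(z0 = pr$b[[1]], theta = theta, sig2 = pr$sig2,
                 alpha = exp(best$par[1]))
  if (free) {
    params$alpha_k <- stats::setNames(exp(best$par[seq_len(m)]), regs)
    params$sig2_k <- stats::setNames(pr$sig2 * c(1, exp(best$par[m + seq_len(m - 1)])), regs)
    params$alpha <- NULL
  }
  list(params = params, lnL = pr$lnL, converged = isTRUE(best$ok),
       n_restarts_used = best$n_restarts_used)
}

.fit_pulsed <- function(tree, x, ctx, opts) {
  # root state is profiled inside the mixture kernel, so the numerical
  # search runs over (log sig2, lambda_j, log delta2) only; a coarse
  # component cap steers the search and the optimum is re-evaluated at a
  # fine cap
  bm <- .profile_gaussian(x, matrix(1, ctx$n, 1), ctx$C)
  depth <- max(ctx$T)
  po <- ape::reorder.phylo(tree, "postorder")
  nt <- ape::Ntip(tree)
  ev <- function(p, cap) {
    pulsed_prune(po$edge, po$edge.length, nt, tree$Nnode, as.numeric(x),
                 0, exp(p[1]), p[2], exp(p[3]), as.integer(cap),
                 1e-10, 1e-12, TRUE)
  }
  obj <- function(p) {
    ll <- ev(p, 128L)[1]
    if (!is.finite(ll)) return(.PENALTY)
    -ll
  }
  lower <- c(log(1e-8), 0, log(1e-8))
  upper <- c(log(1e4), 10, log(1e4))
  warm <- rbind(
    c(log(bm$sig2), 1e-6, log(max(bm$sig2, 1e-6))),
    c(log(bm$sig2 / 4), 2 / depth, log(max(bm$sig2 * depth / 4, 1e-6))),
    c(log(bm$sig2 / 10), 5 / depth, log(max(bm$sig2 * depth / 10, 1e-6))))
  n_lhs <- min(opts$n_restarts, 4L)
  best <- .multi_start(obj, lower, upper, n_lhs, warm = warm,
                       control = list(iter.max = 200, eval.max = 500,
                                      rel.tol = 1e-7))
  if (is.null(best)) stop("optimization failed for PULSED")
  p <- best$par
  fine <- ev(p, 1024L)
  params <- list(z0 = fine[3], sig2 = exp(p[1]), lambda_j = p[2],
                 delta2 = exp(p[3]))
  list(params = params, lnL = fine[1], converged = isTRUE(best$ok),
       n_restarts_used = best$n_restarts_used)
}
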