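# ---- regime maps ------------------------------------------------------------

#' Construct a regime map (piecewise-constant painting of a tree)
#'
#' A regime map carries, for every edge of the tree, an ordered list of
#' (length, regime) segments running rootward to tipward, whose lengths sum
#' to the edge length. Character maps additionally satisfy continuity: a
#' branch's first segment starts in the state in which its parent branch
#' ended.
#'
#' @param tree A `phylo`.
#' @param maps List (one element per row of `tree$edge`) of named numeric
#'   vectors: values are segment lengths (Myr), names are regime labels.
#' @param node_state Optional character vector of the regime at each node.
#' @param states Regime alphabet in canonical order (defaults to the labels
#'   seen, in order of first appearance).
#' @return An object of class `regime_map`.
#' @export
regime_map <- function(tree, maps, node_state = NULL, states = NULL) {
  if (length(maps) != nrow(tree$edge)) stop("need one map entry per edge")
  sums <- vapply(maps, sum, 0)
  bad <- which(abs(sums - tree$edge.length) > 1e-9)
  if (length(bad)) {
    stop("segment lengths do not sum to branch length on edge row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (is.null(states)) {
    states <- unique(unlist(lapply(maps, names)))
  }
  structure(list(tree = tree, maps = maps, node_state = node_state,
                 states = states),
            class = "regime_map")
}

#' Regime alphabet of a regime map
#' @param rmap A `regime_map`.
#' @return Character vector of regime labels in canonical order.
#' @export
regime_states <- function(rmap) rmap$states

#' @export
print.regime_map <- function(x, ...) {
  cat("<regime_map> ", ape::Ntip(x$tree), " tips, regimes: ",
      paste(x$states, collapse = ", "), "; ",
      sum(vapply(x$maps, length, 0L) - 1L), " transition(s)\n", sep = "")
  invisible(x)
}

#' Total number of regime transitions in a map
#' @param rmap A `regime_map`.
#' @return Integer count of within-branch regime changes.
#' @export
n_transitions <- function(rmap) {
  sum(vapply(rmap$maps, function(m) length(m) - 1L, 0L))
}

#' Write a regime map as a segment table
#'
#' One row per segment: edge endpoints, segment index (rootward first),
#' regime and length.
#'
#' @param rmap A `regime_map`.
#' @param path Output CSV path (optional).
#' @return The segment table data.frame, invisibly if written.
#' @export
regime_segment_table <- function(rmap, path = NULL) {
  rows <- lapply(seq_along(rmap$maps), function(e) {
    m <- rmap$maps[[e]]
    data.frame(parent = rmap$tree$edge[e, 1], child = rmap$tree$edge[e, 2],
               segment = seq_along(m), regime = names(m),
               length_myr = as.numeric(m))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Write a regime map in simmap-extended Newick
#'
#' Branch annotations of the form `{state,length:state,length}` (rootward
#' segment first) replace plain branch lengths.
#'
#' @param rmap A `regime_map`.
#' @param path Output file path.
#' @export
write_regime_map <- function(rmap, path) {
  tree <- rmap$tree
  nt <- ape::Ntip(tree)
  edge_of <- integer(nt + tree$Nnode)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  lab <- function(node) {
    core <- if (node <= nt) tree$tip.label[node] else {
      paste0("(", paste(vapply(kids[[as.character(node)]], lab, ""),
                        collapse = ","), ")")
    }
    e <- edge_of[node]
    if (e == 0) return(core)
    m <- rmap$maps[[e]]
    paste0(core, ":{", paste(names(m), format(as.numeric(m), digits = 12),
                             sep = ",", collapse = ":"), "}")
  }
  writeLines(paste0(lab(nt + 1L), ";"), path)
  invisible(path)
}

# ---- Mk model machinery -----------------------------------------------------

#' Build a Mk rate matrix from off-diagonal rates
#'
#' @param rates Numeric vector of off-diagonal rates, row-major over ordered
#'   state pairs (for 3 states: 1->2, 1->3, 2->1, 2->3, 3->1, 3->2).
#' @param states State labels.
#' @return A rate matrix with rows summing to zero.
#' @export
make_q_matrix <- function(rates, states = habitat_states()) {
  k <- length(states)
  if (length(rates) != k * (k - 1)) stop("need k(k-1) off-diagonal rates")
  if (any(rates < 0)) stop("rates must be >= 0")
  Q <- matrix(0, k, k, dimnames = list(states, states))
  idx <- 1L
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    Q[i, j] <- rates[idx]; idx <- idx + 1L
  }
  diag(Q) <- -rowSums(Q)
  Q
}

.validate_q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be square")
  if (any(Q[row(Q) != col(Q)] < 0)) stop("off-diagonal rates must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("Q rows must sum to 0")
  invisible(Q)
}

# eigen-decomposition transition probabilities P(t) for many t at once
# (complex-safe: non-reversible Q can have complex eigenvalues); falls back
# to uniformization when Q is defective (repeated eigenvalues, e.g. sparse
# structures visited by the reversible-jump sampler)
.mk_pmats <- function(Q, times) {
  k <- nrow(Q)
  eg <- eigen(Q)
  Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
  if (is.null(Vi)) return(.mk_pmats_unif(Q, times))
  V <- eg$vectors
  Pflat <- matrix(0i, k * k, length(times))
  for (a in seq_len(k)) {
    Pflat <- Pflat + as.vector(V[, a] %o% Vi[a, ]) %o% exp(eg$values[a] * times)
  }
  P <- array(Re(Pflat), c(k, k, length(times)))
  # defective or ill-conditioned decompositions show up as broken stochastic
  # rows; recompute by uniformization in that case
  rows_ok <- max(abs(apply(P, 3, rowSums) - 1)) < 1e-8 && min(P) > -1e-8
  if (!is.finite(max(P)) || !rows_ok) return(.mk_pmats_unif(Q, times))
  P[P < 0] <- 0
  P
}

# uniformization series P(t) = e^{-Om t} sum (Om t)^n / n! R^n
.mk_pmats_unif <- function(Q, times) {
  k <- nrow(Q)
  Om <- max(-diag(Q))
  P <- array(0, c(k, k, length(times)))
  if (Om <= 0) {
    for (ti in seq_along(times)) P[, , ti] <- diag(k)
    return(P)
  }
  R <- diag(k) + Q / Om
  for (ti in seq_along(times)) {
    ot <- Om * times[ti]
    term <- diag(k)
    acc <- term * exp(-ot)
    logw <- -ot
    n <- 0
    cum <- exp(logw)
    while (1 - cum > 1e-14 && n < 100000) {
      n <- n + 1
      term <- term %*% R
      logw <- logw + log(ot / n)
      acc <- acc + exp(logw) * term
      cum <- cum + exp(logw)
    }
    P[, , ti] <- acc
  }
  P[P < 0] <- 0
  P
}

.root_prior_vec <- function(root_prior, Q) {
  k <- nrow(Q); states <- rownames(Q)
  if (is.numeric(root_prior)) {
    if (length(root_prior) != k) stop("root prior length mismatch")
    return(root_prior / sum(root_prior))
  }
  if (root_prior == "uniform") return(rep(1 / k, k))
  if (root_prior == "stationary") {
    # left null vector of Q; uniform if Q is (numerically) zero
    if (max(abs(Q)) < 1e-14) return(rep(1 / k, k))
    ns <- tryCatch({
      A <- rbind(t(Q), rep(1, k))
      drop(qr.solve(A, c(rep(0, k), 1)))
    }, error = function(e) rep(1 / k, k))
    ns[ns < 0] <- 0
    return(ns / sum(ns))
  }
  if (root_prior %in% states) return(as.numeric(states == root_prior))
  stop("unknown root prior: ", root_prior)
}

# tip partial-likelihood matrix; NA/missing states are fully ambiguous
.tip_partials <- function(tree, tip_states, states) {
  nt <- ape::Ntip(tree)
  L <- matrix(1, nt, length(states))
  ts <- tip_states[tree$tip.label]
  for (i in seq_len(nt)) {
    s <- ts[i]
    if (!is.na(s)) {
      if (!s %in% states) stop("tip state '", s, "' not in alphabet")
      L[i, ] <- as.numeric(states == s)
    }
  }
  L
}

# pruning pass; returns log-likelihood and (scaled) per-node partials
.mk_prune <- function(tree, tipL, Q, root_prior = "stationary") {
  nt <- ape::Ntip(tree); nn <- nt + tree$Nnode
  k <- nrow(Q)
  po <- ape::reorder.phylo(tree, "postorder")
  P <- .mk_pmats(Q, po$edge.length)
  L <- matrix(1, nn, k)
  L[seq_len(nt), ] <- tipL
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    v <- P[, , e] %*% L[ch, ]
    sc <- max(v)
    if (sc <= 0) return(list(lnL = -Inf, partials = L, P = P, po = po))
    logscale <- logscale + log(sc)
    L[par, ] <- L[par, ] * drop(v) / sc
  }
  prior <- .root_prior_vec(root_prior, Q)
  lik <- sum(prior * L[nt + 1L, ])
  list(lnL = if (lik > 0) log(lik) + logscale else -Inf,
       partials = L, P = P, po = po, prior = prior)
}

#' Mk log-likelihood of discrete tip states
#'
#' Felsenstein pruning under a continuous-time Markov model with rate matrix
#' `Q`. Missing tip states are treated as fully ambiguous.
#'
#' @param tree A `phylo`.
#' @param tip_states Named character vector of states (NA allowed).
#' @param Q Rate matrix (rows sum to 0) with state dimnames.
#' @param root_prior `"stationary"` (default), `"uniform"`, a state name, or
#'   a probability vector.
#' @return Log-likelihood.
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "stationary") {
  .validate_q(Q)
  tipL <- .tip_partials(tree, tip_states, rownames(Q))
  .mk_prune(tree, tipL, Q, root_prior)$lnL
}

#' Fit an Mk model by maximum likelihood
#'
#' Rate structures: `"ER"` (one rate), `"SYM"` (symmetric pairs), `"ARD"`
#' (all rates distinct). `select_mk_model()` fits all three and keeps the
#' lowest AICc.
#'
#' @param tree A `phylo`.
#' @param tip_states Named character vector.
#' @param structure One of `"ER"`, `"SYM"`, `"ARD"`.
#' @param states State alphabet (default the 3 habitat states).
#' @param root_prior Passed to [mk_loglik()].
#' @return List with `Q`, `lnL`, `k`, `aicc`, `structure`.
#' @export
fit_mk <- function(tree, tip_states, structure = c("ARD", "SYM", "ER"),
                   states = habitat_states(), root_prior = "stationary") {
  structure <- match.arg(structure)
  k <- length(states)
  npair <- k * (k - 1)
  # map the npair off-diagonal slots onto free parameters
  par_index <- switch(structure,
    ER = rep(1L, npair),
    SYM = {
      idx <- integer(npair); cnt <- 0L; pos <- 1L
      key <- matrix(0L, k, k)
      for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
        a <- min(i, j); b <- max(i, j)
        if (key[a, b] == 0L) { cnt <- cnt + 1L; key[a, b] <- cnt }
        idx[pos] <- key[a, b]; pos <- pos + 1L
      }
      idx
    },
    ARD = seq_len(npair))
  np <- max(par_index)
  tipL <- .tip_partials(tree, tip_states, states)
  obj <- function(lr) {
    Q <- make_q_matrix(exp(lr)[par_index], states)
    ll <- .mk_prune(tree, tipL, Q, root_prior)$lnL
    if (!is.finite(ll)) return(.PENALTY)
    -ll
  }
  tl <- sum(tree$edge.length)
  start <- rep(log(max(1, .parsimony_score(tree, tip_states, states)) / tl), np)
  best <- .multi_start(obj, rep(log(1e-6), np), rep(log(10), np),
                       n_restarts = 3L, warm = start)
  if (is.null(best)) stop("Mk optimization failed")
  Q <- make_q_matrix(exp(best$par)[par_index], states)
  lnL <- -best$objective
  n <- ape::Ntip(tree)
  list(Q = Q, lnL = lnL, k = np, aicc = aicc(lnL, np, n), structure = structure)
}

#' @rdname fit_mk
#' @export
select_mk_model <- function(tree, tip_states, states = habitat_states(),
                            root_prior = "stationary") {
  fits <- lapply(c("ER", "SYM", "ARD"), function(s)
    fit_mk(tree, tip_states, s, states, root_prior))
  fits[[which.min(vapply(fits, `[[`, 0, "aicc"))]]
}

# Sankoff small parsimony with unit costs (polytomy-safe)
.parsimony_score <- function(tree, tip_states, states) {
  nt <- ape::Ntip(tree); nn <- nt + tree$Nnode
  k <- length(states)
  BIG <- 1e6
  cost <- matrix(0, nn, k)
  ts <- tip_states[tree$tip.label]
  for (i in seq_len(nt)) {
    if (!is.na(ts[i])) cost[i, ] <- ifelse(states == ts[i], 0, BIG)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    below <- cost[ch, ]
    cost[par, ] <- cost[par, ] + vapply(seq_len(k), function(s)
      min(below + as.numeric(seq_len(k) != s)), 0)
  }
  min(cost[nt + 1L, ])
}

# ---- reversible-jump MCMC over Mk rate structures ---------------------------

# canonical signature of an assignment vector (0 = zero class)
.rj_signature <- function(assign) {
  lab <- integer(max(assign, 1L))
  out <- character(length(assign))
  nxt <- 0L
  for (i in seq_along(assign)) {
    if (assign[i] == 0L) { out[i] <- "0"; next }
    if (lab[assign[i]] == 0L) { nxt <- nxt + 1L; lab[assign[i]] <- nxt }
    out[i] <- letters[lab[assign[i]]]
  }
  paste(out, collapse = "")
}

# valid reassignment targets for entry i: other existing classes, a fresh
# singleton (if i is not already one), and the zero class (if not there)
.rj_targets <- function(assign, i) {
  cur <- assign[i]
  existing <- setdiff(unique(assign[assign > 0L]), cur)
  t <- as.list(existing)
  singleton <- cur > 0L && sum(assign == cur) == 1L
  if (!singleton) t <- c(t, list("new"))
  if (cur != 0L) t <- c(t, list(0L))
  t
}

#' Reversible-jump MCMC over Mk transition-rate structures
#'
#' Explores groupings of the off-diagonal transition rates into shared-rate
#' classes, including a zero class (structural absence of a transition), in
#' the spirit of the rate-structure averaging done for discrete characters
#' in BayesTraits. The prior is uniform over structures and exponential
#' (mean `rate_mean`) on each class rate; reassignment moves that create a
#' class draw its rate from the prior, so those proposals cancel against the
#' prior in the acceptance ratio.
#'
#' @param tree A `phylo`.
#' @param tip_states Named character vector.
#' @param iterations Total MCMC iterations.
#' @param burnin Iterations discarded (default `iterations/5`).
#' @param thin Keep every `thin`-th sample.
#' @param seed RNG seed (chains with the same seed are identical).
#' @param rate_mean Prior mean of class rates; default is the parsimony
#'   change count divided by total tree length (a data-scale estimate).
#' @param states State alphabet.
#' @param root_prior Root state prior (see [mk_loglik()]).
#' @return List: `samples` (iteration, structure signature, lnL),
#'   `rates` (list of per-sample rate vectors over the 6 entries),
#'   `structure_freq` (visit frequencies), `modal_structure`,
#'   `root_freq` (posterior root-state frequencies), `acceptance`.
#' @export
rjmcmc_mk <- function(tree, tip_states, iterations = 10000L,
                      burnin = floor(iterations / 5), thin = 10L, seed = 1L,
                      rate_mean = NULL, states = habitat_states(),
                      root_prior = "stationary") {
  if (iterations < burnin) stop("iterations must exceed burnin")
  k <- length(states)
  npair <- k * (k - 1)
  tipL <- if (!is.null(tree)) .tip_partials(tree, tip_states, states) else NULL
  if (is.null(rate_mean)) {
    rate_mean <- max(0.5, .parsimony_score(tree, tip_states, states)) /
      sum(tree$edge.length)
  }
  lnL_of <- function(assign, rates) {
    if (is.null(tipL)) return(0)   # prior-only chain (used in calibration)
    entry_rates <- ifelse(assign == 0L, 0, rates[pmax(assign, 1L)])
    Q <- make_q_matrix(entry_rates, states)
    res <- .mk_prune(tree, tipL, Q, root_prior)
    attr(res$lnL, "root_post") <- {
      w <- res$prior * res$partials[ape::Ntip(tree) + 1L, ]
      if (sum(w) > 0) w / sum(w) else rep(1 / k, k)
    }
    res$lnL
  }
  .with_seed(seed, {
    assign <- rep(1L, npair)           # start at equal rates
    rates <- stats::rexp(1, 1 / rate_mean)
    lnL <- lnL_of(assign, rates)
    n_keep <- floor((iterations - burnin) / thin)
    samp_iter <- integer(n_keep); samp_sig <- character(n_keep)
    samp_lnL <- numeric(n_keep); samp_rates <- vector("list", n_keep)
    root_acc <- rep(0, k)
    acc <- c(rate = 0, jump = 0); tries <- c(rate = 0, jump = 0)
    ptr <- 0L
    for (it in seq_len(iterations)) {
      nclass <- max(assign, 0L)
      do_rate <- nclass > 0L && stats::runif(1) < 0.5
      if (do_rate) {
        tries["rate"] <- tries["rate"] + 1
        c_i <- sample.int(nclass, 1L)
        r_old <- rates[c_i]
        r_new <- r_old * exp(stats::runif(1, -log(2), log(2)))
        rates2 <- rates; rates2[c_i] <- r_new
        lnL2 <- lnL_of(assign, rates2)
        logA <- (lnL2 - lnL) + (r_old - r_new) / rate_mean + log(r_new / r_old)
        if (log(stats::runif(1)) < logA) {
          rates <- rates2; lnL <- lnL2; acc["rate"] <- acc["rate"] + 1
        }
      } else {
        tries["jump"] <- tries["jump"] + 1
        i <- sample.int(npair, 1L)
        targets <- .rj_targets(assign, i)
        if (length(targets)) {
          tgt <- targets[[sample.int(length(targets), 1L)]]
          assign2 <- assign; rates2 <- rates
          old_class <- assign[i]
          if (identical(tgt, "new")) {
            newc <- max(assign2) + 1L
            assign2[i] <- newc
            rates2 <- c(rates2, stats::rexp(1, 1 / rate_mean))
          } else {
            assign2[i] <- as.integer(tgt)
          }
          # drop an emptied class and relabel
          if (old_class > 0L && !any(assign2 == old_class)) {
            rates2 <- rates2[-old_class]
            assign2[assign2 > old_class] <- assign2[assign2 > old_class] - 1L
          }
          lnL2 <- lnL_of(assign2, rates2)
          # move-type probability differs between states with and without
          # rate classes (jump-only when everything is in the zero class)
          pj_fwd <- if (nclass > 0L) 0.5 else 1
          pj_rev <- if (max(assign2, 0L) > 0L) 0.5 else 1
          qf <- pj_fwd / length(targets)
          qr <- pj_rev / length(.rj_targets(assign2, i))
          logA <- (lnL2 - lnL) + log(qr / qf)
          if (log(stats::runif(1)) < logA) {
            assign <- assign2; rates <- rates2; lnL <- lnL2
            acc["jump"] <- acc["jump"] + 1
          }
        }
      }
      if (it > burnin && (it - burnin) %% thin == 0L && ptr < n_keep) {
        ptr <- ptr + 1L
        samp_iter[ptr] <- it
        samp_sig[ptr] <- .rj_signature(assign)
        samp_lnL[ptr] <- as.numeric(lnL)
        samp_rates[[ptr]] <- ifelse(assign == 0L, 0, rates[pmax(assign, 1L)])
        rp <- attr(lnL, "root_post")
        if (!is.null(rp)) root_acc <- root_acc + rp
      }
    }
    freq <- sort(table(samp_sig[seq_len(ptr)]), decreasing = TRUE)
    list(samples = data.frame(iteration = samp_iter[seq_len(ptr)],
                              structure = samp_sig[seq_len(ptr)],
                              lnL = samp_lnL[seq_len(ptr)],
                              stringsAsFactors = FALSE),
         rates = samp_rates[seq_len(ptr)],
         structure_freq = freq / max(ptr, 1L),
         modal_structure = if (ptr) names(freq)[1] else NA_character_,
         root_freq = stats::setNames(root_acc / max(ptr, 1L), states),
         acceptance = ifelse(tries > 0, acc / tries, NA),
         rate_mean = rate_mean)
  })
}

# ---- stochastic character mapping -------------------------------------------

# endpoint-conditioned path on one branch by uniformization
.sample_branch_path <- function(a, b, t, Q, P_ab, Rpow_env, Omega, R,
                                max_events = 10000L) {
  k <- nrow(Q)
  if (Omega * t < 1e-14) return(stats::setNames(t, rownames(Q)[a]))
  # sample the number of uniformized events
  u <- stats::runif(1)
  lp0 <- -Omega * t
  cum <- 0; n <- -1L; lpn <- lp0
  Rn_ab <- function(n) .rpow(Rpow_env, R, n)[a, b]
  repeat {
    n <- n + 1L
    if (n > 0L) lpn <- lpn + log(Omega * t / n)
    cum <- cum + exp(lpn) * Rn_ab(n) / P_ab
    if (u <= cum || n >= max_events) break
  }
  if (n >= max_events) stop("uniformization event cap exceeded")
  states <- integer(n + 1L); states[1] <- a
  if (n > 0L) {
    for (j in seq_len(n - 1L)) {
      w <- R[states[j], ] * .rpow(Rpow_env, R, n - j)[, b]
      states[j + 1L] <- sample.int(k, 1L, prob = w)
    }
    states[n + 1L] <- b
  }
  times <- c(0, sort(stats::runif(n, 0, t)), t)
  segs <- numeric(0); labs <- character(0)
  cur <- states[1]; start <- 0
  if (n > 0L) for (j in seq_len(n)) {
    if (states[j + 1L] != cur) {
      segs <- c(segs, times[j + 1L] - start); labs <- c(labs, rownames(Q)[cur])
      start <- times[j + 1L]; cur <- states[j + 1L]
    }
  }
  segs <- c(segs, t - start); labs <- c(labs, rownames(Q)[cur])
  stats::setNames(segs, labs)
}

# lazy cache of matrix powers of R
.rpow <- function(env, R, n) {
  if (n == 0L) return(diag(nrow(R)))
  key <- as.character(n)
  if (is.null(env[[key]])) {
    env[[key]] <- R %*% .rpow(env, R, n - 1L)
  }
  env[[key]]
}

#' Stochastic character mapping
#'
#' Draws full character histories from the posterior of histories given the
#' tip states and rate matrix `Q`: node states are sampled from their joint
#' conditional distribution (pruning upward, sampling preorder), then each
#' branch history is sampled conditional on its endpoint states by
#' uniformization.
#'
#' @param tree A `phylo`.
#' @param tip_states Named character vector.
#' @param Q Rate matrix with state dimnames.
#' @param n_maps Number of maps to draw (default 1000).
#' @param seed RNG seed.
#' @param root_prior Root prior (see [mk_loglik()]).
#' @param max_events Per-branch uniformized event cap.
#' @return List of `regime_map` objects sharing `tree`.
#' @export
stochastic_map <- function(tree, tip_states, Q, n_maps = 1000L, seed = 1L,
                           root_prior = "stationary", max_events = 10000L) {
  .validate_q(Q)
  if (n_maps < 1) stop("n_maps must be >= 1")
  states <- rownames(Q)
  k <- length(states)
  tipL <- .tip_partials(tree, tip_states, states)
  pr <- .mk_prune(tree, tipL, Q, root_prior)
  if (!is.finite(pr$lnL)) stop("tip states have zero likelihood under Q")
  nt <- ape::Ntip(tree); nn <- nt + tree$Nnode
  po <- pr$po
  nedge <- nrow(po$edge)
  # subtree partials per node (tips one-hot/ambiguous, internals from pruning)
  L <- pr$partials
  Omega <- max(-diag(Q))
  R <- if (Omega > 0) diag(k) + Q / Omega else diag(k)
  Rpow_env <- new.env(parent = emptyenv())
  # preorder over edges
  pre <- rev(seq_len(nedge))
  edge_key <- match(paste(tree$edge[, 1], tree$edge[, 2]),
                    paste(po$edge[, 1], po$edge[, 2]))
  .with_seed(seed, {
    lapply(seq_len(n_maps), function(m) {
      node_state <- integer(nn)
      wroot <- pr$prior * L[nt + 1L, ]
      node_state[nt + 1L] <- sample.int(k, 1L, prob = wroot)
      maps_po <- vector("list", nedge)
      for (e in pre) {
        par <- po$edge[e, 1]; ch <- po$edge[e, 2]
        P <- pr$P[, , e]
        w <- P[node_state[par], ] * L[ch, ]
        node_state[ch] <- sample.int(k, 1L, prob = w)
        maps_po[[e]] <- .sample_branch_path(
          node_state[par], node_state[ch], po$edge.length[e], Q,
          P[node_state[par], node_state[ch]], Rpow_env, Omega, R, max_events)
      }
      regime_map(tree, maps_po[edge_key],
                 node_state = states[node_state], states = states)
    })
  })
}

# ---- summaries over maps ----------------------------------------------------

#' Summarize a set of stochastic maps
#'
#' Per-node marginal state frequencies, the distribution of per-map
#' transition counts, and state-dependent lineage-through-time counts on a
#' time grid (median and 95% band across maps).
#'
#' @param maps List of `regime_map` over the same tree.
#' @param time_grid Depths (time from root, Myr) at which to count lineages;
#'   default 101 points spanning the tree.
#' @return A `map_summary` list.
#' @export
summarize_maps <- function(maps, time_grid = NULL) {
  if (!length(maps)) stop("need at least one map")
  tree <- maps[[1]]$tree
  states <- maps[[1]]$states
  depth <- node_depths(tree)
  if (is.null(time_grid)) time_grid <- seq(0, max(depth) * 0.9999, length.out = 101)
  if (max(time_grid) > max(depth) + 1e-9 || min(time_grid) < -1e-9) {
    stop("time grid outside tree span")
  }
  nt <- ape::Ntip(tree); nn <- nt + tree$Nnode
  k <- length(states)
  counts <- array(0L, c(length(maps), k, length(time_grid)),
                  dimnames = list(NULL, states, NULL))
  node_freq <- matrix(0, nn, k, dimnames = list(NULL, states))
  trans <- integer(length(maps))
  for (m in seq_along(maps)) {
    rm <- maps[[m]]
    for (e in seq_len(nrow(tree$edge))) {
      d0 <- depth[tree$edge[e, 1]]
      segs <- rm$maps[[e]]
      bounds <- d0 + cumsum(c(0, as.numeric(segs)))
      for (j in seq_along(segs)) {
        inseg <- time_grid >= bounds[j] & time_grid < bounds[j + 1]
        if (any(inseg)) {
          si <- match(names(segs)[j], states)
          counts[m, si, inseg] <- counts[m, si, inseg] + 1L
        }
      }
    }
    trans[m] <- n_transitions(rm)
    if (!is.null(rm$node_state)) {
      idx <- cbind(seq_len(nn), match(rm$node_state, states))
      node_freq[idx] <- node_freq[idx] + 1
    }
  }
  node_freq <- node_freq / length(maps)
  qs <- apply(counts, c(2, 3), stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  structure(list(states = states, time_grid = time_grid,
                 lineages_median = qs[2, , ], lineages_lo = qs[1, , ],
                 lineages_hi = qs[3, , ], counts = counts,
                 node_freq = node_freq,
                 transition_counts = trans), class = "map_summary")
}

#' Count colonizations of a state across stochastic maps
#'
#' A colonization is a within-branch transition whose destination is
#' `target_state`. Returns the per-map counts with their median and central
#' 95% interval.
#'
#' @param maps List of `regime_map`.
#' @param target_state State being entered (e.g. `"continental"`).
#' @return List: `counts`, `median`, `ci95`.
#' @export
count_colonizations <- function(maps, target_state) {
  counts <- vapply(maps, function(rm) {
    sum(vapply(rm$maps, function(m) {
      if (length(m) < 2L) return(0L)
      sum(names(m)[-1] == target_state)
    }, 0L))
  }, 0L)
  list(counts = counts, median = stats::median(counts),
       ci95 = unname(stats::quantile(counts, c(0.025, 0.975))))
}

# ---- regime paintings -------------------------------------------------------

#' Repaint habitat maps for multi-peak model fitting
#'
#' `three_peak` keeps the three habitat states; `two_peak` merges marine and
#' continental into `"other"`, keeping `"marginal"` distinct (gigantism may
#' have been favoured in both fully marine and continental settings).
#'
#' @param maps A `regime_map` or list of them.
#' @param mode `"three_peak"` or `"two_peak"`.
#' @return Repainted `regime_map`(s), same shape as the input.
#' @export
paint_habitat_regimes <- function(maps, mode = c("three_peak", "two_peak")) {
  mode <- match.arg(mode)
  single <- inherits(maps, "regime_map")
  if (single) maps <- list(maps)
  out <- lapply(maps, function(rm) {
    if (mode == "three_peak") return(rm)
    relab <- function(s) ifelse(s == "marginal", "marginal", "other")
    maps2 <- lapply(rm$maps, function(m) {
      labs <- relab(names(m))
      # merge adjacent equal-state segments
      grp <- cumsum(c(TRUE, labs[-1] != labs[-length(labs)]))
      stats::setNames(as.numeric(tapply(as.numeric(m), grp, sum)),
                      labs[!duplicated(grp)])
    })
    regime_map(rm$tree, maps2,
               node_state = if (!is.null(rm$node_state)) relab(rm$node_state),
               states = intersect(c("marginal", "other"),
                                  unique(unlist(lapply(maps2, names)))))
  })
  if (single) out[[1]] else out
}

#' Paint pre/post extinction-crisis regimes on a tree
#'
#' Every branch segment older than `crisis_age_ma` is painted `PRE`; younger
#' segments are painted `S1` or `S2` when they lie inside the two surviving
#' clades (an edge is inside a clade when its child node descends from the
#' clade's MRCA, stem edge included) and `PRE` otherwise. Branches crossing
#' the crisis age are split exactly at it.
#'
#' @param tree A `phylo`.
#' @param crisis_age_ma Crisis age (Ma; same age scale as [node_ages()]).
#' @param clade1,clade2 Character vectors of tip labels defining the two
#'   surviving clades (must not overlap).
#' @param root_age_ma Optional absolute root age.
#' @return A `regime_map` with regimes `PRE`, `S1`, `S2`.
#' @export
paint_crisis_regimes <- function(tree, crisis_age_ma, clade1, clade2,
                                 root_age_ma = NULL) {
  if (length(intersect(clade1, clade2))) {
    stop("surviving clades overlap: ",
         paste(intersect(clade1, clade2), collapse = ", "))
  }
  ages <- node_ages(tree, root_age_ma)
  clade_nodes <- function(tips) {
    miss <- setdiff(tips, tree$tip.label)
    if (length(miss)) stop("clade tips not in tree: ", paste(miss, collapse = ", "))
    if (length(tips) == 1L) return(match(tips, tree$tip.label))
    mr <- ape::getMRCA(tree, tips)
    c(mr, .descendants(tree, mr))
  }
  c1 <- clade_nodes(clade1); c2 <- clade_nodes(clade2)
  if (length(intersect(c1, c2))) stop("surviving clades overlap on the tree")
  maps <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    reg <- if (ch %in% c1) "S1" else if (ch %in% c2) "S2" else "PRE"
    a_par <- ages[par]; a_ch <- ages[ch]
    if (a_ch >= crisis_age_ma || reg == "PRE") {
      # entirely pre-crisis, or outside both surviving clades
      maps[[e]] <- stats::setNames(len, "PRE")
    } else if (a_par <= crisis_age_ma) {
      maps[[e]] <- stats::setNames(len, reg)
    } else {
      maps[[e]] <- stats::setNames(c(a_par - crisis_age_ma,
                                     crisis_age_ma - a_ch), c("PRE", reg))
    }
  }
  regime_map(tree, maps, states = c("PRE", "S1", "S2"))
}

# descendants of a node (tips + internals)
.descendants <- function(tree, node) {
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- kids[[as.character(node)]]
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    out <- c(out, nd)
    more <- kids[[as.character(nd)]]
    if (!is.null(more)) stack <- c(stack, more)
  }
  out
}
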