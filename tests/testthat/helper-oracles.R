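# Independent oracle implementations used to validate the package's
# numerics. These deliberately avoid the package's own code paths: matrix
# exponentials via Matrix::expm, covariances by explicit path enumeration,
# likelihoods via direct multivariate-normal evaluation with solve().

# random non-ultrametric tree with strictly positive branch lengths
rand_fossil_tree <- function(n, seed = NULL, min_bl = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + min_bl
  tr
}

# log MVN density via solve/determinant (not the package's Cholesky path)
dmvnorm_log_oracle <- function(x, mean, V) {
  n <- length(x)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  q <- drop(t(x - mean) %*% solve(V, x - mean))
  -0.5 * (n * log(2 * pi) + ld + q)
}

# list of edges (parent, child, length) on the path root -> node
path_to_root <- function(tree, node) {
  root <- ape::Ntip(tree) + 1L
  path <- list()
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    path[[length(path) + 1L]] <- c(tree$edge[e, 1], node, tree$edge.length[e])
    node <- tree$edge[e, 1]
  }
  rev(path)
}

# shared path-length matrix by brute-force path intersection
cov_path_enumeration <- function(tree) {
  nt <- ape::Ntip(tree)
  edge_sets <- lapply(seq_len(nt), function(i) {
    p <- path_to_root(tree, i)
    stats::setNames(vapply(p, `[`, 0, 3),
                    vapply(p, function(e) paste(e[1], e[2]), ""))
  })
  C <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    shared <- intersect(names(edge_sets[[i]]), names(edge_sets[[j]]))
    C[i, j] <- sum(edge_sets[[i]][shared])
  }
  C
}

# OU mean/covariance assembled entry-by-entry from the integral formulas
ou_moments_oracle <- function(tree, z0, sig2, alpha, theta) {
  C <- cov_path_enumeration(tree)
  Tt <- diag(C)
  n <- length(Tt)
  M <- z0 * exp(-alpha * Tt) + theta * (1 - exp(-alpha * Tt))
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ta <- C[i, j]
    V[i, j] <- sig2 / (2 * alpha) *
      exp(-alpha * (Tt[i] + Tt[j] - 2 * ta)) * (1 - exp(-2 * alpha * ta))
  }
  list(mean = M, V = V, tips = rownames(C))
}

# Mk likelihood by exhaustive summation over internal-node states
mk_brute_oracle <- function(tree, tip_states, Q, prior) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  states <- rownames(Q)
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  internal <- (nt + 1):nn
  grid <- expand.grid(rep(list(seq_along(states)), length(internal)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    asg <- integer(nn)
    asg[internal] <- as.integer(grid[g, ])
    asg[1:nt] <- match(tip_states[tree$tip.label], states)
    p <- prior[asg[nt + 1]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Ps[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
    }
    total <- total + p
  }
  log(total)
}

# marginal posterior of a node's state by exhaustive enumeration
mk_node_marginal_oracle <- function(tree, tip_states, Q, prior, node) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  states <- rownames(Q)
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  internal <- (nt + 1):nn
  grid <- expand.grid(rep(list(seq_along(states)), length(internal)))
  marg <- stats::setNames(numeric(length(states)), states)
  for (g in seq_len(nrow(grid))) {
    asg <- integer(nn)
    asg[internal] <- as.integer(grid[g, ])
    asg[1:nt] <- match(tip_states[tree$tip.label], states)
    p <- prior[asg[nt + 1]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Ps[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
    }
    marg[asg[node]] <- marg[asg[node]] + p
  }
  marg / sum(marg)
}

# Monte-Carlo pulsed likelihood: average the jump-count-conditional MVN
# density over simulated Poisson jump configurations
pulsed_mc_oracle <- function(tree, x, z0, sig2, lambda, delta2, ndraw,
                             seed = 1) {
  set.seed(seed)
  nt <- ape::Ntip(tree)
  C <- cov_path_enumeration(tree)
  x <- x[rownames(C)]
  # tip-descendant indicator per edge
  desc <- lapply(seq_len(nrow(tree$edge)), function(e) {
    ch <- tree$edge[e, 2]
    if (ch <= nt) return(ch)
    dd <- unlist(lapply(seq_len(nt), function(i)
      if (any(vapply(path_to_root(tree, i), function(p) p[2] == ch, TRUE))) i))
    dd
  })
  counts <- matrix(stats::rpois(ndraw * nrow(tree$edge),
                                lambda * tree$edge.length),
                   nrow(tree$edge), ndraw)
  key <- apply(counts, 2, paste, collapse = ",")
  tab <- table(key)
  dens <- vapply(names(tab), function(k) {
    kv <- as.integer(strsplit(k, ",")[[1]])
    V <- sig2 * C
    for (e in which(kv > 0)) {
      idx <- desc[[e]]
      V[idx, idx] <- V[idx, idx] + delta2 * kv[e]
    }
    exp(dmvnorm_log_oracle(x, rep(z0, nt), V))
  }, 0)
  w <- as.numeric(tab) / ndraw
  m1 <- sum(w * dens)
  m2 <- sum(w * dens^2)
  se <- sqrt((m2 - m1^2) / ndraw)
  list(loglik = log(m1), se_log = se / m1)
}

# high-accuracy ODE integration of the env-OU tip mean along one path
env_ou_mean_ode_oracle <- function(curve, T_total, z0, alpha, theta0, beta,
                                   root_age_ma, h = 1e-3) {
  m <- z0
  t <- 0
  while (t < T_total - 1e-12) {
    hh <- min(h, T_total - t)
    # RK4 on m' = alpha (theta(t) - m)
    th <- function(tt) theta0 + beta * env_value_at(curve, root_age_ma - tt)
    k1 <- alpha * (th(t) - m)
    k2 <- alpha * (th(t + hh / 2) - (m + hh / 2 * k1))
    k3 <- alpha * (th(t + hh / 2) - (m + hh / 2 * k2))
    k4 <- alpha * (th(t + hh) - (m + hh * k3))
    m <- m + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + hh
  }
  m
}

# multi-peak OU mean/covariance by independent per-path segment recursion
oum_moments_oracle <- function(rmap, z0, theta, alpha, sig2) {
  tree <- rmap$tree
  nt <- ape::Ntip(tree)
  # per-tip ordered segment list from root, assembled from edge paths
  seg_path <- function(tip) {
    p <- path_to_root(tree, tip)
    out <- list()
    for (e in p) {
      row <- which(tree$edge[, 1] == e[1] & tree$edge[, 2] == e[2])
      m <- rmap$maps[[row]]
      for (j in seq_along(m)) out[[length(out) + 1L]] <- c(m[[j]], j, row)
    }
    lapply(out, function(s) list(len = s[1],
                                 reg = names(rmap$maps[[s[3]]])[s[2]]))
  }
  paths <- lapply(seq_len(nt), seg_path)
  mean_of <- function(segs) {
    m <- z0
    for (s in segs) {
      d <- exp(-alpha * s$len)
      m <- m * d + theta[[s$reg]] * (1 - d)
    }
    m
  }
  var_along <- function(segs) {
    v <- 0
    for (s in segs) {
      d <- exp(-alpha * s$len)
      v <- v * d^2 + sig2 * (1 - d^2) / (2 * alpha)
    }
    v
  }
  # shared-time (depth of mrca) via path enumeration
  C <- cov_path_enumeration(tree)
  depth <- palaeotrait::node_depths(tree)
  M <- vapply(paths, mean_of, 0)
  V <- matrix(0, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    ta <- C[i, j]
    # variance at the mrca: integrate segments of path i up to depth ta
    truncate_at <- function(segs, tcut) {
      out <- list(); acc <- 0
      for (s in segs) {
        if (acc + s$len <= tcut + 1e-12) {
          out[[length(out) + 1L]] <- s
          acc <- acc + s$len
        } else if (acc < tcut) {
          out[[length(out) + 1L]] <- list(len = tcut - acc, reg = s$reg)
          acc <- tcut
        }
      }
      out
    }
    va <- var_along(truncate_at(paths[[i]], ta))
    Ti <- depth[i]; Tj <- depth[j]
    V[i, j] <- va * exp(-alpha * (Ti - ta)) * exp(-alpha * (Tj - ta))
  }
  list(mean = stats::setNames(M, tree$tip.label), V = V,
       tips = tree$tip.label)
}

# discrete-time forward simulation of the fossilized birth-death process,
# with the same terminal-counting convention as the package's simulator but
# an independent implementation (small fixed time step)
fbd_forward_oracle_count <- function(lambda, mu, psi, duration, dt = 0.02) {
  t_start <- 0; t_end <- NA_real_; parent <- 0L
  alive <- 1L
  nstep <- ceiling(duration / dt)
  for (s in seq_len(nstep)) {
    t <- s * dt
    if (!length(alive)) break
    u <- stats::runif(length(alive))
    born <- alive[u < lambda * dt]
    u2 <- stats::runif(length(alive))
    dead <- alive[u2 < mu * dt]
    for (b in born) {
      parent <- c(parent, b)
      t_start <- c(t_start, t)
      t_end <- c(t_end, NA_real_)
      alive <- c(alive, length(parent))
    }
    if (length(dead)) {
      t_end[dead] <- t
      alive <- setdiff(alive, dead)
    }
  }
  t_end[is.na(t_end)] <- duration
  n_lin <- length(parent)
  fossils <- lapply(seq_len(n_lin), function(l) {
    len <- t_end[l] - t_start[l]
    k <- if (psi > 0 && len > 0) stats::rpois(1, psi * len) else 0L
    if (k > 0) sort(stats::runif(k, t_start[l], t_end[l])) else numeric(0)
  })
  extant <- abs(t_end - duration) < 1e-9
  kids <- split(seq_len(n_lin)[-1], parent[-1])
  sampled_below <- logical(n_lin)
  for (l in order(t_start, decreasing = TRUE)) {
    ch <- kids[[as.character(l)]]
    sampled_below[l] <- length(fossils[[l]]) > 0 ||
      (!is.null(ch) && any(sampled_below[ch]))
  }
  # count terminals: last fossil postdating the last sampled-descendant birth
  n_tips <- 0L
  for (l in seq_len(n_lin)) {
    ch <- kids[[as.character(l)]]
    ch <- ch[sampled_below[ch]]
    latest_birth <- if (length(ch)) max(t_start[ch]) else -Inf
    if (length(fossils[[l]]) && max(fossils[[l]]) > latest_birth) {
      n_tips <- n_tips + 1L
    }
  }
  n_tips
}

# tip labels of the two basal subtrees (stand-in surviving clades)
crisis_split <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  tips_under <- function(nd) {
    if (nd <= ape::Ntip(tree)) return(tree$tip.label[nd])
    sub <- ape::extract.clade(tree, nd)
    sub$tip.label
  }
  list(clade1 = tips_under(kids[1]), clade2 = tips_under(kids[2]))
}

parsimony_min_states <- function(tree, tip_states, states) {
  palaeotrait:::.parsimony_score(tree, tip_states, states)
}
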