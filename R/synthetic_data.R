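# ---- fossilized birth-death tree simulation ---------------------------------

#' Simulate a sampled tree under a fossilized birth-death process
#'
#' Forward birth-death simulation (budding speciation) with Poisson fossil
#' sampling at rate `psi` along every lineage and extant sampling
#' probability `rho` at the stopping time. The returned tree spans the
#' sampled tips only: an extinct lineage is represented by its last fossil
#' sample provided no sampled descendant attaches after it (fossil samples
#' ancestral to other samples are discarded, so no degree-two sampled
#' ancestors appear); unsampled subtrees are pruned. With `psi > 0` the tree
#' is non-ultrametric.
#'
#' @param lambda Speciation rate (> 0, per lineage per Myr).
#' @param mu Extinction rate (>= 0).
#' @param psi Fossil-sampling rate (>= 0).
#' @param duration Stop after this many Myr (mutually exclusive with
#'   `n_extant`).
#' @param n_extant Stop when this many lineages are simultaneously alive.
#' @param rho Sampling probability of lineages alive at the stop time.
#' @param seed RNG seed; the same seed yields the same tree.
#' @param min_tips Minimum sampled tips; fewer triggers a retry.
#' @param max_retries Retries before giving up (total early extinction).
#' @return A `phylo`; tip ages in Myr before the stop time.
#' @export
simulate_fbd_tree <- function(lambda, mu = 0, psi = 0, duration = NULL,
                              n_extant = NULL, rho = 1, seed = 1L,
                              min_tips = 2L, max_retries = 100L) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (mu < 0 || psi < 0) stop("mu and psi must be >= 0")
  if (is.null(duration) == is.null(n_extant)) {
    stop("give exactly one stop condition: duration or n_extant")
  }
  if (!is.null(duration) && duration <= 0) stop("duration must be positive")
  if (!is.null(n_extant) && n_extant < 2) stop("n_extant must be >= 2")
  .with_seed(seed, {
    for (try in seq_len(max_retries)) {
      tr <- .fbd_once(lambda, mu, psi, duration, n_extant, rho)
      if (!is.null(tr) && ape::Ntip(tr) >= min_tips) {
        return(validate_phylogeny(tr, jitter_zero = TRUE))
      }
    }
    stop("no surviving sampled tree in ", max_retries, " attempts; ",
         "increase rates or duration")
  })
}

.fbd_once <- function(lambda, mu, psi, duration, n_extant, rho) {
  # lineage bookkeeping: start/end times, parent lineage, children
  t_start <- 0; t_end <- NA_real_; parent <- 0L
  n_lin <- 1L
  alive <- 1L
  t <- 0
  repeat {
    n_alive <- length(alive)
    if (n_alive == 0L) break
    if (!is.null(n_extant) && n_alive >= n_extant) {
      # let the youngest lineage age: stop just before the next event
      t <- t + stats::rexp(1, n_alive * (lambda + mu))
      break
    }
    wait <- stats::rexp(1, n_alive * (lambda + mu))
    if (!is.null(duration) && t + wait > duration) { t <- duration; break }
    t <- t + wait
    lin <- alive[sample.int(n_alive, 1L)]
    if (stats::runif(1) < lambda / (lambda + mu)) {
      n_lin <- n_lin + 1L
      t_start[n_lin] <- t; t_end[n_lin] <- NA_real_; parent[n_lin] <- lin
      alive <- c(alive, n_lin)
    } else {
      t_end[lin] <- t
      alive <- setdiff(alive, lin)
    }
    if (n_lin > 100000L) return(NULL)   # runaway radiation guard
  }
  t_stop <- t
  extant <- !is.na(match(seq_len(n_lin), alive))
  t_end[extant] <- t_stop
  # fossil sampling by Poisson thinning along each lineage
  fossils <- lapply(seq_len(n_lin), function(l) {
    len <- t_end[l] - t_start[l]
    k <- if (psi > 0 && len > 0) stats::rpois(1, psi * len) else 0L
    if (k > 0) sort(stats::runif(k, t_start[l], t_end[l])) else numeric(0)
  })
  sampled_extant <- extant & (stats::runif(n_lin) < rho)
  kids <- split(seq_len(n_lin)[-1], parent[-1])
  # does any sample exist on/under this lineage?
  sampled_below <- logical(n_lin)
  ord <- order(t_start, decreasing = TRUE)  # children before parents
  for (l in ord) {
    ch <- kids[[as.character(l)]]
    sampled_below[l] <- sampled_extant[l] || length(fossils[[l]]) > 0 ||
      (!is.null(ch) && any(sampled_below[ch]))
  }
  if (!sampled_below[1]) return(NULL)
  tip_count <- 0L
  build <- function(l, from_time) {
    ch <- kids[[as.character(l)]]
    ch <- ch[sampled_below[ch]]
    latest_birth <- if (length(ch)) max(t_start[ch]) else -Inf
    term_time <- if (sampled_extant[l]) t_end[l]
      else if (length(fossils[[l]]) && max(fossils[[l]]) > latest_birth)
        max(fossils[[l]])
      else NA_real_
    if (!is.na(term_time)) ch <- ch[t_start[ch] < term_time]
    cur <- NULL; cur_time <- NA_real_
    if (!is.na(term_time)) {
      tip_count <<- tip_count + 1L
      cur <- paste0("t", tip_count)
      cur_time <- term_time
    }
    for (cl in ch[order(t_start[ch], decreasing = TRUE)]) {
      sub <- build(cl, t_start[cl])
      if (is.null(cur)) {
        cur <- sub$str; cur_time <- sub$time
      } else {
        cur <- paste0("(", cur, ":", cur_time - t_start[cl], ",",
                      sub$str, ":", sub$time - t_start[cl], ")")
        cur_time <- t_start[cl]
      }
    }
    list(str = cur, time = cur_time)
  }
  top <- build(1L, 0)
  if (is.null(top$str) || tip_count < 2L) return(NULL)
  if (!startsWith(top$str, "(")) return(NULL)  # single sampled terminal
  tr <- ape::read.tree(text = paste0(top$str, ";"))
  tr
}

# ---- continuous-trait simulation --------------------------------------------

#' Simulate continuous traits along a tree
#'
#' Branch-wise recursive simulation (independent of the matrix-based
#' likelihood code): Gaussian models draw exact branch transitions, the
#' pulsed model superimposes compound-Poisson normal jumps placed uniformly
#' along branches, and environment-coupled/multi-peak OU use exact
#' per-segment updates (the curve treated as piecewise linear at 0.25 Myr).
#'
#' @param tree A `phylo` (for multi-peak models, `spec$regimes$tree` is
#'   used).
#' @param spec A [model_spec()] with complete parameters.
#' @param nsim Number of replicate tip vectors.
#' @param seed RNG seed.
#' @param return_history Record pulsed jump histories (list of data.frames,
#'   one per replicate) in `attr(, "jumps")`.
#' @return Matrix (tips x nsim) of trait values, rownames = tip labels;
#'   a vector when `nsim = 1`.
#' @export
simulate_continuous <- function(tree, spec, nsim = 1L, seed = 1L,
                                return_history = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$name %in% c("OUM3_HABITAT", "OUM2_HABITAT", "OUM3_CRISIS")) {
    tree <- spec$regimes$tree
  }
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  depth <- node_depths(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge)))
  p <- spec$params
  .with_seed(seed, {
    X <- matrix(NA_real_, nn, nsim)
    X[nt + 1L, ] <- p$z0
    jumps <- if (return_history) vector("list", nsim)
    edge_key <- if (!is.null(spec$regimes))
      .map_edge_index(spec$regimes, po)
    for (e in pre) {
      par <- po$edge[e, 1]; ch <- po$edge[e, 2]
      t <- po$edge.length[e]
      xp <- X[par, ]
      X[ch, ] <- switch(spec$name,
        BM = xp + stats::rnorm(nsim, 0, sqrt(p$sig2 * t)),
        TREND = xp + p$mu_trend * t + stats::rnorm(nsim, 0, sqrt(p$sig2 * t)),
        KAPPA = xp + stats::rnorm(nsim, 0, sqrt(p$sig2 * t^p$kappa)),
        EB = {
          r <- p$r_eb
          v <- if (abs(r) < 1e-12) p$sig2 * t else
            p$sig2 * (exp(r * depth[ch]) - exp(r * depth[par])) / r
          xp + stats::rnorm(nsim, 0, sqrt(v))
        },
        OU = {
          d <- exp(-p$alpha * t)
          v <- p$sig2 * .omexp(2 * p$alpha * t) / (2 * p$alpha)
          p$theta + (xp - p$theta) * d + stats::rnorm(nsim, 0, sqrt(v))
        },
        PULSED = {
          k <- stats::rpois(nsim, p$lambda_j * t)
          if (return_history) {
            for (s in which(k > 0)) {
              jumps[[s]] <- rbind(jumps[[s]], data.frame(
                edge = e, parent = par, child = ch,
                position = stats::runif(k[s], 0, t),
                size = stats::rnorm(k[s], 0, sqrt(p$delta2))))
            }
          }
          xp + stats::rnorm(nsim, 0, sqrt(p$sig2 * t + p$delta2 * k))
        },
        ENV_OU_TEMP = , ENV_OU_OXY =
          .sim_env_ou_branch(xp, depth[par], t, p, spec$curve,
                             spec$root_age_ma, nsim),
        OUM3_HABITAT = , OUM2_HABITAT = , OUM3_CRISIS = {
          segs <- spec$regimes$maps[[edge_key[e]]]
          xx <- xp
          for (j in seq_along(segs)) {
            reg <- names(segs)[j]; s <- segs[[j]]
            th <- p$theta[[reg]]
            al <- if (!is.null(p$alpha_k)) p$alpha_k[[reg]] else p$alpha
            s2 <- if (!is.null(p$sig2_k)) p$sig2_k[[reg]] else p$sig2
            if (al < 1e-12) {
              xx <- xx + stats::rnorm(nsim, 0, sqrt(s2 * s))
            } else {
              d <- exp(-al * s)
              v <- s2 * .omexp(2 * al * s) / (2 * al)
              xx <- th + (xx - th) * d + stats::rnorm(nsim, 0, sqrt(v))
            }
          }
          xx
        },
        stop("unsupported model for simulation: ", spec$name))
    }
    out <- X[seq_len(nt), , drop = FALSE]
    rownames(out) <- tree$tip.label
    if (return_history) attr(out, "jumps") <- jumps
    if (nsim == 1L && !return_history) out <- stats::setNames(out[, 1], tree$tip.label)
    out
  })
}

# exact OU transition along one branch with a piecewise-linear optimum
.sim_env_ou_branch <- function(xp, d0, t, p, curve, root_age_ma, nsim,
                               step = 0.25) {
  if (is.null(curve) || is.null(root_age_ma)) {
    stop("environment-coupled simulation needs curve and root_age_ma")
  }
  a <- max(p$alpha, 1e-10)
  m <- max(1L, ceiling(t / step)); h <- t / m
  ages <- root_age_ma - (d0 + h * (0:m))
  Ev <- env_value_at(curve, ages)
  d <- exp(-a * h)
  one <- .omexp(a * h)
  ramp <- h - one / a
  sdq <- sqrt(p$sig2 * .omexp(2 * a * h) / (2 * a))
  x <- xp
  for (j in seq_len(m)) {
    slope <- (Ev[j + 1] - Ev[j]) / h
    det <- p$theta0 * one + p$beta * (Ev[j] * one + slope * ramp)
    x <- x * d + det + stats::rnorm(nsim, 0, sdq)
  }
  x
}

# ---- discrete-character simulation ------------------------------------------

#' Simulate a discrete character with its full history
#'
#' Gillespie simulation of the continuous-time Markov chain along every
#' branch; the realized history is returned as a `regime_map` so mapping and
#' painting code can be validated against the truth.
#'
#' @param tree A `phylo`.
#' @param Q Rate matrix with state dimnames (rows sum to 0).
#' @param root_state Starting state (default: drawn from the stationary
#'   distribution of `Q`).
#' @param seed RNG seed.
#' @return List: `tip_states` (named character), `map` (`regime_map`),
#'   `n_events`.
#' @export
simulate_discrete <- function(tree, Q, root_state = NULL, seed = 1L) {
  .validate_q(Q)
  states <- rownames(Q)
  k <- length(states)
  nt <- ape::Ntip(tree); nn <- nt + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge)))
  .with_seed(seed, {
    node_state <- integer(nn)
    node_state[nt + 1L] <- if (is.null(root_state)) {
      sample.int(k, 1L, prob = .root_prior_vec("stationary", Q))
    } else match(root_state, states)
    if (is.na(node_state[nt + 1L])) stop("unknown root state")
    maps_po <- vector("list", nrow(po$edge))
    n_events <- 0L
    for (e in pre) {
      par <- po$edge[e, 1]; ch <- po$edge[e, 2]
      t <- po$edge.length[e]
      s <- node_state[par]
      segs <- numeric(0); labs <- character(0)
      pos <- 0
      repeat {
        rate <- -Q[s, s]
        wait <- if (rate > 0) stats::rexp(1, rate) else Inf
        if (pos + wait >= t) {
          segs <- c(segs, t - pos); labs <- c(labs, states[s])
          break
        }
        pos <- pos + wait
        segs <- c(segs, wait)
        labs <- c(labs, states[s])
        s <- sample.int(k, 1L, prob = pmax(Q[s, ], 0) *
                          as.numeric(seq_len(k) != s))
        n_events <- n_events + 1L
      }
      # merge (no-op unless a self-transition slipped in) and store
      maps_po[[e]] <- stats::setNames(segs, labs)
      node_state[ch] <- s
    }
    edge_key <- match(paste(tree$edge[, 1], tree$edge[, 2]),
                      paste(po$edge[, 1], po$edge[, 2]))
    map <- regime_map(tree, maps_po[edge_key],
                      node_state = states[node_state], states = states)
    list(tip_states = stats::setNames(states[node_state[seq_len(nt)]],
                                      tree$tip.label),
         map = map, n_events = n_events)
  })
}

# ---- environmental curves and communities -----------------------------------

#' Simulate a smooth environmental series on a 1 Myr grid
#'
#' Sum of low-frequency harmonics with 1/f amplitude decay, scaled by
#' `roughness`; `roughness = 0` gives a constant series. Values are clipped
#' to `bounds` when supplied.
#'
#' @param window `c(t0, t1)` ages in Ma with `t0 > t1 >= 0`.
#' @param roughness Amplitude scale (same units as `mean`).
#' @param mean Series mean.
#' @param bounds Optional `c(min, max)` clip.
#' @param n_harmonics Number of harmonics (default 6).
#' @param seed RNG seed.
#' @return Data.frame `age_ma`, `value` sampled every 1 Myr from `t0` down
#'   to `t1`.
#' @export
simulate_env_curve <- function(window, roughness = 1, mean = 0, bounds = NULL,
                               n_harmonics = 6L, seed = 1L) {
  t0 <- window[1]; t1 <- window[2]
  if (!(t0 > t1) || t1 < 0) stop("window must satisfy t0 > t1 >= 0")
  ages <- seq(t0, t1, by = -1)
  .with_seed(seed, {
    v <- rep(mean, length(ages))
    if (roughness > 0) {
      u <- (t0 - ages) / (t0 - t1)
      for (j in seq_len(n_harmonics)) {
        a <- stats::rnorm(1) / j; b <- stats::rnorm(1) / j
        v <- v + roughness * (a * cos(2 * pi * j * u) + b * sin(2 * pi * j * u))
      }
    }
    if (!is.null(bounds)) v <- pmin(pmax(v, bounds[1]), bounds[2])
    data.frame(age_ma = ages, value = v)
  })
}

#' Simulate a community/assemblage table
#'
#' Species with log-normal maximum lengths assigned to guilds and
#' assemblages, for exercising the predator/prey tallying rules.
#'
#' @param n_taxa Number of species (>= 1).
#' @param size_meanlog,size_sdlog Log-normal parameters of length (ln cm).
#' @param guild_probs Named probabilities over the eight guilds (defaults to
#'   a mixed fauna).
#' @param n_assemblages Number of assemblages to spread species over.
#' @param seed RNG seed.
#' @return Data.frame `assemblage`, `species`, `max_length_cm`, `guild`.
#' @export
simulate_community <- function(n_taxa, size_meanlog = 3, size_sdlog = 1,
                               guild_probs = NULL, n_assemblages = 5L,
                               seed = 1L) {
  if (n_taxa < 1) stop("n_taxa must be >= 1")
  guilds <- c("carnivorous_fish", "nautiloid", "eurypterine", "stylonurine",
              "hibbertopterid", "sessile", "mobile_benthic", "nektonic")
  if (is.null(guild_probs)) {
    guild_probs <- stats::setNames(
      c(0.10, 0.05, 0.15, 0.08, 0.02, 0.20, 0.25, 0.15), guilds)
  }
  if (!all(names(guild_probs) %in% guilds)) {
    stop("guild_probs names must be drawn from: ", paste(guilds, collapse = ", "))
  }
  .with_seed(seed, {
    data.frame(
      assemblage = sample.int(n_assemblages, n_taxa, replace = TRUE),
      species = sprintf("sp%03d", seq_len(n_taxa)),
      max_length_cm = stats::rlnorm(n_taxa, size_meanlog, size_sdlog),
      guild = sample(names(guild_probs), n_taxa, replace = TRUE,
                     prob = guild_probs))
  })
}

# ---- the default synthetic scenario -----------------------------------------

#' Default parameters of the synthetic eurypterid-like scenario
#'
#' A fossil-rich clade spanning 467-252 Ma with ~135 sampled tips, log body
#' sizes spanning roughly ln(2 cm) to ln(250 cm) generated under a pulsed
#' process rooted at ln(16.7) (a few large jumps against weak Brownian
#' drift), a 3-state habitat character whose direct marine<->continental
#' rates are zero (terrestrialization only through marginal settings),
#' smooth temperature (deg C) and dissolved-oxygen (uM) curves, latitudes
#' unrelated to size, and a mixed community table.
#'
#' @return Named list of scenario parameters.
#' @export
scenario_defaults <- function() {
  list(
    n_tips = 135L, root_age_ma = 467, tip_floor_ma = 252,
    fbd = list(lambda = 0.08, mu = 0.06, psi = 0.045, rho = 0),
    trait = list(z0 = log(16.7), sig2 = 0.001, lambda_j = 3 / 215,
                 delta2 = 0.5),
    q_rates = c(0.008, 0, 0.008, 0.004, 0, 0.002),  # marine/marginal/continental
    root_habitat = "marine",
    temp = list(mean = 28, roughness = 4, bounds = c(15, 40)),
    oxy = list(mean = 190, roughness = 30, bounds = c(120, 260)),
    latitude = list(mean = -15, sd = 20),
    community = list(n_taxa = 160L, n_assemblages = 8L),
    crisis_age_ma = 372,
    n_posterior_trees = 20L,
    bl_jitter_sd = 0.15
  )
}

#' Simulate a complete eurypterid-like analysis scenario
#'
#' Generates everything the pipeline consumes: a reference (mcc-like) FBD
#' tree with `n_tips` fossil tips, a set of pseudo-posterior trees (same
#' topology, branch lengths jittered log-normally to emulate temporal
#' uncertainty), pulsed-model body sizes, a habitat history simulated under
#' a rate matrix with structural marine<->continental zeros, temperature
#' and oxygen curves, palaeolatitudes independent of size, and a community
#' table.
#'
#' @param seed RNG seed.
#' @param config Overrides merged onto [scenario_defaults()].
#' @return List: `mcc`, `trees`, `traits` (data.frame), `habitat_truth`
#'   (`regime_map`), `temp_curve`, `oxy_curve` (sample data.frames),
#'   `community`, `config`.
#' @export
simulate_scenario <- function(seed = 1L, config = list()) {
  cfg <- utils::modifyList(scenario_defaults(), config)
  span <- cfg$root_age_ma - cfg$tip_floor_ma
  # reference tree: retry until tip count is near target, then thin
  mcc <- NULL
  for (k in 1:60) {
    cand <- simulate_fbd_tree(cfg$fbd$lambda, cfg$fbd$mu, cfg$fbd$psi,
                              duration = span, rho = cfg$fbd$rho,
                              seed = seed * 1000L + k, min_tips = 2L)
    if (ape::Ntip(cand) >= cfg$n_tips) { mcc <- cand; break }
  }
  if (is.null(mcc)) stop("scenario tree simulation failed to reach ",
                         cfg$n_tips, " tips")
  if (ape::Ntip(mcc) > cfg$n_tips) {
    keep <- .with_seed(seed + 7L,
                       sample(mcc$tip.label, cfg$n_tips))
    mcc <- prune_to_taxa(mcc, keep)
  }
  mcc$tip.label <- sprintf("taxon_%03d", seq_len(ape::Ntip(mcc)))
  trees <- .with_seed(seed + 11L, {
    lapply(seq_len(cfg$n_posterior_trees), function(i) {
      tr <- mcc
      tr$edge.length <- tr$edge.length *
        stats::rlnorm(length(tr$edge.length), 0, cfg$bl_jitter_sd)
      tr
    })
  })
  class(trees) <- "multiPhylo"
  pulsed_spec <- model_spec("PULSED", cfg$trait)
  x <- simulate_continuous(mcc, pulsed_spec, seed = seed + 13L)
  Q <- make_q_matrix(cfg$q_rates)
  hab <- simulate_discrete(mcc, Q, root_state = cfg$root_habitat,
                           seed = seed + 17L)
  # curves extend well below the tip floor: the pseudo-posterior trees have
  # jittered branch lengths, so their root-to-tip spans exceed the reference
  # tree's and the environment-coupled fits must stay inside the curve range
  env_window <- c(cfg$root_age_ma + 5, max(0, cfg$tip_floor_ma - 40))
  temp <- simulate_env_curve(env_window,
                             roughness = cfg$temp$roughness,
                             mean = cfg$temp$mean, bounds = cfg$temp$bounds,
                             seed = seed + 19L)
  oxy <- simulate_env_curve(env_window,
                            roughness = cfg$oxy$roughness,
                            mean = cfg$oxy$mean, bounds = cfg$oxy$bounds,
                            seed = seed + 23L)
  lat <- .with_seed(seed + 29L, {
    pmin(pmax(stats::rnorm(ape::Ntip(mcc), cfg$latitude$mean,
                           cfg$latitude$sd), -90), 90)
  })
  suborder <- .suborder_split(mcc)
  traits <- data.frame(
    taxon = mcc$tip.label,
    max_length_cm = exp(unname(x[mcc$tip.label])),
    log_size = unname(x[mcc$tip.label]),
    habitat = unname(hab$tip_states[mcc$tip.label]),
    palaeolatitude_deg = lat,
    suborder = suborder)
  community <- simulate_community(cfg$community$n_taxa,
                                  n_assemblages = cfg$community$n_assemblages,
                                  seed = seed + 31L)
  list(mcc = mcc, trees = trees, traits = traits, habitat_truth = hab$map,
       temp_curve = temp, oxy_curve = oxy, community = community,
       config = cfg, seed = seed)
}

# label the two basal subtrees as suborders (Eurypterina / Stylonurina stand-ins)
.suborder_split <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  first <- c(kids[1], if (kids[1] > ape::Ntip(tree)) .descendants(tree, kids[1]))
  tips1 <- first[first <= ape::Ntip(tree)]
  out <- rep("Eurypterina", ape::Ntip(tree))
  out[tips1] <- "Stylonurina"
  out
}
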