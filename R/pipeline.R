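#' Validate a pipeline run configuration
#'
#' Checks every field up front and reports all problems at once. Required:
#' `paths$trees`, `paths$traits`, `out_dir`; `root_age_ma` whenever an
#' environment-coupled model is in `models` (with `paths$temp_curve` /
#' `paths$oxy_curve`); `crisis_age_ma` for the crisis model.
#'
#' @param config Named list (or path to a YAML file).
#' @return The normalized config, invisibly; errors list every offending
#'   field.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    models = trait_model_names(), n_maps = 1000L, n_posterior_trees = NULL,
    thresholds = list(large = 50, giant = 100), crisis_age_ma = NULL,
    root_age_ma = NULL, lambda_policy = "fixed_1",
    seeds = list(maps = 1L, fit = 1L, anova = 1L),
    fit_options = list(n_restarts = 10L), out_dir = NULL, paths = list())
  cfg <- utils::modifyList(defaults, config)
  errs <- character(0)
  need <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  need(!is.null(cfg$paths$trees), "paths$trees is required")
  need(!is.null(cfg$paths$traits), "paths$traits is required")
  need(!is.null(cfg$out_dir), "out_dir is required")
  for (p in c("trees", "mcc", "traits", "temp_curve", "oxy_curve", "community")) {
    if (!is.null(cfg$paths[[p]]) && !file.exists(cfg$paths[[p]])) {
      errs <- c(errs, paste0("paths$", p, " does not exist: ", cfg$paths[[p]]))
    }
  }
  bad <- setdiff(cfg$models, trait_model_names())
  if (length(bad)) errs <- c(errs, paste0("unknown model name(s): ",
                                          paste(bad, collapse = ", ")))
  need(all(unlist(cfg$thresholds) > 0), "thresholds must be positive")
  need(cfg$n_maps >= 1, "n_maps must be >= 1")
  env_models <- intersect(cfg$models, c("ENV_OU_TEMP", "ENV_OU_OXY"))
  if (length(env_models)) {
    need(!is.null(cfg$root_age_ma),
         "root_age_ma is required for environment-coupled models")
    if ("ENV_OU_TEMP" %in% env_models) {
      need(!is.null(cfg$paths$temp_curve), "paths$temp_curve required for ENV_OU_TEMP")
    }
    if ("ENV_OU_OXY" %in% env_models) {
      need(!is.null(cfg$paths$oxy_curve), "paths$oxy_curve required for ENV_OU_OXY")
    }
  }
  if ("OUM3_CRISIS" %in% cfg$models) {
    need(!is.null(cfg$crisis_age_ma), "crisis_age_ma required for OUM3_CRISIS")
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: read inputs; fit environmental curves;
#' select an Mk habitat model and draw stochastic maps (summaries,
#' colonization counts, regime paintings); fit the trait models across the
#' tree set; rank by median AICc weight; reconstruct the root size and count
#' origins of large/giant size; PGLS of size on palaeolatitude; ecospace
#' permutational ANOVA and correlation screen. All outputs are written under
#' `out_dir` together with a manifest (seeds, config, package version). A
#' stage failure halts with a stage-named error; outputs of completed stages
#' remain on disk.
#'
#' @param config Config list or YAML path (see [validate_run_config()]).
#' @return Invisible list with the main in-memory results.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()

  stage("read_inputs", {
    trees <- read_trees(cfg$paths$trees)
    if (!is.null(cfg$n_posterior_trees)) {
      trees <- trees[seq_len(min(length(trees), cfg$n_posterior_trees))]
      class(trees) <- "multiPhylo"
    }
    mcc <- if (!is.null(cfg$paths$mcc)) read_trees(cfg$paths$mcc)[[1]] else trees[[1]]
    traits <- read_trait_table(cfg$paths$traits)
    res$trees <- trees; res$mcc <- mcc; res$traits <- traits
  })
  x <- stats::setNames(res$traits$log_size, res$traits$taxon)
  habitat <- if ("habitat" %in% names(res$traits)) {
    stats::setNames(res$traits$habitat, res$traits$taxon)
  }

  curves <- stage("env_curves", {
    out <- list()
    if (!is.null(cfg$paths$temp_curve)) out$temp <- read_env_curve(cfg$paths$temp_curve)
    if (!is.null(cfg$paths$oxy_curve)) out$oxy <- read_env_curve(cfg$paths$oxy_curve)
    out
  })

  need_maps <- any(c("OUM3_HABITAT", "OUM2_HABITAT") %in% cfg$models)
  if (!is.null(habitat)) {
    stage("habitat_evolution", {
      mk <- select_mk_model(res$mcc, habitat)
      maps <- stochastic_map(res$mcc, habitat, mk$Q, n_maps = cfg$n_maps,
                             seed = cfg$seeds$maps)
      res$mk <- mk
      res$map_summary <- summarize_maps(maps)
      res$colonizations <- count_colonizations(maps, "continental")
      if (need_maps) {
        # one map per posterior tree for the multi-peak fits
        res$tree_maps3 <- lapply(seq_along(res$trees), function(i)
          stochastic_map(res$trees[[i]], habitat, mk$Q, n_maps = 1L,
                         seed = cfg$seeds$maps + i)[[1]])
        res$tree_maps2 <- paint_habitat_regimes(res$tree_maps3, "two_peak")
      }
      utils::write.csv(
        data.frame(time = res$map_summary$time_grid,
                   t(res$map_summary$lineages_median)),
        file.path(cfg$out_dir, "ltt_median.csv"), row.names = FALSE)
      utils::write.csv(
        data.frame(map = seq_along(res$colonizations$counts),
                   colonizations = res$colonizations$counts),
        file.path(cfg$out_dir, "colonizations.csv"), row.names = FALSE)
    })
  }

  stage("trait_models", {
    regime_maps <- list()
    if (need_maps) {
      regime_maps$OUM3_HABITAT <- res$tree_maps3
      regime_maps$OUM2_HABITAT <- res$tree_maps2
    }
    if ("OUM3_CRISIS" %in% cfg$models) {
      clades <- .crisis_clades(cfg, res$mcc)
      crisis_age_rel <- .crisis_age_on_tree(cfg)
      regime_maps$OUM3_CRISIS <- function(tree)
        paint_crisis_regimes(tree, crisis_age_rel(tree), clades$clade1,
                             clades$clade2)
    }
    opts <- utils::modifyList(cfg$fit_options, list(seed = cfg$seeds$fit))
    res$fit_table <- fit_models_to_trees(
      res$trees, x, cfg$models, curves = curves, regime_maps = regime_maps,
      root_age_ma = cfg$root_age_ma, options = opts)
    utils::write.csv(res$fit_table, file.path(cfg$out_dir, "fits.csv"),
                     row.names = FALSE)
  })

  stage("model_ranking", {
    res$rank <- rank_models(res$fit_table)
    utils::write.csv(res$rank, file.path(cfg$out_dir, "rank.csv"),
                     row.names = FALSE)
  })

  stage("ancestral_size", {
    res$root <- ancestral_root(res$mcc, x[res$mcc$tip.label])
    thr <- cfg$thresholds
    res$origins <- list(
      large_mcc = count_size_origins(res$mcc, x[res$mcc$tip.label], log(thr$large)),
      giant_mcc = count_size_origins(res$mcc, x[res$mcc$tip.label], log(thr$giant)),
      large_trees = count_size_origins_trees(res$trees, x, log(thr$large)))
    utils::write.csv(
      data.frame(tree = seq_along(res$origins$large_trees$counts),
                 origins_large = res$origins$large_trees$counts),
      file.path(cfg$out_dir, "origins.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(root_cm = res$root$estimate_cm, root_ci_cm = res$root$ci95_cm,
           origins_large_mcc = res$origins$large_mcc,
           origins_giant_mcc = res$origins$giant_mcc),
      file.path(cfg$out_dir, "root_and_origins.json"), auto_unbox = TRUE,
      digits = NA)
  })

  if ("palaeolatitude_deg" %in% names(res$traits)) {
    stage("pgls_latitude", {
      lat <- stats::setNames(res$traits$palaeolatitude_deg, res$traits$taxon)
      res$pgls <- pgls_trees(res$trees, x, lat, cfg$lambda_policy)
      utils::write.csv(res$pgls$per_tree, file.path(cfg$out_dir, "pgls.csv"),
                       row.names = FALSE)
    })
  }

  if (!is.null(cfg$paths$community)) {
    stage("ecospace", {
      community <- utils::read.csv(cfg$paths$community, stringsAsFactors = FALSE)
      rec <- ecospace_records(community)
      if (length(unique(rec$size_group)) == 2) {
        res$anova <- permutational_anova(rec, seed = cfg$seeds$anova)
        jsonlite::write_json(res$anova, file.path(cfg$out_dir, "anova.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      sizes <- stats::setNames(community$max_length_cm, community$species)
      res$correlations <- correlation_report(rec, sizes, seed = cfg$seeds$anova)
      res$ecospace <- rec
      utils::write.csv(rec, file.path(cfg$out_dir, "ecospace.csv"),
                       row.names = FALSE)
      utils::write.csv(res$correlations,
                       file.path(cfg$out_dir, "correlations.csv"),
                       row.names = FALSE)
    })
  }

  manifest <- list(
    package = "palaeotrait",
    version = as.character(utils::packageVersion("palaeotrait")),
    seeds = cfg$seeds, models = cfg$models, n_maps = cfg$n_maps,
    n_trees = length(res$trees), thresholds = cfg$thresholds,
    root_age_ma = cfg$root_age_ma, crisis_age_ma = cfg$crisis_age_ma)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

# crisis clades: explicit tip lists in the config, or the two basal subtrees
.crisis_clades <- function(cfg, mcc) {
  if (!is.null(cfg$clades)) return(cfg$clades)
  root <- ape::Ntip(mcc) + 1L
  kids <- mcc$edge[mcc$edge[, 1] == root, 2]
  tips_under <- function(nd) {
    if (nd <= ape::Ntip(mcc)) return(mcc$tip.label[nd])
    dd <- .descendants(mcc, nd)
    mcc$tip.label[dd[dd <= ape::Ntip(mcc)]]
  }
  list(clade1 = tips_under(kids[1]), clade2 = tips_under(kids[2]))
}

# convert the absolute crisis age to each tree's own age scale
.crisis_age_on_tree <- function(cfg) {
  function(tree) {
    if (is.null(cfg$root_age_ma)) return(cfg$crisis_age_ma)
    # ages anchored at the youngest tip: express the absolute crisis age
    # relative to this tree's span below root_age_ma
    d <- node_depths(tree)
    span <- max(d[seq_len(ape::Ntip(tree))])
    cfg$crisis_age_ma - (cfg$root_age_ma - span)
  }
}

#' Write a self-contained synthetic demo scenario to disk
#'
#' Emits trees, a reference tree, trait and community CSVs, both
#' environmental curves, a ready-to-run pipeline config (YAML) and a
#' manifest recording the seed and scenario parameters.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param config Scenario overrides (see [scenario_defaults()]).
#' @return The path to the emitted config file.
#' @export
make_demo_data <- function(dir, seed = 1L, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- simulate_scenario(seed = seed, config = config)
  write_trees(sc$trees, file.path(dir, "trees.nwk"))
  write_trees(sc$mcc, file.path(dir, "mcc.nwk"))
  utils::write.csv(sc$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(sc$temp_curve, file.path(dir, "temp_curve.csv"), row.names = FALSE)
  utils::write.csv(sc$oxy_curve, file.path(dir, "oxy_curve.csv"), row.names = FALSE)
  utils::write.csv(sc$community, file.path(dir, "community.csv"), row.names = FALSE)
  cfg <- list(
    paths = list(trees = file.path(dir, "trees.nwk"),
                 mcc = file.path(dir, "mcc.nwk"),
                 traits = file.path(dir, "traits.csv"),
                 temp_curve = file.path(dir, "temp_curve.csv"),
                 oxy_curve = file.path(dir, "oxy_curve.csv"),
                 community = file.path(dir, "community.csv")),
    root_age_ma = sc$config$root_age_ma,
    crisis_age_ma = sc$config$crisis_age_ma,
    out_dir = file.path(dir, "results"),
    seeds = list(maps = seed, fit = seed, anova = seed))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  jsonlite::write_json(list(seed = seed, scenario = sc$config),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(cfg_path)
}
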