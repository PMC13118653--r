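# Synthetic metacommunity generator: a phylogeny with Brownian
# (phylogenetically conserved) traits, a dammed-reach environmental
# gradient with season-dependent heterogeneity, metacommunity sampling
# under tunable selection / dam-mediated dispersal limitation / drift, and
# a pure individual-based neutral source-sink simulator.

#' Simulation configuration
#'
#' Defaults emulate a ten-reach, two-season, four-replicate river survey:
#' libraries in the tens of thousands (lognormal, truncated), a
#' lognormal regional pool, Gaussian trait-environment selection on a
#' Brownian trait, dam-permeability mixing (`rho` per dam crossed), and
#' Dirichlet-multinomial drift. Per-season parameters are named vectors
#' over seasons; by default winter carries a stronger environmental
#' gradient, stronger selection and weaker drift than summer.
#'
#' @param n_taxa regional pool size.
#' @param n_reaches number of ordered reaches.
#' @param seasons season labels.
#' @param n_replicates fish per reach and season.
#' @param lib_meanlog,lib_sdlog,lib_min,lib_max truncated-lognormal library
#'   sizes (reads per sample).
#' @param pool_sdlog lognormal sd of regional pool abundances.
#' @param tree_model phylogeny model for the default tree
#'   (`"birth_death"` or `"coalescent"`).
#' @param sigma_sel per-season selection width (trait units); `Inf`
#'   disables selection.
#' @param rho per-season dam permeability in `[0, 1]` (mixing weight decays
#'   as `rho^dams`).
#' @param env_amplitude per-season amplitude of the longitudinal
#'   environmental gradient.
#' @param env_offset per-season mean level of the gradient scalar (shifts
#'   all reaches; relevant when the gradient is flat).
#' @param theta per-season Dirichlet concentration (large = weak drift).
#' @param reach_sd per-season sd of reach-level lognormal compositional
#'   deviates (reach-scale drift for dispersal limitation to act on).
#' @param bm_rate Brownian trait rate per unit branch length.
#' @param dams_per_segment dams between each pair of adjacent reaches.
#' @param seed master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 2000, n_reaches = 10,
                       seasons = c("summer", "winter"), n_replicates = 4,
                       lib_meanlog = log(55000), lib_sdlog = 0.4,
                       lib_min = 18000, lib_max = 140000,
                       pool_sdlog = 1.5, tree_model = "birth_death",
                       sigma_sel = c(summer = 2.5, winter = 0.25),
                       rho = c(summer = 0.95, winter = 0.3),
                       env_amplitude = c(summer = 0.6, winter = 1.2),
                       env_offset = c(summer = 0, winter = 0),
                       theta = c(summer = 30, winter = 100),
                       reach_sd = c(summer = 0.5, winter = 0.5),
                       bm_rate = 1, dams_per_segment = 1, seed = 1) {
  cfg <- list(n_taxa = n_taxa, n_reaches = n_reaches, seasons = seasons,
              n_replicates = n_replicates, lib_meanlog = lib_meanlog,
              lib_sdlog = lib_sdlog, lib_min = lib_min, lib_max = lib_max,
              pool_sdlog = pool_sdlog, tree_model = tree_model,
              sigma_sel = expand_per_season(sigma_sel, seasons),
              rho = expand_per_season(rho, seasons),
              env_amplitude = expand_per_season(env_amplitude, seasons),
              env_offset = expand_per_season(env_offset, seasons),
              theta = expand_per_season(theta, seasons),
              reach_sd = expand_per_season(reach_sd, seasons),
              bm_rate = bm_rate, dams_per_segment = dams_per_segment,
              seed = seed)
  stopifnot(cfg$n_taxa >= 3, cfg$n_reaches >= 2, cfg$n_replicates >= 1,
            all(cfg$rho >= 0 & cfg$rho <= 1), all(cfg$sigma_sel > 0),
            all(cfg$theta > 0))
  class(cfg) <- "sim_config"
  cfg
}

expand_per_season <- function(x, seasons) {
  if (length(x) == 1L && is.null(names(x))) {
    return(setNames(rep(x, length(seasons)), seasons))
  }
  if (!all(seasons %in% names(x))) stop("per-season parameter missing a season")
  x[seasons]
}

#' Single-regime simulation presets
#'
#' `"winter_like"`: strong gradient, strong conserved selection, low drift.
#' `"summer_like"`: weak gradient, high mixing, high drift.
#' `"neutral"`: no selection, full mixing. `"selection"`: strong selection
#' under a shared (flat) environment. `"dispersal_limited"`: no selection,
#' impermeable dams. `"mixed"`: the two-season study-like default.
#'
#' @param preset preset name.
#' @param seed master seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_preset <- function(preset = c("mixed", "winter_like", "summer_like",
                                  "neutral", "selection", "dispersal_limited"),
                       seed = 1, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    mixed = list(),
    winter_like = list(seasons = "winter",
                       sigma_sel = c(winter = 0.25), rho = c(winter = 0.3),
                       env_amplitude = c(winter = 1.2),
                       theta = c(winter = 100), reach_sd = c(winter = 0.5)),
    summer_like = list(seasons = "summer",
                       sigma_sel = c(summer = 2.5), rho = c(summer = 0.95),
                       env_amplitude = c(summer = 0.6),
                       theta = c(summer = 30), reach_sd = c(summer = 0.5)),
    neutral = list(seasons = "summer", sigma_sel = c(summer = 1e6),
                   rho = c(summer = 1), env_amplitude = c(summer = 0),
                   theta = c(summer = 100), reach_sd = c(summer = 0.5)),
    selection = list(seasons = "summer", sigma_sel = c(summer = 0.3),
                     rho = c(summer = 1), env_amplitude = c(summer = 0),
                     env_offset = c(summer = 1.5),
                     theta = c(summer = 100), reach_sd = c(summer = 0.5)),
    dispersal_limited = list(seasons = "summer", sigma_sel = c(summer = 1e6),
                             rho = c(summer = 0.3),
                             env_amplitude = c(summer = 0),
                             theta = c(summer = 100),
                             reach_sd = c(summer = 0.8)))
  user <- list(...)
  args <- c(user, args[setdiff(names(args), names(user))])
  do.call(sim_config, c(args, list(seed = seed)))
}

#' Simulate a random phylogeny
#'
#' @param n_taxa number of leaves (>= 3).
#' @param model `"coalescent"` (ultrametric) or `"birth_death"`.
#' @param seed integer seed.
#' @return an [ape::phylo] with tip labels `OTU_0001`, ...
#' @export
simulate_tree <- function(n_taxa, model = c("coalescent", "birth_death"),
                          seed = NULL) {
  model <- match.arg(model)
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  tree <- with_seed(seed, {
    if (model == "coalescent") ape::rcoal(n_taxa)
    else ape::rphylo(n_taxa, birth = 1, death = 0.4)
  })
  tree$tip.label <- sprintf("OTU_%04d", seq_len(n_taxa))
  tree
}

#' Simulate a Brownian trait on a phylogeny
#'
#' Preorder walk from the root: each branch adds a normal increment with
#' variance `rate * branch length`, so leaf-trait covariance equals `rate`
#' times shared path length.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param rate Brownian rate.
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @return named numeric vector of leaf trait values.
#' @export
simulate_traits_bm <- function(tree, rate = 1, root_value = 0, seed = NULL) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- ape::reorder.phylo(tree, "cladewise")
  vals <- numeric(nnode)
  vals[ntip + 1L] <- root_value
  with_seed(seed, {
    inc <- rnorm(nrow(edge$edge), 0, sqrt(rate * edge$edge.length))
    for (e in seq_len(nrow(edge$edge))) {
      vals[edge$edge[e, 2L]] <- vals[edge$edge[e, 1L]] + inc[e]
    }
  })
  setNames(vals[seq_len(ntip)], tree$tip.label)
}

#' Simulate the reach environment
#'
#' A monotone longitudinal gradient scalar `e_r` per reach and season,
#' scaled by the per-season amplitude plus a small noise term, and an
#' environmental table whose physicochemical columns are affine functions
#' of `e_r` with measurement noise (NH4/NO3/NO2 included so DIN is
#' derivable and satisfies the component sum).
#'
#' @param config a `sim_config`.
#' @param seed integer seed (default derived from the config seed).
#' @return list with `env` (data.frame incl. DIN) and `e` (matrix reaches x
#'   seasons of the gradient scalar).
#' @export
simulate_environment <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- derive_seed(config$seed, "environment")
  k <- config$n_reaches
  reaches <- sprintf("S%d", seq_len(k))
  base <- if (k > 1) seq(-1, 1, length.out = k) else 0
  with_seed(seed, {
    e <- sapply(config$seasons, function(s) {
      amp <- config$env_amplitude[[s]]
      config$env_offset[[s]] + amp * base +
        rnorm(k, 0, 0.05 * max(amp, 1e-12))
    })
    e <- matrix(e, nrow = k, dimnames = list(reaches, config$seasons))
    rows <- list()
    for (s in config$seasons) {
      es <- e[, s]
      nh4 <- pmax(0.25 + 0.10 * es + rnorm(k, 0, 0.01), 0)
      no3 <- pmax(1.20 + 0.40 * es + rnorm(k, 0, 0.04), 0)
      no2 <- pmax(0.05 + 0.02 * es + rnorm(k, 0, 0.003), 0)
      rows[[s]] <- data.frame(
        reach = reaches, season = s,
        Tem = 18 + 6 * (s == config$seasons[1L]) + 0.5 * es + rnorm(k, 0, 0.2),
        DO = pmax(8.5 - 0.6 * es + rnorm(k, 0, 0.15), 0),
        pH = 7.8 + 0.1 * es + rnorm(k, 0, 0.05),
        EC = pmax(320 + 40 * es + rnorm(k, 0, 8), 0),
        Chla = pmax(4.5 + 1.2 * es + rnorm(k, 0, 0.3), 0),
        TN = pmax(1.8 + 0.5 * es + rnorm(k, 0, 0.05), 0),
        TP = pmax(0.08 + 0.02 * es + rnorm(k, 0, 0.004), 0),
        NH4 = nh4, NO3 = no3, NO2 = no2,
        COD = pmax(3.2 + 0.8 * es + rnorm(k, 0, 0.15), 0),
        stringsAsFactors = FALSE)
    }
    env <- compute_din(do.call(rbind, rows))
    rownames(env) <- NULL
    list(env = env, e = e)
  })
}

#' Dam geometry implied by a configuration
#'
#' @param config a `sim_config`.
#' @return data.frame `reach`, `dams_to_next`.
#' @export
sim_dam_geometry <- function(config) {
  data.frame(reach = sprintf("S%d", seq_len(config$n_reaches)),
             dams_to_next = c(rep(config$dams_per_segment,
                                  config$n_reaches - 1L), NA),
             stringsAsFactors = FALSE)
}

#' Simulate the metacommunity
#'
#' Generative model per season: a lognormal regional pool `pi`; reach-level
#' expected composition `w_r(i)` proportional to
#' `pi_i * exp(-(trait_i - e_r)^2 / (2 sigma_sel^2)) * exp(eps_ri)`, with
#' `eps_ri` reach-level lognormal drift; dam-mediated mixing by a kernel
#' with weight `rho^dams(r, q)` over reaches (low permeability keeps
#' reaches apart, producing an approximately log-linear distance decay in
#' dam count); then each fish is a Dirichlet-multinomial draw around its
#' reach's mixed composition (concentration `theta`), at a truncated
#' lognormal library size.
#'
#' @param config a `sim_config`.
#' @param tree optional phylogeny (simulated if `NULL`).
#' @param traits optional named trait vector (simulated if `NULL`).
#' @param env optional result of [simulate_environment()].
#' @param seed master seed (default `config$seed`).
#' @return list with `table` (counts, OTUs x samples), `samples`
#'   (sample frame), `tree`, `traits`, `env`, `geometry`, and `truth`
#'   (regional pool, reach compositions before/after mixing, per-sample
#'   true probabilities, regime label).
#' @export
simulate_metacommunity <- function(config, tree = NULL, traits = NULL,
                                   env = NULL, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (is.null(tree)) {
    tree <- simulate_tree(config$n_taxa, model = config$tree_model,
                          seed = derive_seed(seed, "tree"))
  }
  if (is.null(traits)) {
    traits <- simulate_traits_bm(tree, rate = config$bm_rate,
                                 seed = derive_seed(seed, "traits"))
  }
  if (is.null(env)) {
    env <- simulate_environment(config, seed = derive_seed(seed, "environment"))
  }
  taxa <- tree$tip.label
  stopifnot(identical(sort(names(traits)), sort(taxa)))
  traits <- traits[taxa]
  # standardize traits so sigma_sel is on a comparable scale to the gradient
  tr <- (traits - mean(traits)) / sd(traits)
  k <- config$n_reaches
  reaches <- sprintf("S%d", seq_len(k))
  geometry <- sim_dam_geometry(config)
  dam_d <- reach_dam_matrix(geometry)
  pool <- with_seed(derive_seed(seed, "pool"), {
    p <- rlnorm(length(taxa), 0, config$pool_sdlog)
    p / sum(p)
  })
  tabs <- list(); samp <- list(); truth_w <- list(); w_reach <- list()
  for (s in config$seasons) {
    sseed <- derive_seed(seed, paste0("season:", s))
    sig <- config$sigma_sel[[s]]
    # reach-level deviates are Brownian on the tree (standardized), so
    # unmeasured reach-scale selection is itself phylogenetically
    # conserved -- reach-to-reach membership turnover stays clade-structured
    w <- sapply(seq_len(k), function(r) {
      sel <- exp(-((tr - env$e[r, s])^2) / (2 * sig^2))
      bmr <- simulate_traits_bm(tree, rate = config$bm_rate,
                                seed = derive_seed(sseed,
                                                   paste0("reach-bm:", r)))
      bmr <- bmr[taxa]
      eps <- exp(config$reach_sd[[s]] * (bmr - mean(bmr)) / sd(bmr))
      v <- pool * sel * eps
      v / sum(v)
    })
    colnames(w) <- reaches
    kernel <- config$rho[[s]]^dam_d
    kernel <- sweep(kernel, 1L, rowSums(kernel), "/")
    wm <- w %*% t(kernel)   # mixed composition per reach
    w_reach[[s]] <- list(before = w, after = wm)
    for (r in seq_len(k)) {
      for (rep_i in seq_len(config$n_replicates)) {
        sid <- sprintf("%s_%s_F%d", s, reaches[r], rep_i)
        cseed <- derive_seed(sseed, sid)
        draw <- with_seed(cseed, {
          lib <- round(min(max(rlnorm(1, config$lib_meanlog, config$lib_sdlog),
                               config$lib_min), config$lib_max))
          alpha <- config$theta[[s]] * wm[, r]
          g <- rgamma(length(alpha), shape = alpha)
          if (sum(g) == 0) g[which.max(alpha)] <- 1
          probs <- g / sum(g)
          list(counts = as.vector(rmultinom(1L, lib, probs)), probs = probs)
        })
        tabs[[sid]] <- draw$counts
        truth_w[[sid]] <- draw$probs
        samp[[sid]] <- data.frame(sample_id = sid, season = s,
                                  reach = reaches[r], replicate = rep_i,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  table <- do.call(cbind, tabs)
  rownames(table) <- taxa
  samples <- do.call(rbind, samp)
  rownames(samples) <- NULL
  samples$reach <- factor(samples$reach, levels = reaches)
  regime <- if (all(config$sigma_sel > 100)) {
    if (all(config$rho < 1)) "dispersal_limited" else "neutral"
  } else if (all(config$env_amplitude == 0)) "selection" else "mixed"
  list(table = table, samples = samples, tree = tree, traits = traits,
       env = env$env, e = env$e, geometry = geometry,
       truth = list(pool = setNames(pool, taxa), reach = w_reach,
                    local = do.call(cbind, truth_w), regime = regime))
}

#' Individual-based neutral local communities (Sloan source-sink)
#'
#' Each sample is a local community of `N` individuals connected to a fixed
#' source pool: starting from a multinomial draw from the pool, each
#' generation performs `N` single-individual Moran replacements (a uniform
#' individual dies; the replacement is a pool immigrant, else a copy of one
#' of the other local individuals). `m` is the immigration rate in the
#' diffusion sense -- the composite neutral parameter is `N m` -- so the
#' per-replacement immigration probability is `N m / (N m + N - 1)` and the
#' stationary count distribution is exactly Dirichlet-multinomial with
#' concentration `N m`, the discrete counterpart of Sloan's beta law with
#' parameters `(N m p, N m (1 - p))`.
#'
#' @param N local community size (>= 100).
#' @param m immigration rate in `(0, 1]` (diffusion convention; see above).
#' @param pool_p regional pool relative abundances (sums to 1).
#' @param n_samples number of independent local communities.
#' @param generations burn-in generations; default `max(100, ceil(4 / m))`,
#'   capped at 500.
#' @param seed master seed.
#' @return count matrix (taxa x samples) with every column summing to `N`.
#' @export
simulate_neutral <- function(N, m, pool_p, n_samples, generations = NULL,
                             seed = NULL) {
  if (N < 100) stop("N must be >= 100")
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  if (abs(sum(pool_p) - 1) > 1e-6) stop("pool_p must sum to 1")
  if (is.null(generations)) generations <- min(max(100, ceiling(4 / m)), 500)
  if (is.null(seed)) seed <- 0
  m_event <- N * m / (N * m + N - 1)
  out <- sapply(seq_len(n_samples), function(i) {
    with_seed(derive_seed(seed, paste0("neutral:", i)), {
      cpp_neutral_moran(as.integer(N), m_event, pool_p,
                        as.integer(generations))
    })
  })
  rownames(out) <- if (!is.null(names(pool_p))) names(pool_p) else
    sprintf("OTU_%04d", seq_along(pool_p))
  colnames(out) <- sprintf("sample_%03d", seq_len(n_samples))
  storage.mode(out) <- "double"
  out
}

#' Assign synthetic taxonomy by phylogenetic clades
#'
#' Cuts the tree's cophenetic distances into `n_phyla` clusters and labels
#' them `Phylum_01`, ...; lower ranks are left `"unclassified"`.
#'
#' @param tree an [ape::phylo].
#' @param n_phyla number of phylum-level groups.
#' @return taxonomy data.frame (`otu_id`, `phylum`, ..., `genus`).
#' @export
sim_taxonomy <- function(tree, n_phyla = 10) {
  d <- ape::cophenetic.phylo(tree)
  cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = "average"),
                      k = min(n_phyla, length(tree$tip.label)))
  data.frame(otu_id = names(cl),
             phylum = sprintf("Phylum_%02d", cl),
             class = "unclassified", order = "unclassified",
             family = "unclassified", genus = "unclassified",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a complete fixture bundle
#'
#' Simulates a metacommunity under `config` and writes every file the
#' pipeline readers consume (counts TSV, Newick tree, metadata, environment,
#' taxonomy, dam geometry) plus a YAML manifest recording the seed and
#' configuration. Re-running with the same config is byte-identical.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory (created if needed).
#' @return named vector of file paths, invisibly; the simulation object is
#'   attached as `attr(, "sim")`.
#' @export
generate_fixture_bundle <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_metacommunity(config)
  paths <- c(table = file.path(out_dir, "otu_table.tsv"),
             tree = file.path(out_dir, "tree.nwk"),
             metadata = file.path(out_dir, "metadata.tsv"),
             env = file.path(out_dir, "environment.tsv"),
             taxonomy = file.path(out_dir, "taxonomy.tsv"),
             geometry = file.path(out_dir, "dam_geometry.tsv"),
             manifest = file.path(out_dir, "manifest.yaml"))
  write_community_table(sim$table, paths[["table"]])
  ape::write.tree(sim$tree, paths[["tree"]])
  write.table(sim$samples, paths[["metadata"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$env, paths[["env"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim_taxonomy(sim$tree), paths[["taxonomy"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$geometry, paths[["geometry"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- list(package = "rivasm", seed = config$seed,
                   regime = sim$truth$regime,
                   config = unclass(config)[c("n_taxa", "n_reaches",
                     "seasons", "n_replicates", "pool_sdlog", "bm_rate",
                     "dams_per_segment")],
                   per_season = lapply(
                     c("sigma_sel", "rho", "env_amplitude", "theta",
                       "reach_sd"),
                     function(f) as.list(config[[f]])))
  yaml::write_yaml(manifest, paths[["manifest"]])
  structure(invisible(paths), sim = sim)
}
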