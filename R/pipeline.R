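# Orchestration: full-run configuration, input cross-validation, the
# stage-ordered analysis, and the TSV report writer.

#' Full-run configuration
#'
#' @param input either a `sim_config` (simulate) or a named list of file
#'   paths (`table`, `tree`, `metadata`, `env`, `taxonomy`, `geometry`).
#' @param depth rarefaction depth for alpha diversity.
#' @param n_perm permutations for matrix tests.
#' @param n_null null draws for betaNTI / RC_Bray.
#' @param bnti_thresh,rc_thresh assembly partition thresholds.
#' @param spec_min,occ_min specialist / core thresholds.
#' @param env_variables environmental variables for the Mantel family.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a `run_config` list.
#' @export
run_config <- function(input, depth = 15000, n_perm = 999, n_null = 999,
                       bnti_thresh = 2, rc_thresh = 0.95,
                       spec_min = 0.7, occ_min = 0.7,
                       env_variables = c("Tem", "DO", "pH", "EC", "Chla",
                                         "TN", "TP", "DIN", "COD"),
                       seed = 1) {
  structure(list(input = input, depth = depth, n_perm = n_perm,
                 n_null = n_null, bnti_thresh = bnti_thresh,
                 rc_thresh = rc_thresh, spec_min = spec_min,
                 occ_min = occ_min, env_variables = env_variables,
                 seed = seed),
            class = "run_config")
}

load_inputs <- function(input) {
  if (inherits(input, "sim_config")) {
    sim <- simulate_metacommunity(input)
    list(table = sim$table, samples = sim$samples, tree = sim$tree,
         env = sim$env, taxonomy = sim_taxonomy(sim$tree),
         geometry = sim$geometry)
  } else {
    list(table = read_community_table(input$table),
         samples = read_sample_frame(input$metadata),
         tree = if (!is.null(input$tree)) read_tree(input$tree),
         env = if (!is.null(input$env)) read_env_table(input$env),
         taxonomy = if (!is.null(input$taxonomy)) read_taxonomy(input$taxonomy),
         geometry = if (!is.null(input$geometry)) read_dam_geometry(input$geometry))
  }
}

#' Cross-validate an input bundle
#'
#' Checks registries against each other (table vs metadata vs tree vs
#' taxonomy vs geometry) and lists orphans both ways.
#'
#' @param inputs list with `table`, `samples` and optionally `tree`,
#'   `taxonomy`, `geometry`, `env`.
#' @param strict error (instead of report) when problems are found.
#' @return data.frame of problems (`check`, `detail`); zero rows when
#'   consistent.
#' @export
validate_inputs <- function(inputs, strict = FALSE) {
  probs <- list()
  note <- function(check, ids) {
    if (length(ids)) {
      probs[[length(probs) + 1L]] <<- data.frame(
        check = check, detail = paste(head(ids, 10L), collapse = ","),
        n = length(ids), stringsAsFactors = FALSE)
    }
  }
  tab_samples <- colnames(inputs$table)
  meta_samples <- inputs$samples$sample_id
  note("sample_in_table_not_metadata", setdiff(tab_samples, meta_samples))
  note("sample_in_metadata_not_table", setdiff(meta_samples, tab_samples))
  if (!is.null(inputs$tree)) {
    note("otu_in_table_not_tree",
         setdiff(rownames(inputs$table), inputs$tree$tip.label))
  }
  if (!is.null(inputs$taxonomy)) {
    note("otu_in_taxonomy_not_table",
         setdiff(inputs$taxonomy$otu_id, rownames(inputs$table)))
  }
  if (!is.null(inputs$geometry)) {
    note("reach_in_metadata_not_geometry",
         setdiff(as.character(inputs$samples$reach), inputs$geometry$reach))
  }
  out <- if (length(probs)) do.call(rbind, probs) else
    data.frame(check = character(), detail = character(), n = integer())
  if (strict && nrow(out)) {
    stop("input validation failed: ",
         paste(out$check, collapse = "; "))
  }
  out
}

#' Run the full assembly analysis
#'
#' Stages, in dependency order: OTU filtering; alpha diversity on rarefied
#' counts with two-way ANOVA effect sizes and Spearman reach trends;
#' Bray-Curtis / PCoA; PERMANOVA (season, and reach within each season) and
#' dispersion tests; distance-decay on dam counts per season; the Mantel
#' family (dams + environment, BH-adjusted) and MRM per season; betaNTI +
#' RC_Bray process partitioning per season; the Sloan neutral fit per
#' season; SPEC-OCCU specialists and core/detected set overlaps.
#'
#' @param config a `run_config`.
#' @return an `analysis_report` list of per-stage tables.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_inputs(config$input)
  issues <- validate_inputs(inputs)
  if (nrow(issues)) stop("inconsistent inputs; see validate_inputs()")
  table <- filter_otus(inputs$table, drop_singletons = TRUE)
  samples <- inputs$samples
  table <- table[, samples$sample_id, drop = FALSE]
  table <- table[rowSums(table) > 0, , drop = FALSE]
  seasons <- unique(samples$season)
  seed <- config$seed
  report <- list()
  report$filtering <- data.frame(
    n_otus = nrow(table), n_samples = ncol(table),
    n_removed = length(attr(table, "removed")))

  # -- alpha diversity ------------------------------------------------
  depth <- min(config$depth, min(colSums(table)))
  alpha <- alpha_diversity(table, tree = inputs$tree, depth = depth,
                           seed = derive_seed(seed, "rarefy"))
  alpha <- merge(alpha, samples, by = "sample_id", sort = FALSE)
  report$alpha <- alpha
  report$alpha_anova <- if (length(seasons) > 1L) {
    do.call(rbind, lapply(intersect(c("shannon", "chao1", "faith_pd"),
                                    names(alpha)), function(idx) {
      cbind(index = idx,
            two_way_anova_partial_eta2(alpha[[idx]], alpha$season, alpha$reach))
    }))
  }
  report$alpha_trend <- do.call(rbind, lapply(seasons, function(s) {
    sub <- alpha[alpha$season == s, ]
    do.call(rbind, lapply(intersect(c("shannon", "chao1", "faith_pd"),
                                    names(alpha)), function(idx) {
      tr <- spearman_trend(sub[[idx]], as.integer(sub$reach))
      data.frame(season = s, index = idx, rho = tr$rho, p = tr$p)
    }))
  }))

  # -- beta diversity -------------------------------------------------
  rel <- tss_normalize(table)
  bc <- bray_curtis(rel)
  ord <- pcoa(bc, n_axes = 2)
  report$pcoa <- data.frame(sample_id = rownames(ord$coordinates),
                            ord$coordinates, row.names = NULL)
  perma <- list()
  if (length(seasons) > 1L) {
    pm <- permanova(bc, samples$season, n_perm = config$n_perm,
                    seed = derive_seed(seed, "permanova:season"))
    perma[["season"]] <- data.frame(test = "season", factor = "season",
                                    F = pm$F, R2 = pm$R2, p = pm$p)
  }
  for (s in seasons) {
    ids <- samples$sample_id[samples$season == s]
    pm <- permanova(bc[ids, ids], samples$reach[samples$season == s],
                    n_perm = config$n_perm,
                    seed = derive_seed(seed, paste0("permanova:reach:", s)))
    bd <- beta_dispersion(bc[ids, ids], samples$reach[samples$season == s],
                          n_perm = config$n_perm,
                          seed = derive_seed(seed, paste0("disp:", s)))
    perma[[paste0("reach:", s)]] <- data.frame(
      test = paste0("reach_", s), factor = "reach",
      F = pm$F, R2 = pm$R2, p = pm$p)
    perma[[paste0("disp:", s)]] <- data.frame(
      test = paste0("dispersion_", s), factor = "reach",
      F = bd$F, R2 = NA_real_, p = bd$p)
  }
  report$permanova <- do.call(rbind, perma)
  rownames(report$permanova) <- NULL

  # -- spatial / environmental ---------------------------------------
  if (!is.null(inputs$geometry)) {
    ddr <- list(); mantelf <- list(); mrms <- list()
    for (s in seasons) {
      sub <- samples[samples$season == s, ]
      ids <- sub$sample_id
      dams <- dam_distance_matrix(inputs$geometry, sub)
      fit <- distance_decay(bc[ids, ids], dams, n_perm = config$n_perm,
                            seed = derive_seed(seed, paste0("ddr:", s)))
      ddr[[s]] <- data.frame(season = s, slope = fit$slope,
                             intercept = fit$intercept, R2 = fit$R2,
                             r_mantel = fit$r_mantel, p = fit$p)
      if (!is.null(inputs$env)) {
        vars <- intersect(config$env_variables,
                          names(compute_din_if_possible(inputs$env)))
        envx <- compute_din_if_possible(inputs$env)
        fam <- mantel_family(bc[ids, ids], envx, sub, vars, s, dams = dams,
                             n_perm = config$n_perm,
                             seed = derive_seed(seed, paste0("mantel:", s)))
        fam$season <- s
        mantelf[[s]] <- fam
        envd <- env_distance(envx, sub, vars, s, combine = TRUE)
        mm <- mrm(bc[ids, ids], list(dams = dams, env = envd),
                  n_perm = config$n_perm,
                  seed = derive_seed(seed, paste0("mrm:", s)))
        mm$coefficients$season <- s
        mm$coefficients$R2 <- mm$R2
        mrms[[s]] <- mm$coefficients
      }
    }
    report$ddr <- do.call(rbind, ddr); rownames(report$ddr) <- NULL
    if (length(mantelf)) report$mantel <- do.call(rbind, mantelf)
    if (length(mrms)) report$mrm <- do.call(rbind, mrms)
    if (!is.null(report$mantel)) rownames(report$mantel) <- NULL
    if (!is.null(report$mrm)) rownames(report$mrm) <- NULL
  }

  # -- assembly null models ------------------------------------------
  if (!is.null(inputs$tree)) {
    asm <- assembly_analysis(table, inputs$tree, samples,
                             n_null = config$n_null,
                             seed = derive_seed(seed, "assembly"),
                             bnti_thresh = config$bnti_thresh,
                             rc_thresh = config$rc_thresh)
    report$assembly <- do.call(rbind, lapply(names(asm), function(s) {
      cbind(season = s, asm[[s]]$fractions)
    }))
    report$assembly_calls <- do.call(rbind, lapply(names(asm), function(s) {
      cbind(season = s, asm[[s]]$calls)
    }))
  }

  # -- neutral model --------------------------------------------------
  report$ncm <- do.call(rbind, lapply(seasons, function(s) {
    ids <- samples$sample_id[samples$season == s]
    sub <- table[, ids, drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    fit <- ncm_fit(ncm_prepare(sub))
    cbind(season = s, ncm_report(fit))
  }))

  # -- SPEC-OCCU and core sets ---------------------------------------
  if (length(seasons) > 1L) {
    so <- spec_occ(rel, samples$season)
    sp <- classify_specialists(so, config$spec_min, config$occ_min)
    report$specialists <- as.data.frame(table(factor(sp$group,
                                                     levels = seasons)))
    names(report$specialists) <- c("season", "n_specialists")
    cs <- core_sets(table, samples$season, occ_min = config$occ_min)
    ds <- detected_sets(table, samples$season)
    report$core_overlap <- cs$overlap
    report$detected_overlap <- ds$overlap
    if (!is.null(inputs$taxonomy)) {
      shared <- intersect(cs$sets[[1L]], cs$sets[[2L]])
      if (length(shared)) {
        report$core_phyla <- phylum_composition(shared, inputs$taxonomy)
      }
    }
  }
  structure(report, class = "analysis_report", seed = seed,
            depth = depth)
}

compute_din_if_possible <- function(env) {
  if (all(c("NH4", "NO3", "NO2") %in% names(env)) && !"DIN" %in% names(env)) {
    compute_din(env)
  } else env
}

#' Write an analysis report as a directory of TSVs
#'
#' One TSV per stage table plus a short human-readable `summary.md` and a
#' YAML manifest (seed, rarefaction depth actually used).
#'
#' @param report an `analysis_report` from [run_full()].
#' @param out_dir output directory.
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report)) {
    obj <- report[[nm]]
    if (is.data.frame(obj)) {
      write.table(obj, file.path(out_dir, paste0(nm, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  yaml::write_yaml(list(seed = attr(report, "seed"),
                        depth = attr(report, "depth"),
                        tables = names(report)),
                   file.path(out_dir, "manifest.yaml"))
  lines <- c("# Analysis summary", "",
             paste0("Stages written: ", paste(names(report), collapse = ", ")))
  writeLines(lines, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}
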