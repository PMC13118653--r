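# Null-model core: abundance-weighted betaMNTD, betaNTI via tip-label
# randomization, abundance-weighted Raup-Crick on Bray-Curtis, and the
# five-way assembly-process partition with season-level summaries.

#' Patristic (leaf-to-leaf path length) distance matrix
#'
#' @param tree an [ape::phylo] with branch lengths, pruned to the taxa of
#'   interest.
#' @return square symmetric matrix over tip labels.
#' @export
patristic_matrix <- function(tree) {
  if (length(tree$tip.label) < 2L) stop("need at least two leaves")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Abundance-weighted beta mean nearest taxon distance (betaMNTD)
#'
#' For communities `i`, `j` with within-community relative abundances `f`
#' over their present taxa:
#' `0.5 * (sum_k f_ki min_l d(k, l) + sum_l f_lj min_k d(l, k))`,
#' where the minima run over the other community's present taxa (shared taxa
#' contribute 0).
#'
#' @param rel_i,rel_j named relative-abundance vectors (or any non-negative
#'   abundances; renormalized over present taxa), names matching `pd`.
#' @param pd patristic matrix covering both communities' taxa.
#' @return numeric scalar.
#' @export
beta_mntd <- function(rel_i, rel_j, pd) {
  if (sum(rel_i) <= 0 || sum(rel_j) <= 0) stop("empty community")
  taxa <- rownames(pd)
  f <- matrix(0, length(taxa), 2L, dimnames = list(taxa, c("i", "j")))
  f[names(rel_i), 1L] <- rel_i
  f[names(rel_j), 2L] <- rel_j
  f <- sweep(f, 2L, colSums(f), "/")
  cpp_bmntd(pd, f)[1L, 2L]
}

#' betaMNTD for all sample pairs
#'
#' @param table abundance matrix (OTUs x samples), rows matching `pd`.
#' @param pd patristic matrix over the table's OTUs.
#' @return square symmetric matrix of betaMNTD values over samples.
#' @export
beta_mntd_all <- function(table, pd) {
  stopifnot(identical(rownames(table), rownames(pd)))
  f <- sweep(table, 2L, colSums(table), "/")
  b <- cpp_bmntd(pd, f)
  dimnames(b) <- list(colnames(table), colnames(table))
  b
}

#' beta nearest taxon index (betaNTI)
#'
#' z-score of observed betaMNTD against a null distribution obtained by
#' shuffling OTU labels across the phylogeny tips (equivalently permuting
#' rows and columns of the patristic matrix). One shared stream of tip
#' shuffles is evaluated against every pair (shuffle once, evaluate all
#' pairs), so results do not depend on pair evaluation order.
#'
#' @param table abundance matrix (OTUs x samples).
#' @param tree phylogeny covering (a superset of) the table's OTUs.
#' @param n_null number of tip shuffles (>= 99).
#' @param seed integer seed.
#' @return list with matrices `bnti`, `bmntd_obs`, `null_mean`, `null_sd`
#'   over samples; pairs with zero null variance are `NA` in `bnti`.
#' @export
beta_nti <- function(table, tree, n_null = 999, seed = NULL) {
  if (n_null < 99) stop("n_null must be >= 99")
  tree <- prune_to_table(tree, table)
  pd <- patristic_matrix(tree)
  table <- table[rownames(pd), , drop = FALSE]
  f <- sweep(table, 2L, colSums(table), "/")
  s <- nrow(pd)
  perms <- with_seed(seed, {
    matrix(unlist(lapply(seq_len(n_null), function(i) sample.int(s))), s, n_null)
  })
  res <- cpp_bnti(pd, f, perms)
  bnti <- (res$obs - res$null_mean) / res$null_sd
  bnti[res$null_sd == 0] <- NA_real_
  dn <- list(colnames(table), colnames(table))
  dimnames(bnti) <- dimnames(res$obs) <- dn
  dimnames(res$null_mean) <- dimnames(res$null_sd) <- dn
  diag(bnti) <- 0
  list(bnti = bnti, bmntd_obs = res$obs,
       null_mean = res$null_mean, null_sd = res$null_sd)
}

#' Abundance-weighted Raup-Crick on Bray-Curtis (RC_Bray)
#'
#' For each sample pair, null communities are rebuilt preserving each
#' sample's observed richness and total count: occurrence is drawn without
#' replacement with probability proportional to metacommunity occupancy,
#' and abundance is filled by draws proportional to metacommunity relative
#' abundance. `RC = 2 * ((#null < obs) + 0.5 * (#null = obs)) / n_null - 1`,
#' in `[-1, 1]`. Each pair's null stream is seeded from a stable hash of
#' the two sample ids, so results do not depend on evaluation order.
#'
#' @param table integer count matrix (the filtered, non-rarefied table by
#'   convention).
#' @param pairs optional 2-column matrix of sample id pairs; default all
#'   pairs.
#' @param n_null null draws per pair (>= 99).
#' @param seed master integer seed.
#' @param weighting `"stegen"` (occupancy-weighted occurrence,
#'   abundance-weighted fill) or `"equiprobable"`.
#' @param meta optional count matrix (same OTU registry) from which the
#'   occupancy and abundance weights are estimated instead of `table`
#'   itself -- e.g. a wider regional metacommunity.
#' @return square symmetric matrix of RC values over samples (or the
#'   requested pairs filled, others `NA`).
#' @export
rc_bray <- function(table, pairs = NULL, n_null = 999, seed = 0,
                    weighting = c("stegen", "equiprobable"), meta = NULL) {
  weighting <- match.arg(weighting)
  if (n_null < 99) stop("n_null must be >= 99")
  if (is.null(meta)) meta <- table
  keep <- rowSums(meta) > 0
  if (!all(rowSums(table[!keep, , drop = FALSE]) == 0)) {
    stop("table contains OTUs absent from the metacommunity weights")
  }
  table <- table[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  if (nrow(table) < 2L) stop("metacommunity needs more than one OTU")
  occ_w <- rowMeans(meta > 0)
  ab_w <- rowSums(meta) / sum(meta)
  if (weighting == "equiprobable") {
    occ_w[] <- 1
    ab_w[] <- 1 / length(ab_w)
  }
  ids <- colnames(table)
  if (is.null(pairs)) {
    pairs <- t(combn(ids, 2L))
  }
  rc <- matrix(NA_real_, ncol(table), ncol(table), dimnames = list(ids, ids))
  diag(rc) <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    pair_key <- paste(sort(c(i, j)), collapse = "||")
    val <- with_seed(derive_seed(seed, pair_key), {
      cpp_rc_bray_pair(table[, i], table[, j], occ_w, ab_w, as.integer(n_null))
    })
    rc[i, j] <- rc[j, i] <- val
  }
  rc
}

#' Partition sample pairs into assembly processes
#'
#' Stegen-style decision rule: `betaNTI > +t` is heterogeneous selection,
#' `betaNTI < -t` homogeneous selection; otherwise `RC > +r` is dispersal
#' limitation, `RC < -r` homogenizing dispersal, and `|RC| <= r` is
#' undominated ("drift"). Defaults `t = 2`, `r = 0.95` are the
#' field-standard thresholds.
#'
#' @param bnti,rc square matrices (or equal-length vectors) of betaNTI and
#'   RC_Bray values per pair.
#' @param bnti_thresh,rc_thresh selection / dispersal thresholds.
#' @return if matrices: data.frame with one row per unordered pair
#'   (`sample_i`, `sample_j`, `bnti`, `rc`, `process`); if vectors: a
#'   character vector of processes. `NA` inputs give `NA` processes.
#' @export
partition_processes <- function(bnti, rc, bnti_thresh = 2, rc_thresh = 0.95) {
  as_pairs <- is.matrix(bnti)
  if (as_pairs) {
    idx <- which(upper.tri(bnti), arr.ind = TRUE)
    ids <- rownames(bnti)
    b <- bnti[upper.tri(bnti)]
    r <- rc[upper.tri(rc)]
  } else {
    b <- bnti; r <- rc
  }
  proc <- ifelse(is.na(b) | (abs(b) <= bnti_thresh & is.na(r)), NA_character_,
          ifelse(b > bnti_thresh, "heterogeneous_selection",
          ifelse(b < -bnti_thresh, "homogeneous_selection",
          ifelse(r > rc_thresh, "dispersal_limitation",
          ifelse(r < -rc_thresh, "homogenizing_dispersal", "undominated")))))
  if (!as_pairs) return(proc)
  data.frame(sample_i = ids[idx[, 1L]], sample_j = ids[idx[, 2L]],
             bnti = b, rc = r, process = proc,
             stringsAsFactors = FALSE)
}

#' Assembly-process fractions
#'
#' Fractions of non-NA pairs per process, with the deterministic
#' (both selections) and stochastic (dispersal limitation + homogenizing
#' dispersal + undominated) aggregates.
#'
#' @param calls data.frame from [partition_processes()] (or a character
#'   vector of processes).
#' @return data.frame of fractions plus aggregates; `n_pairs` and `n_na`
#'   attached as attributes.
#' @export
summarize_fractions <- function(calls) {
  proc <- if (is.data.frame(calls)) calls$process else calls
  n_na <- sum(is.na(proc))
  proc <- proc[!is.na(proc)]
  if (length(proc) == 0L) stop("all calls are NA")
  lev <- c("heterogeneous_selection", "homogeneous_selection",
           "dispersal_limitation", "homogenizing_dispersal", "undominated")
  frac <- table(factor(proc, levels = lev)) / length(proc)
  out <- data.frame(process = c(lev, "deterministic", "stochastic"),
                    fraction = c(as.numeric(frac),
                                 sum(frac[1:2]), sum(frac[3:5])),
                    stringsAsFactors = FALSE)
  attr(out, "n_pairs") <- length(proc)
  attr(out, "n_na") <- n_na
  out
}

#' Within-group assembly analysis
#'
#' Runs betaNTI and RC_Bray over all sample pairs within each level of a
#' grouping column (season by default) and partitions them into processes.
#'
#' @param table count matrix.
#' @param tree phylogeny covering the OTUs.
#' @param samples sample metadata with `sample_id` and the grouping column.
#' @param within grouping column name (default `"season"`).
#' @param n_null null draws.
#' @param seed master seed.
#' @param bnti_thresh,rc_thresh partition thresholds.
#' @return list per group level with `calls` and `fractions`.
#' @export
assembly_analysis <- function(table, tree, samples, within = "season",
                              n_null = 999, seed = 0,
                              bnti_thresh = 2, rc_thresh = 0.95) {
  out <- list()
  for (g in unique(samples[[within]])) {
    ids <- samples$sample_id[samples[[within]] == g]
    sub <- table[, ids, drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    bn <- beta_nti(sub, tree, n_null = n_null,
                   seed = derive_seed(seed, paste0("bnti:", g)))
    rc <- rc_bray(sub, n_null = n_null,
                  seed = derive_seed(seed, paste0("rc:", g)))
    calls <- partition_processes(bn$bnti, rc,
                                 bnti_thresh = bnti_thresh,
                                 rc_thresh = rc_thresh)
    out[[as.character(g)]] <- list(calls = calls,
                                   fractions = summarize_fractions(calls))
  }
  out
}

#' Draw one table realization from the Raup-Crick null
#'
#' Rebuilds every sample of a count table by the same null procedure
#' [rc_bray()] uses (occupancy-weighted occurrence draws preserving the
#' sample's richness, abundance-weighted fill preserving its total).
#' Useful for calibration: RC values computed between communities that were
#' themselves assembled by this procedure should be near-uniform, with
#' `P(|RC| > 0.95)` about 0.05.
#'
#' @param table integer count matrix supplying the registries, the
#'   occupancy/abundance weights, and each sample's richness and total.
#' @param seed integer seed.
#' @param weighting as in [rc_bray()].
#' @param meta optional external metacommunity for the weights, as in
#'   [rc_bray()].
#' @return count matrix of the same shape; each column has the richness and
#'   total of the corresponding input column.
#' @export
rc_null_table <- function(table, seed = NULL,
                          weighting = c("stegen", "equiprobable"),
                          meta = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(meta)) meta <- table
  keep <- rowSums(meta) > 0
  table <- table[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  occ_w <- rowMeans(meta > 0)
  ab_w <- rowSums(meta) / sum(meta)
  if (weighting == "equiprobable") {
    occ_w[] <- 1
    ab_w[] <- 1 / length(ab_w)
  }
  s <- nrow(table)
  with_seed(seed, {
    out <- apply(table, 2L, function(x) {
      rich <- sum(x > 0)
      tot <- sum(x)
      idx <- sample.int(s, rich, prob = occ_w)
      cnt <- numeric(s)
      cnt[idx] <- 1
      extra <- tot - rich
      if (extra > 0) {
        cnt[idx] <- cnt[idx] + as.vector(rmultinom(1L, extra, ab_w[idx]))
      }
      cnt
    })
    rownames(out) <- rownames(table)
    out
  })
}
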