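# Alpha diversity (on rarefied counts), rarefaction curves, Bray-Curtis
# beta diversity, PCoA, PERMANOVA, multivariate dispersion, and the simple
# univariate statistics applied to diversity indices.

#' Shannon diversity of one community
#'
#' `H = -sum p_i log p_i` over positive entries, in nats by default.
#'
#' @param x abundance vector (counts or relative; renormalized internally).
#' @param base log base; `exp(1)` gives nats.
#' @return numeric scalar.
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(x < 0)) stop("negative abundances")
  s <- sum(x)
  if (s <= 0) stop("all-zero community")
  p <- x[x > 0] / s
  -sum(p * log(p)) / log(base)
}

#' Chao1 richness estimator
#'
#' With `S` observed OTUs, `F1` singletons and `F2` doubletons:
#' `S + F1^2 / (2 F2)` when `F2 > 0`, and the bias-corrected
#' `S + F1 (F1 - 1) / (2 (F2 + 1))` when `F2 = 0`.
#'
#' @param x integer count vector (a rarefied sample).
#' @return estimated richness.
#' @export
chao1 <- function(x) {
  if (any(abs(x - round(x)) > 1e-8)) stop("chao1 requires integer counts")
  s <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning the taxa present in
#' the community, including the path to the tree root by default.
#'
#' @param x named abundance vector (names = tip labels), or character vector
#'   of present taxa.
#' @param tree an [ape::phylo] with branch lengths.
#' @param include_root include branches up to the root of `tree`.
#' @return summed branch length.
#' @export
faith_pd <- function(x, tree, include_root = TRUE) {
  present <- if (is.character(x)) x else names(x)[x > 0]
  if (length(present) == 0L) return(0)
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    stop("taxa absent from tree: ", paste(head(missing, 5L), collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  # mark every edge on a path from a present tip toward the root
  tip_idx <- match(present, tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  edge_of <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  on_path <- logical(nrow(tree$edge))
  for (v in tip_idx) {
    while (parent[v] != 0L && !on_path[edge_of[v]]) {
      on_path[edge_of[v]] <- TRUE
      v <- parent[v]
    }
  }
  total <- sum(tree$edge.length[on_path])
  if (!include_root && length(present) >= 1L) {
    # subtract the shared stem above the MRCA of the present set
    mrca <- if (length(present) == 1L) tip_idx else ape::getMRCA(tree, present)
    v <- mrca
    while (!is.null(v) && v != 0L && parent[v] != 0L) {
      total <- total - tree$edge.length[edge_of[v]]
      v <- parent[v]
    }
  }
  total
}

#' Alpha-diversity table for all samples
#'
#' Computes Shannon, Chao1 and Faith's PD per sample, optionally after
#' rarefying to an even depth (the convention for alpha diversity).
#'
#' @param table count matrix (OTUs x samples).
#' @param tree optional phylogeny covering the OTUs (for Faith's PD).
#' @param depth optional rarefaction depth.
#' @param seed seed for rarefaction.
#' @return data.frame with columns `sample_id`, `shannon`, `chao1`,
#'   and `faith_pd` when a tree is given.
#' @export
alpha_diversity <- function(table, tree = NULL, depth = NULL, seed = NULL) {
  if (!is.null(depth)) table <- rarefy_table(table, depth, seed = seed)
  out <- data.frame(
    sample_id = colnames(table),
    shannon = apply(table, 2L, shannon),
    chao1 = apply(table, 2L, chao1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(tree)) {
    tree <- prune_to_table(tree, table)
    out$faith_pd <- apply(table, 2L, function(x) {
      faith_pd(setNames(x, rownames(table)), tree)
    })
  }
  out
}

#' Expected rarefied richness (analytic)
#'
#' Expected number of OTUs observed in a without-replacement subsample of
#' size `depth`, from the hypergeometric absence probability
#' `P(absent) = C(N - n_i, depth) / C(N, depth)`.
#'
#' @param x count vector.
#' @param depth subsample size.
#' @return expected richness.
#' @export
expected_richness <- function(x, depth) {
  n <- sum(x)
  if (depth > n) stop("depth exceeds library size")
  x <- x[x > 0]
  p_absent <- exp(lchoose(n - x, depth) - lchoose(n, depth))
  sum(1 - p_absent)
}

#' Rarefaction curves
#'
#' Per-sample expected richness across depths, analytic by default (the
#' hypergeometric expectation), or the empirical mean over `reps` random
#' subsamples.
#'
#' @param table count matrix.
#' @param depths increasing vector of depths.
#' @param method `"analytic"` or `"resample"`.
#' @param reps resampling replicates (resample method).
#' @param seed seed for resampling.
#' @return data.frame `sample_id`, `depth`, `richness`.
#' @export
rarefaction_curve <- function(table, depths, method = c("analytic", "resample"),
                              reps = 100L, seed = NULL) {
  method <- match.arg(method)
  if (length(depths) == 0L) stop("empty depth list")
  res <- expand.grid(sample_id = colnames(table), depth = depths,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$richness <- NA_real_
  with_seed(seed, {
    for (r in seq_len(nrow(res))) {
      x <- table[, res$sample_id[r]]
      d <- res$depth[r]
      res$richness[r] <- if (method == "analytic") {
        expected_richness(x, d)
      } else {
        mean(replicate(reps, {
          sum(rarefy_table(cbind(s = x), d)[, 1L] > 0)
        }))
      }
    }
  })
  res
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, computed on relative
#' abundances in this pipeline (TSS columns), where it lies in `[0, 1]`.
#'
#' @param table abundance matrix (OTUs x samples); columns must have
#'   positive totals.
#' @return square symmetric dissimilarity matrix with sample labels.
#' @export
bray_curtis <- function(table) {
  if (ncol(table) < 2L) stop("need at least two samples")
  if (any(colSums(table) <= 0)) stop("zero-sum sample")
  n <- ncol(table)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n - 1L)) {
    xi <- table[, i]
    for (j in (i + 1L):n) {
      xj <- table[, j]
      d[i, j] <- d[j, i] <- sum(abs(xi - xj)) / sum(xi + xj)
    }
  }
  d
}

#' Principal coordinates analysis
#'
#' Gower-centered eigen-decomposition of the squared dissimilarities.
#' Negative eigenvalues are reported, not corrected.
#'
#' @param d square symmetric dissimilarity matrix.
#' @param n_axes number of axes to return (default: all positive).
#' @return list with `coordinates` (n x k), `eigenvalues`, and
#'   `proportion_explained` (relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- as_sq_dist(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  centering <- diag(n) - matrix(1 / n, n, n)
  g <- centering %*% a %*% centering
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- e$values > max(abs(e$values), 1e-300) * 1e-10
  k <- if (is.null(n_axes)) sum(pos) else min(n_axes, sum(pos))
  if (k == 0L) {
    # degenerate: all samples coincide
    coords <- matrix(0, n, 1L, dimnames = list(rownames(d), "PCo1"))
    return(list(coordinates = coords, eigenvalues = e$values,
                proportion_explained = rep(0, n)))
  }
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k, k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords,
       eigenvalues = e$values,
       proportion_explained = e$values / sum(e$values[pos]))
}

permanova_stats <- function(d2, groups) {
  # Anderson's pseudo-F from the squared-distance partition
  n <- nrow(d2)
  ss_total <- sum(upper_vec(d2)) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      ss_within <- ss_within +
        sum(upper_vec(d2[idx, idx, drop = FALSE])) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  a <- length(unique(groups))
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(F = f, R2 = ss_between / ss_total)
}

#' PERMANOVA (one factor)
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix: pseudo-F from the squared-distance partition, significance by
#' free permutation of sample labels (optionally restricted within strata),
#' `p = (count(F_perm >= F_obs) + 1) / (n_perm + 1)`.
#'
#' @param d dissimilarity matrix.
#' @param groups factor of group labels, one per sample.
#' @param n_perm number of permutations, or `"exhaustive"` to enumerate all
#'   label permutations (small n only).
#' @param seed seed for the permutation stream.
#' @param strata optional factor restricting permutations to occur within
#'   its levels.
#' @return list with `F`, `R2`, `p`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL, strata = NULL) {
  d <- as_sq_dist(d)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need at least two groups")
  d2 <- d^2
  if (sum(upper_vec(d2)) == 0) stop("total sum of squares is zero")
  obs <- permanova_stats(d2, groups)
  n <- nrow(d)
  exhaustive <- identical(n_perm, "exhaustive")
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  perm_f <- if (exhaustive) {
    perms <- all_permutations(n)
    apply(perms, 1L, function(p) permanova_stats(d2, groups[p])[["F"]])
  } else {
    with_seed(seed, replicate(n_perm, {
      p <- permute_labels(n, strata)
      permanova_stats(d2, groups[p])[["F"]]
    }))
  }
  b <- length(perm_f)
  pval <- if (exhaustive) mean(perm_f >= obs[["F"]] - 1e-12)
          else (sum(perm_f >= obs[["F"]] - 1e-12) + 1) / (b + 1)
  list(F = obs[["F"]], R2 = obs[["R2"]], p = pval,
       n_perm = b)
}

permute_labels <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  p <- seq_len(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    p[idx] <- idx[sample.int(length(idx))]
  }
  p
}

all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}

#' Multivariate dispersion test (betadisper, centroid variant)
#'
#' Distances from each sample to its group centroid in PCoA space, using
#' the standard negative-eigenvalue correction
#' `d^2 = d^2(real axes) - d^2(imaginary axes)` floored at 0, followed by a
#' one-way F test on the dispersions with a permutation p-value.
#'
#' @param d dissimilarity matrix.
#' @param groups factor of group labels.
#' @param n_perm permutations for the F null.
#' @param seed permutation seed.
#' @return list with `distances` (per sample), `group_means`, `F`, `p`,
#'   `df`, and `excluded` (groups of size 1, dropped with a warning).
#' @export
beta_dispersion <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as_sq_dist(d)
  groups <- as.factor(groups)
  sizes <- table(groups)
  excluded <- names(sizes)[sizes < 2L]
  if (length(excluded)) {
    warning("excluding size-1 group(s): ", paste(excluded, collapse = ", "))
    keep <- !(groups %in% excluded)
    d <- d[keep, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  n <- nrow(d)
  a <- -0.5 * d^2
  centering <- diag(n) - matrix(1 / n, n, n)
  g <- centering %*% a %*% centering
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- e$values > tol
  neg <- e$values < -tol
  cr <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  ci <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
  dist_to_centroid <- function(grp) {
    out <- numeric(n)
    for (gl in levels(grp)) {
      idx <- which(grp == gl)
      mur <- colMeans(cr[idx, , drop = FALSE])
      mui <- colMeans(ci[idx, , drop = FALSE])
      d2 <- rowSums(sweep(cr[idx, , drop = FALSE], 2L, mur)^2) -
        rowSums(sweep(ci[idx, , drop = FALSE], 2L, mui)^2)
      out[idx] <- sqrt(pmax(d2, 0))
    }
    out
  }
  z <- dist_to_centroid(groups)
  if (all(z == 0)) stop("all dispersions zero; F undefined")
  f_stat <- function(zv, grp) {
    m <- tapply(zv, grp, mean)
    ni <- tabulate(grp)
    gm <- mean(zv)
    ssb <- sum(ni * (m - gm)^2)
    ssw <- sum((zv - m[grp])^2)
    a <- nlevels(grp)
    (ssb / (a - 1)) / (ssw / (length(zv) - a))
  }
  f_obs <- f_stat(z, groups)
  perm_f <- with_seed(seed, replicate(n_perm, {
    f_stat(z[sample.int(n)], groups)
  }))
  pval <- (sum(perm_f >= f_obs - 1e-12) + 1) / (n_perm + 1)
  list(distances = setNames(z, rownames(d)),
       group_means = tapply(z, groups, mean),
       F = f_obs, p = pval,
       df = c(nlevels(groups) - 1L, n - nlevels(groups)),
       excluded = excluded)
}

#' Two-way ANOVA with partial eta-squared effect sizes
#'
#' Fits `y ~ A * B` with type-II sums of squares (each main effect adjusted
#' for the other, the interaction adjusted for both) and reports, per term,
#' F, p and partial eta-squared `SS_effect / (SS_effect + SS_resid)`.
#' Computed from explicit residual-sum-of-squares differences so that
#' noise-free responses (zero residual) are handled exactly.
#'
#' @param y numeric response.
#' @param a,b factors (e.g. season and reach).
#' @return data.frame with rows for `a`, `b`, `a:b`.
#' @export
two_way_anova_partial_eta2 <- function(y, a, b) {
  a <- droplevels(as.factor(a)); b <- droplevels(as.factor(b))
  if (nlevels(a) < 2L || nlevels(b) < 2L) stop("each factor needs >= 2 levels")
  rss <- function(f) sum(lm(f)$residuals^2)
  full <- lm(y ~ a * b)
  ss_res <- sum(full$residuals^2)
  df_res <- full$df.residual
  ss <- c(
    a = rss(y ~ b) - rss(y ~ a + b),
    b = rss(y ~ a) - rss(y ~ a + b),
    `a:b` = rss(y ~ a + b) - ss_res
  )
  # clamp numerical dust so noise-free designs give exact 0/1 effect sizes
  eps <- 1e-10 * max(sum((y - mean(y))^2), .Machine$double.xmin)
  ss <- pmax(ss, 0)
  ss[ss < eps] <- 0
  if (ss_res < eps) ss_res <- 0
  dfs <- c(nlevels(a) - 1L, nlevels(b) - 1L,
           (nlevels(a) - 1L) * (nlevels(b) - 1L))
  fval <- (ss / dfs) / (ss_res / df_res)
  data.frame(
    term = c("a", "b", "a:b"),
    F = fval,
    p = stats::pf(fval, dfs, df_res, lower.tail = FALSE),
    partial_eta2 = ifelse(ss + ss_res > 0, ss / (ss + ss_res), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Spearman rank trend along an ordered gradient
#'
#' Rank correlation with midrank ties; exact p by enumeration for n <= 9
#' (no ties), t-approximation otherwise.
#'
#' @param values numeric response.
#' @param reach_order numeric position along the gradient.
#' @return list with `rho` and `p`.
#' @export
spearman_trend <- function(values, reach_order) {
  if (length(values) < 3L) stop("need n >= 3")
  if (sd(values) == 0) stop("constant values; rho undefined")
  exact <- length(values) <= 9L && !anyDuplicated(values) &&
    !anyDuplicated(reach_order)
  ct <- suppressWarnings(
    cor.test(values, reach_order, method = "spearman", exact = exact)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}
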