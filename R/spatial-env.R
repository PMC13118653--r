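# Dam-count spatial distances, distance-decay regression, Mantel tests on
# season-standardized environmental distances, MRM, and BH-FDR families.

#' Reach-to-reach dam counts
#'
#' Path-additive dam counts along the ordered reach sequence: the distance
#' between two reaches is the sum of intervening-dam counts over the
#' adjacent segments between them.
#'
#' @param geometry data.frame with `reach` (ordered along the river) and
#'   `dams_to_next` (dams between each reach and the next; last entry
#'   ignored).
#' @return square integer matrix over reaches.
#' @export
reach_dam_matrix <- function(geometry) {
  k <- nrow(geometry)
  seg <- geometry$dams_to_next[-k]
  if (anyNA(seg) || any(seg < 0)) stop("invalid dams_to_next segment counts")
  cum <- c(0, cumsum(seg))
  d <- abs(outer(cum, cum, "-"))
  dimnames(d) <- list(geometry$reach, geometry$reach)
  d
}

#' Sample-level dam-count distance matrix
#'
#' Expands the reach-level dam counts to sample pairs via each sample's
#' reach; same-reach pairs get 0.
#'
#' @param geometry dam geometry table (see [reach_dam_matrix()]).
#' @param samples sample metadata with `sample_id` and `reach`.
#' @return square matrix over samples.
#' @export
dam_distance_matrix <- function(geometry, samples) {
  rd <- reach_dam_matrix(geometry)
  unknown <- setdiff(as.character(samples$reach), rownames(rd))
  if (length(unknown)) stop("unknown reach(es): ", paste(unknown, collapse = ", "))
  idx <- match(as.character(samples$reach), rownames(rd))
  d <- rd[idx, idx, drop = FALSE]
  dimnames(d) <- list(samples$sample_id, samples$sample_id)
  d
}

#' Distance-decay regression on dam counts
#'
#' OLS of the unfolded upper-triangle community dissimilarities on dam
#' counts (slope per dam), with significance from the Mantel permutation of
#' one matrix's rows and columns jointly.
#'
#' @param bc community dissimilarity matrix.
#' @param dams dam-count distance matrix on the same samples.
#' @param n_perm Mantel permutations.
#' @param seed permutation seed.
#' @param alternative `"two.sided"` or `"greater"` (dissimilarity expected
#'   to increase with dams).
#' @return list with `slope`, `intercept`, `R2`, `r_mantel`, `p`, `n_perm`.
#' @export
distance_decay <- function(bc, dams, n_perm = 999, seed = NULL,
                           alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  bc <- as_sq_dist(bc); dams <- as_sq_dist(dams, "dams")
  check_shared_registry(bc, dams)
  y <- upper_vec(bc); x <- upper_vec(dams)
  if (sd(x) == 0) stop("constant dam distances")
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  if (sd(y) == 0) {
    # flat dissimilarities: slope 0 by construction, no test possible
    return(list(slope = 0, intercept = mean(y), R2 = 0,
                r_mantel = NA_real_, p = NA_real_, n_perm = 0L))
  }
  mt <- mantel_test(dams, bc, n_perm = n_perm, seed = seed,
                    alternative = alternative)
  list(slope = slope, intercept = intercept, R2 = cor(x, y)^2,
       r_mantel = mt$r, p = mt$p, n_perm = mt$n_perm)
}

#' Environmental distance matrices (season-standardized)
#'
#' For each variable: restrict to one season, z-score across that season's
#' reaches (population SD), map reach values to samples, and take pairwise
#' Euclidean distances (absolute z differences for a single variable). The
#' multivariable form uses Euclidean distance over the full z-scored vector.
#'
#' @param env environmental table keyed by `reach` and `season`.
#' @param samples sample metadata (`sample_id`, `season`, `reach`) already
#'   restricted to or containing the target season.
#' @param variables character vector of environmental column names.
#' @param season season label to use.
#' @param combine if `TRUE` return one multivariable Euclidean matrix,
#'   otherwise a named list of per-variable matrices.
#' @return matrix or named list of matrices over the season's samples.
#' @export
env_distance <- function(env, samples, variables, season, combine = FALSE) {
  samples <- samples[samples$season == season, , drop = FALSE]
  env <- env[env$season == season, , drop = FALSE]
  if (nrow(samples) == 0L || nrow(env) == 0L) stop("no rows for season ", season)
  zmat <- sapply(variables, function(v) {
    if (!v %in% names(env)) stop("missing environmental variable ", v)
    vals <- env[[v]][match(as.character(samples$reach), as.character(env$reach))]
    if (anyNA(vals)) stop("variable ", v, " missing for some reach")
    mu <- mean(env[[v]])
    sigma <- sqrt(mean((env[[v]] - mu)^2))
    if (sigma == 0) stop("zero-variance variable: ", v)
    (vals - mu) / sigma
  })
  rownames(zmat) <- samples$sample_id
  one <- function(z) {
    d <- as.matrix(dist(z))
    dimnames(d) <- list(samples$sample_id, samples$sample_id)
    d
  }
  if (combine) return(one(zmat))
  setNames(lapply(variables, function(v) one(zmat[, v, drop = FALSE])),
           variables)
}

#' Mantel test
#'
#' Pearson (or Spearman) correlation over the unfolded upper triangles,
#' with significance by simultaneous row+column permutation of `dy`;
#' `p = (count(|r_perm| >= |r_obs|) + 1) / (n_perm + 1)` two-sided by
#' default.
#'
#' @param dx,dy distance matrices on the same samples.
#' @param n_perm permutations.
#' @param seed permutation seed.
#' @param method `"pearson"` or `"spearman"`.
#' @param alternative `"two.sided"` or `"greater"`.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(dx, dy, n_perm = 999, seed = NULL,
                        method = c("pearson", "spearman"),
                        alternative = c("two.sided", "greater")) {
  method <- match.arg(method); alternative <- match.arg(alternative)
  dx <- as_sq_dist(dx, "dx"); dy <- as_sq_dist(dy, "dy")
  check_shared_registry(dx, dy)
  x <- upper_vec(dx)
  if (sd(x) == 0 || sd(upper_vec(dy)) == 0) stop("degenerate (constant) triangle")
  r_of <- function(m) cor(x, upper_vec(m), method = method)
  r_obs <- r_of(dy)
  n <- nrow(dy)
  r_perm <- with_seed(seed, replicate(n_perm, {
    p <- sample.int(n)
    r_of(dy[p, p])
  }))
  pval <- if (alternative == "two.sided") {
    (sum(abs(r_perm) >= abs(r_obs) - 1e-12) + 1) / (n_perm + 1)
  } else {
    (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
  }
  list(r = r_obs, p = pval, n_perm = n_perm)
}

#' Multiple regression on distance matrices (MRM)
#'
#' OLS of the unfolded response triangle on the predictor triangles, with
#' per-coefficient permutation p-values from simultaneous row+column
#' permutation of the response matrix.
#'
#' @param dy response distance matrix.
#' @param predictors named list of predictor distance matrices.
#' @param n_perm permutations.
#' @param seed permutation seed.
#' @return list with `coefficients` (data.frame: term, estimate, p), `R2`,
#'   `n_perm`.
#' @export
mrm <- function(dy, predictors, n_perm = 999, seed = NULL) {
  if (length(predictors) < 1L) stop("need at least one predictor")
  dy <- as_sq_dist(dy, "dy")
  predictors <- lapply(predictors, as_sq_dist)
  do.call(check_shared_registry, c(list(dy), predictors))
  if (is.null(names(predictors))) {
    names(predictors) <- paste0("x", seq_along(predictors))
  }
  x <- cbind(`(Intercept)` = 1,
             sapply(predictors, upper_vec))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("collinear predictor matrices; aliased coefficients are NA")
  }
  fit_coef <- function(yv) qr.coef(qx, yv)
  y <- upper_vec(dy)
  beta <- fit_coef(y)
  resid <- qr.resid(qx, y)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  n <- nrow(dy)
  perm_beta <- with_seed(seed, replicate(n_perm, {
    p <- sample.int(n)
    fit_coef(upper_vec(dy[p, p]))
  }))
  pvals <- vapply(seq_along(beta), function(k) {
    if (is.na(beta[k])) return(NA_real_)
    (sum(abs(perm_beta[k, ]) >= abs(beta[k]) - 1e-12) + 1) / (n_perm + 1)
  }, numeric(1L))
  list(coefficients = data.frame(term = colnames(x), estimate = unname(beta),
                                 p = pvals, stringsAsFactors = FALSE),
       R2 = r2, n_perm = n_perm)
}

#' Benjamini-Hochberg FDR adjustment (one family)
#'
#' Step-up BH with monotonicity enforcement; values are returned in the
#' input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values, same order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Mantel family against a community dissimilarity matrix
#'
#' Runs one Mantel test per environmental variable (plus optionally the dam
#' matrix) within a season, and BH-adjusts p-values within that family.
#'
#' @param bc community dissimilarity matrix over the season's samples.
#' @param env environmental table.
#' @param samples sample metadata restricted to the same samples.
#' @param variables environmental variables to test.
#' @param season season label.
#' @param dams optional dam-count matrix included as the spatial member of
#'   the family.
#' @param n_perm,seed passed to [mantel_test()].
#' @return data.frame with `variable`, `r`, `p`, `q`.
#' @export
mantel_family <- function(bc, env, samples, variables, season, dams = NULL,
                          n_perm = 999, seed = NULL) {
  dxs <- env_distance(env, samples, variables, season)
  if (!is.null(dams)) dxs <- c(list(dams = dams), dxs)
  rows <- lapply(names(dxs), function(v) {
    mt <- mantel_test(dxs[[v]], bc, n_perm = n_perm,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, v))
    data.frame(variable = v, r = mt$r, p = mt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}
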