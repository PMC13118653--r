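test_that("alpha diversity indices match closed forms", {
  expect_equal(shannon(c(0.25, 0.25, 0.25, 0.25)), log(4))
  expect_equal(shannon(c(1.0)), 0)
  expect_equal(shannon(c(0.5, 0.5, 0)), log(2))
  expect_error(shannon(c(0, 0)), "zero")

  expect_equal(chao1(c(1, 1, 2, 2, 3)), 6)
  expect_equal(chao1(c(5, 3, 2)), 3)          # no singletons: S
  expect_equal(chao1(c(1, 1, 1)), 6)          # bias-corrected branch
  expect_error(chao1(c(1.5, 2)), "integer")

  tr <- toy_tree()
  expect_equal(faith_pd(c(A = 1, B = 1), tr), 3)
  expect_equal(faith_pd(c(A = 1, B = 1, C = 1), tr), 5)
  expect_equal(faith_pd(c(C = 2), tr), 2)
  expect_error(faith_pd(c(D = 1), tr), "absent")
})

test_that("Chao1 >= S with equality iff no singletons; Faith monotone", {
  set.seed(7)
  for (i in 1:20) {
    x <- rpois(30, 2)
    s <- sum(x > 0)
    expect_gte(chao1(x), s)
    if (sum(x == 1) == 0) expect_equal(chao1(x), s)
  }
  tree <- simulate_tree(30, seed = 3)
  present <- tree$tip.label[1:5]
  pd1 <- faith_pd(present, tree)
  pd2 <- faith_pd(c(present, tree$tip.label[10]), tree)
  expect_gte(pd2, pd1)
})

test_that("Faith's PD agrees with picante on random communities", {
  tree <- simulate_tree(40, seed = 11)
  tab <- rand_counts(40, 6, seed = 12, lambda = 1)
  rownames(tab) <- tree$tip.label
  ours <- apply(tab, 2, function(x) faith_pd(setNames(x, rownames(tab)), tree))
  ref <- picante::pd(t(tab), tree, include.root = TRUE)$PD
  expect_equal(unname(ours), ref, tolerance = 1e-9)
})

test_that("rarefaction curves use the hypergeometric expectation", {
  x <- c(50, 50)
  # depth = library: observed richness; depth 1: exactly 1
  expect_equal(expected_richness(x, 100), 2)
  expect_equal(expected_richness(x, 1), 1)
  analytic <- 2 * (1 - choose(50, 10) / choose(100, 10))
  expect_equal(expected_richness(x, 10), analytic, tolerance = 1e-12)

  tab <- cbind(s = x); rownames(tab) <- c("a", "b")
  emp <- rarefaction_curve(tab, 10, method = "resample", reps = 500, seed = 5)
  expect_lt(abs(emp$richness - analytic), 0.01)

  curve <- rarefaction_curve(tab, c(1, 5, 20, 100))
  expect_true(all(diff(curve$richness) >= 0))
  expect_error(rarefaction_curve(tab, numeric(0)), "empty")
})

test_that("Bray-Curtis matches hand values, bounds, and vegan", {
  m <- cbind(s1 = c(0.4, 0.6), s2 = c(0.2, 0.8), s3 = c(0.4, 0.6))
  rownames(m) <- c("a", "b")
  d <- bray_curtis(m)
  expect_equal(d["s1", "s2"], 0.2)
  expect_equal(d["s1", "s3"], 0)
  disj <- cbind(x = c(1, 0), y = c(0, 1)); rownames(disj) <- c("a", "b")
  expect_equal(bray_curtis(disj)["x", "y"], 1)

  tab <- tss_normalize(rand_counts(25, 8, seed = 3))
  ours <- bray_curtis(tab)
  ref <- as.matrix(vegan::vegdist(t(tab), method = "bray"))
  expect_equal(ours, ref[rownames(ours), colnames(ours)], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(ours >= 0 & ours <= 1))
  expect_equal(ours, t(ours))
})

test_that("PCoA geometry: two points, simplex, distance reconstruction", {
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa(d2)
  expect_equal(sort(abs(p2$coordinates[, 1])), c(0.3, 0.3), ignore_attr = TRUE)

  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(d3)
  pos <- p3$eigenvalues[p3$eigenvalues > 1e-10]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # Euclidean-embeddable input reconstructs distances
  set.seed(4)
  pts <- matrix(rnorm(20), 10, 2)
  dd <- as.matrix(dist(pts))
  rec <- pcoa(dd)
  drec <- as.matrix(dist(rec$coordinates))
  expect_equal(unname(drec), unname(dd), tolerance = 1e-8)

  identical_d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(max(abs(pcoa(identical_d)$coordinates)), 0)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA matches a coordinate-space oracle and vegan", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(8, 0), 4, 2), matrix(rnorm(6, 2), 3, 2))
  groups <- factor(rep(c("g1", "g2"), c(4, 3)))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:7), paste0("s", 1:7))
  res <- permanova(d, groups, n_perm = "exhaustive")

  # oracle: classic one-way MANOVA sums of squares on coordinates
  gm <- colMeans(pts)
  ss_t <- sum(sweep(pts, 2, gm)^2)
  ss_w <- sum(unlist(lapply(split(as.data.frame(pts), groups), function(g) {
    sum(sweep(as.matrix(g), 2, colMeans(as.matrix(g)))^2)
  })))
  f_oracle <- ((ss_t - ss_w) / 1) / (ss_w / 5)
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$R2, (ss_t - ss_w) / ss_t, tolerance = 1e-10)

  # exhaustive p equals brute-force enumeration p (independent recursion)
  enum <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in enum(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  fs <- vapply(enum(1:7), function(p) {
    g <- groups[p]
    ssw <- sum(unlist(lapply(split(as.data.frame(pts), g), function(gg) {
      sum(sweep(as.matrix(gg), 2, colMeans(as.matrix(gg)))^2)
    })))
    ((ss_t - ssw) / 1) / (ssw / 5)
  }, numeric(1))
  expect_equal(res$p, mean(fs >= f_oracle - 1e-12), tolerance = 1e-12)

  # vegan cross-check of F and R2
  ref <- vegan::adonis2(as.dist(d) ~ groups, permutations = 99)
  expect_equal(res$F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)

  expect_error(permanova(d, rep("g", 7)), "two groups")
  d0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(permanova(d0, c(1, 1, 2, 2)), "zero")
})

test_that("permutation p-values are valid and well calibrated", {
  # under exchangeability, p is super-uniform-ish; check range and KS roughly
  set.seed(21)
  ps <- replicate(120, {
    pts <- matrix(rnorm(16), 8, 2)
    d <- as.matrix(dist(pts)); dimnames(d) <- list(1:8, 1:8)
    permanova(d, rep(1:2, each = 4), n_perm = 59, seed = sample.int(1e6, 1))$p
  })
  expect_true(all(ps > 0 & ps <= 1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)
})

test_that("dispersion test matches an ANOVA oracle and behaves on symmetry", {
  # mirror-image groups: equal dispersion, tiny F
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(6, 5), c(5, 6))
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  groups <- rep(c("a", "b"), each = 3)
  res <- beta_dispersion(d, groups, n_perm = 199, seed = 2)
  expect_equal(unname(diff(res$group_means)), 0, tolerance = 1e-10)
  expect_lt(res$F, 1e-10)

  # oracle: distances to centroid computed directly from coordinates
  set.seed(3)
  pts <- rbind(matrix(rnorm(8, sd = 0.1), 4, 2),
               matrix(rnorm(8, sd = 0.9), 4, 2))
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  groups <- rep(c("tight", "wide"), each = 4)
  res <- beta_dispersion(d, groups, n_perm = 199, seed = 2)
  zd <- unlist(lapply(split(as.data.frame(pts), groups), function(g) {
    sqrt(rowSums(sweep(as.matrix(g), 2, colMeans(as.matrix(g)))^2))
  }))
  f_oracle <- summary(aov(zd ~ rep(c("tight", "wide"), each = 4)))[[1]]$`F value`[1]
  expect_equal(res$F, f_oracle, tolerance = 1e-8)

  # vegan cross-check (centroid variant)
  ref <- vegan::betadisper(as.dist(d), groups, type = "centroid")
  expect_equal(sort(unname(res$distances)), sort(unname(ref$distances)),
               tolerance = 1e-8)

  expect_warning(beta_dispersion(d, c("a", rep("b", 7)), n_perm = 49), "size-1")
  d0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(beta_dispersion(d0, c(1, 1, 2, 2), n_perm = 49), "zero")
})

test_that("two-way ANOVA partial eta squared matches a projection oracle", {
  # noise-free main effect of one factor only
  a <- factor(rep(c("x", "y"), each = 6))
  b <- factor(rep(1:3, 4))
  y <- ifelse(a == "x", 1, 5)
  res <- two_way_anova_partial_eta2(y, a, b)
  expect_equal(res$partial_eta2[res$term == "a"], 1)
  expect_equal(res$partial_eta2[res$term == "b"], 0)

  # additive cell means: interaction SS 0
  a2 <- factor(rep(c("x", "y"), each = 2))
  b2 <- factor(rep(1:2, 2))
  y2 <- c(10, 10, 20, 20) + c(0, 5, 0, 5)
  res2 <- two_way_anova_partial_eta2(y2, a2, b2)
  expect_equal(res2$partial_eta2[res2$term == "a:b"], 0, tolerance = 1e-12)

  # random response: compare with explicit type-II projections
  set.seed(13)
  a3 <- factor(rep(c("u", "v"), each = 12))
  b3 <- factor(rep(rep(1:3, each = 4), 2))
  y3 <- rnorm(24)
  res3 <- two_way_anova_partial_eta2(y3, a3, b3)
  rss <- function(f) sum(resid(lm(f))^2)
  ss_a <- rss(y3 ~ b3) - rss(y3 ~ a3 + b3)
  ss_b <- rss(y3 ~ a3) - rss(y3 ~ a3 + b3)
  ss_ab <- rss(y3 ~ a3 + b3) - rss(y3 ~ a3 * b3)
  ss_r <- rss(y3 ~ a3 * b3)
  expect_equal(res3$partial_eta2,
               c(ss_a / (ss_a + ss_r), ss_b / (ss_b + ss_r),
                 ss_ab / (ss_ab + ss_r)),
               tolerance = 1e-10)
  expect_error(two_way_anova_partial_eta2(y3, factor(rep("u", 24)), b3), "levels")
})

test_that("Spearman trend handles monotone and hand-ranked cases", {
  expect_equal(spearman_trend(1:8, 1:8)$rho, 1)
  expect_equal(spearman_trend(8:1, 1:8)$rho, -1)
  expect_equal(spearman_trend(c(3, 1, 2), c(1, 2, 3))$rho, -0.5)
  expect_error(spearman_trend(rep(2, 5), 1:5), "constant")
})
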