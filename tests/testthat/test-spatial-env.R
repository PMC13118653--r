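test_that("dam distances are path-additive along the reach order", {
  geo <- data.frame(reach = paste0("S", 1:10),
                    dams_to_next = c(rep(1, 9), NA))
  rd <- reach_dam_matrix(geo)
  expect_equal(rd["S1", "S10"], 9)
  expect_equal(rd["S3", "S5"], 2)
  expect_equal(diag(rd), setNames(rep(0, 10), paste0("S", 1:10)))
  # strict triangle equality along the line graph
  for (i in 1:8) for (j in (i + 1):9) for (k in (j + 1):10) {
    expect_equal(rd[i, k], rd[i, j] + rd[j, k])
  }

  geo2 <- data.frame(reach = paste0("S", 1:5),
                     dams_to_next = c(1, 1, 2, 1, NA))
  rd2 <- reach_dam_matrix(geo2)
  expect_equal(rd2["S3", "S5"], 3)

  samples <- data.frame(sample_id = c("a", "b", "c"),
                        reach = c("S1", "S1", "S4"))
  dm <- dam_distance_matrix(geo2, samples)
  expect_equal(dm["a", "b"], 0)
  expect_equal(dm["a", "c"], 4)
  expect_error(dam_distance_matrix(geo2, data.frame(sample_id = "x",
                                                    reach = "S9")), "unknown")
})

test_that("distance decay recovers a planted linear relationship", {
  geo <- data.frame(reach = paste0("S", 1:10), dams_to_next = c(rep(1, 9), NA))
  samples <- data.frame(sample_id = sprintf("f%02d", 1:20),
                        reach = rep(paste0("S", 1:10), each = 2))
  dams <- dam_distance_matrix(geo, samples)
  bc <- 0.1 + 0.02 * dams
  diag(bc) <- 0
  fit <- distance_decay(bc, dams, n_perm = 199, seed = 3)
  expect_equal(fit$slope, 0.02, tolerance = 1e-12)
  expect_equal(fit$R2, 1, tolerance = 1e-9)
  expect_lte(fit$p, 0.01)

  flat <- matrix(0.4, 20, 20, dimnames = dimnames(dams)); diag(flat) <- 0
  expect_equal(distance_decay(flat, dams, n_perm = 99, seed = 1)$slope, 0)
  same <- matrix(0, 20, 20, dimnames = dimnames(dams))
  expect_error(distance_decay(bc, same, n_perm = 99), "constant")
})

test_that("environmental distances are season-standardized with population SD", {
  env <- data.frame(reach = rep(paste0("S", 1:3), 2),
                    season = rep(c("w", "s"), each = 3),
                    Tem = c(10, 20, 30, 1, 2, 3))
  samples <- data.frame(sample_id = paste0("x", 1:3),
                        season = "w", reach = paste0("S", 1:3))
  d <- env_distance(env, samples, "Tem", "w")$Tem
  # z = (-1, 0, 1) under ddof = 0 against sd sqrt(2/3)... population z of 10,20,30
  z <- (c(10, 20, 30) - 20) / sqrt(mean((c(10, 20, 30) - 20)^2))
  expect_equal(d["x1", "x3"], abs(z[1] - z[3]))
  # rescaling a variable leaves its distance matrix unchanged
  env2 <- env; env2$Tem <- env2$Tem * 1000
  d2 <- env_distance(env2, samples, "Tem", "w")$Tem
  expect_equal(d, d2)
  # equal values -> zero distance, and zero variance errors by name
  envc <- env; envc$Tem[1:3] <- 5
  expect_error(env_distance(envc, samples, "Tem", "w"), "Tem")
})

test_that("Mantel statistic, affine invariance, and null calibration", {
  set.seed(6)
  pts <- matrix(rnorm(30), 15, 2)
  dx <- as.matrix(dist(pts)); dimnames(dx) <- list(1:15, 1:15)
  res <- mantel_test(dx, dx, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  res2 <- mantel_test(dx, 3 * dx + 0.2 * (1 - diag(15)), n_perm = 99, seed = 1)
  expect_equal(res2$r, 1, tolerance = 1e-12)

  # agrees with vegan on random matrices
  dy <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  dimnames(dy) <- dimnames(dx)
  ours <- mantel_test(dx, dy, n_perm = 99, seed = 2)
  ref <- vegan::mantel(as.dist(dx), as.dist(dy), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)

  # independent matrices: r near zero on average, p near-uniform
  set.seed(8)
  rs <- ps <- numeric(120)
  for (i in 1:120) {
    a <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
    b <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
    dimnames(a) <- dimnames(b) <- list(1:15, 1:15)
    m <- mantel_test(a, b, n_perm = 59, seed = i)
    rs[i] <- m$r; ps[i] <- m$p
  }
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(120))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)
  expect_error(mantel_test(dx, matrix(0, 15, 15, dimnames = dimnames(dx)),
                           n_perm = 99), "degenerate")
})

test_that("MRM: single predictor equals DDR slope; planted coefficients recovered", {
  geo <- data.frame(reach = paste0("S", 1:8), dams_to_next = c(rep(1, 7), NA))
  samples <- data.frame(sample_id = sprintf("f%02d", 1:16),
                        reach = rep(paste0("S", 1:8), each = 2))
  dams <- dam_distance_matrix(geo, samples)
  set.seed(10)
  noise <- matrix(rnorm(256, sd = 0.01), 16, 16)
  noise <- (noise + t(noise)) / 2; diag(noise) <- 0
  dy <- 0.1 + 0.02 * dams + noise; diag(dy) <- 0
  dimnames(dy) <- dimnames(dams)
  dd <- distance_decay(dy, dams, n_perm = 99, seed = 1)
  mm <- mrm(dy, list(dams = dams), n_perm = 99, seed = 1)
  expect_equal(mm$coefficients$estimate[2], dd$slope, tolerance = 1e-12)

  # two orthogonal planted predictors
  p1 <- dams
  set.seed(11)
  raw <- matrix(rnorm(256), 16, 16); raw <- abs(raw + t(raw)); diag(raw) <- 0
  dimnames(raw) <- dimnames(dams)
  # orthogonalize the unfolded triangles
  v1 <- p1[upper.tri(p1)]
  v2 <- raw[upper.tri(raw)]
  v2 <- v2 - coef(lm(v2 ~ v1))[2] * v1
  p2 <- matrix(0, 16, 16, dimnames = dimnames(dams))
  p2[upper.tri(p2)] <- v2; p2 <- p2 + t(p2)
  y <- matrix(0, 16, 16, dimnames = dimnames(dams))
  y[upper.tri(y)] <- 0.7 * v1 - 0.3 * v2 + rnorm(length(v1), sd = 0.02)
  y <- y + t(y)
  mm2 <- mrm(y, list(a = p1, b = p2), n_perm = 99, seed = 4)
  expect_equal(mm2$coefficients$estimate[2], 0.7, tolerance = 0.02)
  expect_equal(mm2$coefficients$estimate[3], -0.3, tolerance = 0.02)

  expect_warning(mrm(y, list(a = p1, b = 2 * p1), n_perm = 99, seed = 1),
                 "collinear")
})

test_that("BH-FDR matches hand-worked sequences and invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_error(bh_fdr(c(0.1, 1.2)), "outside")
  set.seed(3)
  p <- runif(40)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("mantel_family BH-adjusts within the family", {
  sim <- small_sim()
  tab <- sim$table[rowSums(sim$table) > 0, ]
  rel <- tss_normalize(tab)
  bc <- bray_curtis(rel)
  sub <- sim$samples[sim$samples$season == "winter", ]
  bcw <- bc[sub$sample_id, sub$sample_id]
  dams <- dam_distance_matrix(sim$geometry, sub)
  fam <- mantel_family(bcw, sim$env, sub, c("Tem", "DIN"), "winter",
                       dams = dams, n_perm = 99, seed = 5)
  expect_setequal(fam$variable, c("dams", "Tem", "DIN"))
  expect_true(all(fam$q >= fam$p))
  expect_equal(fam$q, bh_fdr(fam$p))
})
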