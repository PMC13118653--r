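test_that("patristic distances follow hand-computed path sums", {
  tr <- toy_tree()
  pd <- patristic_matrix(tr)
  expect_equal(pd["A", "B"], 2)
  expect_equal(pd["A", "C"], 4)
  # ultrametric: all root-to-leaf depths equal
  ut <- simulate_tree(12, model = "coalescent", seed = 3)
  depths <- ape::node.depth.edgelength(ut)[1:12]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)
  # zero-length cherry
  z <- ape::read.tree(text = "((A:0,B:0):1,C:2);")
  expect_equal(patristic_matrix(z)["A", "B"], 0)
  expect_error(patristic_matrix(ape::read.tree(text = "(A:1);")), "two leaves")
})

test_that("betaMNTD matches hand arithmetic and picante", {
  pd <- patristic_matrix(toy_tree())
  expect_equal(beta_mntd(c(A = 0.5, B = 0.5), c(A = 0.5, B = 0.5), pd), 0)
  expect_equal(beta_mntd(c(A = 1), c(C = 1), pd), 4)
  expect_equal(beta_mntd(c(A = 0.5, B = 0.5), c(C = 1), pd), 4)
  expect_error(beta_mntd(c(A = 0), c(C = 1), pd), "empty")

  tree <- simulate_tree(30, seed = 21)
  tab <- rand_counts(30, 5, seed = 22, lambda = 2)
  rownames(tab) <- tree$tip.label
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  pd30 <- patristic_matrix(tree)
  ours <- beta_mntd_all(tab, pd30)
  ref <- as.matrix(picante::comdistnt(t(tab), pd30, abundance.weighted = TRUE))
  expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("betaNTI is invariant to relabeling and flags degenerate nulls", {
  tree <- simulate_tree(25, seed = 5)
  tab <- rand_counts(25, 6, seed = 6, lambda = 1.5)
  rownames(tab) <- tree$tip.label
  res <- beta_nti(tab, tree, n_null = 99, seed = 7)

  # relabel OTUs consistently in table and tree: identical bNTI
  perm <- sample(25)
  tree2 <- tree; tree2$tip.label <- paste0("X", seq_len(25))[order(perm)][rank(perm)]
  # simpler: rename both with the same map
  map <- setNames(paste0("X", 1:25), tree$tip.label)
  tree2 <- tree; tree2$tip.label <- unname(map[tree$tip.label])
  tab2 <- tab; rownames(tab2) <- unname(map[rownames(tab)])
  res2 <- beta_nti(tab2, tree2, n_null = 99, seed = 7)
  expect_equal(res$bnti, res2$bnti, ignore_attr = TRUE)

  # star tree with equal branch lengths: null variance zero -> NA
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  stab <- matrix(c(3, 0, 1, 0, 0, 2, 0, 4), 4, 2,
                 dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  sres <- beta_nti(stab, star, n_null = 99, seed = 1)
  expect_true(is.na(sres$bnti["s1", "s2"]))

  expect_error(beta_nti(tab, tree, n_null = 10), ">= 99")
})

test_that("betaNTI sign reflects clade structure of co-occurring taxa", {
  tree <- simulate_tree(100, seed = 2)
  pd <- patristic_matrix(tree)
  cl <- cutree(hclust(as.dist(pd), "average"), k = 8)
  clade <- names(cl)[cl == as.integer(names(which.max(table(cl))))]
  a <- clade[seq(1, length(clade), 2)][1:8]
  b <- setdiff(clade, a)[1:8]
  tab <- matrix(0, 100, 4, dimnames = list(tree$tip.label, paste0("s", 1:4)))
  tab[a, 1] <- 10; tab[b, 2] <- 10
  set.seed(4)
  tab[sample(100, 8), 3] <- 10; tab[sample(100, 8), 4] <- 10
  res <- beta_nti(tab, tree, n_null = 999, seed = 5)
  # disjoint same-clade pair: phylogenetically clustered -> negative
  expect_lt(res$bnti["s1", "s2"], -1.5)
  # clade vs random: overdispersed -> positive
  expect_gt(res$bnti["s1", "s3"], 0.5)
})

test_that("RC_Bray respects bounds, identical and disjoint limits, determinism", {
  tab <- rand_counts(40, 8, seed = 31, lambda = 3)
  rc <- rc_bray(tab, n_null = 99, seed = 9)
  v <- rc[upper.tri(rc)]
  expect_true(all(v >= -1 & v <= 1))

  # identical communities: observed BC = 0 below almost every null -> -1
  dup <- cbind(tab[, 1, drop = FALSE], tab[, 1, drop = FALSE])
  colnames(dup) <- c("x", "y")
  meta <- tab; colnames(meta) <- paste0("m", 1:8)
  rci <- rc_bray(dup, n_null = 99, seed = 2, meta = meta)
  expect_lt(rci["x", "y"], -0.95)

  # disjoint supports with obs BC = 1: nulls almost never reach 1 -> +1
  big <- matrix(0, 40, 2, dimnames = list(rownames(tab), c("p", "q")))
  big[1:20, "p"] <- 50; big[21:40, "q"] <- 50
  rcd <- rc_bray(big, n_null = 99, seed = 3, meta = tab)
  expect_gt(rcd["p", "q"], 0.9)

  # determinism: same seed -> identical; pair evaluation order irrelevant
  rc1 <- rc_bray(tab, n_null = 99, seed = 11)
  rc2 <- rc_bray(tab, n_null = 99, seed = 11)
  expect_identical(rc1, rc2)
  prs <- t(combn(colnames(tab), 2))
  rc3 <- rc_bray(tab, pairs = prs[nrow(prs):1, ], n_null = 99, seed = 11)
  expect_equal(rc1, rc3)

  expect_error(rc_bray(tab[1, , drop = FALSE], n_null = 99), "one OTU")
  expect_error(rc_bray(tab, n_null = 9), ">= 99")
})

test_that("betaNTI determinism holds under identical seeds", {
  tree <- simulate_tree(30, seed = 8)
  tab <- rand_counts(30, 5, seed = 9, lambda = 2)
  rownames(tab) <- tree$tip.label
  r1 <- beta_nti(tab, tree, n_null = 99, seed = 3)
  r2 <- beta_nti(tab, tree, n_null = 99, seed = 3)
  expect_identical(r1$bnti, r2$bnti)
})

test_that("process partition follows the two-threshold decision rule", {
  expect_equal(partition_processes(2.5, 0.99), "heterogeneous_selection")
  expect_equal(partition_processes(-2.5, 0.1), "homogeneous_selection")
  expect_equal(partition_processes(0.5, 0.97), "dispersal_limitation")
  expect_equal(partition_processes(0.5, -0.97), "homogenizing_dispersal")
  expect_equal(partition_processes(0.5, 0.2), "undominated")
  expect_true(is.na(partition_processes(NA, 0.2)))
  # boundary: thresholds are exceeded strictly
  expect_equal(partition_processes(2, 0.2), "undominated")
  expect_equal(partition_processes(0, 0.95), "undominated")
  # custom thresholds
  expect_equal(partition_processes(1.5, 0, bnti_thresh = 1), "heterogeneous_selection")
})

test_that("fraction summaries count processes and aggregates correctly", {
  calls <- c("dispersal_limitation", "dispersal_limitation",
             "undominated", "homogeneous_selection")
  fr <- summarize_fractions(calls)
  g <- function(p) fr$fraction[fr$process == p]
  expect_equal(g("dispersal_limitation"), 0.5)
  expect_equal(g("undominated"), 0.25)
  expect_equal(g("homogeneous_selection"), 0.25)
  expect_equal(g("stochastic"), 0.75)
  expect_equal(g("deterministic"), 0.25)
  expect_equal(sum(fr$fraction[1:5]), 1)

  frna <- summarize_fractions(c(calls, NA))
  expect_equal(attr(frna, "n_na"), 1L)
  expect_equal(attr(frna, "n_pairs"), 4L)
  expect_error(summarize_fractions(c(NA_character_)), "all")

  all_hs <- summarize_fractions(rep("homogeneous_selection", 6))
  expect_equal(all_hs$fraction[all_hs$process == "homogeneous_selection"], 1)
  expect_equal(all_hs$fraction[all_hs$process == "stochastic"], 0)
})

test_that("within-season assembly analysis returns consistent calls", {
  sim <- small_sim()
  tab <- sim$table[rowSums(sim$table) > 0, ]
  asm <- assembly_analysis(tab, sim$tree, sim$samples, n_null = 99, seed = 4)
  expect_setequal(names(asm), c("summer", "winter"))
  n <- sum(sim$samples$season == "summer")
  expect_equal(nrow(asm$summer$calls), n * (n - 1) / 2)
  expect_equal(sum(asm$summer$fractions$fraction[1:5]), 1)
})
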