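# Phylogenetic covariance, Blomberg's K, Pagel's lambda.

star_tree <- function(n) {
  phy <- ape::stree(n)
  phy$edge.length <- rep(1, n)
  phy$tip.label <- paste0("t", seq_len(n))
  phy
}

test_that("tree covariance matches shared-path depths", {
  C <- tree_to_covariance(star_tree(5))
  expect_equal(unname(C), diag(5))
  phy <- ape::read.tree(text = "((a:0.4,b:0.4):0.6,c:1);")
  C2 <- tree_to_covariance(phy, c("a", "b"))
  expect_equal(unname(C2), matrix(c(1, 0.6, 0.6, 1), 2))
  expect_error(tree_to_covariance(phy, c("a", "zz")), "unknown tips")
})

test_that("covariance equals a brute-force path-intersection computation", {
  phy <- simulate_tree(20, seed = 61)
  C <- tree_to_covariance(phy)
  # oracle: shared branch length = sum of edge lengths on the intersection
  # of the two root-to-tip edge sets
  paths <- ape::nodepath(phy)
  edge_len <- function(p) {  # edges of a root->tip path as "parent-child"
    keys <- paste(p[-length(p)], p[-1])
    lens <- phy$edge.length[match(keys, paste(phy$edge[, 1], phy$edge[, 2]))]
    setNames(lens, keys)
  }
  for (i in c(1, 5, 12)) for (j in seq_len(20)) {
    ei <- edge_len(paths[[i]]); ej <- edge_len(paths[[j]])
    shared <- sum(ei[intersect(names(ei), names(ej))])
    if (i == j) shared <- sum(ei)
    expect_equal(C[phy$tip.label[i], phy$tip.label[j]], shared,
                 tolerance = 1e-10)
  }
})

test_that("zero-length terminal branches are perturbed with a warning", {
  phy <- ape::read.tree(text = "((a:0,b:0.4):0.6,c:1);")
  expect_warning(C <- tree_to_covariance(phy), "zero-length")
  expect_gt(C["a", "a"], C["a", "b"])
})

test_that("K is exactly 1 on a star phylogeny and affine-invariant", {
  C <- tree_to_covariance(star_tree(8))
  set.seed(62)
  x <- setNames(rnorm(8), rownames(C))
  expect_equal(blomberg_k(x, C), 1, tolerance = 1e-10)
  phy <- simulate_tree(30, seed = 63)
  C2 <- tree_to_covariance(phy)
  y <- simulate_bm_trait(phy, 0.5, seed = 64)
  k <- blomberg_k(y, C2)
  expect_equal(blomberg_k(3.2 * y + 10, C2), k, tolerance = 1e-10)
  pl <- pagel_lambda(y, C2)
  pl2 <- pagel_lambda(3.2 * y + 10, C2)
  expect_equal(pl2$lambda, pl$lambda, tolerance = 1e-6)
  expect_error(blomberg_k(setNames(rep(1, 30), rownames(C2)), C2),
               "constant")
})

test_that("shuffling a trait on an imbalanced tree pulls K below 1", {
  phy <- ape::stree(20, type = "left")
  phy$edge.length <- rep(1, nrow(phy$edge))
  C <- tree_to_covariance(phy)
  x <- simulate_bm_trait(phy, 1, seed = 65)
  set.seed(66)
  k_shuf <- replicate(500, blomberg_k(setNames(sample(x), names(x)), C))
  expect_gte(mean(k_shuf < 1), 0.95)
})

test_that("K and lambda agree with an independent reference implementation", {
  skip_if_not_installed("phytools")
  phy <- simulate_tree(50, seed = 67)
  x <- simulate_bm_trait(phy, 0.02, 0.1, seed = 68)
  C <- tree_to_covariance(phy)
  expect_equal(blomberg_k(x, C),
               as.numeric(phytools::phylosig(phy, x, method = "K")),
               tolerance = 1e-6)
  pl <- pagel_lambda(x, C, lambda_max = 1.05)
  ref <- phytools::phylosig(phy, x, method = "lambda")
  expect_equal(pl$lambda, ref$lambda, tolerance = 5e-3)
  expect_equal(pl$loglik, ref$logL, tolerance = 1e-3)
})

test_that("the K permutation test is deterministic and bounded below", {
  phy <- simulate_tree(40, seed = 69)
  C <- tree_to_covariance(phy)
  x <- simulate_bm_trait(phy, 1, seed = 70)  # strong clade structure
  t1 <- blomberg_k_test(x, C, n_perm = 999, seed = 7)
  t2 <- blomberg_k_test(x, C, n_perm = 999, seed = 7)
  expect_identical(t1$p_value, t2$p_value)
  expect_equal(t1$estimate, blomberg_k(x, C))
  expect_equal(t1$p_value, 0.001)  # minimal achievable at 999 perms
  expect_error(blomberg_k_test(x, C, n_perm = 0), "n_perm")
})

test_that("K permutation p-values are uniform under the null", {
  phy <- simulate_tree(30, seed = 71)
  C <- tree_to_covariance(phy)
  base <- simulate_bm_trait(phy, 1, seed = 72)
  set.seed(73)
  pvals <- replicate(200, {
    x <- setNames(sample(base), names(base))  # null: labels shuffled
    blomberg_k_test(x, C, n_perm = 199, seed = sample.int(1e6, 1))$p_value
  })
  # discrete p grid (199 perms) ties are expected; KS stays usable
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("lambda likelihood at zero matches independent normal densities", {
  phy <- simulate_tree(25, seed = 74)
  C <- tree_to_covariance(phy)
  x <- simulate_bm_trait(phy, 0.3, seed = 75)
  pl <- pagel_lambda(x, C)
  d <- diag(C)
  a <- sum(x / d) / sum(1 / d)           # GLS mean under C(0)
  s2 <- sum((x - a)^2 / d) / length(x)   # profiled rate
  ll0 <- sum(dnorm(x, a, sqrt(s2 * d), log = TRUE))
  expect_equal(pl$loglik0, ll0, tolerance = 1e-8)
  expect_gte(pl$loglik, pl$loglik0 - 1e-8)
})

test_that("the lambda LR test follows the chi-square(1) reference", {
  expect_equal(lambda_lr_test(-10, -10)$p_value, 1)
  expect_equal(lambda_lr_test(-8.0795, -10)$p_value, 0.05, tolerance = 1e-3)
  expect_error(lambda_lr_test(-11, -10), "inconsistency")
  phy <- simulate_tree(100, seed = 76)
  C <- tree_to_covariance(phy)
  x <- simulate_bm_trait(phy, 0.5, seed = 77)
  pl <- pagel_lambda(x, C)
  expect_lt(lambda_lr_test(pl$loglik, pl$loglik0)$p_value, 0.001)
})

test_that("lambda is flagged unidentifiable on a star phylogeny", {
  C <- tree_to_covariance(star_tree(10))
  set.seed(78)
  x <- setNames(rnorm(10), rownames(C))
  expect_error(pagel_lambda(x, C), "unidentifiable")
})

test_that("the phylo_signal wrapper prunes to trait-bearing tips", {
  phy <- simulate_tree(30, seed = 79)
  x <- simulate_bm_trait(phy, 0.1, seed = 80)
  x_sub <- x[1:20]
  ps <- phylo_signal(phy, x_sub, n_perm = 199, seed = 1)
  expect_equal(ps$n_tips, c(20L, 20L))
  expect_setequal(ps$statistic, c("K", "lambda"))
  expect_true(all(ps$p_value > 0 & ps$p_value <= 1))
})
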