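# Forward simulator: tree, traits, taxonomy, tubes, full experiment.

test_that("simulated trees are ultrametric, unit-height and reproducible", {
  phy <- simulate_tree(3, seed = 1)
  expect_equal(length(phy$tip.label), 3L)
  expect_equal(phy$Nnode, 2L)
  depths <- ape::node.depth.edgelength(phy)[1:3]
  expect_equal(depths, rep(1, 3), tolerance = 1e-10)
  big <- simulate_tree(50, seed = 7)
  expect_equal(length(big$tip.label), 50L)
  expect_identical(ape::write.tree(simulate_tree(50, seed = 7)),
                   ape::write.tree(big))
  expect_error(simulate_tree(2), ">= 3")
})

test_that("BM traits collapse to the root value as the rate vanishes", {
  phy <- simulate_tree(10, seed = 2)
  x <- simulate_bm_trait(phy, 1e-18, root_value = 0.25, seed = 3)
  expect_equal(unname(x), rep(0.25, 10), tolerance = 1e-6)
  expect_error(simulate_bm_trait(phy, -1), "sigma2")
})

test_that("BM tip moments match the analytic covariance (Monte Carlo)", {
  star <- ape::stree(6)
  star$edge.length <- rep(1, 6)
  sims <- simulate_bm_trait(star, 1, root_value = 2, seed = 4, nsim = 10000)
  v <- apply(sims, 1, var)
  expect_true(all(abs(v - 1) < 0.05))            # marginal variance = sigma2
  expect_equal(rowMeans(sims), rep(2, 6), tolerance = 0.05,
               ignore_attr = TRUE)
  # sister tips: covariance = sigma2 x shared branch depth
  phy <- ape::read.tree(text = "((a:0.4,b:0.4):0.6,c:1);")
  sims2 <- simulate_bm_trait(phy, 1, seed = 5, nsim = 10000)
  expect_equal(cov(sims2["a", ], sims2["b", ]), 0.6, tolerance = 0.05)
  expect_equal(cov(sims2["a", ], sims2["c", ]), 0, tolerance = 0.05)
})

test_that("taxonomy cuts span one-clade and one-tip-per-clade limits", {
  phy <- simulate_tree(20, seed = 6)
  tax <- assign_taxonomy(phy, c(0, 0.2, 0.4, 0.6, 0.8, 1))
  expect_equal(length(unique(tax$phylum)), 1L)
  expect_equal(length(unique(tax$species)), 20L)
  expect_equal(ncol(tax), 9L)  # taxon + 7 ranks + lineage
})

test_that("taxonomic ranks are strictly nested at any cut depths", {
  phy <- simulate_tree(40, seed = 8)
  set.seed(9)
  for (rep in 1:5) {
    depths <- sort(runif(6, 0.05, 0.95))
    tax <- assign_taxonomy(phy, depths)
    ranks <- c("phylum", "class", "order", "family", "genus", "species")
    for (j in seq_len(length(ranks) - 1L)) {
      child_parent <- unique(tax[, c(ranks[j + 1L], ranks[j])])
      expect_equal(anyDuplicated(child_parent[[1L]]), 0L)
    }
  }
  expect_error(assign_taxonomy(phy, c(0.5, 0.4, 0.6, 0.7, 0.8, 0.9)),
               "increasing")
})

test_that("unlabeled taxa have identical expected profiles in paired tubes", {
  cfg <- sim_config(n_taxa = 10, qpcr_cv = 0, sequencing_depth = Inf,
                    detection_floor = 0,
                    treatment_effect = c(control = 0, STW = 0, LTW = 0),
                    bm_sigma2 = 1e-12, bm_root = 0, seed = 21)
  com <- simulate_community(cfg)
  com$eaf[] <- 0  # exactly unlabeled
  light <- simulate_tube(com, "control", "16O", 1, cfg, seed = 1)
  heavy <- simulate_tube(com, "control", "18O", 1, cfg, seed = 2)
  expect_equal(light$rel_abund, heavy$rel_abund, tolerance = 1e-12)
})

test_that("noise-free tube WADs equal the discretized-Gaussian mean density", {
  cfg <- sim_config(n_taxa = 12, qpcr_cv = 0, sequencing_depth = Inf,
                    detection_floor = 0, seed = 22)
  com <- simulate_community(cfg)
  tube <- simulate_tube(com, "control", "16O", 1, cfg, seed = 1)
  x <- tube$fractions$density_g_ml
  totals <- tube$fractions$total_16s_copies
  rho <- density_from_gc(com$gc)
  edges <- seq(cfg$density_range[1], cfg$density_range[2],
               length.out = cfg$n_fractions + 1L)
  for (k in seq_len(cfg$n_taxa)) {
    mass <- pnorm(edges[-1], rho[k], cfg$profile_sd) -
            pnorm(edges[-length(edges)], rho[k], cfg$profile_sd)
    expected_w <- sum(x * mass) / sum(mass)
    y <- taxon_copies(tube$rel_abund[k, ], totals)
    expect_equal(weighted_average_density(x, y), expected_w,
                 tolerance = 1e-4)
  }
})

test_that("expected WAD rises with true EAF in 18O tubes, not in 16O tubes", {
  cfg <- sim_config(n_taxa = 8, qpcr_cv = 0, sequencing_depth = Inf,
                    detection_floor = 0, seed = 23)
  com_lo <- simulate_community(cfg)
  com_hi <- com_lo
  com_hi$eaf[, "STW"] <- pmin(com_lo$eaf[, "STW"] + 0.1, 0.59)
  wad_of <- function(com, iso) {
    tube <- simulate_tube(com, "STW", iso, 1, cfg, seed = 1)
    x <- tube$fractions$density_g_ml
    tot <- tube$fractions$total_16s_copies
    apply(tube$rel_abund, 1, function(p)
      weighted_average_density(x, taxon_copies(p, tot)))
  }
  expect_true(all(wad_of(com_hi, "18O") > wad_of(com_lo, "18O")))
  expect_equal(wad_of(com_hi, "16O"), wad_of(com_lo, "16O"),
               tolerance = 1e-12)
})

test_that("experiment layout, multinomial conservation and determinism hold", {
  cfg <- sim_config(n_taxa = 15, seed = 24)
  ex <- simulate_experiment(cfg)
  expect_equal(length(unique(ex$samples$tube_id)), 24L)
  expect_s3_class(ex, "sip_experiment")
  # counts sum to the sequencing depth in every fraction carrying DNA
  cs <- colSums(ex$counts)
  expect_true(all(cs %in% c(0L, cfg$sequencing_depth)))
  expect_true(mean(cs == cfg$sequencing_depth) > 0.9)
  ex2 <- simulate_experiment(cfg)
  expect_identical(ex$rel_abund, ex2$rel_abund)
  expect_identical(ex$samples, ex2$samples)
  small <- simulate_experiment(sim_config(
    n_taxa = 5, n_blocks = 1, treatments = "control",
    treatment_effect = c(control = 0), seed = 1))
  expect_equal(length(unique(small$samples$tube_id)), 2L)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_fractions = 3), ">= 4")
  expect_error(sim_config(density_range = c(1.7, 1.6)), "min < max")
  expect_error(sim_config(profile_sd = 0), "profile_sd")
  expect_error(sim_config(rank_depths = rep(0.5, 6)), "increasing")
})
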