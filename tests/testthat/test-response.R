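# Treatment-level growth statistics: contrasts, Q10, delta-EAF,
# occurrence partition, rank aggregation.

test_that("percent increase reproduces the headline treatment contrasts", {
  expect_equal(round(percent_increase(0.095, 0.070)), 36)
  expect_equal(round(percent_increase(0.176, 0.070)), 151)
  expect_equal(percent_increase(0.176, 0.070) / 100 + 1, 2.514,
               tolerance = 1e-3)
  expect_equal(percent_increase(0.3, 0.3), 0)
  expect_error(percent_increase(1, 0), "> 0")
})

test_that("Q10 follows the van't Hoff identities and printed values", {
  expect_equal(q10(1.36, 1.6), 6.83, tolerance = 1e-3)
  expect_equal(q10(2.51, 1.6), 314.8, tolerance = 1e-3)
  for (r in c(0.5, 1, 2, 7.3)) expect_equal(q10(r, 10), r)
  expect_equal(q10(1, 3.7), 1)
  # log-linearity: log Q10 = (10/dT) log r
  set.seed(51)
  r <- runif(10, 0.2, 5); dt <- runif(10, 0.5, 12)
  expect_equal(log(q10(r, dt)), (10 / dt) * log(r))
  expect_error(q10(-1, 5), "> 0")
  expect_error(q10(2, 0), "> 0")
})

test_that("degenerate assemblage contrasts are handled exactly", {
  same <- list(a = c(0.1, 0.2, 0.3, 0.4), b = c(0.1, 0.2, 0.3, 0.4))
  ct <- assemblage_mean_contrast(same)
  expect_lt(ct$anova$F, 1e-10)
  expect_equal(ct$means$letter[1], ct$means$letter[2])
  far <- list(a = c(0, 0, 0, 0), b = c(1, 1, 1, 1))
  ct2 <- assemblage_mean_contrast(far)
  expect_lt(ct2$anova$p, 1e-6)
  expect_false(ct2$means$letter[1] == ct2$means$letter[2])
  expect_warning(assemblage_mean_contrast(
    list(a = rep(1, 3), b = rep(1, 3))), "identical")
})

test_that("Tukey decisions agree with a permutation contrast", {
  set.seed(52)
  groups <- list(control = rnorm(40, 0.07, 0.03),
                 STW = rnorm(40, 0.075, 0.03),   # null-ish shift
                 LTW = rnorm(40, 0.18, 0.03))    # strong shift
  ct <- assemblage_mean_contrast(groups)
  perm_p <- function(a, b, n_perm = 4000) {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      s <- sample(length(pool), length(a))
      if (abs(mean(pool[s]) - mean(pool[-s])) >= obs) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  }
  pairs <- list(c("STW", "control"), c("LTW", "control"), c("LTW", "STW"))
  for (pr in pairs) {
    tk <- ct$tukey$p_adj[ct$tukey$contrast %in%
                           c(paste(pr, collapse = "-"),
                             paste(rev(pr), collapse = "-"))]
    expect_equal(tk < 0.05, perm_p(groups[[pr[1]]], groups[[pr[2]]]) < 0.05)
  }
  # letters: LTW separated, STW/control shared
  ml <- setNames(ct$means$letter, ct$means$treatment)
  expect_equal(ml[["control"]], ml[["STW"]])
  expect_false(ml[["LTW"]] == ml[["control"]])
})

test_that("delta-EAF is antisymmetric and zero for identical treatments", {
  ex <- noisy_experiment()
  fit <- qsip(ex, n_boot = 100, seed = 3)
  ab <- delta_eaf(fit, "STW", "control", n_boot = 100, seed = 4)
  ba <- delta_eaf(fit, "control", "STW", n_boot = 100, seed = 4)
  expect_equal(ab$delta_eaf,
               -ba$delta_eaf[match(ab$taxon, ba$taxon)])
  same <- delta_eaf(fit, "control", "control", n_boot = 100, seed = 4)
  expect_true(all(same$delta_eaf == 0))
  expect_true(all(same$response == "neutral"))
})

test_that("a clean simulated shift is classified positive throughout", {
  cfg <- sim_config(n_taxa = 20, qpcr_cv = 0, sequencing_depth = Inf,
                    detection_floor = 0, treatments = c("control", "warm"),
                    treatment_effect = c(control = 0, warm = 0.1),
                    bm_root = 0.15, bm_sigma2 = 0.002, seed = 53)
  fit <- qsip(simulate_experiment(cfg), n_boot = 100, seed = 1)
  rt <- delta_eaf(fit, "warm", "control", n_boot = 100, seed = 1)
  expect_gt(nrow(rt), 10)
  expect_true(all(rt$response == "positive"))
  expect_equal(rt$delta_eaf, rep(0.1, nrow(rt)), tolerance = 0.01)
})

test_that("taxa growing in only one treatment are excluded but partitioned", {
  eaf <- rbind(fake_eaf_row("t1", "control", 0.1),
               fake_eaf_row("t1", "warm", 0.2),
               fake_eaf_row("t2", "warm", 0.15),
               fake_eaf_row("t3", "control", 0.05))
  fit <- fake_fit(eaf)
  rt <- delta_eaf(fit, "warm", "control", n_boot = 50, seed = 1)
  expect_equal(rt$taxon, "t1")
  expect_setequal(attr(rt, "excluded"), c("t2", "t3"))
  op <- occurrence_partition(fit)
  expect_setequal(op$membership$category[op$membership$taxon == "t2"],
                  "warm")
  expect_equal(sum(op$categories$n_taxa), 3L)
})

test_that("the occurrence partition is complete and count-consistent", {
  ex <- noisy_experiment()
  fit <- qsip(ex, n_boot = 100, seed = 6)
  op <- occurrence_partition(fit)
  growing <- unique(fit$eaf$taxon[fit$eaf$growing])
  expect_setequal(op$membership$taxon, growing)
  expect_equal(anyDuplicated(op$membership$taxon), 0L)
  expect_equal(sum(op$categories$n_taxa), length(growing))
  # per-category means only defined for member treatments
  for (i in seq_len(nrow(op$categories))) {
    trs <- strsplit(op$categories$category[i], "+", fixed = TRUE)[[1]]
    for (tr in op$treatments) {
      m <- op$categories[[paste0("mean_", tr)]][i]
      expect_identical(is.na(m), !(tr %in% trs))
    }
  }
})

test_that("disjoint growing sets yield only single-treatment categories", {
  eaf <- rbind(fake_eaf_row(c("t1", "t2"), "control", c(0.1, 0.2)),
               fake_eaf_row(c("t3", "t4"), "warm", c(0.1, 0.2)))
  op <- occurrence_partition(fake_fit(eaf))
  expect_setequal(op$categories$category, c("control", "warm"))
  expect_equal(op$categories$n_taxa, c(2L, 2L))
})

test_that("rank aggregation enforces the three-representatives rule", {
  taxa <- sprintf("t%02d", 1:12)
  tax <- data.frame(taxon = taxa,
                    order = rep(c("Big", "Small"), c(8, 4)))
  eaf <- rbind(
    fake_eaf_row(taxa[1:8], "control", seq(0.05, 0.12, by = 0.01)),
    fake_eaf_row(taxa[1:8], "warm", seq(0.05, 0.12, by = 0.01) + 0.04),
    fake_eaf_row(taxa[9:10], "control", c(0.2, 0.3)),  # only 2 in control
    fake_eaf_row(taxa[9:12], "warm", c(0.2, 0.3, 0.25, 0.28)))
  out <- aggregate_by_rank(fake_fit(eaf), tax, "order", min_taxa = 3,
                           control = "control")
  expect_equal(out$group, "Big")
  expect_equal(out$delta_eaf, 0.04, tolerance = 1e-12)
  expect_true(any(grepl("Small", attr(out, "omitted"))))
  expect_error(aggregate_by_rank(fake_fit(eaf), tax, "clade"), "unknown rank")
})

test_that("one shared order reproduces the assemblage contrast", {
  ex <- noiseless_experiment()
  fit <- qsip(ex, n_boot = 50, seed = 1)
  tax <- data.frame(taxon = rownames(ex$rel_abund), order = "only")
  out <- aggregate_by_rank(fit, tax, "order", min_taxa = 3)
  ge <- fit$eaf[fit$eaf$growing, ]
  for (tr in unique(out$treatment)) {
    shared <- intersect(ge$taxon[ge$treatment == tr],
                        ge$taxon[ge$treatment == "control"])
    d <- mean(ge$mean_eaf[ge$treatment == tr & ge$taxon %in% shared]) -
         mean(ge$mean_eaf[ge$treatment == "control" & ge$taxon %in% shared])
    expect_equal(out$delta_eaf[out$treatment == tr], d, tolerance = 1e-12)
  }
})
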