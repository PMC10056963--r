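# Shared fixtures, built once per test run.

# Small noiseless experiment: exact expected abundances, no qPCR noise,
# no dropout. Ideal for recovery and round-trip checks.
noiseless_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_experiment(sim_config(
        n_taxa = 40, qpcr_cv = 0, sequencing_depth = Inf,
        detection_floor = 0, seed = 11))
    cache
  }
})

# Small experiment with default noise levels.
noisy_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_experiment(sim_config(n_taxa = 60, seed = 12))
    cache
  }
})

# Fabricate a minimal qsip_fit carrying a chosen EAF table, for testing
# downstream set logic (occurrence partition, rank aggregation)
# independently of the estimator.
fake_fit <- function(eaf, n_blocks = 4L) {
  taxa <- unique(eaf$taxon)
  treatments <- unique(eaf$treatment)
  be <- array(NA_real_, c(length(taxa), n_blocks, length(treatments)),
              dimnames = list(taxa, paste0("b", seq_len(n_blocks)),
                              treatments))
  for (i in seq_len(nrow(eaf)))
    be[eaf$taxon[i], , eaf$treatment[i]] <- eaf$raw_mean[i]
  structure(list(eaf = eaf, block_eaf = be,
                 wad = matrix(NA_real_, length(taxa), 0,
                              dimnames = list(taxa, NULL)),
                 settings = list(ci_level = 0.90)),
            class = "qsip_fit")
}

fake_eaf_row <- function(taxon, treatment, mean_eaf) {
  data.frame(taxon = taxon, treatment = treatment, mean_eaf = mean_eaf,
             raw_mean = mean_eaf, ci_lo = mean_eaf, ci_hi = mean_eaf,
             n_blocks = 4L, truncated = FALSE, growing = mean_eaf > 0,
             gc = 0.5, ref_fallback = FALSE, stringsAsFactors = FALSE)
}

# brute-force longest run of TRUEs, used as the filter oracle
longest_run <- function(present) {
  best <- 0L; cur <- 0L
  for (v in present) {
    cur <- if (v) cur + 1L else 0L
    best <- max(best, cur)
  }
  best
}
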