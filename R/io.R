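#' Write a simulated SIP dataset to plain-text files
#'
#' Writes the experiment in the package's interchange formats:
#' `fractions.tsv` (tube metadata + per-fraction density and qPCR totals),
#' `rel_abund.tsv` (taxa x fraction-samples relative abundances),
#' `counts.tsv` (if counts exist), `taxonomy.tsv` (taxon + 7-rank
#' semicolon-delimited lineage), `tree.nwk` (Newick), `truth.json`
#' (simulator ground truth, if present) and `manifest.json` (seed, config,
#' constants version). Fraction indices are 1-based in files.
#'
#' @param experiment a `sip_experiment`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sip_dataset <- function(experiment, dir) {
  stopifnot(inherits(experiment, "sip_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(d, f, rn = FALSE)
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  smp <- experiment$samples
  names(smp)[names(smp) == "fraction"] <- "fraction_idx"
  tsv(smp, "fractions.tsv")
  tsv(data.frame(taxon = rownames(experiment$rel_abund),
                 experiment$rel_abund, check.names = FALSE),
      "rel_abund.tsv")
  if (!is.null(experiment$counts))
    tsv(data.frame(taxon = rownames(experiment$counts), experiment$counts,
                   check.names = FALSE), "counts.tsv")
  tsv(experiment$taxonomy[, c("taxon", "lineage")], "taxonomy.tsv")
  ape::write.tree(experiment$tree, file.path(dir, "tree.nwk"))
  if (!is.null(experiment$truth)) {
    tr <- experiment$truth
    truth <- list(gc = as.list(tr$gc), weights = as.list(tr$weights),
                  eaf = apply(tr$eaf, 2L, as.list),
                  config = unclass(tr$config))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(format = "sipgrowth-dataset-1",
                   constants = qsip_constants()$version,
                   seed = if (!is.null(experiment$truth))
                     experiment$truth$config$seed else NA,
                   n_taxa = nrow(experiment$rel_abund),
                   n_samples = nrow(experiment$samples))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a SIP dataset from plain-text files
#'
#' Counterpart of [write_sip_dataset]; also reads externally produced
#' datasets in the same layout. `tree.nwk`, `counts.tsv` and `truth.json`
#' are optional.
#'
#' @param dir dataset directory.
#' @return a `sip_experiment` (with `truth = NULL` for real data).
#' @export
read_sip_dataset <- function(dir) {
  req <- file.path(dir, c("fractions.tsv", "rel_abund.tsv", "taxonomy.tsv"))
  if (!all(file.exists(req)))
    stop("dataset incomplete; missing: ",
         paste(basename(req[!file.exists(req)]), collapse = ", "))
  smp <- utils::read.table(file.path(dir, "fractions.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  names(smp)[names(smp) == "fraction_idx"] <- "fraction"
  rel <- utils::read.table(file.path(dir, "rel_abund.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  rel_m <- as.matrix(rel[, -1L, drop = FALSE])
  rownames(rel_m) <- rel$taxon
  cnt_m <- NULL
  if (file.exists(file.path(dir, "counts.tsv"))) {
    cnt <- utils::read.table(file.path(dir, "counts.tsv"), sep = "\t",
                             header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    cnt_m <- as.matrix(cnt[, -1L, drop = FALSE])
    rownames(cnt_m) <- cnt$taxon
  }
  tax <- utils::read.table(file.path(dir, "taxonomy.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  tax <- parse_lineage(tax)
  tree <- if (file.exists(file.path(dir, "tree.nwk")))
    ape::read.tree(file.path(dir, "tree.nwk")) else NULL
  structure(list(samples = smp, rel_abund = rel_m, counts = cnt_m,
                 taxonomy = tax, tree = tree, truth = NULL),
            class = "sip_experiment")
}

# expand semicolon-delimited SILVA-style lineage strings into rank columns
parse_lineage <- function(tax) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus",
             "species")
  if (all(ranks %in% names(tax))) {
    if (!"lineage" %in% names(tax))
      tax$lineage <- apply(tax[, ranks], 1L, paste, collapse = ";")
    return(tax)
  }
  if (!"lineage" %in% names(tax))
    stop("taxonomy needs a 'lineage' column or the 7 rank columns")
  parts <- strsplit(tax$lineage, ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- length(ranks)
    p
  }, character(length(ranks))))
  m[m == ""] <- NA_character_
  out <- data.frame(taxon = tax$taxon, m, stringsAsFactors = FALSE)
  names(out) <- c("taxon", ranks)
  out$lineage <- tax$lineage
  out
}

#' Analysis configuration
#'
#' Bundles the tunable settings of [run_sip_analysis]; round-trips through
#' YAML via [read_sip_config] / [write_sip_config].
#'
#' @param min_consecutive occurrence-filter run length.
#' @param n_boot bootstrap resamples for EAF and delta-EAF CIs.
#' @param ci_level two-sided CI level.
#' @param delta_T warming magnitude (degrees C) for Q10.
#' @param n_perm permutations for the Blomberg K test.
#' @param lambda_max upper bound of the lambda search.
#' @param varcomp_levels taxonomic ranks entered as nested random effects.
#' @param rank,min_taxa rank-level aggregation settings.
#' @param control reference treatment label.
#' @param seed integer seed for all stochastic stages.
#' @return named list of class `sip_analysis_config`.
#' @export
sip_config <- function(min_consecutive = 3L, n_boot = 1000L,
                       ci_level = 0.90, delta_T = 1.6, n_perm = 999L,
                       lambda_max = 1,
                       varcomp_levels = c("phylum", "class", "order",
                                          "family", "genus"),
                       rank = "order", min_taxa = 3L,
                       control = "control", seed = 1L) {
  structure(list(min_consecutive = as.integer(min_consecutive),
                 n_boot = as.integer(n_boot), ci_level = ci_level,
                 delta_T = delta_T, n_perm = as.integer(n_perm),
                 lambda_max = lambda_max,
                 varcomp_levels = varcomp_levels, rank = rank,
                 min_taxa = as.integer(min_taxa), control = control,
                 seed = as.integer(seed)),
            class = "sip_analysis_config")
}

#' @rdname sip_config
#' @param path YAML file path.
#' @export
read_sip_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sip_config, vals)
}

#' @rdname sip_config
#' @param config a `sip_analysis_config`.
#' @export
write_sip_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full qSIP growth analysis
#'
#' Chains the pipeline stages in order: per-taxon EAF estimation
#' ([qsip]), assemblage contrast with Q10 conversion, per-taxon delta-EAF
#' responses, occurrence partition, rank-level aggregation, phylogenetic
#' signal of EAF and delta-EAF (skipped with a warning when no tree is
#' available), and nested taxonomic variance components (levels with a
#' single group are dropped with a note; skipped if none remain).
#'
#' @param experiment a `sip_experiment` or a dataset directory for
#'   [read_sip_dataset].
#' @param config a [sip_config].
#' @param outdir optional directory; when given, tables are written as TSV
#'   and a `report.json` summary alongside.
#' @return list of class `sip_report`: `fit`, `contrast`, `q10`,
#'   `responses` (per warming treatment), `partition`, `rank_table`,
#'   `signal` (per trait, or `NULL`), `varcomp` (per treatment, or
#'   `NULL`), `config`.
#' @export
run_sip_analysis <- function(experiment, config = sip_config(),
                             outdir = NULL) {
  if (is.character(experiment)) experiment <- read_sip_dataset(experiment)
  stopifnot(inherits(experiment, "sip_experiment"),
            inherits(config, "sip_analysis_config"))
  fit <- qsip(experiment, min_consecutive = config$min_consecutive,
              n_boot = config$n_boot, ci_level = config$ci_level,
              seed = config$seed)
  treatments <- unique(fit$eaf$treatment)
  warming <- setdiff(treatments, config$control)
  contrast <- assemblage_mean_contrast(fit)
  ctl_mean <- contrast$means$mean[contrast$means$treatment == config$control]
  q10_tab <- data.frame(
    treatment = warming,
    ratio = contrast$means$mean[match(warming, contrast$means$treatment)] /
      ctl_mean,
    delta_T = config$delta_T)
  q10_tab$percent_increase <- percent_increase(
    contrast$means$mean[match(warming, contrast$means$treatment)], ctl_mean)
  q10_tab$q10 <- q10(q10_tab$ratio, config$delta_T)
  responses <- lapply(warming, function(tr)
    delta_eaf(fit, tr, config$control, n_boot = config$n_boot,
              ci_level = config$ci_level, seed = config$seed))
  names(responses) <- warming
  partition <- occurrence_partition(fit)
  rank_table <- aggregate_by_rank(fit, experiment$taxonomy, config$rank,
                                  config$min_taxa, config$control)
  signal <- NULL
  if (!is.null(experiment$tree)) {
    traits <- c(
      stats::setNames(lapply(treatments, function(tr) {
        d <- fit$eaf[fit$eaf$treatment == tr & fit$eaf$growing, ]
        stats::setNames(d$mean_eaf, d$taxon)
      }), paste0("EAF_", treatments)),
      stats::setNames(lapply(responses, function(r)
        stats::setNames(r$delta_eaf, r$taxon)),
        paste0("dEAF_", names(responses))))
    signal <- lapply(traits, function(x) {
      if (length(x) < 4L || stats::var(x) == 0) return(NULL)
      phylo_signal(experiment$tree, x, n_perm = config$n_perm,
                   lambda_max = config$lambda_max, seed = config$seed)
    })
  } else {
    warning("no tree in dataset; phylogenetic-signal stage skipped")
  }
  varcomp <- lapply(treatments, function(tr) {
    d <- fit$eaf[fit$eaf$treatment == tr, ]
    x <- stats::setNames(d$mean_eaf, d$taxon)
    lv <- usable_levels(x, experiment$taxonomy, config$varcomp_levels)
    if (!length(lv)) return(NULL)
    vc <- fit_nested_varcomp(x, experiment$taxonomy, lv)
    vc$test <- varcomp_significance(vc)
    vc
  })
  names(varcomp) <- treatments
  report <- structure(list(fit = fit, contrast = contrast, q10 = q10_tab,
                           responses = responses, partition = partition,
                           rank_table = rank_table, signal = signal,
                           varcomp = varcomp, config = config),
                      class = "sip_report")
  if (!is.null(outdir)) write_sip_report(report, outdir)
  report
}

# levels of the taxonomy with >= 2 groups among the scored taxa
usable_levels <- function(x, taxonomy, levels) {
  idx <- match(names(x), taxonomy$taxon)
  keep <- character()
  for (lv in levels) {
    if (!lv %in% names(taxonomy)) next
    g <- taxonomy[[lv]][idx]
    if (length(unique(g[!is.na(g)])) >= 2L) keep <- c(keep, lv)
    else message("varcomp level '", lv, "' has < 2 groups; dropped")
  }
  keep
}

# write the report tables (TSV) and a JSON summary
write_sip_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tsv <- function(d, f)
    utils::write.table(d, file.path(outdir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tsv(report$fit$eaf, "eaf_table.tsv")
  for (tr in names(report$responses))
    tsv(report$responses[[tr]], paste0("delta_eaf_", tr, ".tsv"))
  tsv(report$partition$categories, "occurrence_partition.tsv")
  tsv(report$rank_table, "rank_aggregate.tsv")
  summary_list <- list(
    settings = unclass(report$config),
    constants = qsip_constants()$version,
    assemblage = report$contrast$means,
    anova = report$contrast$anova,
    q10 = report$q10,
    signal = lapply(report$signal, function(s)
      if (is.null(s)) NULL else as.data.frame(s)),
    varcomp = lapply(report$varcomp, function(v)
      if (is.null(v)) NULL else
        list(components = v$components,
             p_value = if (!is.null(v$test)) v$test$p_value else NA)))
  jsonlite::write_json(summary_list, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(outdir)
}

#' @export
print.sip_report <- function(x, ...) {
  cat("qSIP growth analysis report\n\nAssemblage contrast:\n")
  print(x$contrast)
  cat("\nWarming responses:\n")
  print(x$q10, digits = 3, row.names = FALSE)
  if (!is.null(x$signal)) {
    cat("\nPhylogenetic signal:\n")
    for (nm in names(x$signal)) {
      s <- x$signal[[nm]]
      if (is.null(s)) next
      cat(sprintf("  %-12s K = %.3f (p = %.3g), lambda = %.3f (p = %.3g)\n",
                  nm, s$estimate[1], s$p_value[1], s$estimate[2],
                  s$p_value[2]))
    }
  }
  invisible(x)
}
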