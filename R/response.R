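#' Assemblage mean EAF contrast across treatments
#'
#' One-way ANOVA on taxon-level EAF values by treatment, with Tukey HSD
#' pairwise comparisons and a compact letter display (treatments sharing a
#' letter do not differ at `alpha`). The taxon is the unit of replication,
#' matching the assemblage-level boxplot comparison this mirrors; the
#' pseudo-replication caveat (taxa within a block are not independent) is
#' discussed in the methods vignette, and a block-mean alternative is
#' available via `unit = "block"`.
#'
#' @param x a `qsip_fit`, or a named list of numeric vectors (one per
#'   treatment) of taxon EAF values.
#' @param alpha significance level for letter grouping (default 0.05).
#' @param unit `"taxon"` (default) or `"block"`: with a `qsip_fit` and
#'   `"block"`, per-block mean EAFs are the observation unit.
#' @return list of class `eaf_contrast`: `means` (data.frame `treatment`,
#'   `n`, `mean`, `se`, `letter`), `anova` (`F`, `df1`, `df2`, `p`),
#'   `tukey` (pairwise data.frame).
#' @export
assemblage_mean_contrast <- function(x, alpha = 0.05,
                                     unit = c("taxon", "block")) {
  unit <- match.arg(unit)
  if (inherits(x, "qsip_fit")) {
    if (unit == "taxon") {
      vals <- split(x$eaf$mean_eaf, x$eaf$treatment)
    } else {
      be <- x$block_eaf
      vals <- lapply(dimnames(be)[[3]], function(tr)
        colMeans(pmax(be[, , tr], 0), na.rm = TRUE))
      names(vals) <- dimnames(be)[[3]]
    }
    vals <- vals[unique(x$eaf$treatment)]
  } else vals <- x
  if (length(vals) < 2L) stop("need >= 2 treatments")
  if (any(vapply(vals, length, 1L) < 2L))
    stop("each treatment needs >= 2 values")
  d <- data.frame(eaf = unlist(vals, use.names = FALSE),
                  treatment = factor(rep(names(vals),
                                         vapply(vals, length, 1L)),
                                     levels = names(vals)))
  if (stats::var(d$eaf) == 0) {
    warning("all values identical; groups degenerate, assigning one letter")
    means <- data.frame(treatment = names(vals),
                        n = vapply(vals, length, 1L),
                        mean = vapply(vals, mean, 1),
                        se = 0, letter = "a")
    return(structure(list(means = means,
                          anova = data.frame(F = 0, df1 = length(vals) - 1L,
                                             df2 = nrow(d) - length(vals),
                                             p = 1),
                          tukey = NULL), class = "eaf_contrast"))
  }
  fit <- stats::aov(eaf ~ treatment, data = d)
  av <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$treatment
  pw <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"], row.names = NULL)
  # zero residual variance makes Tukey p NaN; exact ties are then decisive
  bad <- !is.finite(pw$p_adj)
  pw$p_adj[bad] <- ifelse(abs(pw$diff[bad]) > 1e-12, 0, 1)
  means <- data.frame(treatment = names(vals),
                      n = vapply(vals, length, 1L),
                      mean = vapply(vals, mean, 1),
                      se = vapply(vals, function(v)
                        stats::sd(v) / sqrt(length(v)), 1))
  means$letter <- tukey_letters(means$treatment, pw, alpha)
  rownames(means) <- NULL
  structure(list(means = means,
                 anova = data.frame(F = av$`F value`[1L],
                                    df1 = av$Df[1L], df2 = av$Df[2L],
                                    p = av$`Pr(>F)`[1L]),
                 tukey = pw),
            class = "eaf_contrast")
}

# Compact letter display for pairwise Tukey p-values (insert-and-absorb;
# adequate for the handful of treatment groups this package compares).
tukey_letters <- function(groups, pairwise, alpha) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairwise))) {
    gg <- strsplit(pairwise$contrast[i], "-", fixed = TRUE)[[1L]]
    if (pairwise$p_adj[i] < alpha) sig[gg[1L], gg[2L]] <- sig[gg[2L], gg[1L]] <- TRUE
  }
  sets <- list(groups)  # candidate same-letter sets, split on significance
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    if (!sig[i, j]) next
    for (s in seq_along(sets)) {
      if (all(groups[c(i, j)] %in% sets[[s]])) {
        sets <- c(sets, list(setdiff(sets[[s]], groups[i])),
                  list(setdiff(sets[[s]], groups[j])))
        sets[s] <- NULL
        break
      }
    }
  }
  # drop subsets, keep maximal sets in stable order
  sets <- unique(sets)
  keep <- vapply(seq_along(sets), function(s)
    !any(vapply(seq_along(sets), function(t)
      t != s && all(sets[[s]] %in% sets[[t]]), TRUE)), TRUE)
  sets <- sets[keep]
  letters_out <- vapply(groups, function(g)
    paste(letters[which(vapply(sets, function(s) g %in% s, TRUE))],
          collapse = ""), "")
  letters_out
}

#' @export
print.eaf_contrast <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  print(x$means, digits = 3)
  invisible(x)
}

#' Percent increase of a treatment mean over the control mean
#'
#' @param mean_treatment,mean_control treatment and control means;
#'   `mean_control` must be > 0.
#' @return `100 * (mean_treatment - mean_control) / mean_control`.
#' @export
percent_increase <- function(mean_treatment, mean_control) {
  if (any(mean_control <= 0)) stop("mean_control must be > 0")
  100 * (mean_treatment - mean_control) / mean_control
}

#' Van't Hoff Q10 temperature sensitivity
#'
#' Converts the fold change `ratio` of a rate observed across a warming of
#' `delta_T` degrees C into the equivalent fold change per 10 degrees:
#' \eqn{Q_{10} = ratio^{10/\Delta T}}.
#'
#' @param ratio rate ratio (> 0), e.g. warmed mean / control mean.
#' @param delta_T temperature difference in degrees C (> 0).
#' @return the Q10 value.
#' @export
q10 <- function(ratio, delta_T) {
  if (any(ratio <= 0)) stop("ratio must be > 0")
  if (any(delta_T <= 0)) stop("delta_T must be > 0")
  ratio^(10 / delta_T)
}

#' Per-taxon growth response to a treatment (delta-EAF)
#'
#' For every taxon growing in both the focal treatment and the control,
#' computes \eqn{\Delta EAF = EAF_{treatment} - EAF_{control}} with a joint
#' block-bootstrap confidence interval (the same resampled block set is
#' applied to both treatments, preserving the paired block structure) and
#' classifies the response: `positive` if the CI lies above zero,
#' `negative` if below, `neutral` otherwise.
#'
#' @param fit a `qsip_fit`.
#' @param treatment focal treatment label.
#' @param control reference treatment label.
#' @param n_boot bootstrap resamples (default 1000).
#' @param ci_level two-sided CI level (default matches the fit).
#' @param ci_method `"expanded"` (default) widens the percentile interval
#'   by the small-sample factor of Hesterberg's expanded percentile
#'   interval (quantile tails at
#'   \eqn{\Phi(-\sqrt{n/(n-1)}\, t_{\alpha/2, n-1})} for \eqn{n} blocks);
#'   with as few as four blocks the plain percentile interval undercovers
#'   badly and misclassifies ~10\% per tail under the null, while the
#'   expanded interval restores near-nominal error. `"percentile"` gives
#'   the plain interval.
#' @param seed integer seed.
#' @return data.frame of class `response_table`: `taxon`, `delta_eaf`,
#'   `ci_lo`, `ci_hi`, `response` (factor positive/neutral/negative),
#'   `treatment`, `control`. Taxa not growing in both treatments are
#'   excluded; exclusion counts are in `attr(, "excluded")`.
#' @export
delta_eaf <- function(fit, treatment, control = "control", n_boot = 1000L,
                      ci_level = fit$settings$ci_level,
                      ci_method = c("expanded", "percentile"), seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(fit, "qsip_fit"))
  treatments <- dimnames(fit$block_eaf)[[3]]
  if (!all(c(treatment, control) %in% treatments))
    stop("unknown treatment label")
  ge <- fit$eaf[fit$eaf$growing, ]
  taxa <- intersect(ge$taxon[ge$treatment == treatment],
                    ge$taxon[ge$treatment == control])
  excluded <- setdiff(union(ge$taxon[ge$treatment == treatment],
                            ge$taxon[ge$treatment == control]), taxa)
  bt <- fit$block_eaf[taxa, , treatment, drop = FALSE]
  bc <- fit$block_eaf[taxa, , control, drop = FALSE]
  dim(bt) <- dim(bc) <- c(length(taxa), dim(fit$block_eaf)[2L])
  et <- ge[ge$treatment == treatment, ]
  ec <- ge[ge$treatment == control, ]
  est <- et$mean_eaf[match(taxa, et$taxon)] -
         ec$mean_eaf[match(taxa, ec$taxon)]
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nb <- dim(fit$block_eaf)[2L]
  idx <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = nb)
  boot_t <- boot_block_means(bt, idx)
  boot_c <- boot_block_means(bc, idx)
  dboot <- pmax(boot_t, 0) - pmax(boot_c, 0)
  tail_p <- (1 - ci_level) / 2
  if (ci_method == "expanded")
    tail_p <- stats::pnorm(-sqrt(nb / (nb - 1)) *
                             stats::qt(1 - tail_p, nb - 1))
  ci <- t(apply(dboot, 1L, function(v) {
    if (all(is.na(v))) return(c(NA_real_, NA_real_))
    stats::quantile(v, c(tail_p, 1 - tail_p), na.rm = TRUE, names = FALSE)
  }))
  response <- factor(ifelse(ci[, 1L] > 0, "positive",
                     ifelse(ci[, 2L] < 0, "negative", "neutral")),
                     levels = c("positive", "neutral", "negative"))
  out <- data.frame(taxon = taxa, delta_eaf = est,
                    ci_lo = ci[, 1L], ci_hi = ci[, 2L],
                    response = response, treatment = treatment,
                    control = control, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  class(out) <- c("response_table", "data.frame")
  out
}

#' Occurrence partition of growing taxa across treatments
#'
#' Assigns every growing taxon to exactly one of the \eqn{2^k - 1}
#' treatment-membership categories (the cells of a Venn diagram over the
#' growing-taxon sets) and summarizes each category's per-treatment mean
#' EAF. Within categories spanning two treatments the means are compared
#' by a Student's t test; categories spanning three or more use one-way
#' ANOVA with Tukey HSD.
#'
#' @param fit a `qsip_fit`.
#' @param alpha significance level for within-category contrasts.
#' @return list of class `occurrence_partition`: `membership` (data.frame
#'   `taxon`, `category`), `categories` (data.frame `category`,
#'   `n_treatments`, `n_taxa`, one `mean_<treatment>` column per member
#'   treatment, `test`, `p`), `treatments`.
#' @export
occurrence_partition <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "qsip_fit"))
  ge <- fit$eaf[fit$eaf$growing, ]
  treatments <- unique(fit$eaf$treatment)
  if (length(treatments) < 2L) stop("need >= 2 treatments")
  grow <- lapply(treatments, function(tr) ge$taxon[ge$treatment == tr])
  names(grow) <- treatments
  all_taxa <- unique(unlist(grow))
  member <- vapply(treatments, function(tr) all_taxa %in% grow[[tr]],
                   logical(length(all_taxa)))
  if (length(all_taxa) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, treatments))
  category <- apply(member, 1L, function(m)
    paste(treatments[m], collapse = "+"))
  membership <- data.frame(taxon = all_taxa, category = category,
                           stringsAsFactors = FALSE)
  cats <- unique(category)
  rows <- lapply(cats, function(cc) {
    trs <- strsplit(cc, "+", fixed = TRUE)[[1L]]
    taxa <- all_taxa[category == cc]
    mns <- vapply(trs, function(tr)
      mean(ge$mean_eaf[ge$treatment == tr & ge$taxon %in% taxa]), 1)
    row <- data.frame(category = cc, n_treatments = length(trs),
                      n_taxa = length(taxa), stringsAsFactors = FALSE)
    for (tr in treatments)
      row[[paste0("mean_", tr)]] <-
        if (tr %in% trs) mns[[tr]] else NA_real_
    if (length(trs) >= 2L && length(taxa) >= 2L) {
      vals <- lapply(trs, function(tr)
        ge$mean_eaf[ge$treatment == tr & ge$taxon %in% taxa])
      if (length(trs) == 2L) {
        tt <- tryCatch(stats::t.test(vals[[1L]], vals[[2L]]),
                       error = function(e) NULL)
        row$test <- "t"
        row$p <- if (is.null(tt)) NA_real_ else tt$p.value
      } else {
        names(vals) <- trs
        ct <- assemblage_mean_contrast(vals, alpha = alpha)
        row$test <- "anova_tukey"
        row$p <- ct$anova$p
      }
    } else {
      row$test <- NA_character_
      row$p <- NA_real_
    }
    row
  })
  structure(list(membership = membership,
                 categories = do.call(rbind, rows),
                 treatments = treatments),
            class = "occurrence_partition")
}

#' @export
print.occurrence_partition <- function(x, ...) {
  cat("Occurrence partition of", nrow(x$membership), "growing taxa over",
      length(x$treatments), "treatments\n")
  print(x$categories, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Aggregate EAF and delta-EAF at a taxonomic rank
#'
#' Group-level means for each warming treatment versus the control. A group
#' (e.g. an order) is reported only when it has at least `min_taxa` growing
#' representatives in both the warming treatment and the control; its
#' delta-EAF is the mean taxon-level difference over the representatives
#' growing in both.
#'
#' @param fit a `qsip_fit`.
#' @param taxonomy taxonomy data.frame with a `taxon` column and rank
#'   columns (as produced by [assign_taxonomy] or [read_sip_dataset]).
#' @param rank rank column name (phylum..genus).
#' @param min_taxa minimum representatives per group in both treatments
#'   (default 3).
#' @param control reference treatment label.
#' @return data.frame: `group`, `treatment`, `n_treatment`, `n_control`,
#'   `n_shared`, `mean_eaf_treatment`, `mean_eaf_control`, `delta_eaf`.
#'   Groups failing the rule are omitted; their names are in
#'   `attr(, "omitted")`.
#' @export
aggregate_by_rank <- function(fit, taxonomy, rank, min_taxa = 3L,
                              control = "control") {
  stopifnot(inherits(fit, "qsip_fit"))
  if (!rank %in% names(taxonomy))
    stop("unknown rank: ", rank)
  ge <- fit$eaf[fit$eaf$growing, ]
  ge$group <- taxonomy[[rank]][match(ge$taxon, taxonomy$taxon)]
  ge <- ge[!is.na(ge$group), ]
  treatments <- setdiff(unique(ge$treatment), control)
  omitted <- character()
  rows <- list()
  for (tr in treatments) {
    gt <- ge[ge$treatment == tr, ]
    gctl <- ge[ge$treatment == control, ]
    for (grp in unique(ge$group)) {
      tt <- gt[gt$group == grp, ]
      ct <- gctl[gctl$group == grp, ]
      if (nrow(tt) < min_taxa || nrow(ct) < min_taxa) {
        omitted <- c(omitted, paste0(tr, ":", grp))
        next
      }
      shared <- intersect(tt$taxon, ct$taxon)
      d_eaf <- if (length(shared))
        mean(tt$mean_eaf[match(shared, tt$taxon)] -
             ct$mean_eaf[match(shared, ct$taxon)]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, treatment = tr,
        n_treatment = nrow(tt), n_control = nrow(ct),
        n_shared = length(shared),
        mean_eaf_treatment = mean(tt$mean_eaf),
        mean_eaf_control = mean(ct$mean_eaf),
        delta_eaf = d_eaf, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), treatment = character(),
               n_treatment = integer(), n_control = integer(),
               n_shared = integer(), mean_eaf_treatment = numeric(),
               mean_eaf_control = numeric(), delta_eaf = numeric())
  attr(out, "omitted") <- omitted
  out
}
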