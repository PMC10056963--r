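#' Per-fraction taxon 16S copies
#'
#' Scales a taxon's per-fraction relative abundances by the per-fraction
#' total 16S copy numbers (qPCR), the quantity whose density-weighted mean
#' defines the taxon's WAD.
#'
#' @param p per-fraction relative abundances in \eqn{[0,1]}.
#' @param totals per-fraction total 16S copies (>= 0).
#' @return per-fraction taxon copy numbers `p * totals`.
#' @export
taxon_copies <- function(p, totals) {
  if (length(p) != length(totals)) stop("p and totals differ in length")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  if (any(totals < 0, na.rm = TRUE)) stop("totals must be >= 0")
  p * totals
}

#' Weighted average density of a taxon across gradient fractions
#'
#' \eqn{W = \sum_i x_i y_i / \sum_i y_i}: the taxon-copy-weighted mean
#' buoyant density. Scale-invariant in `y`; returns `NA` when the taxon is
#' absent from every fraction (total copies zero), which downstream stages
#' treat as "WAD undefined", not as an error.
#'
#' @param x per-fraction buoyant densities (g mL^-1).
#' @param y per-fraction taxon copies (>= 0).
#' @return the WAD (g mL^-1), or `NA_real_` if `sum(y) == 0`.
#' @export
weighted_average_density <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (any(y < 0, na.rm = TRUE)) stop("y must be >= 0")
  s <- sum(y)
  if (!is.finite(s) || s <= 0) return(NA_real_)
  sum(x * y) / s
}

#' Consecutive-fraction occurrence filter
#'
#' A taxon qualifies for EAF estimation in a tube only if it occurs
#' (nonzero copies) in at least `min_run` consecutive density fractions —
#' scattered single-fraction detections are treated as noise.
#'
#' @param y per-fraction taxon copies, ordered by fraction index.
#' @param min_run minimum run length (default 3).
#' @return `TRUE` iff some run of `min_run` consecutive fractions all have
#'   `y > 0`.
#' @export
consecutive_fraction_filter <- function(y, min_run = 3L) {
  stopifnot(min_run >= 1L)
  r <- rle(y > 0)
  any(r$values & r$lengths >= min_run)
}

# WAD of every taxon in every tube + filter flags.
# Returns list(w = taxa x tubes matrix, pass = logical matrix, tubes = df).
tube_wads <- function(experiment, min_consecutive = 3L) {
  smp <- experiment$samples
  tubes <- unique(smp[, c("tube_id", "treatment", "block", "isotope")])
  taxa <- rownames(experiment$rel_abund)
  w <- matrix(NA_real_, length(taxa), nrow(tubes),
              dimnames = list(taxa, tubes$tube_id))
  pass <- matrix(FALSE, length(taxa), nrow(tubes),
                 dimnames = list(taxa, tubes$tube_id))
  for (j in seq_len(nrow(tubes))) {
    sel <- smp$tube_id == tubes$tube_id[j]
    ord <- order(smp$fraction[sel])
    sid <- smp$sample_id[sel][ord]
    x <- smp$density_g_ml[sel][ord]
    tot <- smp$total_16s_copies[sel][ord]
    if (any(diff(x) <= 0)) stop("densities not strictly increasing in tube ",
                                tubes$tube_id[j])
    y <- sweep(experiment$rel_abund[, sid, drop = FALSE], 2L, tot, "*")
    pass[, j] <- apply(y, 1L, consecutive_fraction_filter,
                       min_run = min_consecutive)
    ys <- rowSums(y)
    ok <- pass[, j] & ys > 0
    w[ok, j] <- (y[ok, , drop = FALSE] %*% x) / ys[ok]
  }
  list(w = w, pass = pass, tubes = tubes)
}

#' Fit per-taxon excess atom fraction estimates to a SIP experiment
#'
#' The central estimator. For every taxon and tube it computes the weighted
#' average density ([weighted_average_density]) from relative abundances
#' and qPCR totals, applies the consecutive-fraction occurrence filter, and
#' then, per treatment and block, converts the WAD shift between the paired
#' 18O and 16O tubes into a raw per-block EAF ([eaf_from_wad_shift]).
#' Per-taxon treatment estimates are the mean over qualifying blocks, with
#' a percentile block-bootstrap confidence interval; negative treatment
#' means are truncated to zero (and flagged) so EAF is interpretable as
#' relative growth.
#'
#' When a taxon fails the occurrence filter in the paired 16O tube, the
#' unlabeled reference density falls back to the taxon's mean WAD across
#' all qualifying 16O tubes of the same treatment (flagged in the output);
#' a block with no usable unlabeled reference or a failing 18O tube does
#' not contribute.
#'
#' @param experiment a `sip_experiment` (from [simulate_experiment] or
#'   [read_sip_dataset]).
#' @param min_consecutive occurrence-filter run length (default 3).
#' @param n_boot bootstrap resamples of blocks (default 1000).
#' @param ci_level two-sided confidence level (default 0.90).
#' @param average `"eaf"` (default) averages per-block EAFs;
#'   `"wad"` averages per-block density shifts first and converts once.
#' @param seed integer seed for the bootstrap.
#' @return object of class `qsip_fit` with components
#'   \describe{
#'     \item{eaf}{data.frame: `taxon`, `treatment`, `mean_eaf`
#'       (post-truncation), `raw_mean`, `ci_lo`, `ci_hi` (pre-truncation
#'       bootstrap percentile bounds), `n_blocks`, `truncated`, `growing`,
#'       `gc`, `ref_fallback`.}
#'     \item{block_eaf}{taxa x blocks x treatments array of raw per-block
#'       EAFs (`NA` where the block did not qualify).}
#'     \item{wad, pass}{taxa x tubes WAD and filter matrices.}
#'     \item{settings}{call settings incl. the constants version.}
#'   }
#' @export
qsip <- function(experiment, min_consecutive = 3L, n_boot = 1000L,
                 ci_level = 0.90, average = c("eaf", "wad"), seed = 1L) {
  stopifnot(inherits(experiment, "sip_experiment"))
  average <- match.arg(average)
  tw <- tube_wads(experiment, min_consecutive)
  tubes <- tw$tubes
  taxa <- rownames(tw$w)
  treatments <- unique(tubes$treatment)
  blocks <- sort(unique(tubes$block))
  block_eaf <- array(NA_real_,
                     dim = c(length(taxa), length(blocks), length(treatments)),
                     dimnames = list(taxa, paste0("b", blocks), treatments))
  block_dw <- block_eaf   # per-block density shifts, for average = "wad"
  block_wl <- block_eaf   # per-block unlabeled reference WADs
  ref_fallback <- matrix(FALSE, length(taxa), length(treatments),
                         dimnames = list(taxa, treatments))
  for (tr in treatments) {
    light_ids <- tubes$tube_id[tubes$treatment == tr & tubes$isotope == "16O"]
    light_w <- tw$w[, light_ids, drop = FALSE]
    light_mean <- rowMeans(light_w, na.rm = TRUE)  # NaN if none pass
    for (b in blocks) {
      lid <- tubes$tube_id[tubes$treatment == tr & tubes$block == b &
                           tubes$isotope == "16O"]
      hid <- tubes$tube_id[tubes$treatment == tr & tubes$block == b &
                           tubes$isotope == "18O"]
      if (length(lid) != 1L || length(hid) != 1L)
        stop("treatment ", tr, " block ", b,
             " must have exactly one 16O and one 18O tube")
      w_lab <- tw$w[, hid]
      w_ref <- tw$w[, lid]
      fb <- is.na(w_ref) & !is.na(w_lab) & is.finite(light_mean)
      w_ref[fb] <- light_mean[fb]
      ref_fallback[fb, tr] <- TRUE
      ok <- !is.na(w_lab) & !is.na(w_ref)
      bi <- match(b, blocks)
      block_wl[ok, bi, tr] <- w_ref[ok]
      block_dw[ok, bi, tr] <- w_lab[ok] - w_ref[ok]
      block_eaf[ok, bi, tr] <- eaf_from_wad_shift(w_lab[ok], w_ref[ok])
    }
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- matrix(sample.int(length(blocks), length(blocks) * n_boot,
                           replace = TRUE), nrow = length(blocks))
  rows <- vector("list", length(treatments))
  for (ti in seq_along(treatments)) {
    tr <- treatments[ti]
    be <- block_eaf[, , ti, drop = FALSE][, , 1L, drop = FALSE]
    dim(be) <- dim(block_eaf)[1:2]
    nb <- rowSums(!is.na(be))
    keep <- nb >= 1L
    est <- if (average == "eaf") {
      rowMeans(be, na.rm = TRUE)
    } else {
      wl <- block_wl[, , ti]; dim(wl) <- dim(be)
      dw <- block_dw[, , ti]; dim(dw) <- dim(be)
      wlm <- rowMeans(wl, na.rm = TRUE)
      eaf_from_wad_shift(wlm + rowMeans(dw, na.rm = TRUE), wlm)
    }
    ci <- matrix(NA_real_, length(taxa), 2L)
    if (any(keep)) {
      boot <- boot_block_means(be[keep, , drop = FALSE], idx)
      ci[keep, ] <- t(apply(boot, 1L, stats::quantile,
                            probs = c((1 - ci_level) / 2,
                                      1 - (1 - ci_level) / 2),
                            na.rm = TRUE, names = FALSE))
    }
    gc_est <- suppressWarnings(
      gc_from_density(rowMeans(block_wl[, , ti, drop = FALSE][, , 1L],
                               na.rm = TRUE)))
    rows[[ti]] <- data.frame(
      taxon = taxa, treatment = tr,
      mean_eaf = pmax(est, 0), raw_mean = est,
      ci_lo = ci[, 1L], ci_hi = ci[, 2L],
      n_blocks = nb, truncated = est < 0, growing = est > 0,
      gc = as.numeric(gc_est), ref_fallback = ref_fallback[, tr],
      stringsAsFactors = FALSE)[keep, ]
  }
  eaf <- do.call(rbind, rows)
  rownames(eaf) <- NULL
  structure(list(eaf = eaf, block_eaf = block_eaf, wad = tw$w,
                 pass = tw$pass, tubes = tubes,
                 settings = list(min_consecutive = min_consecutive,
                                 n_boot = n_boot, ci_level = ci_level,
                                 average = average, seed = seed,
                                 constants = qsip_constants()$version)),
            class = "qsip_fit")
}

# bootstrap means over resampled block columns; be = taxa x blocks matrix
# (NA = block not qualifying), idx = blocks x n_boot resample indices.
# Mean over available resampled blocks, NA if none available.
boot_block_means <- function(be, idx) {
  n_boot <- ncol(idx)
  out <- matrix(NA_real_, nrow(be), n_boot)
  obs <- !is.na(be)
  be0 <- ifelse(obs, be, 0)
  for (r in seq_len(n_boot)) {
    cols <- idx[, r]
    num <- rowSums(be0[, cols, drop = FALSE])
    den <- rowSums(obs[, cols, drop = FALSE])
    out[, r] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

#' @export
print.qsip_fit <- function(x, ...) {
  cat("qSIP excess atom fraction fit\n")
  cat("  taxa x tubes:", nrow(x$wad), "x", ncol(x$wad),
      " | occurrence filter: >=", x$settings$min_consecutive,
      "consecutive fractions\n")
  tab <- table(x$eaf$treatment[x$eaf$growing])
  cat("  growing taxa per treatment:\n")
  for (tr in unique(x$eaf$treatment))
    cat(sprintf("    %-10s %4d growing, mean EAF %.3f\n", tr,
                if (tr %in% names(tab)) tab[[tr]] else 0L,
                mean(x$eaf$mean_eaf[x$eaf$treatment == tr])))
  invisible(x)
}

#' @export
summary.qsip_fit <- function(object, ...) {
  sp <- split(object$eaf, object$eaf$treatment)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    treatment = d$treatment[1L],
    n_taxa = nrow(d),
    n_growing = sum(d$growing),
    n_truncated = sum(d$truncated),
    mean_eaf = mean(d$mean_eaf),
    se_eaf = stats::sd(d$mean_eaf) / sqrt(nrow(d)))))
  rownames(out) <- NULL
  class(out) <- c("summary.qsip_fit", "data.frame")
  out
}

#' Extract taxon EAF estimates from a fit
#'
#' @param object a `qsip_fit`.
#' @param ... unused.
#' @return taxa x treatments matrix of post-truncation mean EAFs (`NA`
#'   where a taxon had no qualifying block).
#' @export
coef.qsip_fit <- function(object, ...) {
  treatments <- unique(object$eaf$treatment)
  taxa <- rownames(object$wad)
  m <- matrix(NA_real_, length(taxa), length(treatments),
              dimnames = list(taxa, treatments))
  m[cbind(match(object$eaf$taxon, taxa),
          match(object$eaf$treatment, treatments))] <- object$eaf$mean_eaf
  m
}

#' Boxplot of taxon EAF estimates by treatment
#'
#' @param x a `qsip_fit`.
#' @param ... passed to [graphics::boxplot].
#' @export
plot.qsip_fit <- function(x, ...) {
  graphics::boxplot(mean_eaf ~ treatment, data = x$eaf,
                    ylab = expression("EAF " ^ 18 * O),
                    xlab = "treatment", ...)
  invisible(x)
}
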