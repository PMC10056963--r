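#' Phylogenetic covariance matrix from a tree
#'
#' Builds the Brownian-motion tip covariance matrix of a tree, optionally
#' restricted to a tip subset: \eqn{C_{ij}} is the root-to-MRCA depth of
#' tips \eqn{i, j} and \eqn{C_{ii}} the root-to-tip depth. Zero-length
#' terminal branches (common in insertion trees) are perturbed to
#' \eqn{10^{-8}} of tree height with a warning so the matrix stays
#' positive-definite; duplicate tips at zero distance raise an error
#' naming them.
#'
#' @param phy an [ape::phylo] tree with nonnegative branch lengths.
#' @param tips optional character vector of tip labels to keep.
#' @return symmetric positive-definite covariance matrix with tip-label
#'   dimnames.
#' @export
tree_to_covariance <- function(phy, tips = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (!is.null(tips)) {
    missing <- setdiff(tips, phy$tip.label)
    if (length(missing))
      stop("unknown tips: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  n <- length(phy$tip.label)
  height <- max(ape::node.depth.edgelength(phy))
  term <- phy$edge[, 2L] <= n
  zero_term <- term & phy$edge.length == 0
  if (any(zero_term)) {
    warning(sum(zero_term), " zero-length terminal branch(es) perturbed ",
            "to 1e-8 x tree height")
    phy$edge.length[zero_term] <- 1e-8 * height
  }
  depth <- ape::node.depth.edgelength(phy)
  mrca <- ape::mrca(phy)
  C <- matrix(depth[mrca], n, n,
              dimnames = list(phy$tip.label, phy$tip.label))
  diag(C) <- depth[seq_len(n)]
  # a tip subset keeps the full tree's root as depth origin: pure index
  # selection, so shared root-to-MRCA path lengths are unchanged
  if (!is.null(tips)) C <- C[tips, tips]
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    d <- as.matrix(stats::dist(C))  # identical rows = coincident tips
    dup <- which(d < 1e-12 & upper.tri(d), arr.ind = TRUE)
    stop("covariance not positive-definite; coincident tips: ",
         paste(unique(phy$tip.label[c(dup)]), collapse = ", "))
  }
  C
}

# GLS pieces under covariance C via one Cholesky factorization; falls back
# to an eigendecomposition with clipped eigenvalues when C is numerically
# near-singular (trees with divergences very close to the present).
# Returns list(a = GLS mean, q = (x-a)' C^-1 (x-a), logdet, s11, U).
gls_pieces <- function(x, C) {
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U)) {
    eg <- eigen(C, symmetric = TRUE)
    ev <- pmax(eg$values, 1e-10 * max(eg$values))
    M <- eg$vectors %*% (ev * t(eg$vectors))
    U <- chol((M + t(M)) / 2)
  }
  z1 <- forwardsolve(t(U), rep(1, length(x)))
  zx <- forwardsolve(t(U), x)
  s11 <- sum(z1 * z1)
  a <- sum(z1 * zx) / s11
  r <- zx - a * z1
  list(a = a, q = sum(r * r), logdet = 2 * sum(log(diag(U))), s11 = s11,
       U = U)
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' \deqn{K = \frac{(x-\hat a 1)'(x-\hat a 1)}{(x-\hat a 1)' C^{-1}
#' (x-\hat a 1)} \bigg/ \frac{\mathrm{tr}(C) - n / (1'C^{-1}1)}{n-1}}
#' with the GLS root estimate \eqn{\hat a = (1'C^{-1}x)/(1'C^{-1}1)}.
#' K equals 1 in expectation when the trait evolved by Brownian motion on
#' the tree, is below 1 when relatives resemble each other less than BM
#' predicts, and above 1 when they resemble each other more. Computed with
#' Cholesky solves; the explicit inverse is never formed.
#'
#' @param x named trait vector (names = tip labels) or unnamed vector
#'   aligned with `rownames(C)`.
#' @param C phylogenetic covariance from [tree_to_covariance].
#' @return the K statistic (> 0). Invariant to shifting and positive
#'   scaling of `x`.
#' @export
blomberg_k <- function(x, C) {
  x <- align_trait(x, C)
  n <- length(x)
  if (n < 4L) stop("need >= 4 tips")
  if (stats::var(x) == 0) stop("trait is constant; signal undefined")
  g <- gls_pieces(x, C)
  observed <- sum((x - g$a)^2) / g$q
  expected <- (sum(diag(C)) - n / g$s11) / (n - 1)
  observed / expected
}

#' Permutation test for Blomberg's K
#'
#' Randomizes trait values across tips `n_perm` times;
#' \eqn{p = (1 + \#\{K_{perm} \ge K_{obs}\}) / (1 + n_{perm})}.
#'
#' @param x named trait vector.
#' @param C phylogenetic covariance matrix.
#' @param n_perm number of permutations (default 999, must be >= 1).
#' @param seed integer seed (the test is deterministic given it).
#' @return list of class `signal_test`: `statistic = "K"`, `estimate`,
#'   `p_value`, `n_tips`, `n_perm`.
#' @export
blomberg_k_test <- function(x, C, n_perm = 999L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  x <- align_trait(x, C)
  n <- length(x)
  if (n < 4L) stop("need >= 4 tips")
  if (stats::var(x) == 0) stop("trait is constant; signal undefined")
  g <- gls_pieces(x, C)
  expected <- (sum(diag(C)) - n / g$s11) / (n - 1)
  k_of <- function(m) {
    # columns of m are trait vectors; vectorized K via triangular solves
    zi <- forwardsolve(t(g$U), m)
    z1 <- forwardsolve(t(g$U), rep(1, n))
    a <- colSums(z1 * zi) / g$s11
    num <- colSums(sweep(m, 2L, a)^2)
    den <- colSums((zi - outer(z1, a))^2)
    num / den / expected
  }
  k_obs <- k_of(matrix(x, ncol = 1L))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perms <- replicate(n_perm, sample(x))
  k_perm <- k_of(perms)
  structure(list(statistic = "K", estimate = as.numeric(k_obs),
                 p_value = (1 + sum(k_perm >= k_obs)) / (1 + n_perm),
                 n_tips = n, n_perm = n_perm, seed = seed),
            class = "signal_test")
}

# profile log-likelihood of the lambda model at a given lambda
lambda_loglik <- function(lambda, x, C) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  g <- gls_pieces(x, Cl)
  s2 <- g$q / length(x)
  -0.5 * (length(x) * log(2 * pi * s2) + g$logdet + length(x))
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Pagel's \eqn{\lambda} rescales the off-diagonal phylogenetic covariance,
#' \eqn{C(\lambda)_{ij} = \lambda C_{ij}} for \eqn{i \ne j}, and is
#' estimated by maximizing the multivariate-normal likelihood with the
#' root state and rate profiled out analytically
#' (\eqn{\hat\sigma^2(\lambda) = (x - \hat a 1)' C(\lambda)^{-1}
#' (x - \hat a 1) / n}). \eqn{\lambda = 0} means no signal (independent
#' tips), \eqn{\lambda = 1} full Brownian motion. The search interval is
#' \eqn{[0, \lambda_{max}]} (default cap 1); the boundary values are
#' always evaluated explicitly so boundary optima are exact.
#'
#' On a star phylogeny (all off-diagonal covariances zero) \eqn{\lambda}
#' does not enter the likelihood; this is detected and reported as an
#' error rather than returning an arbitrary estimate.
#'
#' @param x named trait vector.
#' @param C phylogenetic covariance matrix.
#' @param lambda_max upper search bound (default 1). Values above 1 are
#'   permitted only while \eqn{C(\lambda)} stays positive-definite; the
#'   bound is shrunk with a message if necessary.
#' @return list of class `pagel_lambda`: `lambda`, `loglik` (at the
#'   optimum), `loglik0` (at \eqn{\lambda = 0}), `sigma2`, `n_tips`.
#' @export
pagel_lambda <- function(x, C, lambda_max = 1) {
  x <- align_trait(x, C)
  n <- length(x)
  if (n < 4L) stop("need >= 4 tips")
  if (stats::var(x) == 0) stop("trait is constant; signal undefined")
  off <- C[upper.tri(C)]
  if (all(abs(off) < 1e-12 * max(diag(C))))
    stop("star phylogeny: lambda is unidentifiable")
  # C(lambda) = lambda C + (1-lambda) diag(C) is positive-definite on
  # [0, 1]; above 1 the bound is found by bisection and the search capped
  pd_ok <- function(l) {
    Cl <- C * l; diag(Cl) <- diag(C)
    inherits(tryCatch(chol(Cl), error = function(e) e), "matrix")
  }
  if (lambda_max > 1 && !pd_ok(lambda_max)) {
    lo <- 1; hi <- lambda_max
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (pd_ok(mid)) lo <- mid else hi <- mid
    }
    lambda_max <- lo
    message("lambda upper bound reduced to ", signif(lambda_max, 6),
            " to keep C(lambda) positive-definite")
  }
  f <- function(l) lambda_loglik(l, x, C)
  opt <- stats::optimize(f, c(0, lambda_max), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, f(0)), c(lambda_max, f(lambda_max)))
  if (lambda_max > 1) cand <- rbind(cand, c(1, f(1)))
  best <- cand[which.max(cand[, 2L]), ]
  Cl <- C * best[1L]; diag(Cl) <- diag(C)
  g <- gls_pieces(x, Cl)
  structure(list(lambda = best[1L], loglik = best[2L], loglik0 = cand[2L, 2L],
                 sigma2 = g$q / n, n_tips = n),
            class = "pagel_lambda")
}

#' Likelihood-ratio test of Pagel's lambda against zero
#'
#' \eqn{LR = 2(\log L(\hat\lambda) - \log L(0))}, compared to a chi-square
#' with one degree of freedom. Because \eqn{\lambda = 0} sits on the
#' boundary of the parameter space this p-value is conservative.
#'
#' @param loglik_hat log-likelihood at the ML estimate.
#' @param loglik_0 log-likelihood at \eqn{\lambda = 0}.
#' @return list of class `signal_test`: `statistic = "lambda_LR"`, `LR`,
#'   `p_value`, `df = 1`.
#' @export
lambda_lr_test <- function(loglik_hat, loglik_0) {
  lr <- 2 * (loglik_hat - loglik_0)
  if (lr < -1e-8)
    stop("logLik at the ML estimate is below logLik(0): internal inconsistency")
  lr <- max(lr, 0)
  structure(list(statistic = "lambda_LR", LR = lr,
                 p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                 df = 1L),
            class = "signal_test")
}

#' Phylogenetic signal of a tip trait (K and lambda)
#'
#' Convenience wrapper: prunes the tree to trait-bearing tips, builds the
#' covariance, and runs Blomberg's K with its permutation test and Pagel's
#' lambda with its likelihood-ratio test.
#'
#' @param phy an [ape::phylo] tree.
#' @param x named trait vector over a subset of the tips; tips without a
#'   trait value (or with `NA`) are pruned before analysis.
#' @param n_perm permutations for the K test.
#' @param lambda_max upper bound of the lambda search.
#' @param seed integer seed.
#' @return data.frame of class `phylo_signal`: one row per statistic with
#'   `statistic`, `estimate`, `p_value`, `n_tips`.
#' @export
phylo_signal <- function(phy, x, n_perm = 999L, lambda_max = 1, seed = 1L) {
  x <- x[!is.na(x)]
  if (is.null(names(x))) stop("x must be named by tip label")
  C <- tree_to_covariance(phy, names(x))
  kt <- blomberg_k_test(x, C, n_perm = n_perm, seed = seed)
  pl <- pagel_lambda(x, C, lambda_max = lambda_max)
  lt <- lambda_lr_test(pl$loglik, pl$loglik0)
  out <- data.frame(statistic = c("K", "lambda"),
                    estimate = c(kt$estimate, pl$lambda),
                    p_value = c(kt$p_value, lt$p_value),
                    n_tips = length(x))
  class(out) <- c("phylo_signal", "data.frame")
  out
}

#' @export
print.signal_test <- function(x, ...) {
  cat(sprintf("%s = %s, p = %.4g\n", x$statistic,
              signif(if (!is.null(x$estimate)) x$estimate else x$LR, 4),
              x$p_value))
  invisible(x)
}

#' @export
print.pagel_lambda <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.4f (logLik %.3f; logLik at 0 %.3f)\n",
              x$lambda, x$loglik, x$loglik0))
  invisible(x)
}

# match a trait vector to the covariance row order
align_trait <- function(x, C) {
  if (!is.null(names(x))) {
    if (!all(rownames(C) %in% names(x)))
      stop("trait missing for tips: ",
           paste(utils::head(setdiff(rownames(C), names(x)), 5L),
                 collapse = ", "))
    x <- x[rownames(C)]
  } else if (length(x) != nrow(C)) {
    stop("unnamed trait must have length nrow(C)")
  }
  if (anyNA(x)) stop("trait contains NA")
  as.numeric(x)
}
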