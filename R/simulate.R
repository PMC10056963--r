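#' Simulation configuration for a fractionated SIP experiment
#'
#' Bundles and validates the parameters of the forward simulator. Defaults
#' emulate a field \eqn{^{18}}O-water qSIP warming experiment: three
#' treatments (ambient control, short-term warming `STW`, long-term warming
#' `LTW`) in four blocks, each block assayed with paired natural-abundance
#' (16O) and enriched (18O) tubes — 24 tubes in all — and each tube
#' fractionated on a CsCl buoyant-density grid.
#'
#' @param n_taxa number of taxa (tree tips).
#' @param n_blocks experimental blocks (paired-tube replicates) per treatment.
#' @param treatments ordered treatment labels; the first is the reference.
#' @param n_fractions density fractions per tube (>= 4).
#' @param density_range gradient limits, g mL^-1.
#' @param profile_sd within-tube diffusion broadening of a taxon's density
#'   profile (Gaussian sd, g mL^-1).
#' @param sequencing_depth reads per fraction; `Inf` yields exact expected
#'   relative abundances (no multinomial noise).
#' @param qpcr_total total 16S copies per tube before fractionation.
#' @param qpcr_cv lognormal coefficient of variation of per-fraction qPCR
#'   totals; 0 disables qPCR noise.
#' @param bm_sigma2 Brownian-motion rate of the latent growth trait on the
#'   unit-height phylogeny (trait variance at the tips).
#' @param bm_root root value of the latent growth trait (control-mean EAF).
#' @param treatment_effect named additive shifts of the latent trait per
#'   treatment.
#' @param eaf_clamp range to which true EAF values are clamped; the upper
#'   default 0.6 reflects the cap imposed by ~66 atom% labeling water.
#' @param detection_floor relative abundance below which a taxon drops out
#'   of a fraction (models sparse-fraction dropout).
#' @param rank_depths six increasing tree-cut heights in (0,1) defining the
#'   simulated phylum..species clades (see [assign_taxonomy]).
#' @param seed integer seed from which all of the simulator's randomness is
#'   derived (see [split_seed]).
#' @return object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_taxa = 200L,
                       n_blocks = 4L,
                       treatments = c("control", "STW", "LTW"),
                       n_fractions = 18L,
                       density_range = c(1.640, 1.760),
                       profile_sd = 0.006,
                       sequencing_depth = 1e4,
                       qpcr_total = 1e8,
                       qpcr_cv = 0.15,
                       bm_sigma2 = 0.01,
                       bm_root = 0.07,
                       treatment_effect = c(control = 0, STW = 0.025, LTW = 0.106),
                       eaf_clamp = c(0, 0.6),
                       detection_floor = 0.002,
                       rank_depths = c(0.10, 0.25, 0.40, 0.55, 0.70, 0.85),
                       seed = 1L) {
  cfg <- list(n_taxa = as.integer(n_taxa), n_blocks = as.integer(n_blocks),
              treatments = as.character(treatments),
              n_fractions = as.integer(n_fractions),
              density_range = as.numeric(density_range),
              profile_sd = profile_sd, sequencing_depth = sequencing_depth,
              qpcr_total = qpcr_total, qpcr_cv = qpcr_cv,
              bm_sigma2 = bm_sigma2, bm_root = bm_root,
              treatment_effect = treatment_effect, eaf_clamp = eaf_clamp,
              detection_floor = detection_floor, rank_depths = rank_depths,
              seed = as.integer(seed))
  if (cfg$n_taxa < 3L) stop("n_taxa must be >= 3")
  if (cfg$n_fractions < 4L) stop("n_fractions must be >= 4")
  if (cfg$n_blocks < 1L) stop("n_blocks must be >= 1")
  if (length(cfg$density_range) != 2L ||
      cfg$density_range[1] >= cfg$density_range[2])
    stop("density_range must be (min, max) with min < max")
  if (cfg$profile_sd <= 0) stop("profile_sd must be > 0")
  if (cfg$sequencing_depth <= 0 || cfg$qpcr_total <= 0)
    stop("sequencing_depth and qpcr_total must be positive")
  if (cfg$qpcr_cv < 0) stop("qpcr_cv must be >= 0")
  if (is.null(names(cfg$treatment_effect)))
    names(cfg$treatment_effect) <- cfg$treatments
  if (!all(cfg$treatments %in% names(cfg$treatment_effect)))
    stop("treatment_effect must be named by treatment")
  if (length(cfg$rank_depths) != 6L || any(diff(cfg$rank_depths) <= 0) ||
      any(cfg$rank_depths <= 0 | cfg$rank_depths >= 1))
    stop("rank_depths must be 6 strictly increasing values in (0,1)")
  class(cfg) <- "sim_config"
  cfg
}

#' Derive child RNG seeds from a master seed
#'
#' All simulator randomness flows from one master seed through this
#' splitter, so that sub-simulations (tree, traits, each tube) are
#' independently reseeded yet fully reproducible.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Yule (pure-birth) tree rescaled to unit root-to-tip height; the taxon
#' unit is the tip (ASV analogue). Deterministic given `seed`.
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed integer seed.
#' @return an [ape::phylo] ultrametric tree with tip labels
#'   `taxon_001, ...` and root-to-tip height 1.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  phy <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / depth
  phy$tip.label <- sprintf("taxon_%03d", seq_len(n_taxa))
  phy
}

#' Simulate Brownian-motion trait values on a tree
#'
#' Draws independent Gaussian increments along each branch (variance
#' `sigma2` times branch length), accumulating from the root; the marginal
#' variance of tip \eqn{i} is `sigma2` times its root-to-tip depth and the
#' covariance of two tips is `sigma2` times their shared path length. This
#' traversal construction is deliberately independent of the analytic
#' phylogenetic covariance matrix used by the signal statistics, so the two
#' can be checked against each other.
#'
#' @param phy an [ape::phylo] tree.
#' @param sigma2 Brownian rate (> 0).
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @param nsim number of independent replicate trait vectors.
#' @return named numeric vector of tip values (`nsim = 1`) or a
#'   tips-by-`nsim` matrix.
#' @export
simulate_bm_trait <- function(phy, sigma2, root_value = 0, seed = 1L,
                              nsim = 1L) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  phy <- ape::reorder.phylo(phy, "cladewise")
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  val <- matrix(NA_real_, n_node, nsim)
  root <- n_tip + 1L
  val[root, ] <- root_value
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]; chl <- phy$edge[e, 2L]
    val[chl, ] <- val[par, ] +
      stats::rnorm(nsim, 0, sqrt(sigma2 * phy$edge.length[e]))
  }
  out <- val[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- phy$tip.label
  if (nsim == 1L) out[, 1L] else out
}

#' Assign a nested taxonomy by cutting an ultrametric tree
#'
#' Labels each tip by the clade it falls in when the tree is cut at each of
#' six increasing depths (phylum, class, order, family, genus, species),
#' with the domain fixed at `"Bacteria"` for a 7-rank SILVA-style lineage.
#' A tip's clade at cut depth `d` is the child end of the edge whose parent
#' lies above the cut (`parent depth < d <= child depth`); at `d = 0` all
#' tips share one clade (the root), at `d = 1` every tip is its own clade.
#' Because a deeper cut always refines a shallower one, the resulting ranks
#' are strictly nested by construction.
#'
#' @param phy ultrametric [ape::phylo] tree with unit height.
#' @param rank_depths six strictly increasing cut heights in (0, 1); the
#'   boundary values 0 and 1 are also accepted (whole-tree / per-tip cuts).
#' @return data.frame with columns `taxon`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`, `species`, `lineage` (semicolon-delimited).
#' @export
assign_taxonomy <- function(phy, rank_depths = c(0.10, 0.25, 0.40, 0.55,
                                                 0.70, 0.85)) {
  if (length(rank_depths) != 6L || any(diff(rank_depths) <= 0))
    stop("rank_depths must be 6 strictly increasing cut heights")
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  depth <- ape::node.depth.edgelength(phy)
  n_tip <- length(phy$tip.label)
  paths <- ape::nodepath(phy)  # root -> tip node sequences
  lab <- matrix(NA_character_, n_tip, length(ranks))
  pre <- c("P", "C", "O", "F", "G", "S")
  for (j in seq_along(rank_depths)) {
    d <- rank_depths[j]
    for (i in seq_len(n_tip)) {
      p <- paths[[i]]
      node <- p[which(depth[p] >= d - 1e-12)[1L]]
      lab[i, j] <- paste0(pre[j], node)
    }
  }
  tax <- data.frame(taxon = phy$tip.label, domain = "Bacteria", lab,
                    stringsAsFactors = FALSE)
  names(tax) <- c("taxon", "domain", ranks)
  tax$lineage <- apply(tax[, c("domain", ranks)], 1L, paste, collapse = ";")
  tax
}

#' Simulate the ground-truth community of a SIP experiment
#'
#' Draws the phylogeny, per-taxon GC content, nested taxonomy, relative
#' biomass weights, and per-treatment true EAF values. The growth trait
#' evolves by Brownian motion on the tree (so it carries phylogenetic
#' signal); each treatment adds its configured shift before clamping to the
#' attainable EAF range.
#'
#' @param config a [sim_config].
#' @return list of class `sip_truth`: `tree`, `gc`, `weights`, `taxonomy`,
#'   `eaf` (taxa x treatments matrix), `latent` (pre-clamp trait),
#'   `clamped` (logical matrix), `config`.
#' @export
simulate_community <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- split_seed(config$seed, 4L)
  tree <- simulate_tree(config$n_taxa, seeds[1L])
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seeds[2L])
  gc <- stats::rbeta(config$n_taxa, 20, 20)  # bacterial GC ~ 0.3-0.7
  names(gc) <- tree$tip.label
  set.seed(seeds[3L])
  w <- stats::rlnorm(config$n_taxa, 0, 1)
  weights <- w / sum(w)
  names(weights) <- tree$tip.label
  latent <- simulate_bm_trait(tree, config$bm_sigma2, config$bm_root,
                              seed = seeds[4L])
  eaf <- sapply(config$treatments, function(tr)
    latent + config$treatment_effect[[tr]])
  clamped <- eaf < config$eaf_clamp[1] | eaf > config$eaf_clamp[2]
  eaf <- pmin(pmax(eaf, config$eaf_clamp[1]), config$eaf_clamp[2])
  rownames(eaf) <- rownames(clamped) <- tree$tip.label
  structure(list(tree = tree, gc = gc, weights = weights,
                 taxonomy = assign_taxonomy(tree, config$rank_depths),
                 eaf = eaf, latent = latent, clamped = clamped,
                 config = config),
            class = "sip_truth")
}

# Discretize a Gaussian density profile onto the fraction grid.
# Returns taxa x fractions matrix of (unnormalized) mass.
profile_mass <- function(rho, weights, edges, sd) {
  n_frac <- length(edges) - 1L
  m <- vapply(seq_len(n_frac), function(i)
    weights * (stats::pnorm(edges[i + 1L], rho, sd) -
               stats::pnorm(edges[i], rho, sd)),
    numeric(length(rho)))
  dimnames(m) <- list(names(rho), NULL)
  m
}

#' Simulate one density-fractionated tube
#'
#' Places each taxon's DNA at its equilibrium buoyant density — the
#' GC-determined unlabeled density, shifted upward in \eqn{^{18}}O tubes
#' according to the taxon's true EAF via [wad_shift_from_eaf] — spreads it
#' over the density grid as a Gaussian with sd `profile_sd`, and generates
#' the two measured quantities per fraction: total 16S copies (the tube
#' total apportioned by mass share, with lognormal qPCR noise) and
#' multinomial sequencing counts at `sequencing_depth` (relative abundances
#' below `detection_floor` drop out before the draw).
#'
#' @param community a `sip_truth` from [simulate_community].
#' @param treatment,isotope,block tube metadata; `isotope` is `"16O"` or
#'   `"18O"`.
#' @param config the [sim_config] (defaults to the community's).
#' @param seed integer seed for this tube's noise.
#' @return list: `fractions` (data.frame `fraction`, `density_g_ml`,
#'   `total_16s_copies`), `rel_abund` (taxa x fractions matrix),
#'   `counts` (taxa x fractions integer matrix, `NULL` when
#'   `sequencing_depth = Inf`).
#' @export
simulate_tube <- function(community, treatment, isotope, block,
                          config = community$config, seed = 1L) {
  stopifnot(inherits(community, "sip_truth"),
            isotope %in% c("16O", "18O"),
            treatment %in% config$treatments)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rho <- density_from_gc(community$gc)
  if (isotope == "18O")
    rho <- wad_shift_from_eaf(community$eaf[, treatment], community$gc)
  rng <- config$density_range
  outside <- rho < rng[1] - 3 * config$profile_sd |
             rho > rng[2] + 3 * config$profile_sd
  if (any(outside))
    warning(sum(outside), " taxon densities fall outside the gradient by ",
            "more than 3 profile sd; their mass is truncated")
  edges <- seq(rng[1], rng[2], length.out = config$n_fractions + 1L)
  mass <- profile_mass(rho, community$weights, edges, config$profile_sd)
  frac_mass <- colSums(mass)
  share_of_tube <- frac_mass / sum(frac_mass)
  noise <- if (config$qpcr_cv > 0) {
    s <- sqrt(log(1 + config$qpcr_cv^2))
    stats::rlnorm(config$n_fractions, -s^2 / 2, s)
  } else rep(1, config$n_fractions)
  totals <- config$qpcr_total * share_of_tube * noise
  # within-fraction composition, with rare-taxon dropout
  p <- sweep(mass, 2L, pmax(frac_mass, .Machine$double.xmin), "/")
  p[p < config$detection_floor] <- 0
  csum <- colSums(p)
  ok <- csum > 0
  p[, ok] <- sweep(p[, ok, drop = FALSE], 2L, csum[ok], "/")
  if (is.finite(config$sequencing_depth)) {
    counts <- matrix(0L, nrow(p), ncol(p), dimnames = dimnames(p))
    for (i in which(ok))
      counts[, i] <- stats::rmultinom(1L, config$sequencing_depth, p[, i])
    rel <- counts / config$sequencing_depth
  } else {
    counts <- NULL
    rel <- p
  }
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  list(fractions = data.frame(fraction = seq_len(config$n_fractions),
                              density_g_ml = mids,
                              total_16s_copies = totals),
       rel_abund = rel, counts = counts)
}

#' Simulate a complete paired-isotope SIP experiment
#'
#' Generates the full tube layout — every treatment in every block, each
#' with a paired 16O and 18O tube (with defaults, 3 treatments x 4 blocks
#' x 2 isotopes = 24 tubes) — and assembles the fraction table and
#' taxon-by-sample relative abundance matrix the estimation pipeline
#' consumes, together with the retained ground truth.
#'
#' @param config a [sim_config].
#' @return object of class `sip_experiment`: `samples` (data.frame
#'   `sample_id`, `tube_id`, `treatment`, `block`, `isotope`, `fraction`,
#'   `density_g_ml`, `total_16s_copies`), `rel_abund` (taxa x samples),
#'   `counts` (taxa x samples or `NULL`), `taxonomy`, `tree`, `truth`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  community <- simulate_community(config)
  layout <- expand.grid(isotope = c("16O", "18O"),
                        block = seq_len(config$n_blocks),
                        treatment = config$treatments,
                        stringsAsFactors = FALSE)
  layout$tube_id <- sprintf("%s_b%d_%s", layout$treatment, layout$block,
                            layout$isotope)
  tube_seeds <- split_seed(config$seed + 1L, nrow(layout))
  samples <- vector("list", nrow(layout))
  rel <- vector("list", nrow(layout))
  cnt <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    tube <- simulate_tube(community, layout$treatment[i], layout$isotope[i],
                          layout$block[i], config, seed = tube_seeds[i])
    sid <- sprintf("%s_f%02d", layout$tube_id[i], tube$fractions$fraction)
    samples[[i]] <- data.frame(sample_id = sid,
                               tube_id = layout$tube_id[i],
                               treatment = layout$treatment[i],
                               block = layout$block[i],
                               isotope = layout$isotope[i],
                               tube$fractions,
                               stringsAsFactors = FALSE)
    colnames(tube$rel_abund) <- sid
    rel[[i]] <- tube$rel_abund
    if (!is.null(tube$counts)) {
      colnames(tube$counts) <- sid
      cnt[[i]] <- tube$counts
    }
  }
  structure(list(samples = do.call(rbind, samples),
                 rel_abund = do.call(cbind, rel),
                 counts = if (length(cnt)) do.call(cbind, cnt) else NULL,
                 taxonomy = community$taxonomy,
                 tree = community$tree,
                 truth = community),
            class = "sip_experiment")
}

#' @export
print.sip_experiment <- function(x, ...) {
  n_tube <- length(unique(x$samples$tube_id))
  cat("Simulated SIP experiment:", nrow(x$rel_abund), "taxa,",
      n_tube, "tubes,", nrow(x$samples), "fraction samples\n")
  cat("Treatments:", paste(unique(x$samples$treatment), collapse = ", "),
      " blocks:", length(unique(x$samples$block)), "\n")
  invisible(x)
}
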