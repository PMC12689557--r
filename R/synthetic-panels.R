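#' Generate a drug-target table with planted synergistic pairs
#'
#' Emulates a DGIdb-style drug-to-target-gene table. Each planted
#' synergistic pair jointly covers one planted module of the hierarchy: the
#' two drugs split the module's genes between them (so neither alone covers
#' it). All other drugs draw their targets from genes outside every planted
#' module, so no other pair covers a module. An optional `pair_filter`
#' function (taking the two drug ids, returning TRUE to keep) restricts the
#' candidate pair list downstream; no filtering rule is planted by default.
#'
#' @param n_drugs number of drugs (>= 2 * n_synergistic_pairs)
#' @param targets_per_drug targets per non-synergistic drug
#' @param hierarchy a \linkS4class{BioHierarchy} with planted modules
#' @param n_synergistic_pairs number of planted synergistic pairs (at most
#'   the number of planted modules)
#' @param seed integer seed
#' @return list with `targets` (data.frame drug, gene), `synergistic_pairs`
#'   (data.frame drugA, drugB, module) and `drugs` (character ids)
#' @examples
#' h <- genHierarchy(30, 12, 5, n_modules = 1, seed = 1)
#' panel <- genDrugPanel(n_drugs = 6, targets_per_drug = 3, hierarchy = h,
#'                       n_synergistic_pairs = 1, seed = 2)
#' panel$synergistic_pairs
#' @export
genDrugPanel <- function(n_drugs, targets_per_drug, hierarchy,
                         n_synergistic_pairs = 1, seed = 1) {
  stopifnot(n_drugs >= 1, targets_per_drug >= 1)
  genes <- rownames(hierarchy@geneAdj)
  if (targets_per_drug > length(genes))
    stop("targets_per_drug must not exceed the number of genes")
  mods <- plantedModules(hierarchy)
  if (n_synergistic_pairs > length(mods))
    stop("n_synergistic_pairs exceeds the number of planted modules")
  if (2 * n_synergistic_pairs > n_drugs)
    stop("need at least two drugs per planted synergistic pair")

  rng <- .localRNG(seed)
  on.exit(rng$restore(), add = TRUE)

  drugs <- sprintf("d%02d", seq_len(n_drugs))
  module_genes <- unique(unlist(mods))
  free_genes <- setdiff(genes, module_genes)
  if (!length(free_genes) && n_drugs > 2 * n_synergistic_pairs)
    stop("no non-module genes left for the non-synergistic drugs")

  tgt <- vector("list", n_drugs)
  pairs <- NULL
  for (k in seq_len(n_synergistic_pairs)) {
    mg <- mods[[k]]
    half <- ceiling(length(mg) / 2)
    a <- 2 * k - 1; b <- 2 * k
    tgt[[a]] <- mg[seq_len(half)]
    tgt[[b]] <- mg[(half + 1):length(mg)]
    pairs <- rbind(pairs, data.frame(drugA = drugs[a], drugB = drugs[b],
                                     module = names(mods)[k]))
  }
  used <- if (n_synergistic_pairs > 0) 2 * n_synergistic_pairs else 0
  for (i in seq_len(n_drugs)) {
    if (i <= used) next
    pool <- if (length(free_genes) >= targets_per_drug) free_genes else genes
    tgt[[i]] <- sort(sample(pool, targets_per_drug))
  }
  targets <- data.frame(
    drug = rep(drugs, lengths(tgt)),
    gene = unlist(tgt), row.names = NULL)
  list(targets = targets, synergistic_pairs = pairs, drugs = drugs)
}

#' Generate median-effect dose-response data with known combination index
#'
#' Single-drug fractions affected follow the median-effect model
#' `fa = (D/Dm)^m / (1 + (D/Dm)^m)` with optional Gaussian noise added on
#' the logit scale (which keeps fa inside (0,1); values are additionally
#' clipped to `(eps, 1 - eps)` with `eps = 1e-6`). Combination points are
#' built from the Loewe-additive isobole: for each requested effect level
#' `fa`, the additive dose pair `(w1 * DxA, w2 * DxB)` (weights from
#' `combo_design$ratio`, default 1:1) is scaled by the planted
#' `interaction` factor, so the true combination index at that point equals
#' `interaction` exactly by construction (CI 1 = additive, < 1 synergy).
#'
#' @param Dm1,m1,Dm2,m2 median-effect parameters of drugs A and B (positive)
#' @param doses single-drug dose grid (default the 6-point 0.25-8 uM design)
#' @param combo_design list: `fa_levels` (effect levels for combination
#'   points, default `seq(0.2, 0.8, by = 0.1)`), `ratio` (two weights,
#'   default `c(0.5, 0.5)`), `interaction` (planted true CI, default 1)
#' @param noise_sd logit-scale noise standard deviation (0 = exact)
#' @param seed integer seed
#' @return list with `single` (data.frame drug, dose, fa), `combo`
#'   (data.frame d1, d2, fa, true_ci), `true` (the planted parameters)
#' @examples
#' panel <- genDoseResponse(Dm1 = 2, m1 = 1, Dm2 = 4, m2 = 1.5,
#'                          combo_design = list(interaction = 0.5), seed = 1)
#' head(panel$combo)
#' @export
genDoseResponse <- function(Dm1, m1, Dm2, m2,
                            doses = c(8, 4, 2, 1, 0.5, 0.25),
                            combo_design = list(), noise_sd = 0, seed = 1) {
  stopifnot(Dm1 > 0, m1 > 0, Dm2 > 0, m2 > 0, noise_sd >= 0)
  if (any(doses <= 0) || anyDuplicated(doses))
    stop("doses must be positive and distinct")
  cfg <- modifyList(list(fa_levels = seq(0.2, 0.8, by = 0.1),
                         ratio = c(0.5, 0.5), interaction = 1), combo_design)
  rng <- .localRNG(seed)
  on.exit(rng$restore(), add = TRUE)
  eps <- 1e-6

  fa_of <- function(D, Dm, m) (D / Dm)^m / (1 + (D / Dm)^m)
  noisy <- function(fa) {
    if (noise_sd > 0) {
      l <- log(fa / (1 - fa)) + rnorm(length(fa), sd = noise_sd)
      fa <- 1 / (1 + exp(-l))
    }
    pmin(pmax(fa, eps), 1 - eps)
  }
  single <- rbind(
    data.frame(drug = "A", dose = doses, fa = noisy(fa_of(doses, Dm1, m1))),
    data.frame(drug = "B", dose = doses, fa = noisy(fa_of(doses, Dm2, m2))))

  dx <- function(fa, Dm, m) Dm * (fa / (1 - fa))^(1 / m)
  fl <- cfg$fa_levels
  combo <- data.frame(
    d1 = cfg$interaction * cfg$ratio[1] * dx(fl, Dm1, m1),
    d2 = cfg$interaction * cfg$ratio[2] * dx(fl, Dm2, m2),
    fa = noisy(fl),
    true_ci = cfg$interaction)
  list(single = single, combo = combo,
       true = list(Dm1 = Dm1, m1 = m1, Dm2 = Dm2, m2 = m2,
                   interaction = cfg$interaction, clip_eps = eps))
}

#' Generate a limiting-dilution plate with known stem-cell frequency
#'
#' Under the single-hit Poisson model the probability that a well seeded
#' with `dose` cells forms no sphere is `exp(-f * dose)`; positive-well
#' counts are Binomial(`wells`, `1 - exp(-f * dose)`) per dose.
#'
#' @param true_f sphere-initiating cell frequency in (0, 1)
#' @param doses cells per well (default the 200/100/50/25 design)
#' @param wells replicate wells per dose (default 10)
#' @param seed integer seed
#' @return data.frame (dose, wells, positive) with attribute `true_f`
#' @examples
#' genDilution(true_f = 1 / 170, seed = 1)
#' @export
genDilution <- function(true_f, doses = c(200, 100, 50, 25), wells = 10,
                        seed = 1) {
  if (true_f <= 0 || true_f >= 1) stop("true_f must be in (0, 1)")
  if (any(doses <= 0) || anyDuplicated(doses)) stop("doses must be positive and distinct")
  rng <- .localRNG(seed)
  on.exit(rng$restore(), add = TRUE)
  pos <- rbinom(length(doses), size = wells, prob = 1 - exp(-true_f * doses))
  out <- data.frame(dose = doses, wells = wells, positive = pos)
  attr(out, "true_f") <- true_f
  out
}

#' Generate metabolite intensity tables with planted pathway signal
#'
#' Intensities are log-normal per metabolite and group. For each planted
#' comparison (a pair of group names) a stated set of metabolites is shifted
#' by the stated log2 fold change in the *first* group of the pair. A
#' pathway library is built so that each planted pathway collects planted
#' metabolites (plus background pathways of unshifted metabolites), making
#' the planted pathways truly enriched among differential hits.
#'
#' @param groups group names (default `c("combo", "model", "drugA",
#'   "drugB")`); >= 2 required
#' @param n_metabolites metabolites measured
#' @param n_per_group samples per group (default 6)
#' @param planted list of plants, each a list with `comparison`
#'   (two group names), `metabolites` (ids or indices) and `lfc` (log2
#'   shift applied to the first group); default: none
#' @param library_spec list: `pathways` named list pathway -> metabolite ids
#'   (default: planted metabolites grouped into "planted_pw<k>" plus
#'   background pathways of size `bg_size` covering the rest),
#'   `bg_size` (default 10)
#' @param seed integer seed
#' @return list with `intensities` (metabolite x sample matrix), `groups`
#'   (named factor), `library` (named list pathway -> metabolites),
#'   `planted` (the plant specification with resolved metabolite ids)
#' @examples
#' mp <- genMetabolitePanel(planted = list(list(
#'   comparison = c("combo", "model"), metabolites = 1:5, lfc = 2)), seed = 1)
#' names(mp$library)
#' @export
genMetabolitePanel <- function(groups = c("combo", "model", "drugA", "drugB"),
                               n_metabolites = 60, n_per_group = 6,
                               planted = list(), library_spec = list(),
                               seed = 1) {
  if (length(groups) < 2) stop("need at least two groups")
  spec <- modifyList(list(pathways = NULL, bg_size = 10), library_spec)
  rng <- .localRNG(seed)
  on.exit(rng$restore(), add = TRUE)

  mets <- sprintf("m%03d", seq_len(n_metabolites))
  samples <- paste(rep(groups, each = n_per_group),
                   rep(seq_len(n_per_group), length(groups)), sep = "_")
  grp <- setNames(factor(rep(groups, each = n_per_group), levels = groups),
                  samples)
  mu <- rnorm(n_metabolites, mean = 10, sd = 1)
  logx <- matrix(rnorm(n_metabolites * length(samples), mean = mu, sd = 0.5),
                 nrow = n_metabolites, dimnames = list(mets, samples))

  resolved <- list()
  for (pl in planted) {
    ids <- pl$metabolites
    if (is.numeric(ids)) ids <- mets[ids]
    if (!all(ids %in% mets)) stop("planted metabolites must be measured")
    if (!all(pl$comparison %in% groups)) stop("unknown group in planted comparison")
    logx[ids, grp == pl$comparison[1]] <-
      logx[ids, grp == pl$comparison[1]] + pl$lfc
    resolved[[length(resolved) + 1]] <-
      list(comparison = pl$comparison, metabolites = ids, lfc = pl$lfc)
  }
  intens <- 2^logx

  lib <- spec$pathways
  if (is.null(lib)) {
    lib <- list()
    pk <- 0
    for (pl in resolved) {
      pk <- pk + 1
      lib[[sprintf("planted_pw%d", pk)]] <- pl$metabolites
    }
    rest <- setdiff(mets, unique(unlist(lib)))
    bg <- split(rest, ceiling(seq_along(rest) / spec$bg_size))
    names(bg) <- sprintf("background_pw%d", seq_along(bg))
    lib <- c(lib, bg)
  } else {
    if (!all(unlist(lib) %in% mets))
      stop("library references unmeasured metabolites")
    for (pl in resolved)
      if (!any(vapply(lib, function(s) all(pl$metabolites %in% s), logical(1))))
        stop("planted pathway absent from library")
  }
  list(intensities = intens, groups = grp, library = lib, planted = resolved)
}
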