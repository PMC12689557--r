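#' Generate a synthetic tumor/normal cohort with planted signal
#'
#' Emulates a TPM-scale expression study with recurrence-free survival:
#' expression is drawn log-normally per gene, a planted subset of genes gets a
#' group shift of \code{lfc} log2 units in tumors (the differential signal),
#' and tumor survival times follow an exponential proportional-hazards model
#' whose linear predictor is \code{sum(beta_g * z_g)} over the planted
#' prognostic genes, where \code{z_g} is the standardized log2 expression
#' among tumor samples. Censoring is independent exponential, calibrated so
#' the expected censored fraction is approximately \code{censoring}.
#'
#' Planted genes occupy the first gene ids: prognostic genes are
#' \code{g001..g<n_prognostic>} and differential genes start at the first
#' gene, so the default prognostic set coincides with the first planted
#' module of [genHierarchy()].
#'
#' @param n_tumor,n_normal sample counts per group
#' @param n_genes number of genes
#' @param n_deg number of planted differentially expressed genes
#' @param n_prognostic number of planted prognostic genes
#' @param effect_sizes list with elements \code{lfc} (planted log2 fold
#'   change, default 2; recycled over DEGs with alternating sign unless a
#'   vector is given), \code{beta} (planted Cox coefficient, default 1,
#'   recycled over prognostic genes) and \code{base_hazard} (events/month,
#'   default 0.05)
#' @param censoring target censoring fraction in `[0, 1)`
#' @param seed integer seed; the output is a pure function of the arguments
#' @return a \linkS4class{SyntheticCohort}
#' @examples
#' coh <- genCohort(n_tumor = 40, n_normal = 10, n_genes = 100,
#'                  n_deg = 10, n_prognostic = 5, seed = 1)
#' coh
#' @export
genCohort <- function(n_tumor, n_normal, n_genes,
                      n_deg = 0, n_prognostic = 0,
                      effect_sizes = list(), censoring = 0.2, seed = 1) {
  stopifnot(n_tumor >= 1, n_normal >= 0, n_genes >= 1)
  if (n_deg > n_genes) stop("n_deg must not exceed n_genes")
  if (n_prognostic > n_genes) stop("n_prognostic must not exceed n_genes")
  if (censoring < 0 || censoring >= 1) stop("censoring rate must be in [0, 1)")
  es <- modifyList(list(lfc = 2, beta = 1, base_hazard = 0.05), effect_sizes)
  if (!all(is.finite(unlist(es)))) stop("effect sizes must be finite")

  rng <- .localRNG(seed)
  on.exit(rng$restore(), add = TRUE)

  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- c(sprintf("t%03d", seq_len(n_tumor)),
               if (n_normal > 0) sprintf("n%03d", seq_len(n_normal)))
  group <- c(rep("tumor", n_tumor), rep("normal", n_normal))

  # baseline log2 expression: per-gene mean ~ N(6, 1.5), residual sd 1
  mu <- rnorm(n_genes, mean = 6, sd = 1.5)
  log2x <- matrix(rnorm(n_genes * length(samples), mean = mu, sd = 1),
                  nrow = n_genes, dimnames = list(genes, samples))

  true_lfc <- setNames(numeric(n_genes), genes)
  if (n_deg > 0) {
    lfc <- es$lfc
    if (length(lfc) == 1) lfc <- lfc * rep_len(c(1, -1), n_deg)
    lfc <- rep_len(lfc, n_deg)
    true_lfc[seq_len(n_deg)] <- lfc
    log2x[seq_len(n_deg), group == "tumor"] <-
      log2x[seq_len(n_deg), group == "tumor"] + lfc
  }
  expr <- 2^log2x

  true_beta <- setNames(numeric(n_genes), genes)
  if (n_prognostic > 0)
    true_beta[seq_len(n_prognostic)] <- rep_len(es$beta, n_prognostic)

  # survival for tumor samples: exponential PH on standardized log2 expression
  tum <- which(group == "tumor")
  lp <- rep(0, n_tumor)
  prog <- which(true_beta != 0)
  if (length(prog)) {
    z <- t(scale(t(log2x[prog, tum, drop = FALSE])))
    z[is.nan(z)] <- 0
    lp <- as.vector(crossprod(z, true_beta[prog]))
  }
  h <- es$base_hazard * exp(lp)
  t_event <- rexp(n_tumor, rate = h)
  time <- t_event
  event <- rep(1, n_tumor)
  if (censoring > 0) {
    # exponential censoring with rate theta; P(censored | h) = theta/(theta+h),
    # so solve mean(theta/(theta+h)) = censoring for theta (exact marginal
    # rate even when the hazard distribution is heavy-tailed)
    root <- uniroot(function(lt) mean(exp(lt) / (exp(lt) + h)) - censoring,
                    lower = log(min(h)) - 20, upper = log(max(h)) + 20)
    t_cens <- rexp(n_tumor, rate = exp(root$root))
    event <- as.numeric(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  }

  cd <- S4Vectors::DataFrame(
    group = group,
    time = c(time, rep(NA_real_, n_normal)),
    event = c(event, rep(NA_real_, n_normal)),
    row.names = samples
  )
  rd <- S4Vectors::DataFrame(true_lfc = true_lfc, true_beta = true_beta,
                             row.names = genes)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr), colData = cd, rowData = rd)
  methods::new("SyntheticCohort", se)
}

# run code under a private RNG state so generators are pure functions of seed
.localRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}

#' Write / read a cohort as plain TSV files
#'
#' `writeCohort` writes `expression.tsv` (genes x samples with a header row
#' of sample ids), `survival.tsv` (sample, time, event; tumor samples only)
#' and `groups.tsv` (sample, group) plus `truth.tsv` (gene, true_lfc,
#' true_beta) into `dir`. `readCohort` reads them back.
#'
#' @param cohort a \linkS4class{SyntheticCohort}
#' @param dir directory (created if missing)
#' @return `writeCohort` returns `dir` invisibly; `readCohort` a
#'   \linkS4class{SyntheticCohort}
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  e <- exprMatrix(cohort)
  write.table(data.frame(gene = rownames(e), e, check.names = FALSE),
              file.path(dir, "expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(survivalData(cohort), file.path(dir, "survival.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gl <- groupLabels(cohort)
  write.table(data.frame(sample = names(gl), group = as.character(gl)),
              file.path(dir, "groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = rownames(e),
                         true_lfc = trueLog2FC(cohort),
                         true_beta = trueBeta(cohort)),
              file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  ex <- read.delim(file.path(dir, "expression.tsv"), check.names = FALSE)
  expr <- as.matrix(ex[, -1, drop = FALSE])
  rownames(expr) <- ex$gene
  gr <- read.delim(file.path(dir, "groups.tsv"))
  su <- read.delim(file.path(dir, "survival.tsv"))
  tr <- if (file.exists(file.path(dir, "truth.tsv")))
    read.delim(file.path(dir, "truth.tsv"))
  else data.frame(gene = rownames(expr), true_lfc = 0, true_beta = 0)
  group <- setNames(gr$group, gr$sample)[colnames(expr)]
  time <- setNames(su$time, su$sample)[colnames(expr)]
  event <- setNames(su$event, su$sample)[colnames(expr)]
  cd <- S4Vectors::DataFrame(group = unname(group), time = unname(time),
                             event = unname(event), row.names = colnames(expr))
  tr <- tr[match(rownames(expr), tr$gene), ]
  rd <- S4Vectors::DataFrame(true_lfc = tr$true_lfc, true_beta = tr$true_beta,
                             row.names = rownames(expr))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr), colData = cd, rowData = rd)
  methods::new("SyntheticCohort", se)
}
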