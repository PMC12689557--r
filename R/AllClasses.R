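#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rnorm runif rexp rbinom pnorm qnorm qchisq pt var
#'   sd median quantile p.adjust phyper pchisq glm binomial coef vcov lm
#'   setNames uniroot
#' @importFrom utils head combn modifyList read.delim write.table
NULL

#' SyntheticCohort: expression + survival with planted ground truth
#'
#' A \linkS4class{SummarizedExperiment} subclass holding a gene-by-sample
#' expression matrix (assay \code{"expr"}, TPM-like non-negative values),
#' per-sample group labels (\code{tumor}/\code{normal}) and recurrence-free
#' survival (\code{time} in months, \code{event} 0/1; \code{NA} for normal
#' samples) in \code{colData}, and the planted truth in \code{rowData}:
#' \code{true_lfc} (planted log2 fold change, 0 for non-differential genes)
#' and \code{true_beta} (planted Cox coefficient, 0 for non-prognostic genes).
#'
#' @seealso [genCohort()], [exprMatrix()], [groupLabels()], [survivalData()]
#' @export
setClass("SyntheticCohort", contains = "SummarizedExperiment")

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'expr' is required")
  else if (any(SummarizedExperiment::assay(object, "expr") < 0))
    msg <- c(msg, "expression must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  need <- c("group", "time", "event")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, sprintf("colData must contain %s", paste(need, collapse = ", ")))
  else {
    if (!all(cd$group %in% c("tumor", "normal")))
      msg <- c(msg, "group labels must be 'tumor' or 'normal'")
    tum <- cd$group == "tumor"
    if (any(is.na(cd$time[tum])) || any(is.na(cd$event[tum])))
      msg <- c(msg, "survival must be defined for every tumor sample")
    if (any(cd$time[tum] <= 0, na.rm = TRUE))
      msg <- c(msg, "survival times must be positive")
    if (!all(cd$event[tum] %in% c(0, 1)))
      msg <- c(msg, "event indicator must be 0/1")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("true_lfc", "true_beta") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain true_lfc and true_beta")
  if (length(msg)) msg else TRUE
})

#' BioHierarchy: the layered gene-protein-pathway-survival network topology
#'
#' Binary intra-level adjacency matrices (\code{geneAdj}, \code{proteinAdj},
#' \code{pathwayAdj}; square, zero diagonal) and binary inter-level maps
#' (\code{geneToProtein}: proteins x genes; \code{proteinToPathway}:
#' pathways x proteins). The survival level always has exactly one node that
#' aggregates every pathway, so no map is stored for it. \code{plantedModules}
#' records gene sets wired (by the synthetic generator) to drive survival.
#'
#' @seealso [genHierarchy()], [buildHierarchy()]
#' @export
setClass("BioHierarchy",
  representation(
    geneAdj = "matrix",
    proteinAdj = "matrix",
    pathwayAdj = "matrix",
    geneToProtein = "matrix",
    proteinToPathway = "matrix",
    plantedModules = "list"
  )
)

.checkBinary <- function(m, what) {
  if (!all(m %in% c(0, 1))) return(sprintf("%s must be binary", what))
  NULL
}

setValidity("BioHierarchy", function(object) {
  msg <- character()
  for (nm in c("geneAdj", "proteinAdj", "pathwayAdj")) {
    A <- slot(object, nm)
    if (nrow(A) != ncol(A)) msg <- c(msg, sprintf("%s must be square", nm))
    msg <- c(msg, .checkBinary(A, nm))
    if (nrow(A) > 0 && any(diag(A) != 0))
      msg <- c(msg, sprintf("%s must have a zero diagonal", nm))
  }
  M1 <- object@geneToProtein
  M2 <- object@proteinToPathway
  msg <- c(msg, .checkBinary(M1, "geneToProtein"), .checkBinary(M2, "proteinToPathway"))
  if (ncol(M1) != nrow(object@geneAdj))
    msg <- c(msg, "geneToProtein columns must match gene nodes")
  if (nrow(M1) != nrow(object@proteinAdj))
    msg <- c(msg, "geneToProtein rows must match protein nodes")
  if (ncol(M2) != nrow(object@proteinAdj))
    msg <- c(msg, "proteinToPathway columns must match protein nodes")
  if (nrow(M2) != nrow(object@pathwayAdj))
    msg <- c(msg, "proteinToPathway rows must match pathway nodes")
  genes <- rownames(object@geneAdj)
  for (mod in object@plantedModules)
    if (!all(mod %in% genes))
      msg <- c(msg, "planted module genes must be declared gene nodes")
  if (length(msg)) msg else TRUE
})

#' BFRegModel: a fitted hierarchical survival network
#'
#' Holds the \linkS4class{BioHierarchy} topology, the trained parameter list
#' (embedding table, per-level message/update weights, masked cross-level
#' weight matrices and biases, edge-scoring perceptron, linear risk readout),
#' the training configuration, input standardization constants, the
#' per-epoch loss history and the held-out concordance index.
#'
#' @seealso [bfregTrain()], [bfregForward()], [integratedGradients()]
#' @export
setClass("BFRegModel",
  representation(
    hierarchy = "BioHierarchy",
    params = "list",
    config = "list",
    standardize = "list",
    history = "data.frame",
    valCIndex = "numeric",
    valSamples = "character"
  )
)

#' MedianEffectFit: Chou-Talalay median-effect parameters for one drug
#'
#' Slope \code{m} (sigmoidicity of the median-effect plot), median-effect
#' dose \code{Dm} (the IC50 analog, in the dose units of the input) and the
#' linear correlation coefficient \code{r} of the log-log fit.
#'
#' @seealso [fitMedianEffect()], [doseForEffect()], [combinationIndex()]
#' @export
setClass("MedianEffectFit",
  representation(m = "numeric", Dm = "numeric", r = "numeric",
                 nPoints = "integer", drug = "character")
)

setValidity("MedianEffectFit", function(object) {
  msg <- character()
  if (length(object@Dm) != 1 || !is.finite(object@Dm) || object@Dm <= 0)
    msg <- c(msg, "Dm must be a single positive number")
  if (length(object@m) != 1 || !is.finite(object@m))
    msg <- c(msg, "m must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' PathwaySets: per-comparison enriched pathways and their intersections
#'
#' For each biological context (e.g. \code{in_vitro}, \code{in_vivo}) the
#' per-comparison top-k enriched pathway sets, the common set (their
#' intersection within the context) and the cross-context core set.
#'
#' @seealso [commonPathways()], [corePathways()]
#' @export
setClass("PathwaySets",
  representation(perComparison = "list", common = "list", core = "character")
)

setValidity("PathwaySets", function(object) {
  msg <- character()
  canon <- function(s) unique(tolower(trimws(s)))   # name matching is case-insensitive
  for (ctx in names(object@common)) {
    sets <- object@perComparison[[ctx]]
    if (!is.null(sets)) {
      for (s in sets)
        if (!all(canon(object@common[[ctx]]) %in% canon(s)))
          msg <- c(msg, sprintf("common set of '%s' must be contained in every per-comparison set", ctx))
    }
    if (!all(canon(object@core) %in% canon(object@common[[ctx]])))
      msg <- c(msg, "core set must be contained in every context common set")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  rd <- SummarizedExperiment::rowData(object)
  cat("SyntheticCohort:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  tumor:", sum(cd$group == "tumor"), " normal:", sum(cd$group == "normal"), "\n")
  cat("  planted DEGs:", sum(rd$true_lfc != 0),
      " prognostic genes:", sum(rd$true_beta != 0), "\n")
  tum <- cd$group == "tumor"
  if (any(tum))
    cat("  events:", sum(cd$event[tum]), "/", sum(tum), "tumor samples\n")
})

setMethod("show", "BioHierarchy", function(object) {
  cat("BioHierarchy: ", nrow(object@geneAdj), " genes -> ",
      nrow(object@proteinAdj), " proteins -> ",
      nrow(object@pathwayAdj), " pathways -> survival\n", sep = "")
  cat("  intra-level edges:",
      sum(object@geneAdj) / 2, "gene,",
      sum(object@proteinAdj) / 2, "protein,",
      sum(object@pathwayAdj) / 2, "pathway\n")
  if (length(object@plantedModules))
    cat("  planted modules:", length(object@plantedModules),
        "(sizes", paste(lengths(object@plantedModules), collapse = ", "), ")\n")
})

setMethod("show", "BFRegModel", function(object) {
  cat("BFRegModel (hierarchical survival network)\n")
  show(object@hierarchy)
  cat("  embedding dim:", object@config$dim,
      " epochs run:", nrow(object@history), "\n")
  if (length(object@valCIndex))
    cat("  held-out c-index:", format(object@valCIndex, digits = 4), "\n")
})

setMethod("show", "MedianEffectFit", function(object) {
  cat("MedianEffectFit", if (length(object@drug)) paste0("[", object@drug, "]"), ":",
      "m =", format(object@m, digits = 4),
      " Dm =", format(object@Dm, digits = 6),
      " r =", format(object@r, digits = 4),
      " (", object@nPoints, "points )\n")
})

setMethod("show", "PathwaySets", function(object) {
  cat("PathwaySets\n")
  for (ctx in names(object@common))
    cat("  ", ctx, ": common set of ", length(object@common[[ctx]]),
        " pathway(s)\n", sep = "")
  cat("  core:", if (length(object@core)) paste(object@core, collapse = ", ")
      else "(empty)", "\n")
})
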