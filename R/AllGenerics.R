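#' Accessors for SyntheticCohort and BioHierarchy
#'
#' \code{exprMatrix} returns the gene-by-sample expression matrix;
#' \code{groupLabels} the named tumor/normal factor; \code{survivalData} a
#' data.frame (sample, time, event) restricted to tumor samples;
#' \code{trueLog2FC} and \code{trueBeta} the planted per-gene truth;
#' \code{plantedModules} the generator's planted gene modules;
#' \code{nGenes}, \code{nProteins}, \code{nPathways} the level sizes.
#'
#' @param object a \linkS4class{SyntheticCohort} or \linkS4class{BioHierarchy}
#' @return see description; vectors are named by gene or sample id
#' @name accessors
#' @examples
#' coh <- genCohort(n_tumor = 10, n_normal = 5, n_genes = 20, seed = 1)
#' dim(exprMatrix(coh)); table(groupLabels(coh)); head(survivalData(coh))
NULL

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(object) standardGeneric("exprMatrix"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("survivalData", function(object) standardGeneric("survivalData"))

#' @rdname accessors
#' @export
setGeneric("trueLog2FC", function(object) standardGeneric("trueLog2FC"))

#' @rdname accessors
#' @export
setGeneric("trueBeta", function(object) standardGeneric("trueBeta"))

#' @rdname accessors
#' @export
setGeneric("plantedModules", function(object) standardGeneric("plantedModules"))

#' @rdname accessors
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))

#' @rdname accessors
#' @export
setGeneric("nProteins", function(object) standardGeneric("nProteins"))

#' @rdname accessors
#' @export
setGeneric("nPathways", function(object) standardGeneric("nPathways"))

#' @rdname accessors
#' @export
setMethod("exprMatrix", "SyntheticCohort", function(object)
  SummarizedExperiment::assay(object, "expr"))

#' @rdname accessors
#' @export
setMethod("groupLabels", "SyntheticCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  setNames(factor(cd$group, levels = c("normal", "tumor")), rownames(cd))
})

#' @rdname accessors
#' @export
setMethod("survivalData", "SyntheticCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  tum <- cd$group == "tumor"
  data.frame(sample = rownames(cd)[tum],
             time = cd$time[tum], event = cd$event[tum],
             row.names = rownames(cd)[tum])
})

#' @rdname accessors
#' @export
setMethod("trueLog2FC", "SyntheticCohort", function(object)
  setNames(SummarizedExperiment::rowData(object)$true_lfc, rownames(object)))

#' @rdname accessors
#' @export
setMethod("trueBeta", "SyntheticCohort", function(object)
  setNames(SummarizedExperiment::rowData(object)$true_beta, rownames(object)))

#' @rdname accessors
#' @export
setMethod("plantedModules", "BioHierarchy", function(object) object@plantedModules)

#' @rdname accessors
#' @export
setMethod("nGenes", "BioHierarchy", function(object) nrow(object@geneAdj))

#' @rdname accessors
#' @export
setMethod("nProteins", "BioHierarchy", function(object) nrow(object@proteinAdj))

#' @rdname accessors
#' @export
setMethod("nPathways", "BioHierarchy", function(object) nrow(object@pathwayAdj))
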