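#' Apply drug target inhibition to an expression profile
#'
#' Models drug action as multiplicative inhibition of target-gene
#' expression: every gene targeted by at least one of the given drugs is
#' multiplied by `1 - inhibition`. For drug pairs the target sets are
#' unioned first, so a gene targeted by both drugs is scaled once, not
#' twice. `inhibition = 1` (the default, full knockdown) sets targets to 0.
#'
#' @param inputs named gene expression vector (TPM-like scale)
#' @param drugs one or more drug ids
#' @param map drug-target table: data.frame with columns `drug`, `gene`
#'   (as produced by [genDrugPanel()]`$targets`)
#' @param inhibition fraction in `[0, 1]`
#' @return the modified expression vector
#' @examples
#' map <- data.frame(drug = c("d1", "d2"), gene = c("g1", "g2"))
#' applyDrug(c(g1 = 10, g2 = 10, g3 = 10), c("d1", "d2"), map)
#' @export
applyDrug <- function(inputs, drugs, map, inhibition = 1) {
  if (inhibition < 0 || inhibition > 1) stop("inhibition must be in [0, 1]")
  unknown <- setdiff(drugs, unique(map$drug))
  if (length(unknown))
    stop("unknown drug id(s): ", paste(unknown, collapse = ", "))
  targets <- unique(map$gene[map$drug %in% drugs])
  targets <- intersect(targets, names(inputs))
  inputs[targets] <- inputs[targets] * (1 - inhibition)
  inputs
}

#' Synergy score of a drug pair under the fitted network
#'
#' The pair's predicted benefit: the mean, over evaluation samples, of
#' `risk(untreated) - risk(pair-treated)`, where treatment multiplies the
#' pair's (unioned) target genes by `1 - inhibition` before the model's
#' standardization and forward pass. Higher scores mean better predicted
#' recurrence-free survival under the combination. A pair of identical
#' drugs is scored as the single drug, with a warning.
#'
#' @param model a \linkS4class{BFRegModel}
#' @param expr genes x samples evaluation matrix (expression scale); by
#'   convention the model's held-out samples
#' @param pair character vector of two drug ids
#' @param map drug-target table (`drug`, `gene`)
#' @param inhibition fraction in `[0, 1]` (default 1)
#' @return scalar synergy score
#' @export
scorePair <- function(model, expr, pair, map, inhibition = 1) {
  stopifnot(length(pair) == 2)
  if (pair[1] == pair[2]) {
    warning("pair of identical drugs; scored as a single drug")
    pair <- pair[1]
  }
  base <- predictRisk(model, expr)
  treated <- apply(expr, 2, applyDrug, drugs = pair, map = map,
                   inhibition = inhibition)
  rownames(treated) <- rownames(expr)
  mean(base - predictRisk(model, treated))
}

#' Score every candidate drug pair
#'
#' Enumerates all unordered drug pairs (optionally restricted by
#' `pair_filter`), scores each with [scorePair()], and returns the table
#' ready for [rankCombos()].
#'
#' @inheritParams scorePair
#' @param drugs drug ids (default: all drugs in `map`)
#' @param pair_filter optional `function(drugA, drugB)` returning `TRUE`
#'   to keep the pair
#' @return data.frame: drugA, drugB, synergy_score
#' @export
scoreAllPairs <- function(model, expr, map, drugs = NULL,
                          inhibition = 1, pair_filter = NULL) {
  if (is.null(drugs)) drugs <- sort(unique(map$drug))
  if (length(drugs) < 2) stop("need at least two drugs")
  pairs <- t(combn(sort(drugs), 2))
  if (!is.null(pair_filter)) {
    keep <- mapply(pair_filter, pairs[, 1], pairs[, 2])
    pairs <- pairs[keep, , drop = FALSE]
  }
  base <- predictRisk(model, expr)
  scores <- vapply(seq_len(nrow(pairs)), function(k) {
    treated <- apply(expr, 2, applyDrug, drugs = pairs[k, ], map = map,
                     inhibition = inhibition)
    rownames(treated) <- rownames(expr)
    mean(base - predictRisk(model, treated))
  }, numeric(1))
  data.frame(drugA = pairs[, 1], drugB = pairs[, 2], synergy_score = scores)
}

#' Rank scored pairs and retain the top fraction
#'
#' Sorts descending by synergy score, breaking ties by the lexicographic
#' pair id (`drugA|drugB`), assigns ranks 1..n, and flags the top
#' `ceiling(retain_fraction * n)` pairs as retained. The result is
#' invariant to the input row order, and raising a pair's score never
#' lowers its rank.
#'
#' @param scores data.frame with `drugA`, `drugB`, `synergy_score`
#' @param retain_fraction fraction retained (default 0.30)
#' @return the input with `rank` and `retained` columns, sorted by rank
#' @examples
#' sc <- data.frame(drugA = c("a", "b"), drugB = c("b", "c"),
#'                  synergy_score = c(1, 2))
#' rankCombos(sc, retain_fraction = 0.5)
#' @export
rankCombos <- function(scores, retain_fraction = 0.30) {
  if (retain_fraction < 0 || retain_fraction > 1)
    stop("retain_fraction must be in [0, 1]")
  if (!nrow(scores))
    return(cbind(scores, rank = integer(0), retained = logical(0)))
  if (!all(is.finite(scores$synergy_score)))
    stop("synergy scores must be finite")
  pair_id <- paste(scores$drugA, scores$drugB, sep = "|")
  o <- order(-scores$synergy_score, pair_id)
  out <- scores[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$retained <- out$rank <= ceiling(retain_fraction * nrow(out))
  rownames(out) <- NULL
  out
}
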