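#' Differential metabolites between two treatment groups
#'
#' Welch t-test per metabolite on log2 intensities between the two groups
#' of a comparison, with the fold change as the difference of group means
#' of log2 intensity. A metabolite is significant when both `p <
#' p_threshold` (raw p by default; set `adjust = TRUE` for BH) and
#' `|log2FC| > fc_threshold` hold — the conjunction is required. A
#' metabolite with zero variance in both groups gets p = 1 and is flagged.
#'
#' @param panel list with `intensities` (metabolite x sample matrix) and
#'   `groups` (named factor), as from [genMetabolitePanel()]
#' @param comparison two group names; the fold change is group 1 over
#'   group 2
#' @param p_threshold p threshold (default 0.05)
#' @param fc_threshold absolute log2 fold-change threshold (default 1)
#' @param adjust apply Benjamini-Hochberg before thresholding
#'   (default FALSE)
#' @return data.frame: metabolite, log2FC, p_value, adjusted_p,
#'   significant, zero_variance
#' @examples
#' mp <- genMetabolitePanel(planted = list(list(
#'   comparison = c("combo", "model"), metabolites = 1:5, lfc = 2)), seed = 1)
#' dm <- differentialMetabolites(mp, c("combo", "model"))
#' sum(dm$significant)
#' @export
differentialMetabolites <- function(panel, comparison, p_threshold = 0.05,
                                    fc_threshold = 1, adjust = FALSE) {
  stopifnot(length(comparison) == 2)
  grp <- panel$groups
  if (!all(comparison %in% levels(grp))) stop("unknown group in comparison")
  i1 <- names(grp)[grp == comparison[1]]
  i2 <- names(grp)[grp == comparison[2]]
  if (length(i1) < 2 || length(i2) < 2)
    stop("need at least two samples per group")
  lx <- log2(panel$intensities)
  res <- welchRows(lx[, i1, drop = FALSE], lx[, i2, drop = FALSE],
                   fc_threshold = fc_threshold, p_threshold = p_threshold,
                   id_col = "metabolite")
  pcol <- if (adjust) res$adjusted_p else res$p_value
  res$significant <- pcol < p_threshold & abs(res$log2FC) > fc_threshold
  res$direction <- NULL
  res
}

#' Hypergeometric pathway over-representation
#'
#' One-sided hypergeometric test per pathway: with `N` background
#' metabolites, `K` of them in the pathway, `n` hits and `k` hits in the
#' pathway, `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`. Pathway
#' membership is intersected with the background first; ranking is by
#' ascending p with alphabetical tie-breaking. Empty hit sets give p = 1
#' everywhere.
#'
#' @param hits character vector of differential metabolite ids (must be a
#'   subset of `background`)
#' @param library named list: pathway -> metabolite ids (see [readGmt()])
#' @param background character vector of measured metabolite ids
#' @return data.frame: pathway, k, K, n, N, p_value, rank
#' @examples
#' lib <- list(pwA = c("m1", "m2"), pwB = c("m3", "m4"))
#' pathwayEnrichment(c("m1", "m2"), lib, paste0("m", 1:10))
#' @export
pathwayEnrichment <- function(hits, library, background) {
  if (!length(library)) stop("pathway library is empty")
  hits <- unique(hits)
  background <- unique(background)
  if (!all(hits %in% background)) stop("hits must be a subset of background")
  N <- length(background)
  n <- length(hits)
  rows <- lapply(names(library), function(pw) {
    members <- intersect(library[[pw]], background)
    K <- length(members)
    k <- length(intersect(hits, members))
    p <- if (n == 0 || K == 0) 1 else
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N, p_value = p)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$pathway), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top-k pathways of an enrichment table
#'
#' The first `min(k, n)` pathways by rank (ascending enrichment p,
#' alphabetical within ties, as ranked by [pathwayEnrichment()]).
#'
#' @param table an [pathwayEnrichment()] result (must carry `rank`)
#' @param k how many to keep (default 25)
#' @return character vector of pathway names
#' @export
topPathways <- function(table, k = 25) {
  stopifnot("rank" %in% names(table))
  table$pathway[order(table$rank)][seq_len(min(k, nrow(table)))]
}

#' Intersection of per-comparison pathway sets
#'
#' The pathways common to every input set (exact set intersection after
#' trimming and case-folding, since pathway names from different exports
#' differ in capitalization). Commutative, associative and idempotent.
#'
#' @param ... two or more character vectors (or a single list of them)
#' @return sorted character vector of common pathways
#' @examples
#' commonPathways(c("glutathione metabolism", "purine metabolism"),
#'                c("Glutathione metabolism"))
#' @export
commonPathways <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]])) sets <- sets[[1]]
  norm <- lapply(sets, function(s) unique(tolower(trimws(s))))
  sort(Reduce(intersect, norm))
}

#' Cross-context core pathways
#'
#' The intersection of the two context-level common sets (e.g. the in
#' vitro and in vivo common pathways): the pathways perturbed by the
#' combination in both systems.
#'
#' @param in_vitro_common,in_vivo_common character vectors
#' @return sorted character vector
#' @examples
#' corePathways(c("glutathione metabolism", "purine metabolism"),
#'              c("glutathione metabolism", "tca cycle"))
#' @export
corePathways <- function(in_vitro_common, in_vivo_common) {
  commonPathways(in_vitro_common, in_vivo_common)
}

#' Read / write pathway libraries in GMT format
#'
#' GMT is tab-separated, one set per line: name, description, then member
#' ids. `readGmt` returns a named list of member vectors; `writeGmt`
#' writes one.
#'
#' @param path file path
#' @param library named list pathway -> member ids
#' @param descriptions optional character vector (recycled; default "na")
#' @return `readGmt`: named list; `writeGmt`: `path` invisibly
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @rdname readGmt
#' @export
writeGmt <- function(library, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(library))
  lines <- vapply(seq_along(library), function(i)
    paste(c(names(library)[i], descriptions[i], library[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Full per-context pathway-set analysis
#'
#' Runs the complete metabolomics procedure for one or more contexts: per
#' comparison, differential metabolites (p and fold-change filter), then
#' hypergeometric enrichment against the library, then top-k selection;
#' per context, the common set (intersection over comparisons); across
#' contexts, the core set.
#'
#' @param panels named list of contexts (e.g. `in_vitro`, `in_vivo`), each
#'   a panel as accepted by [differentialMetabolites()] and carrying a
#'   `library`
#' @param comparisons list of 2-vectors of group names (shared across
#'   contexts); default: `combo` against every other group
#' @param top_k pathways kept per comparison (default 25)
#' @param ... passed to [differentialMetabolites()]
#' @return a \linkS4class{PathwaySets}
#' @export
pathwaySetAnalysis <- function(panels, comparisons = NULL, top_k = 25, ...) {
  if (is.null(names(panels))) stop("panels must be a named list of contexts")
  per <- list(); common <- list()
  for (ctx in names(panels)) {
    panel <- panels[[ctx]]
    cmps <- comparisons
    if (is.null(cmps)) {
      g <- levels(panel$groups)
      cmps <- lapply(setdiff(g, g[1]), function(other) c(g[1], other))
    }
    background <- intersect(rownames(panel$intensities),
                            unique(unlist(panel$library)))
    sets <- lapply(cmps, function(cmp) {
      dm <- differentialMetabolites(panel, cmp, ...)
      hits <- intersect(dm$metabolite[dm$significant], background)
      topPathways(pathwayEnrichment(hits, panel$library, background), top_k)
    })
    names(sets) <- vapply(cmps, paste, character(1), collapse = "_vs_")
    per[[ctx]] <- sets
    common[[ctx]] <- commonPathways(sets)
  }
  core <- if (length(common) >= 2) Reduce(intersect, common) else
    unlist(common, use.names = FALSE)
  methods::new("PathwaySets", perComparison = per, common = common,
               core = sort(core))
}
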