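#' Construct a BioHierarchy from edge lists and maps
#'
#' Builds the layered gene-protein-pathway-survival topology from intra-level
#' edge lists (two-column data.frames of node ids) and inter-level maps
#' (two-column data.frames: child id, parent id). Every edge endpoint and map
#' entry must reference a declared node of the proper level.
#'
#' @param genes,proteins,pathways character vectors of node ids per level
#' @param gene_edges,protein_edges,pathway_edges data.frames with columns
#'   `source`, `target` (undirected; both orientations are set)
#' @param gene_to_protein,protein_to_pathway data.frames with columns
#'   `child`, `parent`
#' @param planted_modules optional list of gene-id sets (ground truth
#'   bookkeeping for synthetic hierarchies)
#' @return a \linkS4class{BioHierarchy}
#' @examples
#' h <- buildHierarchy(genes = c("g1", "g2"), proteins = "p1", pathways = "q1",
#'   gene_edges = data.frame(source = "g1", target = "g2"),
#'   gene_to_protein = data.frame(child = c("g1", "g2"), parent = "p1"),
#'   protein_to_pathway = data.frame(child = "p1", parent = "q1"))
#' @export
buildHierarchy <- function(genes, proteins, pathways,
                           gene_edges = NULL, protein_edges = NULL,
                           pathway_edges = NULL,
                           gene_to_protein, protein_to_pathway,
                           planted_modules = list()) {
  adj <- function(nodes, edges, lvl) {
    A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    if (!is.null(edges) && nrow(edges)) {
      s <- as.character(edges[[1]]); t <- as.character(edges[[2]])
      bad <- !(s %in% nodes) | !(t %in% nodes)
      if (any(bad))
        stop(sprintf("%s edges reference undeclared nodes: %s", lvl,
                     paste(unique(c(s[bad], t[bad])), collapse = ", ")))
      keep <- s != t
      A[cbind(s[keep], t[keep])] <- 1
      A[cbind(t[keep], s[keep])] <- 1
    }
    A
  }
  mapm <- function(children, parents, map, lvl) {
    M <- matrix(0, length(parents), length(children),
                dimnames = list(parents, children))
    ch <- as.character(map[[1]]); pa <- as.character(map[[2]])
    bad <- !(ch %in% children) | !(pa %in% parents)
    if (any(bad))
      stop(sprintf("%s map references undeclared nodes: %s", lvl,
                   paste(unique(c(ch[bad], pa[bad])), collapse = ", ")))
    M[cbind(pa, ch)] <- 1
    M
  }
  methods::new("BioHierarchy",
    geneAdj = adj(genes, gene_edges, "gene"),
    proteinAdj = adj(proteins, protein_edges, "protein"),
    pathwayAdj = adj(pathways, pathway_edges, "pathway"),
    geneToProtein = mapm(genes, proteins, gene_to_protein, "gene-to-protein"),
    proteinToPathway = mapm(proteins, pathways, protein_to_pathway,
                            "protein-to-pathway"),
    plantedModules = planted_modules)
}

#' Generate a random layered hierarchy with planted functional modules
#'
#' Intra-level graphs are Erdos-Renyi at `edge_density`; every gene maps to
#' at least one protein and every protein to at least one pathway. Each
#' planted module is a connected gene set (wired as a path) whose member
#' genes map to a dedicated block of proteins that all share one pathway,
#' so the module forms a coherent route to the survival node. Module genes
#' are taken from the front of the gene list (module 1 = first
#' `module_size` genes), matching the planted prognostic genes of
#' [genCohort()].
#'
#' @param n_genes,n_proteins,n_pathways level sizes (all positive)
#' @param edge_density intra-level edge probability in `[0, 1]`
#' @param n_modules number of planted modules
#' @param module_size genes per planted module (default 10)
#' @param seed integer seed
#' @return a \linkS4class{BioHierarchy}
#' @examples
#' h <- genHierarchy(n_genes = 30, n_proteins = 12, n_pathways = 5,
#'                   n_modules = 1, seed = 1)
#' plantedModules(h)
#' @export
genHierarchy <- function(n_genes, n_proteins, n_pathways,
                         edge_density = 0.05, n_modules = 1,
                         module_size = 10, seed = 1) {
  stopifnot(n_genes >= 1, n_proteins >= 1, n_pathways >= 1)
  if (edge_density < 0 || edge_density > 1)
    stop("edge_density must be in [0, 1]")
  if (n_modules * module_size > n_genes)
    stop("planted modules cannot cover more genes than exist")
  if (n_modules > n_pathways || n_modules * 2 > n_proteins)
    stop("not enough proteins/pathways to host the planted modules")

  rng <- .localRNG(seed)
  on.exit(rng$restore(), add = TRUE)

  genes <- sprintf("g%03d", seq_len(n_genes))
  proteins <- sprintf("p%03d", seq_len(n_proteins))
  pathways <- sprintf("q%03d", seq_len(n_pathways))

  er <- function(n) {
    A <- matrix(0, n, n)
    if (n > 1 && edge_density > 0) {
      up <- which(upper.tri(A))
      A[up] <- rbinom(length(up), 1, edge_density)
      A <- A + t(A)
    }
    A
  }
  Ag <- er(n_genes); dimnames(Ag) <- list(genes, genes)
  Ap <- er(n_proteins); dimnames(Ap) <- list(proteins, proteins)
  Aq <- er(n_pathways); dimnames(Aq) <- list(pathways, pathways)

  # every gene to >=1 protein, every protein to >=1 pathway
  M1 <- matrix(0, n_proteins, n_genes, dimnames = list(proteins, genes))
  M1[cbind(sample.int(n_proteins, n_genes, replace = TRUE), seq_len(n_genes))] <- 1
  M2 <- matrix(0, n_pathways, n_proteins, dimnames = list(pathways, proteins))
  M2[cbind(sample.int(n_pathways, n_proteins, replace = TRUE),
           seq_len(n_proteins))] <- 1

  modules <- list()
  if (n_modules > 0) {
    prot_per_mod <- max(2, n_proteins %/% max(1, 2 * n_modules))
    for (k in seq_len(n_modules)) {
      gidx <- ((k - 1) * module_size + 1):(k * module_size)
      modules[[k]] <- genes[gidx]
      # connect as a path so the module is a connected gene set
      if (module_size > 1) {
        i <- gidx[-length(gidx)]; j <- gidx[-1]
        Ag[cbind(i, j)] <- 1; Ag[cbind(j, i)] <- 1
      }
      pidx <- ((k - 1) * prot_per_mod + 1):(k * prot_per_mod)
      # rewire module genes onto the module's protein block
      M1[, gidx] <- 0
      M1[cbind(pidx[((seq_along(gidx) - 1) %% length(pidx)) + 1], gidx)] <- 1
      # module proteins share pathway k
      M2[, pidx] <- 0
      M2[k, pidx] <- 1
    }
    names(modules) <- sprintf("module%d", seq_len(n_modules))
  }
  diag(Ag) <- 0; diag(Ap) <- 0; diag(Aq) <- 0

  methods::new("BioHierarchy", geneAdj = Ag, proteinAdj = Ap, pathwayAdj = Aq,
               geneToProtein = M1, proteinToPathway = M2,
               plantedModules = modules)
}

#' Write / read a hierarchy as edge-list and map TSVs
#'
#' `writeHierarchy` writes `gene_edges.tsv`, `protein_edges.tsv`,
#' `pathway_edges.tsv` (columns `source`, `target`; each undirected edge
#' once), `gene_to_protein.tsv` and `protein_to_pathway.tsv` (columns
#' `child`, `parent`) and `nodes.tsv` (`node`, `level`) into `dir`.
#'
#' @param hierarchy a \linkS4class{BioHierarchy}
#' @param dir directory (created if missing)
#' @return `writeHierarchy` returns `dir` invisibly; `readHierarchy` a
#'   \linkS4class{BioHierarchy}
#' @export
writeHierarchy <- function(hierarchy, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edges <- function(A) {
    idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    data.frame(source = rownames(A)[idx[, 1]], target = colnames(A)[idx[, 2]])
  }
  maps <- function(M) {
    idx <- which(M == 1, arr.ind = TRUE)
    o <- order(idx[, 2], idx[, 1])
    data.frame(child = colnames(M)[idx[o, 2]], parent = rownames(M)[idx[o, 1]])
  }
  w <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  w(edges(hierarchy@geneAdj), "gene_edges.tsv")
  w(edges(hierarchy@proteinAdj), "protein_edges.tsv")
  w(edges(hierarchy@pathwayAdj), "pathway_edges.tsv")
  w(maps(hierarchy@geneToProtein), "gene_to_protein.tsv")
  w(maps(hierarchy@proteinToPathway), "protein_to_pathway.tsv")
  w(data.frame(
      node = c(rownames(hierarchy@geneAdj), rownames(hierarchy@proteinAdj),
               rownames(hierarchy@pathwayAdj)),
      level = rep(c("gene", "protein", "pathway"),
                  c(nGenes(hierarchy), nProteins(hierarchy),
                    nPathways(hierarchy)))),
    "nodes.tsv")
  invisible(dir)
}

#' @rdname writeHierarchy
#' @export
readHierarchy <- function(dir) {
  nodes <- read.delim(file.path(dir, "nodes.tsv"))
  rd <- function(f) read.delim(file.path(dir, f))
  buildHierarchy(
    genes = nodes$node[nodes$level == "gene"],
    proteins = nodes$node[nodes$level == "protein"],
    pathways = nodes$node[nodes$level == "pathway"],
    gene_edges = rd("gene_edges.tsv"),
    protein_edges = rd("protein_edges.tsv"),
    pathway_edges = rd("pathway_edges.tsv"),
    gene_to_protein = rd("gene_to_protein.tsv"),
    protein_to_pathway = rd("protein_to_pathway.tsv"))
}
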