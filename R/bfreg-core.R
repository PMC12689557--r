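# Hierarchical survival network: topology from a BioHierarchy, GNN-style
# message passing within each level, masked linear propagation between
# levels, optional learnable adjacency, linear risk readout.
#
# All gradients are hand-derived; .bfregBackwardOne is checked against
# central finite differences in the test suite.

# activations: "logistic" saturates in (0,1); "mix" adds an identity path
# (z + logistic(z)) so gradients keep magnitude through the level stack
.sigma <- function(z, activation = "logistic") {
  s <- 1 / (1 + exp(-z))
  if (activation == "mix") z + s else s
}

# derivative from the pre-activation
.dsigma <- function(z, activation = "logistic") {
  s <- 1 / (1 + exp(-z))
  d <- s * (1 - s)
  if (activation == "mix") 1 + d else d
}

#' Scale per-node inputs into embedding space
#'
#' Each node's scalar input value is embedded linearly, `H_i = x_i * e_i`,
#' where `e_i` is the node's (learned) direction vector. The embedding is
#' therefore exactly zero for a zero input and homogeneous of degree one.
#'
#' @param values named numeric vector of node input values
#' @param directions nodes x dim matrix of direction vectors, rows aligned
#'   with (or named by) `values`
#' @return nodes x dim embedding matrix
#' @examples
#' initEmbeddings(c(a = 2, b = 0), rbind(a = c(1, 1), b = c(1, -1)))
#' @export
initEmbeddings <- function(values, directions) {
  stopifnot(all(is.finite(values)), nrow(directions) == length(values))
  if (!is.null(names(values)) && !is.null(rownames(directions)))
    directions <- directions[names(values), , drop = FALSE]
  unname(values) * directions
}

#' One round of intra-level message passing
#'
#' GNN update on one level: each node receives `w_msg * H_j` from every
#' neighbour `j`, scaled by the (possibly learned) edge weight, and updates
#' as `sigma(w_self * H_i + sum_j weight_ij * w_msg * H_j)`. With an empty
#' adjacency the output is `sigma(w_self * H_i)` for every node. The update
#' is equivariant under node relabelling.
#'
#' @param states nodes x dim embedding matrix
#' @param adjacency binary or weighted adjacency (rows receive from columns)
#' @param w_self,w_msg scalar self and message weights
#' @param activation `"logistic"` (default) or `"mix"` (identity +
#'   logistic)
#' @return updated nodes x dim embedding matrix
#' @examples
#' H <- rbind(c(1, 0), c(0, 1))
#' messagePass(H, matrix(c(0, 1, 1, 0), 2), w_self = 1, w_msg = 0.5)
#' @export
messagePass <- function(states, adjacency, w_self = 1, w_msg = 1,
                        activation = "logistic") {
  if (nrow(adjacency) != nrow(states) || ncol(adjacency) != nrow(states))
    stop("adjacency dimensions must match the node set")
  .sigma(w_self * states + w_msg * (adjacency %*% states), activation)
}

#' Masked cross-level propagation
#'
#' Each level-(l+1) node aggregates the embeddings of the level-l nodes it
#' is mapped to: `out = sigma((M * W) %*% states + b)`, where `*` is
#' element-wise masking, so an entry of `W` at a masked position (`M = 0`)
#' can never influence the output, and with an all-zero map every output
#' row equals `sigma(b)`.
#'
#' @param states level-l nodes x dim matrix
#' @param M binary map, level-(l+1) nodes x level-l nodes
#' @param W weight matrix, same shape as `M` (shared across channels)
#' @param b per-target-node bias vector
#' @param activation `"logistic"` (default) or `"mix"`
#' @return level-(l+1) nodes x dim matrix
#' @examples
#' crossLevelPropagate(rbind(c(1, 2), c(3, 4)),
#'   M = matrix(c(1, 0), 1, 2), W = matrix(c(2, 99), 1, 2), b = 0)
#' @export
crossLevelPropagate <- function(states, M, W, b, activation = "logistic") {
  if (!all(dim(M) == dim(W))) stop("W must have the shape of M")
  if (ncol(M) != nrow(states)) stop("map columns must match source nodes")
  .sigma((M * W) %*% states + b, activation)
}

# edge scores for all ordered off-diagonal pairs via a 2-layer perceptron
# on the concatenated endpoint embeddings; returns the intermediates the
# backward pass needs
.edgeScores <- function(states, mlp, pairI, pairJ) {
  featt <- cbind(states[pairI, , drop = FALSE], states[pairJ, , drop = FALSE])
  Z1 <- tanh(sweep(featt %*% t(mlp$W1), 2, mlp$b1, "+"))
  beta <- drop(Z1 %*% mlp$w2) + mlp$b2
  list(featt = featt, Z1 = Z1, beta = beta)
}

#' Learnable adjacency from embeddings
#'
#' Scores every ordered node pair with a two-layer perceptron on the
#' concatenated embeddings, `beta_ij = mlp(c(H_i, H_j))`, and returns the
#' effective weighted adjacency: `beta_ij` where the prior adjacency has an
#' edge, and `alpha * beta_ij` (a small penalty for uncertain edges,
#' `alpha = 0.005`) where it does not. Known biology is thus kept at full
#' weight while unannotated interactions can still be discovered.
#'
#' @param states nodes x dim embedding matrix
#' @param A binary prior adjacency
#' @param mlp list with `W1` (hidden x 2*dim), `b1` (hidden), `w2`
#'   (hidden), `b2` (scalar)
#' @param alpha penalty for absent edges (default 0.005)
#' @return weighted adjacency matrix (zero diagonal)
#' @export
learnableAdjacency <- function(states, A, mlp, alpha = 0.005) {
  n <- nrow(states)
  if (!all(dim(A) == c(n, n))) stop("adjacency must be square over the nodes")
  off <- which(row(A) != col(A))
  pairI <- row(A)[off]; pairJ <- col(A)[off]
  es <- .edgeScores(states, mlp, pairI, pairJ)
  K <- ifelse(A == 1, 1, alpha)
  W <- matrix(0, n, n, dimnames = dimnames(A))
  W[cbind(pairI, pairJ)] <- K[cbind(pairI, pairJ)] * es$beta
  W
}

#' Initialize network parameters for a hierarchy
#'
#' Draws the embedding table, the per-level self/message weights, the
#' masked cross-level weights (scaled by fan-in) and the edge-scoring
#' perceptron (its output bias starts at 1, so the learned adjacency begins
#' at the binary prior). The linear risk readout starts at zero: the
#' untrained network scores every sample 0, and the risk ordering is
#' entirely learned rather than inherited from initialization noise.
#'
#' @param hierarchy a \linkS4class{BioHierarchy}
#' @param dim embedding dimension (default 16)
#' @param hidden hidden width of the edge-scoring perceptron (default 8)
#' @param learn_adj use the learnable adjacency at the gene level
#'   (default TRUE)
#' @param alpha absent-edge penalty (default 0.005)
#' @param rounds intra-level message-passing rounds per level (default 1)
#' @param activation `"mix"` (identity + logistic, default) or
#'   `"logistic"`
#' @param seed integer seed
#' @return list with `params` (all trainable arrays) and `config`
#' @export
bfregInit <- function(hierarchy, dim = 16, hidden = 8, learn_adj = TRUE,
                      alpha = 0.005, rounds = 1, activation = "mix",
                      seed = 1) {
  stopifnot(rounds >= 1, activation %in% c("mix", "logistic"))
  rng <- .localRNG(seed)
  on.exit(rng$restore(), add = TRUE)
  ng <- nGenes(hierarchy); np <- nProteins(hierarchy); nq <- nPathways(hierarchy)
  wInit <- function(M) {
    W <- matrix(rnorm(length(M), sd = 1 / sqrt(pmax(1, rowSums(M)))),
                nrow(M), ncol(M))
    dimnames(W) <- dimnames(M)
    W
  }
  M3 <- matrix(1, 1, nq)  # the survival node aggregates every pathway
  params <- list(
    E = matrix(rnorm(ng * dim, sd = 1 / sqrt(dim)), ng, dim,
               dimnames = list(rownames(hierarchy@geneAdj), NULL)),
    wSelf = c(gene = 1, protein = 1, pathway = 1),
    wMsg = c(gene = 0.5, protein = 0.5, pathway = 0.5),
    W1 = wInit(hierarchy@geneToProtein), b1 = numeric(np),
    W2 = wInit(hierarchy@proteinToPathway), b2 = numeric(nq),
    W3 = wInit(M3), b3 = 0,
    v = numeric(dim), c = 0,
    adj = list(W1 = matrix(rnorm(hidden * 2 * dim, sd = 1 / sqrt(2 * dim)),
                           hidden, 2 * dim),
               b1 = numeric(hidden),
               w2 = rnorm(hidden, sd = 1 / sqrt(hidden)),
               b2 = 1)
  )
  A <- hierarchy@geneAdj
  off <- which(row(A) != col(A))
  config <- list(dim = dim, hidden = hidden, learn_adj = learn_adj,
                 alpha = alpha, rounds = rounds, activation = activation,
                 pairI = row(A)[off], pairJ = col(A)[off],
                 Kmask = ifelse(A == 1, 1, alpha) * (row(A) != col(A)))
  list(params = params, config = config)
}

# full forward pass for one input vector; optionally keeps every
# intermediate needed by the backward pass (pre-activations included)
.bfregForwardOne <- function(hierarchy, params, config, x, keep = FALSE) {
  act <- config$activation %||% "logistic"
  H0 <- unname(x) * params$E
  cache <- if (keep) list(x = x, H0 = H0, gene = list()) else NULL
  H <- H0
  Ag <- hierarchy@geneAdj
  for (r in seq_len(config$rounds)) {
    if (config$learn_adj) {
      es <- .edgeScores(H, params$adj, config$pairI, config$pairJ)
      Aeff <- matrix(0, nrow(Ag), ncol(Ag))
      Aeff[cbind(config$pairI, config$pairJ)] <-
        config$Kmask[cbind(config$pairI, config$pairJ)] * es$beta
    } else {
      es <- NULL
      Aeff <- Ag
    }
    S <- Aeff %*% H
    Z <- params$wSelf["gene"] * H + params$wMsg["gene"] * S
    Hn <- .sigma(Z, act)
    if (keep) cache$gene[[r]] <- list(H = H, es = es, Aeff = Aeff, S = S, Z = Z)
    H <- Hn
  }
  Zp <- (hierarchy@geneToProtein * params$W1) %*% H + params$b1
  P <- .sigma(Zp, act)
  if (keep) { cache$Hg <- H; cache$Zp <- Zp; cache$protein <- list() }
  Ap <- hierarchy@proteinAdj
  for (r in seq_len(config$rounds)) {
    S <- Ap %*% P
    Z <- params$wSelf["protein"] * P + params$wMsg["protein"] * S
    Pn <- .sigma(Z, act)
    if (keep) cache$protein[[r]] <- list(H = P, S = S, Z = Z)
    P <- Pn
  }
  Zq <- (hierarchy@proteinToPathway * params$W2) %*% P + params$b2
  Q <- .sigma(Zq, act)
  if (keep) { cache$Hp <- P; cache$Zq <- Zq; cache$pathway <- list() }
  Aq <- hierarchy@pathwayAdj
  for (r in seq_len(config$rounds)) {
    S <- Aq %*% Q
    Z <- params$wSelf["pathway"] * Q + params$wMsg["pathway"] * S
    Qn <- .sigma(Z, act)
    if (keep) cache$pathway[[r]] <- list(H = Q, S = S, Z = Z)
    Q <- Qn
  }
  Zs <- params$W3 %*% Q + params$b3        # survival map is all-ones
  Ssur <- .sigma(Zs, act)
  risk <- sum(params$v * drop(Ssur)) + params$c
  if (keep) { cache$Hq <- Q; cache$Zs <- Zs; cache$Ssur <- Ssur }
  list(risk = risk, cache = cache)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.zeroGrads <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

# backward pass for one sample; returns grads (same shape as params) and
# the gradient with respect to the gene input vector
.bfregBackwardOne <- function(hierarchy, params, config, cache, drisk) {
  act <- config$activation %||% "logistic"
  g <- .zeroGrads(params)
  g$v <- drisk * drop(cache$Ssur)
  g$c <- drisk
  dSsur <- matrix(drisk * params$v, 1)

  dZ <- dSsur * .dsigma(cache$Zs, act)
  g$W3 <- dZ %*% t(cache$Hq)
  g$b3 <- sum(dZ)
  dH <- t(params$W3) %*% dZ               # gradient w.r.t. pathway states

  Aq <- hierarchy@pathwayAdj
  for (r in rev(seq_len(config$rounds))) {
    layer <- cache$pathway[[r]]
    dZ <- dH * .dsigma(layer$Z, act)
    g$wSelf["pathway"] <- g$wSelf["pathway"] + sum(dZ * layer$H)
    g$wMsg["pathway"] <- g$wMsg["pathway"] + sum(dZ * layer$S)
    dH <- params$wSelf["pathway"] * dZ + params$wMsg["pathway"] * (t(Aq) %*% dZ)
  }
  M2 <- hierarchy@proteinToPathway
  dZ <- dH * .dsigma(cache$Zq, act)
  g$W2 <- (dZ %*% t(cache$Hp)) * M2
  g$b2 <- rowSums(dZ)
  dH <- t(M2 * params$W2) %*% dZ

  Ap <- hierarchy@proteinAdj
  for (r in rev(seq_len(config$rounds))) {
    layer <- cache$protein[[r]]
    dZ <- dH * .dsigma(layer$Z, act)
    g$wSelf["protein"] <- g$wSelf["protein"] + sum(dZ * layer$H)
    g$wMsg["protein"] <- g$wMsg["protein"] + sum(dZ * layer$S)
    dH <- params$wSelf["protein"] * dZ + params$wMsg["protein"] * (t(Ap) %*% dZ)
  }
  M1 <- hierarchy@geneToProtein
  dZ <- dH * .dsigma(cache$Zp, act)
  g$W1 <- (dZ %*% t(cache$Hg)) * M1
  g$b1 <- rowSums(dZ)
  dH <- t(M1 * params$W1) %*% dZ

  for (r in rev(seq_len(config$rounds))) {
    layer <- cache$gene[[r]]
    dZ <- dH * .dsigma(layer$Z, act)
    g$wSelf["gene"] <- g$wSelf["gene"] + sum(dZ * layer$H)
    g$wMsg["gene"] <- g$wMsg["gene"] + sum(dZ * layer$S)
    dS <- params$wMsg["gene"] * dZ
    dH <- params$wSelf["gene"] * dZ + t(layer$Aeff) %*% dS
    if (config$learn_adj) {
      es <- layer$es
      dAeff <- dS %*% t(layer$H)
      dbeta <- config$Kmask[cbind(config$pairI, config$pairJ)] *
        dAeff[cbind(config$pairI, config$pairJ)]
      g$adj$w2 <- g$adj$w2 + drop(crossprod(es$Z1, dbeta))
      g$adj$b2 <- g$adj$b2 + sum(dbeta)
      dpre1 <- (dbeta %o% params$adj$w2) * (1 - es$Z1^2)
      g$adj$W1 <- g$adj$W1 + crossprod(dpre1, es$featt)
      g$adj$b1 <- g$adj$b1 + colSums(dpre1)
      dfeat <- dpre1 %*% params$adj$W1
      d <- config$dim
      accI <- rowsum(dfeat[, seq_len(d), drop = FALSE], config$pairI)
      accJ <- rowsum(dfeat[, d + seq_len(d), drop = FALSE], config$pairJ)
      dH[as.integer(rownames(accI)), ] <-
        dH[as.integer(rownames(accI)), ] + accI
      dH[as.integer(rownames(accJ)), ] <-
        dH[as.integer(rownames(accJ)), ] + accJ
    }
  }
  g$E <- unname(cache$x) * dH
  dx <- rowSums(dH * params$E)
  names(dx) <- rownames(params$E)
  list(grads = g, dx = dx)
}

#' Forward pass: gene inputs to a survival risk score
#'
#' Runs the full network: linear embedding of the gene inputs, the
#' configured rounds of intra-level message passing at each level,
#' masked cross-level propagation gene -> protein -> pathway -> survival,
#' and the linear readout of the survival-node embedding to a scalar risk.
#' Deterministic given the parameters. A gene whose every route to the
#' survival node is masked cannot influence the score.
#'
#' @param hierarchy a \linkS4class{BioHierarchy}
#' @param params,config from [bfregInit()] (or a fitted model's slots)
#' @param inputs named numeric vector covering every gene node
#' @return scalar risk score
#' @examples
#' h <- genHierarchy(10, 4, 2, n_modules = 0, seed = 1)
#' net <- bfregInit(h, dim = 4, seed = 1)
#' x <- setNames(rnorm(10), rownames(h@geneAdj))
#' bfregForward(h, net$params, net$config, x)
#' @export
bfregForward <- function(hierarchy, params, config, inputs) {
  genes <- rownames(hierarchy@geneAdj)
  missing <- setdiff(genes, names(inputs))
  if (length(missing))
    stop("missing gene input(s): ", paste(missing, collapse = ", "))
  .bfregForwardOne(hierarchy, params, config, inputs[genes])$risk
}
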