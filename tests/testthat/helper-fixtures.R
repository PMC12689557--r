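# shared builders for small, fully specified fixtures

# a 3-gene / 2-protein / 1-pathway hierarchy with known wiring
toyHierarchy <- function() {
  buildHierarchy(
    genes = c("g1", "g2", "g3"),
    proteins = c("p1", "p2"),
    pathways = "q1",
    gene_edges = data.frame(source = "g1", target = "g2"),
    gene_to_protein = data.frame(child = c("g1", "g2", "g3"),
                                 parent = c("p1", "p1", "p2")),
    protein_to_pathway = data.frame(child = c("p1", "p2"), parent = "q1"))
}

# deterministic tiny parameter set for the toy hierarchy (d = 2)
toyParams <- function() {
  list(
    E = matrix(c(1, 0.5, -1, 0.2, 0.3, -0.4), 3, 2,
               dimnames = list(c("g1", "g2", "g3"), NULL)),
    wSelf = c(gene = 1, protein = 0.8, pathway = 1.2),
    wMsg = c(gene = 0.5, protein = 0.4, pathway = 0.3),
    W1 = matrix(c(0.6, 0, 0.7, 0, 0, -0.5), 2, 3,
                dimnames = list(c("p1", "p2"), c("g1", "g2", "g3"))),
    b1 = c(0.1, -0.1),
    W2 = matrix(c(0.9, 0.4), 1, 2, dimnames = list("q1", c("p1", "p2"))),
    b2 = 0.05,
    W3 = matrix(1.1, 1, 1), b3 = -0.2,
    v = c(0.7, -0.3), c = 0.15,
    adj = list(W1 = matrix(seq(-0.3, 0.4, length.out = 16), 4, 4),
               b1 = c(0.1, 0, -0.1, 0.2),
               w2 = c(0.5, -0.2, 0.3, 0.1), b2 = 0.4)
  )
}

toyConfig <- function(learn_adj = FALSE, activation = "logistic") {
  A <- toyHierarchy()@geneAdj
  off <- which(row(A) != col(A))
  list(dim = 2, hidden = 4, learn_adj = learn_adj, alpha = 0.005,
       rounds = 1, activation = activation,
       pairI = row(A)[off], pairJ = col(A)[off],
       Kmask = ifelse(A == 1, 1, 0.005) * (row(A) != col(A)))
}

# independent straight-line re-evaluation of the toy network (no shared
# code with the package implementation)
oracleToyForward <- function(x, p, learn_adj = FALSE, alpha = 0.005,
                             activation = "logistic") {
  sig <- function(z) {
    s <- 1 / (1 + exp(-z))
    if (activation == "mix") z + s else s
  }
  H <- rbind(x[1] * p$E[1, ], x[2] * p$E[2, ], x[3] * p$E[3, ])
  A <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)
  if (learn_adj) {
    Aw <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      z1 <- tanh(p$adj$W1 %*% c(H[i, ], H[j, ]) + p$adj$b1)
      beta <- sum(p$adj$w2 * z1) + p$adj$b2
      Aw[i, j] <- if (A[i, j] == 1) beta else alpha * beta
    }
    A <- Aw
  }
  H <- sig(p$wSelf["gene"] * H + p$wMsg["gene"] * (A %*% H))
  M1 <- rbind(c(1, 1, 0), c(0, 0, 1))
  P <- sig((M1 * p$W1) %*% H + p$b1)
  P <- sig(p$wSelf["protein"] * P + p$wMsg["protein"] * (matrix(0, 2, 2) %*% P))
  M2 <- matrix(1, 1, 2)
  Q <- sig((M2 * p$W2) %*% P + p$b2)
  Q <- sig(p$wSelf["pathway"] * Q + p$wMsg["pathway"] * (matrix(0, 1, 1) %*% Q))
  S <- sig(p$W3 %*% Q + p$b3)
  sum(p$v * as.vector(S)) + p$c
}

# a small cohort + hierarchy + trained model, built once per test run and
# reused by the combo-ranking tests (training is the slow part)
smallTrainedModel <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    h <- genHierarchy(n_genes = 20, n_proteins = 10, n_pathways = 4,
                      n_modules = 1, module_size = 6, seed = 7)
    coh <- genCohort(n_tumor = 150, n_normal = 0, n_genes = 20,
                     n_prognostic = 6, seed = 7)
    fit <- bfregTrain(h, coh, config = list(epochs = 15, lr = 4e-4,
                                            dim = 8, seed = 7))
    cache <<- list(hierarchy = h, cohort = coh, model = fit)
    cache
  }
})
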