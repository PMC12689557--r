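test_that("embeddings are linear in the input value", {
  E <- rbind(a = c(1, 2), b = c(-0.5, 0.3), c = c(0.2, 0.1))
  expect_equal(initEmbeddings(c(a = 0, b = 0, c = 0), E),
               matrix(0, 3, 2, dimnames = dimnames(E)))
  h1 <- initEmbeddings(c(a = 1, b = 2, c = -1), E)
  h2 <- initEmbeddings(c(a = 2, b = 4, c = -2), E)
  expect_equal(h2, 2 * h1)
  expect_equal(unname(h1[2, ]), 2 * c(-0.5, 0.3), tolerance = 1e-12)
})

test_that("message passing: no neighbours, hand-computed 2-node, equivariance", {
  H <- rbind(c(0.4), c(-0.2))
  empty <- matrix(0, 2, 2)
  expect_equal(messagePass(H, empty, w_self = 1.3, w_msg = 9),
               1 / (1 + exp(-1.3 * H)), tolerance = 1e-12)
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  out <- messagePass(H, A, w_self = 2, w_msg = 0.5)
  expect_equal(out[1, 1], 1 / (1 + exp(-(2 * 0.4 + 0.5 * -0.2))),
               tolerance = 1e-12)
  expect_equal(out[2, 1], 1 / (1 + exp(-(2 * -0.2 + 0.5 * 0.4))),
               tolerance = 1e-12)
  # permutation equivariance on a random graph
  set.seed(1)
  H3 <- matrix(rnorm(12), 4, 3)
  A3 <- matrix(rbinom(16, 1, 0.5), 4, 4); diag(A3) <- 0
  p <- c(3, 1, 4, 2)
  out1 <- messagePass(H3, A3, 1, 0.7)[p, ]
  out2 <- messagePass(H3[p, ], A3[p, p], 1, 0.7)
  expect_equal(out1, out2, tolerance = 1e-12)
})

test_that("cross-level propagation masks absent relations exactly", {
  X <- rbind(c(1, 2), c(3, 4))
  M <- matrix(c(1, 0), 1, 2)
  W <- matrix(c(2, 5), 1, 2)
  b <- 0.3
  out <- crossLevelPropagate(X, M, W, b)
  expect_equal(drop(out), 1 / (1 + exp(-(2 * X[1, ] + 0.3))),
               tolerance = 1e-12)
  # a parameter at a masked position cannot change anything
  W2 <- W; W2[1, 2] <- -1e6
  expect_identical(out, crossLevelPropagate(X, M, W2, b))
  # all-zero map: every output is sigma(b)
  out0 <- crossLevelPropagate(X, matrix(0, 2, 2), matrix(1, 2, 2), c(0.1, -0.2))
  expect_equal(out0, cbind(1 / (1 + exp(-c(0.1, -0.2))),
                           1 / (1 + exp(-c(0.1, -0.2)))), tolerance = 1e-12)
})

test_that("learnable adjacency applies the absent-edge penalty and the MLP", {
  # forced arithmetic: beta = 0.8 on a present and an absent edge
  H <- rbind(c(1, 0), c(0, 1))
  mlp <- list(W1 = matrix(0, 2, 4), b1 = c(10, 10), w2 = c(0.4, 0.4), b2 = 0)
  # tanh(10) ~ 1 -> beta = 0.8 for every pair
  A1 <- matrix(c(0, 1, 1, 0), 2, 2)
  W <- learnableAdjacency(H, A1, mlp)
  expect_equal(W[1, 2], 0.8, tolerance = 1e-6)
  A0 <- matrix(0, 2, 2)
  W0 <- learnableAdjacency(H, A0, mlp)
  expect_equal(W0[1, 2], 0.004, tolerance = 1e-8)   # alpha * beta
  expect_equal(diag(W0), c(0, 0))
  # hand-computed two-layer perceptron on fixture embeddings
  p <- toyParams()
  Hf <- rbind(c(0.3, -0.1), c(0.2, 0.5), c(-0.4, 0.1))
  A <- toyHierarchy()@geneAdj
  Wf <- learnableAdjacency(Hf, A, p$adj)
  z1 <- tanh(p$adj$W1 %*% c(Hf[1, ], Hf[2, ]) + p$adj$b1)
  beta12 <- sum(p$adj$w2 * z1) + p$adj$b2
  expect_equal(unname(Wf["g1", "g2"]), beta12, tolerance = 1e-10)
  z1 <- tanh(p$adj$W1 %*% c(Hf[1, ], Hf[3, ]) + p$adj$b1)
  expect_equal(unname(Wf["g1", "g3"]),
               0.005 * (sum(p$adj$w2 * z1) + p$adj$b2), tolerance = 1e-10)
})

test_that("forward pass matches an independently coded evaluation", {
  h <- toyHierarchy()
  p <- toyParams()
  x <- c(g1 = 0.7, g2 = -1.2, g3 = 0.4)
  for (act in c("logistic", "mix")) {
    for (la in c(FALSE, TRUE)) {
      cfg <- toyConfig(learn_adj = la, activation = act)
      expect_equal(bfregForward(h, p, cfg, x),
                   oracleToyForward(x, p, learn_adj = la, activation = act),
                   tolerance = 1e-10)
    }
  }
  expect_error(bfregForward(h, p, toyConfig(), c(g1 = 1, g2 = 2)), "g3")
})

test_that("all-zero inputs give the closed-form bias-only score", {
  h <- toyHierarchy()
  p <- toyParams()
  cfg <- toyConfig(learn_adj = FALSE, activation = "logistic")
  sig <- function(z) 1 / (1 + exp(-z))
  # H0 = 0 -> gene level sigma(0) = 1/2 everywhere, then biased chain
  Hg <- matrix(0.5, 3, 2)
  P <- sig((rbind(c(1, 1, 0), c(0, 0, 1)) * p$W1) %*% Hg + p$b1)
  P <- sig(p$wSelf["protein"] * P)
  Q <- sig((matrix(1, 1, 2) * p$W2) %*% P + p$b2)
  Q <- sig(p$wSelf["pathway"] * Q)
  S <- sig(p$W3 %*% Q + p$b3)
  expect_equal(bfregForward(h, p, cfg, c(g1 = 0, g2 = 0, g3 = 0)),
               sum(p$v * drop(S)) + p$c, tolerance = 1e-12)
})

test_that("a gene with every route masked cannot influence the score", {
  # g4 is isolated: no intra-level edges, no protein parent
  h <- buildHierarchy(
    genes = c("g1", "g2", "g3", "g4"), proteins = c("p1", "p2"),
    pathways = "q1",
    gene_edges = data.frame(source = "g1", target = "g2"),
    gene_to_protein = data.frame(child = c("g1", "g2", "g3"),
                                 parent = c("p1", "p1", "p2")),
    protein_to_pathway = data.frame(child = c("p1", "p2"), parent = "q1"))
  net <- bfregInit(h, dim = 3, learn_adj = FALSE, seed = 2)
  net$params$v <- rnorm(3)   # non-zero readout so the score is informative
  x <- c(g1 = 1, g2 = -1, g3 = 0.5, g4 = 0)
  x2 <- x; x2["g4"] <- 1e3
  expect_identical(bfregForward(h, net$params, net$config, x),
                   bfregForward(h, net$params, net$config, x2))
  # masked cross-level parameter positions are inert too
  p2 <- net$params
  p2$W1["p2", "g1"] <- 1e6   # M1[p2, g1] = 0
  expect_identical(bfregForward(h, net$params, net$config, x),
                   bfregForward(h, p2, net$config, x))
})

test_that("Cox loss: closed form at zero scores, 2-subject form, shift invariance", {
  time <- c(3, 1, 2, 5, 4)
  event <- c(1, 1, 0, 1, 1)
  H0 <- numeric(5)
  # |R_i| at the event times 1, 3, 4, 5 are 5, 3, 2, 1
  expect_equal(coxLoss(H0, time, event), log(5) + log(3) + log(2) + log(1),
               tolerance = 1e-12)
  h12 <- c(1, 0)
  expect_equal(coxLoss(h12, time = c(1, 2), event = c(1, 1)),
               -(1 - log(exp(1) + exp(0))) - (0 - log(exp(0))),
               tolerance = 1e-12)
  H <- rnorm(5)
  expect_equal(coxLoss(H, time, event), coxLoss(H + 100, time, event),
               tolerance = 1e-8)
  expect_error(coxLoss(H0, time, rep(0, 5)), "event")
})

test_that("Cox loss gradient vanishes along covariates at the coxFit optimum", {
  coh <- genCohort(120, 0, 4, n_prognostic = 2, seed = 19)
  sv <- survivalData(coh)
  X <- t(log2(exprMatrix(coh) + 1))[sv$sample, ]
  fit <- coxFit(sv, X)
  H <- as.vector(fit$X %*% fit$coef)   # fit$X is the centered design
  g <- SynergyScreen:::.coxLossGrad(H, sv$time, sv$event)$grad
  expect_lt(max(abs(crossprod(fit$X, g))), 1e-6)
})

test_that("concordance index equals brute-force enumeration on random fixtures", {
  bruteCIndex <- function(s, t, e) {
    num <- den <- 0
    n <- length(s)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (t[i] < t[j] && e[i] == 1) {
        den <- den + 1
        if (s[i] > s[j]) num <- num + 1
        else if (s[i] == s[j]) num <- num + 0.5
      }
    }
    if (den == 0) stop("no comparable pairs")
    num / den
  }
  expect_equal(concordanceIndex(c(3, 2, 1), 1:3, rep(1, 3)), 1)
  expect_equal(concordanceIndex(rep(1, 4), 1:4, rep(1, 4)), 0.5)
  set.seed(99)
  for (k in 1:100) {
    n <- sample(4:12, 1)
    s <- sample(round(rnorm(n), 1))     # rounded -> score ties occur
    t <- sample(n)
    e <- rbinom(n, 1, 0.7)
    if (sum(e[t < max(t)]) == 0) next
    expect_identical(concordanceIndex(s, t, e), bruteCIndex(s, t, e))
  }
})

test_that("analytic gradients match finite differences", {
  h <- genHierarchy(n_genes = 7, n_proteins = 4, n_pathways = 2,
                    n_modules = 1, module_size = 3, edge_density = 0.4,
                    seed = 3)
  x <- setNames(rnorm(7), rownames(h@geneAdj))
  for (act in c("logistic", "mix")) {
    net <- bfregInit(h, dim = 3, hidden = 3, learn_adj = TRUE,
                     activation = act, seed = 5)
    net$params$v <- rnorm(3)   # non-trivial readout
    fw <- SynergyScreen:::.bfregForwardOne(h, net$params, net$config, x,
                                           keep = TRUE)
    bk <- SynergyScreen:::.bfregBackwardOne(h, net$params, net$config,
                                            fw$cache, 1)
    eps <- 1e-6
    # inputs
    num_dx <- vapply(seq_along(x), function(i) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      (bfregForward(h, net$params, net$config, xp) -
         bfregForward(h, net$params, net$config, xm)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(unname(bk$dx) - num_dx)), 1e-7 * (1 + max(abs(num_dx))))
    # a representative subset of every parameter block
    v0 <- unlist(net$params)
    g_ana <- unlist(bk$grads)
    restore <- function(tpl, val) {
      if (is.list(tpl)) return(Map(restore, tpl, val))
      v <- unlist(val); attributes(v) <- attributes(tpl); v
    }
    fobj <- function(vec) {
      p <- restore(net$params, utils::relist(vec, net$params))
      bfregForward(h, p, net$config, x)
    }
    idx <- round(seq(1, length(v0), length.out = 40))
    g_num <- vapply(idx, function(i) {
      vp <- v0; vp[i] <- vp[i] + eps
      vm <- v0; vm[i] <- vm[i] - eps
      (fobj(vp) - fobj(vm)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(unname(g_ana[idx]) - g_num)), 1e-6 * (1 + max(abs(g_num))))
  }
})

test_that("training is reproducible and reports a sensible history", {
  h <- genHierarchy(n_genes = 12, n_proteins = 6, n_pathways = 3,
                    n_modules = 1, module_size = 4, seed = 2)
  coh <- genCohort(60, 0, 12, n_prognostic = 4, seed = 2)
  f1 <- bfregTrain(h, coh, config = list(epochs = 4, dim = 4, seed = 9))
  f2 <- bfregTrain(h, coh, config = list(epochs = 4, dim = 4, seed = 9))
  expect_identical(f1@history, f2@history)
  expect_identical(f1@params, f2@params)
  expect_equal(nrow(f1@history), 4)
  expect_true(all(is.finite(f1@history$val_loss)))
  expect_setequal(colnames(f1@history), c("epoch", "train_loss", "val_loss"))
  expect_length(f1@valSamples, 12)   # 20% of 60
})

test_that("a zero-signal cohort trains to chance-level concordance", {
  h <- genHierarchy(n_genes = 20, n_proteins = 10, n_pathways = 4,
                    n_modules = 0, seed = 3)
  coh <- genCohort(300, 0, 20, n_prognostic = 0, seed = 3)
  fit <- bfregTrain(h, coh, config = list(epochs = 8, dim = 8, seed = 3))
  expect_lt(abs(fit@valCIndex - 0.5), 0.1)
})

test_that("integrated gradients: zero at the baseline, first-order, complete", {
  sm <- smallTrainedModel()
  genes <- rownames(sm$hierarchy@geneAdj)
  x0 <- setNames(numeric(20), genes)
  expect_equal(unname(integratedGradients(sm$model, x0, x0, steps = 8)),
               numeric(20))
  set.seed(4)
  x <- setNames(rnorm(20), genes)
  # completeness: sum of attributions telescopes to F(x) - F(x0)
  ig <- integratedGradients(sm$model, x, x0, steps = 512)
  fcfg <- SynergyScreen:::.forwardConfig(sm$model)
  fx <- bfregForward(sm$hierarchy, sm$model@params, fcfg, x)
  f0 <- bfregForward(sm$hierarchy, sm$model@params, fcfg, x0)
  expect_lt(abs(sum(ig) - (fx - f0)), 1e-3)
  # near-linear regime: IG of a tiny displacement equals grad . dx
  dx <- setNames(rep(1e-4, 20), genes)
  ig_small <- integratedGradients(sm$model, x0 + dx, x0, steps = 4)
  fw <- SynergyScreen:::.bfregForwardOne(sm$hierarchy, sm$model@params,
                                         fcfg, x0, keep = TRUE)
  g0 <- SynergyScreen:::.bfregBackwardOne(sm$hierarchy, sm$model@params,
                                          fcfg, fw$cache, 1)$dx
  expect_equal(unname(ig_small), unname(g0 * 1e-4), tolerance = 1e-3)
})
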