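#' Cox partial-likelihood loss over a batch of risk scores
#'
#' `L = -sum_{i: event} (H_i - log sum_{j: t_j >= t_i} exp(H_j))`, computed
#' with a max-shift inside the log-sum-exp so it is numerically stable, and
#' invariant to adding a constant to every score. The sum runs over events
#' only; the risk set is all samples still under observation at the event
#' time (Breslow convention for ties).
#'
#' @param scores per-sample risk scores
#' @param time,event observed times and event indicators (1 = event)
#' @return scalar loss
#' @examples
#' coxLoss(c(0, 0, 0), time = c(1, 2, 3), event = c(1, 1, 1))
#' # = log(3) + log(2) + log(1)
#' @export
coxLoss <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  if (sum(event) < 1) stop("Cox loss needs at least one event")
  m <- max(scores)
  w <- exp(scores - m)
  ev <- which(event == 1)
  denom <- vapply(ev, function(i) sum(w[time >= time[i]]), numeric(1))
  -sum((scores[ev] - m) - log(denom))
}

# loss and gradient with respect to the scores (same definition as coxLoss)
.coxLossGrad <- function(scores, time, event) {
  m <- max(scores)
  w <- exp(scores - m)
  ev <- which(event == 1)
  denom <- vapply(ev, function(i) sum(w[time >= time[i]]), numeric(1))
  loss <- -sum((scores[ev] - m) - log(denom))
  grad <- -as.numeric(event == 1)
  for (k in seq_along(ev)) {
    inset <- time >= time[ev[k]]
    grad[inset] <- grad[inset] + w[inset] / denom[k]
  }
  list(loss = loss, grad = grad)
}

#' Concordance index for censored survival data
#'
#' Fraction of comparable sample pairs whose predicted risk ordering
#' matches the observed survival ordering. A pair is comparable when the
#' shorter observed time ends in an event; it is concordant when that
#' sample has the higher risk score, and score ties count 1/2. Equals
#' brute-force enumeration of all pairs.
#'
#' @param scores per-sample risk scores (higher = higher risk)
#' @param time,event observed times and event indicators
#' @return fraction in `[0, 1]`
#' @examples
#' concordanceIndex(c(3, 2, 1), time = c(1, 2, 3), event = c(1, 1, 1))
#' @export
concordanceIndex <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  shorter <- outer(time, time, "<")              # [i, j]: t_i < t_j
  comparable <- shorter & (event == 1)           # row i is the event
  nc <- sum(comparable)
  if (nc == 0) stop("no comparable pairs")
  hi <- outer(scores, scores, ">")
  tie <- outer(scores, scores, "==")
  (sum(hi & comparable) + 0.5 * sum(tie & comparable)) / nc
}

.adamInit <- function(params)
  list(m = .zeroGrads(params), v = .zeroGrads(params), t = 0)

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  t <- state$t + 1
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(step, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  out <- step(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

.addGrads <- function(a, b) {
  Map(function(x, y) if (is.list(x)) .addGrads(x, y) else x + y, a, b)
}

.scaleGrads <- function(a, s) rapply(a, function(x) x * s, how = "replace")

#' Train the hierarchical survival network
#'
#' Splits the tumor samples into train/validation by a seeded shuffle,
#' standardizes `log2(expr + 1)` per gene, and minimizes the Cox
#' partial-likelihood loss (risk sets formed within each minibatch, or over
#' the whole set with `full_risk_set = TRUE`) with Adam. Training stops
#' early when the validation loss has not improved for `patience` epochs;
#' the parameters with the best validation loss are kept. The training
#' report records per-epoch train/validation loss and the final held-out
#' concordance index.
#'
#' @param hierarchy a \linkS4class{BioHierarchy} whose genes are (a subset
#'   of) the cohort's genes
#' @param cohort a \linkS4class{SyntheticCohort} (tumor samples are used)
#' @param config list overriding any of: `lr` (1e-4), `batch` (32),
#'   `epochs` (200), `train_frac` (0.8), `patience` (10), `dim` (16),
#'   `hidden` (8), `learn_adj` (TRUE), `alpha` (0.005), `rounds` (1),
#'   `activation` ("mix"), `full_risk_set` (FALSE), `seed` (1)
#' @return a \linkS4class{BFRegModel}
#' @examples
#' \donttest{
#' h <- genHierarchy(20, 8, 3, n_modules = 1, module_size = 5, seed = 1)
#' coh <- genCohort(80, 0, 20, n_prognostic = 5, seed = 1)
#' fit <- bfregTrain(h, coh, config = list(epochs = 3, dim = 4))
#' }
#' @export
bfregTrain <- function(hierarchy, cohort, config = list()) {
  cfg <- modifyList(list(lr = 1e-4, batch = 32, epochs = 200,
                         train_frac = 0.8, patience = 10, dim = 16,
                         hidden = 8, learn_adj = TRUE, alpha = 0.005,
                         rounds = 1, activation = "mix",
                         full_risk_set = FALSE, seed = 1),
                    config)
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1)
    stop("train_frac must be in (0, 1)")
  genes <- rownames(hierarchy@geneAdj)
  ex <- exprMatrix(cohort)
  if (!all(genes %in% rownames(ex)))
    stop("cohort is missing hierarchy genes")
  sv <- survivalData(cohort)
  if (!nrow(sv)) stop("cohort has no survival outcomes")

  lx <- log2(ex[genes, sv$sample, drop = FALSE] + 1)
  mu <- rowMeans(lx)
  sdv <- apply(lx, 1, sd)
  sdv[sdv == 0] <- 1
  Z <- (lx - mu) / sdv

  rng <- .localRNG(cfg$seed)
  on.exit(rng$restore(), add = TRUE)

  n <- nrow(sv)
  perm <- sample.int(n)
  ntr <- max(1, round(cfg$train_frac * n))
  tr <- perm[seq_len(ntr)]
  va <- perm[-seq_len(ntr)]
  if (!length(va)) stop("validation split is empty; lower train_frac")

  net <- bfregInit(hierarchy, dim = cfg$dim, hidden = cfg$hidden,
                   learn_adj = cfg$learn_adj, alpha = cfg$alpha,
                   rounds = cfg$rounds, activation = cfg$activation,
                   seed = sample.int(.Machine$integer.max, 1))
  params <- net$params
  fcfg <- net$config
  adam <- .adamInit(params)

  riskOf <- function(idx, params) {
    vapply(idx, function(i)
      .bfregForwardOne(hierarchy, params, fcfg, Z[, i])$risk, numeric(1))
  }
  valLoss <- function(params) {
    s <- riskOf(va, params)
    coxLoss(s, sv$time[va], sv$event[va]) / max(1, sum(sv$event[va]))
  }

  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- NULL
  wait <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(tr)
    nb <- ceiling(length(ord) / cfg$batch)
    eploss <- 0; epev <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * cfg$batch + 1):min(b * cfg$batch, length(ord))]
      if (sum(sv$event[idx]) < 1) next
      caches <- lapply(idx, function(i)
        .bfregForwardOne(hierarchy, params, fcfg, Z[, i], keep = TRUE))
      scores <- vapply(caches, `[[`, numeric(1), "risk")
      lg <- if (cfg$full_risk_set) {
        # risk sets over the whole training split: recompute all scores
        all_s <- riskOf(tr, params)
        all_s[match(idx, tr)] <- scores
        gfull <- .coxLossGrad(all_s, sv$time[tr], sv$event[tr])
        list(loss = gfull$loss, grad = gfull$grad[match(idx, tr)])
      } else .coxLossGrad(scores, sv$time[idx], sv$event[idx])
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; lower the learning rate")
      nev <- if (cfg$full_risk_set) sum(sv$event[tr]) else sum(sv$event[idx])
      grads <- NULL
      for (k in seq_along(idx)) {
        bk <- .bfregBackwardOne(hierarchy, params, fcfg, caches[[k]]$cache,
                                lg$grad[k] / nev)
        grads <- if (is.null(grads)) bk$grads else .addGrads(grads, bk$grads)
      }
      st <- .adamStep(params, grads, adam, lr = cfg$lr)
      params <- st$params
      adam <- st$state
      eploss <- eploss + lg$loss
      epev <- epev + nev
    }
    vl <- valLoss(params)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = eploss / max(1, epev),
                                   val_loss = vl))
    if (vl < best$loss - 1e-10) {
      best <- list(loss = vl, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  params <- best$params
  vscores <- riskOf(va, params)
  ci <- concordanceIndex(vscores, sv$time[va], sv$event[va])
  methods::new("BFRegModel",
    hierarchy = hierarchy, params = params,
    config = c(fcfg[c("dim", "hidden", "learn_adj", "alpha", "rounds",
                      "activation")],
               cfg[c("lr", "batch", "epochs", "train_frac", "patience",
                     "full_risk_set", "seed")]),
    standardize = list(mean = mu, sd = sdv),
    history = hist, valCIndex = ci, valSamples = sv$sample[va])
}

#' Predict risk scores for expression profiles
#'
#' Applies the model's stored standardization (`log2(expr + 1)`, per-gene
#' z-score) and the forward pass to each column of `expr`.
#'
#' @param model a \linkS4class{BFRegModel}
#' @param expr genes x samples matrix on the expression (TPM-like) scale,
#'   containing at least the hierarchy's genes
#' @return named numeric vector of risk scores
#' @export
predictRisk <- function(model, expr) {
  genes <- rownames(model@hierarchy@geneAdj)
  if (!all(genes %in% rownames(expr)))
    stop("expression matrix is missing hierarchy genes")
  lx <- log2(expr[genes, , drop = FALSE] + 1)
  Z <- (lx - model@standardize$mean) / model@standardize$sd
  fcfg <- .forwardConfig(model)
  vapply(seq_len(ncol(Z)), function(i)
    .bfregForwardOne(model@hierarchy, model@params, fcfg, Z[, i])$risk,
    numeric(1)) |> setNames(colnames(expr))
}

# rebuild the pair-index cache the forward pass needs from a fitted model
.forwardConfig <- function(model) {
  A <- model@hierarchy@geneAdj
  off <- which(row(A) != col(A))
  c(model@config[c("dim", "hidden", "learn_adj", "alpha", "rounds",
                   "activation")],
    list(pairI = row(A)[off], pairJ = col(A)[off],
         Kmask = ifelse(A == 1, 1, model@config$alpha) * (row(A) != col(A))))
}

#' Integrated-gradients attribution of the risk score to gene inputs
#'
#' `IG_g = (x_g - x0_g) * mean_k dF/dx_g` evaluated along the straight path
#' `x0 + (k/steps) * (x - x0)`, `k = 1..steps`. For a linear score this is
#' exact at any number of steps, and the completeness identity
#' `sum_g IG_g -> F(x) - F(x0)` holds as `steps` grows. Inputs are on the
#' network's standardized scale (see [predictRisk()] for the raw-expression
#' pipeline).
#'
#' @param model a \linkS4class{BFRegModel}
#' @param input named gene vector (network input scale)
#' @param baseline reference gene vector (default all zero)
#' @param steps path resolution (default 64)
#' @return named per-gene attribution vector
#' @export
integratedGradients <- function(model, input, baseline = NULL, steps = 64) {
  stopifnot(steps >= 1)
  genes <- rownames(model@hierarchy@geneAdj)
  x <- input[genes]
  x0 <- if (is.null(baseline)) setNames(numeric(length(genes)), genes)
        else baseline[genes]
  fcfg <- .forwardConfig(model)
  acc <- numeric(length(genes))
  for (k in seq_len(steps)) {
    xs <- x0 + (k / steps) * (x - x0)
    fw <- .bfregForwardOne(model@hierarchy, model@params, fcfg, xs, keep = TRUE)
    bk <- .bfregBackwardOne(model@hierarchy, model@params, fcfg, fw$cache, 1)
    if (!all(is.finite(bk$dx))) stop("non-finite gradient along the path")
    acc <- acc + bk$dx
  }
  setNames((x - x0) * acc / steps, genes)
}
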