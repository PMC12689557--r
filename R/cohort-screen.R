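#' Differential-expression screen (Welch t-test, BH adjustment)
#'
#' Per-gene Welch two-sample t-test of tumor versus normal on log2
#' expression, Benjamini-Hochberg adjustment, and a direction call:
#' `up`/`down` when both `|log2FC| > fc_threshold` and
#' `adjusted_p < p_threshold` hold, `ns` otherwise. A gene with zero
#' variance in both groups gets p = 1 and is flagged.
#'
#' @param cohort a \linkS4class{SyntheticCohort} (or any object with
#'   [exprMatrix()] and [groupLabels()] methods)
#' @param fc_threshold absolute log2 fold-change threshold (default 1)
#' @param p_threshold adjusted-p threshold (default 0.05)
#' @param pseudocount added before log2 (default 0; expression must then be
#'   strictly positive)
#' @return data.frame: gene, log2FC (tumor minus normal mean of log2),
#'   p_value, adjusted_p, direction, zero_variance
#' @examples
#' coh <- genCohort(20, 20, 100, n_deg = 10, seed = 1)
#' deg <- differentialExpression(coh)
#' table(deg$direction)
#' @export
differentialExpression <- function(cohort, fc_threshold = 1,
                                   p_threshold = 0.05, pseudocount = 0) {
  x <- exprMatrix(cohort) + pseudocount
  if (any(x <= 0))
    stop("expression must be positive on the log scale; set pseudocount > 0")
  g <- groupLabels(cohort)
  it <- g == "tumor"; inn <- g == "normal"
  if (sum(it) < 2 || sum(inn) < 2)
    stop("need at least two samples per group")
  lx <- log2(x)
  welchRows(lx[, it, drop = FALSE], lx[, inn, drop = FALSE],
            fc_threshold = fc_threshold, p_threshold = p_threshold,
            id_col = "gene")
}

# vectorized per-row Welch t-test of x (group 1) vs y (group 2) on the rows
welchRows <- function(x, y, fc_threshold, p_threshold, id_col = "feature") {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  lfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  zerovar <- se2 == 0
  tstat <- ifelse(zerovar, 0, lfc / sqrt(se2))
  df <- ifelse(zerovar, 1,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))))
  p <- ifelse(zerovar, 1, 2 * pt(abs(tstat), df = df, lower.tail = FALSE))
  padj <- p.adjust(p, method = "BH")
  hit <- abs(lfc) > fc_threshold & padj < p_threshold
  dir <- ifelse(!hit, "ns", ifelse(lfc > 0, "up", "down"))
  out <- data.frame(id = rownames(x), log2FC = lfc, p_value = p,
                    adjusted_p = padj, direction = dir,
                    zero_variance = zerovar, row.names = NULL)
  names(out)[1] <- id_col
  out
}

#' Cox proportional-hazards fit (Breslow partial likelihood)
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with
#' step-halving (the log partial likelihood never decreases across
#' iterations), declaring convergence when `max |score| < 1e-8` or after
#' `max_iter` iterations. Standard errors come from the inverse observed
#' information; Wald 95% confidence intervals and `AIC = 2k - 2 logPL` are
#' reported. Constant covariates are dropped with a warning; a coefficient
#' walking beyond `|beta| > 15` is treated as monotone likelihood (perfect
#' separation), capped and flagged.
#'
#' @param survival data.frame with columns `time` and `event` (1 = event)
#' @param covariates numeric matrix, samples in rows aligned with
#'   `survival` rows; column names identify the genes/covariates
#' @param max_iter Newton iteration cap (default 100)
#' @param tol score convergence tolerance (default 1e-8)
#' @return object of class `coxFit`: list with `coef`, `se`, `hr`,
#'   `ci_lower`, `ci_upper` (hazard-ratio scale), `logPL`, `AIC`,
#'   `iterations`, `logPL_trace`, `converged`, `flags`, plus the data used
#' @examples
#' coh <- genCohort(100, 0, 10, n_prognostic = 2, seed = 1)
#' sv <- survivalData(coh)
#' X <- t(log2(exprMatrix(coh)))[sv$sample, 1:3]
#' coxFit(sv, X)$coef
#' @export
coxFit <- function(survival, covariates, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(covariates)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  time <- survival$time; event <- survival$event
  stopifnot(length(time) == nrow(X), all(is.finite(X)))
  if (sum(event) < 1) stop("need at least one event")

  keep <- apply(X, 2, function(v) var(v) > 0)
  if (any(!keep)) {
    warning("dropping constant covariates: ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  k <- ncol(X)
  if (k == 0) {
    ll0 <- coxLogPL(numeric(0), X, time, event)
    return(structure(list(coef = numeric(0), se = numeric(0), hr = numeric(0),
                          ci_lower = numeric(0), ci_upper = numeric(0),
                          logPL = ll0, AIC = -2 * ll0, iterations = 0L,
                          logPL_trace = ll0, converged = TRUE,
                          flags = character(0),
                          time = time, event = event, X = X),
                     class = "coxFit"))
  }
  # center covariates for numerical stability; beta is unaffected
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)

  beta <- numeric(k)
  ll <- coxLogPL(beta, Xc, time, event)
  trace <- ll
  flags <- character(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d <- coxDerivatives(beta, Xc, time, event)
    if (max(abs(d$score)) < tol) { converged <- TRUE; iter <- iter - 1L; break }
    step <- tryCatch(solve(d$info, d$score),
                     error = function(e) d$score / (max(diag(d$info)) + 1e-12))
    # step-halving: never accept a decrease of the log partial likelihood
    h <- 1
    repeat {
      cand <- beta + h * step
      llc <- coxLogPL(cand, Xc, time, event)
      if (llc >= ll - 1e-12 || h < 1e-8) break
      h <- h / 2
    }
    beta <- cand; ll <- llc
    trace <- c(trace, ll)
    if (any(abs(beta) > 15)) {
      flags <- c(flags, "monotone_likelihood")
      beta <- pmin(pmax(beta, -15), 15)
      warning("monotone likelihood detected; coefficient capped at |15|")
      ll <- coxLogPL(beta, Xc, time, event)
      break
    }
  }
  d <- coxDerivatives(beta, Xc, time, event)
  if (max(abs(d$score)) < tol) converged <- TRUE
  se <- sqrt(diag(solve(d$info)))
  ci_l <- beta - qnorm(0.975) * se
  ci_u <- beta + qnorm(0.975) * se
  structure(list(
    coef = setNames(beta, colnames(X)), se = setNames(se, colnames(X)),
    hr = setNames(exp(beta), colnames(X)),
    ci_lower = setNames(exp(ci_l), colnames(X)),
    ci_upper = setNames(exp(ci_u), colnames(X)),
    logPL = ll, AIC = 2 * k - 2 * ll, iterations = iter,
    logPL_trace = trace, converged = converged, flags = flags,
    time = time, event = event, X = Xc), class = "coxFit")
}

#' @export
print.coxFit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow):",
      length(x$coef), "covariate(s),", sum(x$event), "events\n")
  if (length(x$coef)) {
    tab <- data.frame(coef = x$coef, HR = x$hr, lower95 = x$ci_lower,
                      upper95 = x$ci_upper, se = x$se)
    print(round(tab, 4))
  }
  cat("logPL:", format(x$logPL, digits = 6), " AIC:",
      format(x$AIC, digits = 6), " iterations:", x$iterations, "\n")
  invisible(x)
}

# Breslow log partial likelihood; risk set = {j : time_j >= time_i}
coxLogPL <- function(beta, X, time, event) {
  eta <- if (length(beta)) as.vector(X %*% beta) else numeric(length(time))
  m <- max(eta)
  # iterate event times in decreasing order, accumulating the risk-set sum
  o <- order(time, decreasing = TRUE)
  cum <- 0
  ll <- 0
  i <- 1
  n <- length(time)
  while (i <= n) {
    # add all subjects tied at this time to the risk set first
    tt <- time[o[i]]
    j <- i
    while (j <= n && time[o[j]] == tt) {
      cum <- cum + exp(eta[o[j]] - m)
      j <- j + 1
    }
    for (kk in i:(j - 1)) {
      oi <- o[kk]
      if (event[oi] == 1) ll <- ll + (eta[oi] - m) - log(cum)
    }
    i <- j
  }
  ll
}

# score vector and observed information of the Breslow partial likelihood
coxDerivatives <- function(beta, X, time, event) {
  n <- nrow(X); k <- ncol(X)
  eta <- as.vector(X %*% beta)
  m <- max(eta)
  w <- exp(eta - m)
  o <- order(time, decreasing = TRUE)
  S0 <- 0
  S1 <- numeric(k)
  S2 <- matrix(0, k, k)
  score <- numeric(k)
  info <- matrix(0, k, k)
  i <- 1
  while (i <= n) {
    tt <- time[o[i]]
    j <- i
    while (j <= n && time[o[j]] == tt) {
      oi <- o[j]
      S0 <- S0 + w[oi]
      S1 <- S1 + w[oi] * X[oi, ]
      S2 <- S2 + w[oi] * tcrossprod(X[oi, ])
      j <- j + 1
    }
    for (kk in i:(j - 1)) {
      oi <- o[kk]
      if (event[oi] == 1) {
        xbar <- S1 / S0
        score <- score + X[oi, ] - xbar
        info <- info + S2 / S0 - tcrossprod(xbar)
      }
    }
    i <- j
  }
  list(score = score, info = info)
}

#' Stepwise AIC selection over a Cox model
#'
#' Greedy stepwise search minimizing AIC, starting (backward) from the full
#' candidate model or (forward) from the null model. Candidates are
#' processed in sorted-id order and AIC ties are broken toward the smaller
#' model, so the search is deterministic. The winner's AIC never exceeds the
#' AIC of the full or the null model.
#'
#' @param survival data.frame with `time`, `event`
#' @param covariates samples x candidates matrix (column names = gene ids)
#' @param direction `"backward"` (default) or `"forward"`
#' @return list: `model` (the winning [coxFit()]), `selected` (gene ids),
#'   `path` (data.frame of visited steps with AIC), `aic_null`, `aic_full`
#' @examples
#' coh <- genCohort(150, 0, 8, n_prognostic = 2, seed = 11)
#' sv <- survivalData(coh)
#' X <- t(log2(exprMatrix(coh)))[sv$sample, ]
#' stepwiseCox(sv, X)$selected
#' @export
stepwiseCox <- function(survival, covariates, direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  X <- as.matrix(covariates)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  cand <- sort(colnames(X))
  if (!length(cand)) stop("candidate set must be nonempty")
  if (sum(survival$event) <= length(cand))
    warning("fewer events than candidate covariates; selection may be unstable")
  fitAIC <- function(sel) {
    f <- coxFit(survival, X[, sel, drop = FALSE])
    list(fit = f, aic = f$AIC)
  }
  nullFit <- fitAIC(character(0))
  fullFit <- fitAIC(cand)
  cur_sel <- if (direction == "backward") cand else character(0)
  cur <- if (direction == "backward") fullFit else nullFit
  path <- data.frame(step = 0L, action = "start",
                     k = length(cur_sel), AIC = cur$aic)
  step <- 0L
  repeat {
    step <- step + 1L
    moves <- if (direction == "backward") cur_sel else setdiff(cand, cur_sel)
    if (!length(moves)) break
    best <- NULL
    for (g in moves) {     # sorted-id order: moves inherits cand's order
      sel <- if (direction == "backward") setdiff(cur_sel, g) else
        sort(c(cur_sel, g))
      f <- fitAIC(sel)
      better <- if (is.null(best)) TRUE else f$aic < best$aic - 1e-12
      if (better) best <- list(sel = sel, fit = f$fit, aic = f$aic, move = g)
    }
    # accept only strict improvement; ties go to the smaller model, which
    # for backward means dropping on a tie and for forward means stopping
    accept <- if (direction == "backward") best$aic <= cur$aic + 1e-12
      else best$aic < cur$aic - 1e-12
    if (!accept) break
    cur_sel <- best$sel
    cur <- list(fit = best$fit, aic = best$aic)
    path <- rbind(path, data.frame(
      step = step,
      action = paste(if (direction == "backward") "drop" else "add", best$move),
      k = length(cur_sel), AIC = best$aic))
  }
  list(model = cur$fit, selected = cur_sel, path = path,
       aic_null = nullFit$aic, aic_full = fullFit$aic)
}
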