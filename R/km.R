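#' Kaplan-Meier product-limit estimator
#'
#' Returns the survival curve as the closed-form product over distinct
#' event times: `S(t) = prod_{t_j <= t} (1 - d_j / n_j)` with `d_j` events
#' and `n_j` at risk at time `t_j`.
#'
#' @param time,event numeric vectors (event 1 = observed, 0 = censored)
#' @return data.frame: time (distinct event times), n_risk, n_event,
#'   survival (non-increasing)
#' @examples
#' kmEstimate(c(1, 2, 2, 3, 5), c(1, 1, 0, 1, 0))
#' @export
kmEstimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  data.frame(time = et, n_risk = n_risk, n_event = n_event,
             survival = cumprod(1 - n_event / n_risk))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom: at each distinct
#' event time the observed events in group 1 are compared with the
#' hypergeometric expectation given the pooled risk set, and
#' `X^2 = (sum O - sum E)^2 / sum V`.
#'
#' @param time,event as in [kmEstimate()]
#' @param group two-level factor or character vector
#' @return list: `statistic`, `p_value` (chi-square, 1 df), `observed`,
#'   `expected` (per group)
#' @examples
#' logrankTest(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 1, 0, 1),
#'             c("a", "a", "a", "b", "b", "b"))
#' @export
logrankTest <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("log-rank test requires exactly two groups")
  et <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in et) {
    atrisk <- time >= t
    n <- sum(atrisk)
    n1 <- sum(atrisk & g == levels(g)[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == levels(g)[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  obs <- c(O, sum(event == 1) - O)
  exp_ <- c(E, sum(event == 1) - E)
  names(obs) <- names(exp_) <- levels(g)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = obs, expected = exp_)
}

#' Risk stratification by a fitted Cox model
#'
#' Scores each sample with the linear predictor `sum(beta_g * x_g)`, splits
#' at the median (rank-based, so group sizes differ by at most one), and
#' compares the high- and low-risk Kaplan-Meier curves with the log-rank
#' test. Refuses to stratify when all scores are identical.
#'
#' @param model a [coxFit()] result (or any list with a named `coef` vector)
#' @param survival data.frame with `time`, `event`, aligned with
#'   `covariates` rows
#' @param covariates samples x genes matrix containing the model's genes
#' @return list: `score` (per-sample risk score), `group` (high/low factor),
#'   `km` (named list of per-group [kmEstimate()] tables), `logrank`
#'   (from [logrankTest()])
#' @examples
#' coh <- genCohort(100, 0, 10, n_prognostic = 2, seed = 7)
#' sv <- survivalData(coh)
#' X <- t(log2(exprMatrix(coh)))[sv$sample, ]
#' fit <- coxFit(sv, X[, 1:2])
#' rs <- riskStratify(fit, sv, X)
#' rs$logrank$p_value
#' @export
riskStratify <- function(model, survival, covariates) {
  genes <- names(model$coef)
  X <- as.matrix(covariates)
  if (!all(genes %in% colnames(X)))
    stop("covariates must contain all model genes")
  score <- as.vector(X[, genes, drop = FALSE] %*% model$coef)
  if (length(unique(score)) == 1)
    stop("all risk scores identical; stratification refused")
  n <- length(score)
  # rank-based median split; ties resolved by sample order, sizes differ <= 1
  high <- rank(score, ties.method = "first") > n / 2
  group <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  km <- lapply(split(seq_len(n), group), function(idx)
    kmEstimate(survival$time[idx], survival$event[idx]))
  lr <- logrankTest(survival$time, survival$event, group)
  list(score = score, group = group, km = km, logrank = lr)
}
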