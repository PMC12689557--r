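test_that("Welch p-values match stats::t.test to 1e-10 on a fixed table", {
  set.seed(42)
  x <- matrix(rnorm(40, mean = 5), 5, 8,
              dimnames = list(paste0("g", 1:5),
                              c(paste0("t", 1:4), paste0("n", 1:4))))
  x[1, 1:4] <- x[1, 1:4] + 3
  coh <- local({
    cd <- S4Vectors::DataFrame(group = rep(c("tumor", "normal"), each = 4),
                               time = c(rep(1, 4), rep(NA, 4)),
                               event = c(rep(1, 4), rep(NA, 4)),
                               row.names = colnames(x))
    rd <- S4Vectors::DataFrame(true_lfc = numeric(5), true_beta = numeric(5),
                               row.names = rownames(x))
    methods::new("SyntheticCohort", SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = 2^x), colData = cd, rowData = rd))
  })
  deg <- differentialExpression(coh)
  for (g in 1:5) {
    tt <- t.test(x[g, 1:4], x[g, 5:8])   # Welch by default
    expect_equal(deg$p_value[g], tt$p.value, tolerance = 1e-10)
    expect_equal(deg$log2FC[g], unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
  expect_identical(deg$adjusted_p, p.adjust(deg$p_value, "BH"))
})

test_that("DEG direction calls require both thresholds; zero variance flagged", {
  e <- matrix(4, 3, 8, dimnames = list(paste0("g", 1:3),
                                       c(paste0("t", 1:4), paste0("n", 1:4))))
  e[2, 1:4] <- c(6.0, 6.1, 5.9, 6.0)      # big shift, tiny p -> up
  e[3, ] <- e[3, ] + rep(c(0.02, -0.02), 4)  # tiny shift -> ns
  cd <- S4Vectors::DataFrame(group = rep(c("tumor", "normal"), each = 4),
                             time = c(rep(1, 4), rep(NA, 4)),
                             event = c(rep(1, 4), rep(NA, 4)),
                             row.names = colnames(e))
  rd <- S4Vectors::DataFrame(true_lfc = numeric(3), true_beta = numeric(3),
                             row.names = rownames(e))
  coh <- methods::new("SyntheticCohort",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = 2^e), colData = cd, rowData = rd))
  deg <- differentialExpression(coh)
  expect_true(deg$zero_variance[1])
  expect_equal(deg$p_value[1], 1)
  expect_identical(deg$direction, c("ns", "up", "ns"))
  expect_equal(deg$log2FC[1], 0)
})

test_that("planted DEGs are recovered at high recall and low FP", {
  coh <- genCohort(20, 20, 500, n_deg = 50,
                   effect_sizes = list(lfc = 2), seed = 42)
  deg <- differentialExpression(coh, fc_threshold = 1, p_threshold = 0.05)
  planted <- names(which(trueLog2FC(coh) != 0))
  called <- deg$gene[deg$direction != "ns"]
  recall <- length(intersect(called, planted)) / length(planted)
  fp <- length(setdiff(called, planted))
  expect_gte(recall, 0.9)
  expect_lte(fp, 5)
})

test_that("BH adjustment preserves the p-value ordering", {
  coh <- genCohort(10, 10, 100, n_deg = 10, seed = 5)
  deg <- differentialExpression(coh)
  expect_identical(order(deg$p_value), order(deg$adjusted_p, deg$p_value))
  expect_true(all(deg$adjusted_p >= deg$p_value))
})

test_that("coxFit matches a brute-force partial-likelihood maximizer", {
  # 3 subjects, all events, one binary covariate: grid search oracle
  sv <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  X <- matrix(c(1, 0, 1), 3, 1, dimnames = list(NULL, "x"))
  # hand-written partial likelihood: risk sets {1,2,3}, {2,3}, {3}
  logpl <- function(b) (b - log(2 * exp(b) + 1)) + (0 - log(1 + exp(b))) + 0
  grid <- seq(-5, 5, by = 1e-4)
  b_star <- grid[which.max(vapply(grid, logpl, numeric(1)))]
  fit <- coxFit(sv, X)
  expect_equal(unname(fit$coef), b_star, tolerance = 1e-3)
  d <- SynergyScreen:::coxDerivatives(fit$coef, X, sv$time, sv$event)
  expect_lt(abs(d$score), 1e-6)
  expect_equal(unname(fit$logPL), unname(logpl(fit$coef)), tolerance = 1e-9)
})

test_that("coxFit agrees with survival::coxph (Breslow ties) on random data", {
  skip_if_not_installed("survival")
  set.seed(17)
  for (rep in 1:5) {
    n <- 120
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    lp <- X %*% c(0.8, -0.5, 0)
    time <- round(rexp(n, exp(lp)), 2) + 0.01   # induces ties
    event <- rbinom(n, 1, 0.8)
    sv <- data.frame(time = time, event = event)
    fit <- coxFit(sv, X)
    ref <- survival::coxph(survival::Surv(time, event) ~ X,
                           ties = "breslow")
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
    expect_equal(fit$logPL, unname(ref$loglik[2]), tolerance = 1e-8)
    expect_equal(fit$AIC, 2 * 3 - 2 * unname(ref$loglik[2]), tolerance = 1e-8)
  }
})

test_that("Newton iterations never decrease the log partial likelihood", {
  coh <- genCohort(150, 0, 6, n_prognostic = 2, seed = 13)
  sv <- survivalData(coh)
  X <- t(log2(exprMatrix(coh) + 1))[sv$sample, ]
  fit <- coxFit(sv, X)
  expect_true(all(diff(fit$logPL_trace) >= -1e-12))
  expect_true(fit$converged)
})

test_that("coxFit guards: constant covariates, no events, separation", {
  sv <- data.frame(time = 1:6, event = rep(1, 6))
  X <- cbind(flat = rep(2, 6), ok = rnorm(6))
  expect_warning(fit <- coxFit(sv, X), "constant")
  expect_named(fit$coef, "ok")
  expect_error(coxFit(data.frame(time = 1:3, event = rep(0, 3)),
                      matrix(rnorm(3))), "event")
  # perfectly separating covariate: monotone likelihood flagged and capped
  Xs <- matrix(c(6:1), 6, 1, dimnames = list(NULL, "sep"))
  expect_warning(fs <- coxFit(sv, Xs), "monotone")
  expect_true("monotone_likelihood" %in% fs$flags)
  expect_lte(abs(unname(fs$coef)), 15)
})

test_that("stepwise AIC selection recovers planted genes and respects AIC", {
  coh <- genCohort(400, 0, 8, n_prognostic = 3,
                   effect_sizes = list(beta = 1), seed = 11)
  sv <- survivalData(coh)
  lx <- log2(exprMatrix(coh) + 1)[, sv$sample]
  X <- scale(t(lx))          # samples x genes, standardized per gene
  sel <- stepwiseCox(sv, X)
  expect_true(all(c("g001", "g002", "g003") %in% sel$selected))
  expect_lte(sel$model$AIC, sel$aic_full + 1e-8)
  expect_lte(sel$model$AIC, sel$aic_null + 1e-8)
  # forward search also keeps the planted genes
  self <- stepwiseCox(sv, X, direction = "forward")
  expect_true(all(c("g001", "g002", "g003") %in% self$selected))
})

test_that("a single strong candidate is retained; pure noise mostly is not", {
  outcomes <- character(25)
  for (s in 1:25) {
    coh <- genCohort(120, 0, 4, n_prognostic = 0, seed = 500 + s)
    sv <- survivalData(coh)
    X <- t(log2(exprMatrix(coh) + 1))[sv$sample, ]
    sel <- suppressWarnings(stepwiseCox(sv, X))
    outcomes[s] <- paste(sel$selected, collapse = ",")
  }
  # the null model is returned more often than any individual gene
  n_null <- sum(outcomes == "")
  per_gene <- vapply(sprintf("g%03d", 1:4),
                     function(g) sum(outcomes == g), integer(1))
  expect_gt(n_null, max(per_gene))
  coh <- genCohort(300, 0, 1, n_prognostic = 1,
                   effect_sizes = list(beta = 1.2), seed = 3)
  sv <- survivalData(coh)
  X <- t(log2(exprMatrix(coh) + 1))[sv$sample, , drop = FALSE]
  sel <- stepwiseCox(sv, X)
  expect_identical(sel$selected, "g001")
  expect_lt(sel$model$AIC, sel$aic_null)
})

test_that("KM estimator equals the closed-form product limit", {
  t_ <- c(1, 2, 2, 3, 5, 6)
  e_ <- c(1, 1, 0, 1, 0, 1)
  km <- kmEstimate(t_, e_)
  expect_equal(km$time, c(1, 2, 3, 6))
  expect_equal(km$survival,
               cumprod(c(1 - 1 / 6, 1 - 1 / 5, 1 - 1 / 3, 1 - 1 / 1)))
  expect_true(all(diff(km$survival) <= 0))
  skip_if_not_installed("survival")
  sf <- survival::survfit(survival::Surv(t_, e_) ~ 1)
  expect_equal(km$survival, summary(sf)$surv, tolerance = 1e-12)
})

test_that("log-rank statistic equals the hand-computed O-E sum", {
  # 6 + 6 fixture with censoring
  t_ <- c(1, 3, 5, 7, 9, 11, 2, 4, 6, 8, 10, 12)
  e_ <- c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1)
  g_ <- rep(c("A", "B"), each = 6)
  lr <- logrankTest(t_, e_, g_)
  # hand computation at each event time
  O <- E <- V <- 0
  for (tt in sort(unique(t_[e_ == 1]))) {
    n <- sum(t_ >= tt); n1 <- sum(t_ >= tt & g_ == "A")
    d <- sum(t_ == tt & e_ == 1); d1 <- sum(t_ == tt & e_ == 1 & g_ == "A")
    O <- O + d1; E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$statistic, (O - E)^2 / V, tolerance = 1e-10)
  skip_if_not_installed("survival")
  sd_ <- survival::survdiff(survival::Surv(t_, e_) ~ g_)
  expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-8)
})

test_that("risk stratification splits at the median and separates survival", {
  coh <- genCohort(400, 0, 10, n_prognostic = 3,
                   effect_sizes = list(beta = 1), seed = 7)
  sv <- survivalData(coh)
  lx <- log2(exprMatrix(coh) + 1)[, sv$sample]
  X <- t(scale(t(lx)))
  fit <- coxFit(sv, t(X)[, c("g001", "g002", "g003")])
  rs <- riskStratify(fit, sv, t(X))
  expect_lte(abs(diff(table(rs$group))), 1)
  expect_lt(rs$logrank$p_value, 0.05)
  # the high-risk curve sits below the low-risk curve where both are defined
  lo <- rs$km$low; hi <- rs$km$high
  common <- intersect(lo$time, hi$time)
  for (tt in common) {
    expect_lte(hi$survival[max(which(hi$time <= tt))],
               lo$survival[max(which(lo$time <= tt))] + 1e-12)
  }
  expect_error(riskStratify(list(coef = c(g001 = 0)), sv, t(X)), "identical")
})

test_that("identical survival in both groups gives log-rank p near 1", {
  set.seed(21)
  t_ <- rexp(400); e_ <- rbinom(400, 1, 0.8)
  g_ <- rep(c("A", "B"), 200)
  lr <- logrankTest(t_, e_, g_)
  expect_gt(lr$p_value, 0.05)
})
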