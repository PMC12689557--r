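#' Limiting-dilution (single-hit Poisson) frequency estimate
#'
#' Under the single-hit model a well seeded with `dose` cells stays
#' negative with probability `exp(-f * dose)`, so the positive-well
#' probability follows a binomial GLM with complementary log-log link and
#' `log(dose)` offset: `cloglog(p) = log(f) + log(dose)`. The frequency
#' `f` is estimated by maximum likelihood through that regression, with a
#' Wald 95% confidence interval on `log(f)` (the default of the standard
#' limiting-dilution webtool) or a profile-likelihood interval with
#' `ci = "profile"`. The display string is the conventional reciprocal
#' form, e.g. `"1/169.7"`.
#'
#' @param data data.frame with columns `dose` (cells per well), `wells`
#'   (replicates) and `positive` (sphere-forming wells), as produced by
#'   [genDilution()]
#' @param ci `"wald"` (default) or `"profile"`
#' @return list: `f_hat`, `ci_lower`, `ci_upper` (frequencies), `display`
#'   (reciprocal string), `logLik`
#' @examples
#' eldaFit(data.frame(dose = c(200, 100, 50, 25), wells = 10,
#'                    positive = c(7, 5, 3, 1)))
#' @export
eldaFit <- function(data, ci = c("wald", "profile")) {
  ci <- match.arg(ci)
  stopifnot(all(c("dose", "wells", "positive") %in% names(data)))
  if (any(data$positive > data$wells)) stop("positive wells exceed wells")
  if (length(unique(data$dose)) < 2) stop("need at least two distinct doses")
  if (all(data$positive == data$wells))
    stop("all wells positive at every dose: frequency unbounded")
  allneg <- all(data$positive == 0)
  fit <- suppressWarnings(glm(
    cbind(positive, wells - positive) ~ offset(log(dose)),
    family = binomial(link = "cloglog"), data = data))
  logf <- unname(coef(fit)[1])
  se <- sqrt(vcov(fit)[1, 1])
  if (allneg) {
    # no positives: only an upper bound is identified
    warning("no positive wells: reporting an upper bound only")
    # MLE is at f -> 0; bound from the likelihood-ratio at f where the
    # probability of observing all-negative drops to 5%
    ub <- -log(0.05) / sum(data$dose * data$wells)
    return(list(f_hat = 0, ci_lower = 0, ci_upper = ub,
                display = "0 (upper bound only)", logLik = 0,
                flag = "all_negative"))
  }
  f_hat <- exp(logf)
  if (ci == "wald") {
    lo <- exp(logf - qnorm(0.975) * se)
    hi <- exp(logf + qnorm(0.975) * se)
  } else {
    ll <- function(lf) {
      p <- 1 - exp(-exp(lf) * data$dose)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      sum(data$positive * log(p) + (data$wells - data$positive) * log(1 - p))
    }
    l0 <- ll(logf)
    crit <- l0 - qchisq(0.95, 1) / 2
    lo <- exp(stats::uniroot(function(lf) ll(lf) - crit,
                             c(logf - 10, logf))$root)
    hi <- exp(stats::uniroot(function(lf) ll(lf) - crit,
                             c(logf, min(logf + 10, -1e-9)))$root)
  }
  list(f_hat = f_hat, ci_lower = lo, ci_upper = hi,
       display = sprintf("1/%.1f", 1 / f_hat),
       logLik = as.numeric(stats::logLik(fit)))
}

#' Tumor growth inhibition
#'
#' `TGI (%) = (1 - mean(treated) / mean(control)) * 100`. Scale-invariant:
#' multiplying every weight by the same constant leaves TGI unchanged.
#'
#' @param control_weights,treated_weights tumor weights (g) per group
#' @return TGI in percent
#' @examples
#' tgi(control_weights = c(1.1, 0.9, 1.0), treated_weights = c(0.3, 0.35))
#' @export
tgi <- function(control_weights, treated_weights) {
  if (!length(control_weights) || !length(treated_weights))
    stop("both groups must be non-empty")
  mc <- mean(control_weights)
  if (mc <= 0) stop("control mean weight must be positive")
  (1 - mean(treated_weights) / mc) * 100
}

#' Tumor volume from caliper measurements
#'
#' `volume = length * width^2 / 2` (mm^3). Warns when width exceeds
#' length (the measurements are conventionally the major and minor axes).
#'
#' @param length,width tumor dimensions in mm (positive)
#' @return volume in mm^3
#' @examples
#' tumorVolume(10, 10)   # 500
#' @export
tumorVolume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("length and width must be positive")
  if (any(width > length))
    warning("width exceeds length; check the measurement order")
  length * width^2 / 2
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per gene,
#' `ddCt = mean(dCt treated) - mean(dCt control)` and the relative
#' expression is `2^-ddCt` (1 = unchanged, 0.5 = halved). Per-sample fold
#' changes relative to the control mean are also returned for dispersion
#' reporting.
#'
#' @param records data.frame with columns `gene`, `group` (`control` /
#'   `treated`), `ct_target`, `ct_reference`
#' @return data.frame per gene: gene, ddct, rel_expr, plus the per-sample
#'   fold changes as attribute `"per_sample"`
#' @examples
#' ddct(data.frame(gene = "SOX2", group = c("control", "treated"),
#'                 ct_target = c(25, 27), ct_reference = c(18, 18)))
#' @export
ddct <- function(records) {
  need <- c("gene", "group", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(records)))
  if (any(!is.finite(records$ct_target)) || any(!is.finite(records$ct_reference)))
    stop("missing or non-finite Ct values")
  if (any(records$ct_target <= 0) || any(records$ct_reference <= 0))
    stop("Ct values must be positive")
  if (!all(c("control", "treated") %in% records$group))
    stop("need at least one control and one treated sample")
  records$dct <- records$ct_target - records$ct_reference
  per_sample <- NULL
  out <- do.call(rbind, lapply(split(records, records$gene), function(r) {
    m_ctrl <- mean(r$dct[r$group == "control"])
    m_trt <- mean(r$dct[r$group == "treated"])
    dd <- m_trt - m_ctrl
    per_sample <<- rbind(per_sample, data.frame(
      gene = r$gene, group = r$group, fold = 2^-(r$dct - m_ctrl)))
    data.frame(gene = r$gene[1], ddct = dd, rel_expr = 2^-dd)
  }))
  rownames(out) <- NULL
  attr(out, "per_sample") <- per_sample
  out
}
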