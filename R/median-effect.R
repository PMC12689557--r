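#' Fit the median-effect (Chou) dose-effect model
#'
#' Ordinary least squares on the linearized median-effect equation:
#' `log10(fa / (1 - fa)) = m * log10(D) - m * log10(Dm)`, so the slope is
#' `m` and `Dm = 10^(-intercept / m)`. Points with `fa` exactly 0 or 1
#' carry no information on this scale and are excluded with a warning;
#' at least two usable points with distinct doses are required. `r` is the
#' correlation coefficient of the linear fit.
#'
#' @param doses positive dose vector
#' @param fa fractions affected in `[0, 1]` (strictly inside to be usable);
#'   alternatively pass `viability` in percent and `fa` is taken as
#'   `1 - viability / 100`
#' @param viability optional percent-viability vector (used when `fa` is
#'   missing)
#' @param drug optional drug label
#' @return a \linkS4class{MedianEffectFit}
#' @examples
#' d <- c(8, 4, 2, 1, 0.5, 0.25)
#' fitMedianEffect(d, (d / 2) / (1 + d / 2))   # Dm = 2, m = 1
#' @export
fitMedianEffect <- function(doses, fa, viability = NULL, drug = character(0)) {
  if (missing(fa) || is.null(fa)) {
    if (is.null(viability)) stop("supply fa or viability")
    fa <- 1 - viability / 100
  }
  stopifnot(length(doses) == length(fa))
  if (any(doses <= 0)) stop("doses must be positive")
  usable <- fa > 0 & fa < 1
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with fa of exactly 0 or 1 excluded")
    doses <- doses[usable]; fa <- fa[usable]
  }
  if (length(unique(doses)) < 2)
    stop("need at least two usable points with distinct doses")
  x <- log10(doses)
  y <- log10(fa / (1 - fa))
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  if (!is.finite(m) || m == 0) stop("degenerate median-effect fit (slope 0)")
  methods::new("MedianEffectFit", m = m, Dm = 10^(-b / m),
               r = suppressWarnings(stats::cor(x, y)),
               nPoints = length(x), drug = drug)
}

#' Predicted fraction affected at a dose
#'
#' The median-effect curve of a fit: `fa = (D/Dm)^m / (1 + (D/Dm)^m)`.
#' At `D = Dm` this is exactly 0.5 (the defining property of the
#' median-effect dose).
#'
#' @param fit a \linkS4class{MedianEffectFit}
#' @param dose positive dose(s)
#' @return fraction(s) affected in (0, 1)
#' @export
medianEffectFa <- function(fit, dose) {
  stopifnot(all(dose > 0))
  r <- (dose / fit@Dm)^fit@m
  r / (1 + r)
}

#' Dose required for a given effect level
#'
#' Inverts the median-effect equation: `Dx = Dm * (fa / (1 - fa))^(1/m)`.
#' At `fa = 0.5` this returns `Dm`.
#'
#' @param fit a \linkS4class{MedianEffectFit}
#' @param fa effect level(s), strictly inside (0, 1)
#' @return dose(s)
#' @examples
#' f <- fitMedianEffect(c(1, 2, 4), c(1, 2, 4) / (1 + c(1, 2, 4)))
#' doseForEffect(f, 0.8)   # m = 1, Dm = 1 -> 4
#' @export
doseForEffect <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1)) stop("fa must be strictly inside (0, 1)")
  fit@Dm * (fa / (1 - fa))^(1 / fit@m)
}

#' Combination index at a combination point
#'
#' Two-term (mutually exclusive / classic) combination index at effect
#' level `fa`: `CI = d1 / DxA(fa) + d2 / DxB(fa)`, where `Dx` is each
#' drug's single-agent dose producing `fa`. Classification follows the
#' standard reading: synergy for `CI < 1`, additivity at `CI = 1` (within
#' tolerance 1e-9, since exact equality is measure-zero), antagonism for
#' `CI > 1`.
#'
#' @param fitA,fitB \linkS4class{MedianEffectFit} objects for the two drugs
#' @param d1,d2 doses of drugs A and B in the combination
#' @param fa observed fraction affected at that dose pair, in (0, 1)
#' @param tol additivity tolerance (default 1e-9)
#' @return data.frame: d1, d2, fa, ci, class
#' @examples
#' f <- fitMedianEffect(c(1, 2, 4), c(1, 2, 4) / (1 + c(1, 2, 4)))
#' combinationIndex(f, f, d1 = 2, d2 = 2, fa = 0.8)   # self-combo: CI = 1
#' @export
combinationIndex <- function(fitA, fitB, d1, d2, fa, tol = 1e-9) {
  if (fitA@m <= 0 || fitB@m <= 0) stop("degenerate fit: m must be positive")
  stopifnot(length(d1) == length(d2), length(d2) == length(fa))
  if (any(fa <= 0 | fa >= 1)) stop("fa must be strictly inside (0, 1)")
  ci <- d1 / doseForEffect(fitA, fa) + d2 / doseForEffect(fitB, fa)
  cls <- ifelse(abs(ci - 1) <= tol, "additive",
                ifelse(ci < 1, "synergy", "antagonism"))
  data.frame(d1 = d1, d2 = d2, fa = fa, ci = ci, class = cls)
}

#' Fa-CI curve over a panel of combination points
#'
#' Computes the combination index at every combination point and returns
#' the table sorted by effect level, the standard display for judging how
#' synergy varies with the fraction affected.
#'
#' @param fitA,fitB \linkS4class{MedianEffectFit} objects
#' @param combos data.frame with columns `d1`, `d2`, `fa`
#' @return data.frame (fa, d1, d2, ci, class) sorted by fa
#' @export
faCiCurve <- function(fitA, fitB, combos) {
  if (!nrow(combos)) stop("need at least one combination point")
  res <- combinationIndex(fitA, fitB, combos$d1, combos$d2, combos$fa)
  res <- res[order(res$fa), c("fa", "d1", "d2", "ci", "class")]
  rownames(res) <- NULL
  res
}
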