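#' Presence/absence stratification of a signature exposure
#'
#' Present iff the exposure proportion is at least `cutoff` (boundary
#' inclusive, default 15%).
#'
#' @param exposures numeric exposure proportions.
#' @param cutoff presence cutoff (default 0.15).
#' @return character vector "present"/"absent".
#' @export
stratify_presence <- function(exposures, cutoff = 0.15) {
  ifelse(exposures >= cutoff, "present", "absent")
}

#' Tertile stratification
#'
#' Splits values at the empirical 1/3 and 2/3 order statistics: the
#' lower tertile gets `ceiling(n/3)` observations and the upper tertile
#' `floor(n/3)` (ties at a boundary go to the lower group). Two-group
#' survival tests use only the low/high groups.
#'
#' @param values numeric vector (>= 3 values, not all identical).
#' @return factor with levels low, mid, high.
#' @export
stratify_tertiles <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (length(unique(values)) == 1) stop("degenerate strata: all values equal")
  srt <- sort(values)
  lo_cut <- srt[ceiling(n / 3)]
  hi_cut <- srt[n - floor(n / 3)]
  lab <- ifelse(values <= lo_cut, "low",
                ifelse(values > hi_cut, "high", "mid"))
  factor(lab, levels = c("low", "mid", "high"))
}

#' Kaplan-Meier product-limit curve
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame: time, n_risk, n_event, surv (step function;
#'   censored-only data gives surv = 1 throughout).
#' @export
km_curve <- function(times, events) {
  if (any(times < 0)) stop("negative survival time")
  stopifnot(length(times) == length(events))
  et <- sort(unique(times[events == 1]))
  if (length(et) == 0) {
    return(data.frame(time = numeric(0), n_risk = numeric(0),
                      n_event = numeric(0), surv = numeric(0)))
  }
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = et, n_risk = n_risk, n_event = n_event, surv = surv)
}

#' (Weighted) log-rank test
#'
#' Standard observed-minus-expected chi-square across event times with
#' the full hypergeometric covariance (equivalent to
#' `survival::survdiff` when weights are unit). With per-subject weights
#' (for example inverse probability weights), each subject's
#' contribution to the at-risk and event counts is multiplied by its
#' weight; the same weighted counts enter the covariance, giving the
#' weight-adjusted statistic used for covariate-adjusted comparisons.
#'
#' @param times follow-up times.
#' @param events event indicators (0/1).
#' @param groups group labels (>= 2 groups, each non-empty).
#' @param weights optional per-subject positive weights.
#' @return list: statistic (chi-square), df, p, observed, expected,
#'   group sizes, weighting ("none"/"weighted").
#' @export
logrank_test <- function(times, events, groups, weights = NULL) {
  groups <- as.factor(droplevels(as.factor(groups)))
  K <- nlevels(groups)
  if (K < 2) stop("need at least two groups")
  if (any(times < 0)) stop("negative survival time")
  n <- length(times)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w <= 0)) stop("weights must be positive")
  g <- as.integer(groups)
  et <- sort(unique(times[events == 1]))
  O <- E <- rep(0, K)
  V <- matrix(0, K, K)
  for (t in et) {
    at_risk <- times >= t
    Yg <- vapply(seq_len(K), function(k) sum(w[at_risk & g == k]),
                 numeric(1))
    dg <- vapply(seq_len(K), function(k) {
      sum(w[times == t & events == 1 & g == k])
    }, numeric(1))
    Y <- sum(Yg); d <- sum(dg)
    if (Y <= 0 || d <= 0) next
    O <- O + dg
    E <- E + d * Yg / Y
    if (Y > 1) {
      frac <- Yg / Y
      Vt <- d * ((Y - d) / (Y - 1)) * (diag(frac) - tcrossprod(frac))
      V <- V + Vt
    }
  }
  idx <- seq_len(K - 1)
  diff <- (O - E)[idx]
  Vsub <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(as.numeric(t(diff) %*% solve(Vsub, diff)),
                   error = function(e) {
                     as.numeric(t(diff) %*% MASS::ginv(Vsub) %*% diff)
                   })
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = K - 1, lower.tail = FALSE)
  list(statistic = stat, df = K - 1, p = p,
       observed = stats::setNames(O, levels(groups)),
       expected = stats::setNames(E, levels(groups)),
       n = as.integer(table(groups)),
       weighting = if (is.null(weights)) "none" else "weighted")
}

#' Inverse probability weights from categorical covariate strata
#'
#' Propensities are estimated by the stratum cross-tabulation
#' (nonparametric, exact for categorical covariates such as stage and
#' treatment). If a stratum lacks a group, 0.5 is added to every cell of
#' that stratum before forming proportions. Weights are 1/propensity,
#' normalised to mean 1 within each group.
#'
#' @param groups group labels.
#' @param strata covariate stratum per subject (for example the
#'   interaction of stage and treatment).
#' @return numeric weight per subject.
#' @export
ipw_weights <- function(groups, strata) {
  groups <- as.factor(groups)
  strata <- as.factor(strata)
  if (length(groups) != length(strata)) stop("length mismatch")
  tab <- table(strata, groups)
  smoothed <- apply(tab, 1, function(row) any(row == 0))
  tab <- tab + ifelse(smoothed, 0.5, 0)[row(tab)]
  prop <- tab / rowSums(tab)
  w <- 1 / prop[cbind(as.integer(strata), as.integer(groups))]
  for (gl in levels(groups)) {
    sel <- groups == gl
    w[sel] <- w[sel] / mean(w[sel])
  }
  as.numeric(w)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p p-values in \[0, 1\].
#' @return q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sided exact binomial enrichment test
#'
#' Sums the probabilities of all outcomes no more likely than the
#' observed count (the standard exact two-sided binomial test).
#'
#' @param k observed count in the group.
#' @param n group size.
#' @param p0 expected proportion in (0, 1].
#' @return two-sided p-value.
#' @export
binomial_enrichment_test <- function(k, n, p0) {
  if (k < 0 || k > n || n < 1) stop("invalid counts")
  if (p0 <= 0 || p0 > 1) stop("p0 must be in (0, 1]")
  as.numeric(stats::binom.test(k, n, p = p0,
                               alternative = "two.sided")$p.value)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return list: r, p.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need n >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
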