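## Statistical layer for pharmacological and egg-laying assays: paralysis
## time courses (log-rank), convulsion proportions (Fisher + Bonferroni),
## group comparisons (t-test / one- and two-way ANOVA with Bonferroni), and
## the percent-rescue statistic for drug effects on reversal rates.

#' Fraction of animals still moving over time
#'
#' For paralysis assays scored at fixed timepoints: at each time `t` the
#' value is the percentage of animals in the group whose paralysis time
#' exceeds `t` (right-censored animals count as moving through their
#' censoring time).
#'
#' @param records data.frame with columns `group`, `time` (minutes) and
#'   `event` (1 = paralyzed at `time`, 0 = censored).
#' @param timepoints numeric vector of assay timepoints (minutes).
#' @return data.frame `group`, `time`, `pct_moving`; within each group the
#'   curve is monotone non-increasing and starts at 100% for `t = 0`.
#' @examples
#' rec <- data.frame(group = "wt", time = c(10, 20, 30, 40), event = 1)
#' fractionMoving(rec, c(0, 15, 35, 60))
#' @export
fractionMoving <- function(records, timepoints) {
  stopifnot(all(c("group", "time", "event") %in% names(records)))
  if (!nrow(records)) stop("no records supplied")
  if (any(records$time <= 0)) stop("paralysis/censoring times must be > 0")
  groups <- unique(records$group)
  do.call(rbind, lapply(groups, function(g) {
    r <- records[records$group == g, ]
    if (!nrow(r)) stop("empty group: ", g)
    pct <- vapply(timepoints, function(t)
      100 * mean(r$time > t | (r$event == 0 & r$time >= t)), numeric(1))
    data.frame(group = g, time = timepoints, pct_moving = pct)
  }))
}

#' Log-rank test between two paralysis-time distributions
#'
#' Standard two-group log-rank chi-square (1 df) on right-censored event
#' times, as used to compare drug-induced paralysis time courses between
#' genotypes.
#'
#' @param groupA,groupB data.frames with columns `time` and `event`
#'   (1 = event observed, 0 = censored).
#' @return list with `statistic` (chi-square), `p`, and `df` (= 1).
#' @export
logrankTest <- function(groupA, groupB) {
  stopifnot(nrow(groupA) >= 2, nrow(groupB) >= 2)
  if (sum(groupA$event) + sum(groupB$event) == 0)
    stop("no events in either group: log-rank statistic undefined")
  df <- rbind(cbind(groupA[c("time", "event")], g = 0L),
              cbind(groupB[c("time", "event")], g = 1L))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Fisher's exact tests with Bonferroni correction
#'
#' Two-sided Fisher's exact test per 2x2 table (e.g. convulsing vs not, per
#' genotype against control), with the p-values multiplied by the number of
#' comparisons and capped at 1.
#'
#' @param tables a single 2x2 matrix or a list of them.
#' @param nComparisons Bonferroni multiplier; defaults to the number of
#'   tables.
#' @return data.frame `comparison`, `p_raw`, `p_adj`.
#' @examples
#' proportionTest(list(matrix(c(18, 2, 5, 15), 2)), nComparisons = 3)
#' @export
proportionTest <- function(tables, nComparisons = NULL) {
  if (is.matrix(tables)) tables <- list(tables)
  if (is.null(nComparisons)) nComparisons <- length(tables)
  res <- lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    if (!all(dim(tb) == c(2, 2))) stop("each table must be 2x2")
    if (any(tb < 0) || any(tb != round(tb))) stop("counts must be non-negative integers")
    p <- stats::fisher.test(tb, alternative = "two.sided")$p.value
    data.frame(comparison = i, p_raw = p, p_adj = min(1, p * nComparisons))
  })
  do.call(rbind, res)
}

#' Group comparisons for per-animal measurements
#'
#' For readouts such as eggs retained in utero or reversals per minute:
#' either pairwise two-sample t-tests, a one-way ANOVA followed by
#' Bonferroni-adjusted pairwise t-tests (pooled SD), or a two-way ANOVA
#' (group x batch) with the same pairwise follow-up on the group factor.
#'
#' @param values numeric vector of per-animal values.
#' @param group factor/character of group labels (>= 2 groups, >= 2 values
#'   each).
#' @param method `"anova_bonferroni"`, `"t_test"` or `"two_way"`.
#' @param block second factor (e.g. experiment day) for `method =
#'   "two_way"`.
#' @return list with `omnibus` (data.frame: statistic, df, p; F for ANOVA
#'   methods, NA for `"t_test"`) and `pairwise` (data.frame `groupA`,
#'   `groupB`, `p_adj`, Bonferroni-adjusted).
#' @export
groupCompare <- function(values, group,
                         method = c("anova_bonferroni", "t_test", "two_way"),
                         block = NULL) {
  method <- match.arg(method)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("need at least 2 values per group")
  if (all(tapply(values, group, stats::var) == 0))
    stop("zero within-group variance everywhere: tests undefined")
  lev <- levels(group)
  pairs <- utils::combn(lev, 2)
  nPairs <- ncol(pairs)
  if (method == "t_test") {
    pw <- apply(pairs, 2, function(pr) {
      tt <- stats::t.test(values[group == pr[1]], values[group == pr[2]],
                          var.equal = FALSE)
      tt$p.value
    })
    omni <- data.frame(statistic = NA_real_, df = NA_real_, p = NA_real_)
    padj <- pmin(1, pw * nPairs)
  } else {
    fit <- if (method == "two_way") {
      if (is.null(block)) stop("method 'two_way' requires a block factor")
      stats::aov(values ~ group + factor(block))
    } else {
      stats::aov(values ~ group)
    }
    an <- stats::anova(fit)
    omni <- data.frame(statistic = an["group", "F value"],
                       df = an["group", "Df"], p = an["group", "Pr(>F)"])
    pt <- stats::pairwise.t.test(values, group, p.adjust.method = "bonferroni")
    padj <- apply(pairs, 2, function(pr) {
      m <- pt$p.value
      if (pr[2] %in% rownames(m) && pr[1] %in% colnames(m)) m[pr[2], pr[1]]
      else m[pr[1], pr[2]]
    })
  }
  list(omnibus = omni,
       pairwise = data.frame(groupA = pairs[1, ], groupB = pairs[2, ],
                             p_adj = unname(padj)))
}

#' Percent rescue of an abnormal reversal rate by a drug
#'
#' Quantifies how far a drug moves a mutant's reversal rate back towards the
#' wild-type (solvent-treated) rate:
#' \deqn{rescue = (1 - \Delta_1/\Delta_2) \cdot 100}
#' with \eqn{\Delta_1 = r_{drug} - r_{wt}} (mutant-with-drug minus
#' wild-type-with-solvent) and \eqn{\Delta_2 = r_{nodrug} - r_{wt}}
#' (mutant-with-solvent minus wild-type-with-solvent). The statistic is 0%
#' when the drug leaves the mutant rate unchanged and 100% when it restores
#' the wild-type rate. Callers must supply solvent-matched rates, since
#' solvents themselves shift reversal rates.
#'
#' @param rDrug mutant reversal rate with the drug (events/min).
#' @param rNoDrug mutant reversal rate with solvent only.
#' @param rWt wild-type reversal rate with solvent only.
#' @return list with `rescue_pct`, `delta1`, `delta2`.
#' @examples
#' percentRescue(rDrug = 6, rNoDrug = 10, rWt = 2)$rescue_pct  # 50
#' @export
percentRescue <- function(rDrug, rNoDrug, rWt) {
  stopifnot(is.finite(rDrug), is.finite(rNoDrug), is.finite(rWt))
  delta1 <- rDrug - rWt
  delta2 <- rNoDrug - rWt
  if (delta2 == 0)
    stop("undefined: the untreated mutant rate equals the wild-type rate (delta2 = 0)")
  list(rescue_pct = (1 - delta1 / delta2) * 100, delta1 = delta1,
       delta2 = delta2)
}
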