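# Survival relevance scoring: Kaplan-Meier curves, logrank tests, hazard
# ratios from a univariate proportional-hazards fit (Breslow ties), a
# minimum-p "best cutoff" dichotomization scan, and mean-expression
# signature scores. Estimation is delegated to the survival package; this
# module fixes the conventions (tie handling, scan grid, degenerate-input
# behavior) and the output contracts.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator. The returned step function starts at
#' `S(0) = 1` and is non-increasing.
#'
#' @param time,event follow-up times (> 0) and event flags (1 = event,
#'   0 = censored).
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv`, beginning
#'   with the (0, 1) anchor row.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, sf$time), n_risk = c(length(time), sf$n.risk),
             n_event = c(0, sf$n.event), surv = c(1, sf$surv))
}

#' Two-group logrank test
#'
#' Standard observed-minus-expected logrank statistic with hypergeometric
#' variance; the p-value comes from a chi-square distribution with 1 df.
#' Identical groups give statistic 0 and p = 1.
#'
#' @param time,event follow-up data.
#' @param group two-level grouping vector.
#' @return list with `chisq` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop("need exactly two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq),
       p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Hazard ratio from a univariate proportional-hazards fit
#'
#' Cox partial-likelihood fit on a binary group indicator with Breslow tie
#' handling; `HR = exp(coefficient)` for the second factor level versus the
#' first, with a 95% Wald confidence interval. When a group has no events
#' the ratio is unbounded and is reported as `NA` with a warning.
#'
#' @param time,event follow-up data.
#' @param group two-level grouping vector; the first level is the
#'   reference.
#' @return list: `hr`, `lower`, `upper`, `coef`, `se`.
#' @export
hazard_ratio <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop("need exactly two groups")
  ev <- tapply(event, group, sum)
  if (any(ev == 0)) {
    warning("a group has no events: hazard ratio unbounded, reported NA")
    return(list(hr = NA_real_, lower = NA_real_, upper = NA_real_,
                coef = NA_real_, se = NA_real_))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ group,
                         ties = "breslow")
  co <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  list(hr = exp(co), lower = exp(co - 1.96 * se),
       upper = exp(co + 1.96 * se), coef = co, se = se)
}

#' Best-cutoff dichotomization by minimum logrank p
#'
#' Scans candidate cutoffs at every score percentile between `scan[1]` and
#' `scan[2]` (defaults 20 and 80), splits patients into high (> cutoff)
#' versus low, and returns the cutoff minimizing the logrank p-value. The
#' returned p-value is cutoff-optimized and carries no selection
#' correction; it is flagged as such.
#'
#' @param time,event follow-up data.
#' @param score continuous per-patient score.
#' @param scan percentile range to scan, within \[20, 80\].
#' @return list: `cutoff`, `p`, `chisq`, `high` (logical group labels),
#'   `cutoff_optimized = TRUE`.
#' @export
best_cutoff_split <- function(time, event, score, scan = c(20, 80)) {
  stopifnot(length(scan) == 2, scan[1] >= 20, scan[2] <= 80,
            scan[1] < scan[2])
  if (length(unique(score)) < 2)
    stop("constant score: no valid split")
  cand <- unique(quantile(score, seq(scan[1], scan[2]) / 100, type = 7))
  best <- NULL
  for (ct in cand) {
    high <- score > ct
    if (!any(high) || all(high)) next
    lr <- logrank_test(time, event, high)
    if (is.null(best) || lr$p < best$p)
      best <- list(cutoff = unname(ct), p = lr$p, chisq = lr$chisq,
                   high = high)
  }
  if (is.null(best)) stop("no valid split in the scanned range")
  best$cutoff_optimized <- TRUE
  best
}

#' Mean-expression signature score
#'
#' Unweighted mean of the gene set's expression rows, per patient. Genes
#' absent from the matrix are dropped with a warning; an empty intersection
#' is an error.
#'
#' @param expression genes x patients matrix.
#' @param gene_set character vector of gene ids.
#' @return named numeric vector, one score per patient.
#' @export
signature_score <- function(expression, gene_set) {
  found <- intersect(gene_set, rownames(expression))
  if (!length(found))
    stop("none of the signature genes are in the expression matrix")
  if (length(found) < length(gene_set))
    warning(sprintf("%d signature gene(s) missing from the matrix, dropped",
                    length(gene_set) - length(found)))
  colMeans(expression[found, , drop = FALSE])
}
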