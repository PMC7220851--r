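# Knockdown differential expression on count matrices: median-of-ratios
# size factors, a negative-binomial Wald test with method-of-moments
# dispersion, threshold-based DEG calling, the cross-cell-line common-DEG
# rule, and 2^-ddCT quantification for qPCR confirmation. The Wald test is
# deliberately desk-scale: gene-wise moment dispersion estimates with no
# shrinkage, because the downstream filters operate on raw p-values and
# fold-change thresholds, not on the dispersion fit itself.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over genes of
#' `count / geometric mean across samples`, using as reference only genes
#' with positive counts in every sample.
#'
#' @param counts genes x samples integer matrix (>= 2 samples).
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2) stop("need at least 2 samples")
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use))
    stop("no gene has positive counts in all samples; ",
         "consider a pseudo-reference over nonzero genes")
  apply(counts[use, , drop = FALSE], 2,
        function(col) exp(median(log(col) - log_gm[use])))
}

#' Negative-binomial Wald test for a two-group comparison
#'
#' Per gene: normalized counts are `count / size factor`; `baseMean` is
#' their mean over all samples, and genes with `baseMean` below
#' `base_mean_min` (default 10) are excluded from testing. The log2 fold
#' change is `log2(mean_treatment / mean_reference)` with each group mean
#' floored at 0.5 normalized counts to avoid infinities. The NB dispersion
#' `alpha` in `var = mu + alpha * mu^2` is estimated per gene by the method
#' of moments from the pooled within-group variance, floored at 1e-8. The
#' Wald statistic is the log2 fold change divided by its delta-method
#' standard error,
#' `SE^2 = (1/ln(2)^2) * sum_k (1/mean_k + alpha) / n_k`,
#' with a two-sided normal p-value.
#'
#' @param counts genes x samples integer matrix.
#' @param condition character/factor of length `ncol(counts)` with exactly
#'   two levels.
#' @param reference the level to treat as control; the other level is the
#'   treatment whose fold change is reported.
#' @param factors optional size factors (computed from `counts` when
#'   `NULL`).
#' @param base_mean_min minimum baseMean of normalized counts (default 10);
#'   set to 0 to test everything.
#' @param normalized_base_mean compute baseMean on normalized counts
#'   (default `TRUE`); `FALSE` uses raw counts for the filter.
#' @return data.frame, one row per tested gene: `gene_id`, `baseMean`,
#'   `log2FoldChange`, `stat`, `pvalue`.
#' @export
nb_wald_test <- function(counts, condition, reference,
                         factors = NULL, base_mean_min = 10,
                         normalized_base_mean = TRUE) {
  condition <- as.character(condition)
  lev <- unique(condition)
  if (length(lev) != 2) stop("condition must have exactly two groups")
  if (!reference %in% lev) stop("reference level not found in condition")
  treat <- setdiff(lev, reference)
  if (min(table(condition)) < 2) stop("need >= 2 samples per group")
  if (is.null(factors)) factors <- size_factors(counts)
  q <- sweep(counts, 2, factors, "/")
  base_mean <- if (normalized_base_mean) rowMeans(q) else rowMeans(counts)
  keep <- base_mean >= base_mean_min
  q <- q[keep, , drop = FALSE]
  bm <- rowMeans(q)

  it <- condition == treat
  n_t <- sum(it); n_r <- sum(!it)
  m_t <- rowMeans(q[, it, drop = FALSE])
  m_r <- rowMeans(q[, !it, drop = FALSE])
  v_t <- apply(q[, it, drop = FALSE], 1, var)
  v_r <- apply(q[, !it, drop = FALSE], 1, var)
  pooled_var <- ((n_t - 1) * v_t + (n_r - 1) * v_r) / (n_t + n_r - 2)
  alpha <- pmax((pooled_var - bm) / bm^2, 1e-8)

  m_tf <- pmax(m_t, 0.5)
  m_rf <- pmax(m_r, 0.5)
  lfc <- log2(m_tf / m_rf)
  se <- sqrt(((1 / m_tf + alpha) / n_t + (1 / m_rf + alpha) / n_r)) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  pval <- 2 * pnorm(-abs(stat))
  data.frame(gene_id = rownames(q), baseMean = bm, log2FoldChange = lfc,
             stat = stat, pvalue = pval, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Call differentially expressed genes
#'
#' Strict thresholds on the raw Wald p-value and the absolute log2 fold
#' change: down iff `p < p_cut` and `lfc < -lfc_cut`; up iff `p < p_cut`
#' and `lfc > lfc_cut`. A fold change of exactly `lfc_cut` is not called.
#' No multiple-testing correction is applied to the DEG p-values: the
#' operative filter is the joint p / fold-change threshold.
#'
#' @param records data.frame from [nb_wald_test()].
#' @param p_cut p-value cutoff (default 0.05).
#' @param lfc_cut absolute log2 fold-change cutoff (default 1).
#' @return list with character vectors `down` and `up`.
#' @export
call_degs <- function(records, p_cut = 0.05, lfc_cut = 1) {
  sig <- records$pvalue < p_cut
  list(down = records$gene_id[sig & records$log2FoldChange < -lfc_cut],
       up = records$gene_id[sig & records$log2FoldChange > lfc_cut])
}

#' Common DEGs across cell lines
#'
#' Per direction, genes called in at least `min_lines` of the cell lines;
#' the total is the size of the union of common-down and common-up sets. A
#' gene down in some lines and up in others can appear in both direction
#' sets.
#'
#' @param down_sets,up_sets lists of character vectors, one per cell line.
#' @param min_lines minimum number of lines (default 2).
#' @return list: `down`, `up`, `n_down`, `n_up`, `total`.
#' @export
common_degs <- function(down_sets, up_sets, min_lines = 2) {
  in_at_least <- function(sets, k) {
    tab <- table(unlist(lapply(sets, unique)))
    sort(names(tab)[tab >= k])
  }
  down <- in_at_least(down_sets, min_lines)
  up <- in_at_least(up_sets, min_lines)
  list(down = down, up = up, n_down = length(down), n_up = length(up),
       total = length(union(down, up)))
}

#' Relative quantification by the 2^-ddCT method
#'
#' `RQ = 2^-((ct_target_treated - ct_ref_treated) -
#' (ct_target_ctrl - ct_ref_ctrl))`: expression of the target gene in the
#' treated condition relative to control, normalized to a reference gene.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_ctrl,ct_ref_ctrl
#'   threshold-cycle values.
#' @return relative quantity (1 = no change, 0.5 = halved).
#' @export
ddct_quantify <- function(ct_target_treated, ct_ref_treated,
                          ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
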