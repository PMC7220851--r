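# From called regions to a candidate driver-gene list: focality filters,
# gene mapping, copy-number / expression Spearman correlation under BH FDR
# control, and merging of per-cohort lists.

#' Genes overlapping a set of regions
#'
#' @param regions region data.frame (`chrom`, `start`, `end`).
#' @param annotation a [genome_annotation()].
#' @return data.frame with `gene_id` and `region` (row index of the first
#'   overlapping region), one row per unique overlapping gene.
#' @export
genes_in_regions <- function(regions, annotation) {
  g <- annotation$genes
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    ov <- which(g$chrom == regions$chrom[i] &
                g$start < regions$end[i] & g$end > regions$start[i])
    if (length(ov))
      hits[[length(hits) + 1L]] <- data.frame(gene_id = g$gene_id[ov],
                                              region = i,
                                              stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(gene_id = character(), region = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[!duplicated(out$gene_id), , drop = FALSE]
}

#' Keep focal driver-candidate regions
#'
#' Retains only leaf regions -- those at the highest nesting level, with no
#' called region strictly inside them -- whose overlapping-gene count lies
#' in `[min_genes, max_genes]`. Focal, gene-sparse regions are the ones
#' most likely to pinpoint a driver.
#'
#' @param regions region data.frame with `is_leaf` populated (see
#'   [nesting_forest()]).
#' @param annotation a [genome_annotation()].
#' @param min_genes,max_genes inclusive bounds on the overlapping-gene
#'   count (defaults 1 and 100).
#' @return filtered region data.frame with an added `n_genes` column.
#' @export
filter_focal_regions <- function(regions, annotation, min_genes = 1,
                                 max_genes = 100) {
  if (is.null(regions$is_leaf)) stop("nesting levels not populated")
  g <- annotation$genes
  n_genes <- vapply(seq_len(nrow(regions)), function(i) {
    sum(g$chrom == regions$chrom[i] &
        g$start < regions$end[i] & g$end > regions$start[i])
  }, integer(1))
  regions$n_genes <- n_genes
  keep <- regions$is_leaf & n_genes >= min_genes & n_genes <= max_genes
  regions[keep, , drop = FALSE]
}

#' Spearman correlation of copy number and expression
#'
#' Rank correlation with average ranks on ties; the two-sided p-value uses
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2`
#' degrees of freedom. A constant vector leaves rho undefined: reported as
#' `NA` with a warning.
#'
#' @param cn,expression equal-length numeric vectors (length >= 4, finite).
#' @return list with `rho` and `p`.
#' @export
spearman_cn_expression <- function(cn, expression) {
  if (length(cn) != length(expression)) stop("unequal lengths")
  if (length(cn) < 4) stop("need at least 4 paired observations")
  if (any(!is.finite(cn)) || any(!is.finite(expression)))
    stop("non-finite values")
  if (length(unique(cn)) == 1 || length(unique(expression)) == 1) {
    warning("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  n <- length(cn)
  rho <- cor(rank(cn), rank(expression))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = max(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Step-up control of the false discovery rate: reject iff the BH-adjusted
#' q-value is at most `fdr_level`.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param fdr_level target FDR.
#' @return list with `q_values` and logical `reject`.
#' @export
bh_adjust <- function(p_values, fdr_level) {
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stopifnot(fdr_level > 0, fdr_level < 1)
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, reject = q <= fdr_level)
}

#' Correlation filter over a tested gene set
#'
#' Runs the Spearman copy-number / expression test for each gene, adjusts
#' within the tested set by Benjamini-Hochberg, and flags as selected the
#' genes with positive rho and q at most `fdr_level`. Genes with undefined
#' rho (constant input) are kept in the table but never selected, and are
#' excluded from the multiplicity adjustment.
#'
#' @param gene_ids genes to test (must be rows of both matrices).
#' @param cn,expression genes x samples matrices on aligned samples.
#' @param fdr_level correlation FDR level (default 0.1).
#' @return data.frame: `gene_id`, `spearman_rho`, `p_value`, `q_value`,
#'   `selected`.
#' @export
cn_expression_candidates <- function(gene_ids, cn, expression,
                                     fdr_level = 0.1) {
  stopifnot(all(gene_ids %in% rownames(cn)),
            all(gene_ids %in% rownames(expression)))
  res <- lapply(gene_ids, function(g) {
    suppressWarnings(spearman_cn_expression(cn[g, ], expression[g, ]))
  })
  rho <- vapply(res, `[[`, numeric(1), "rho")
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- rep(NA_real_, length(p))
  sel <- rep(FALSE, length(p))
  ok <- !is.na(p)
  if (any(ok)) {
    adj <- bh_adjust(p[ok], fdr_level)
    q[ok] <- adj$q_values
    sel[ok] <- adj$reject & rho[ok] > 0
  }
  data.frame(gene_id = gene_ids, spearman_rho = rho, p_value = p,
             q_value = q, selected = sel, stringsAsFactors = FALSE)
}

#' Select amplification-dependent candidate driver genes
#'
#' Maps focal regions to the genes they contain, tests each gene's
#' copy-number / expression Spearman correlation, adjusts within the tested
#' set (BH), and keeps genes with positive rho whose q-value passes
#' `fdr_level`.
#'
#' @param regions focal regions (typically [filter_focal_regions()]
#'   output).
#' @param annotation a [genome_annotation()].
#' @param cn genes x samples log2 copy-number matrix
#'   (see [gene_level_cn()]).
#' @param expression genes x samples log2 expression matrix.
#' @param fdr_level correlation FDR level (default 0.1).
#' @param cohort cohort label recorded on every row.
#' @return data.frame of retained candidates: `gene_id`, `region`,
#'   `spearman_rho`, `p_value`, `q_value`, `cohort`.
#' @export
select_candidates <- function(regions, annotation, cn, expression,
                              fdr_level = 0.1, cohort = "cohort") {
  gm <- genes_in_regions(regions, annotation)
  if (!nrow(gm))
    return(data.frame(gene_id = character(), region = integer(),
                      spearman_rho = numeric(), p_value = numeric(),
                      q_value = numeric(), cohort = character(),
                      stringsAsFactors = FALSE))
  tab <- cn_expression_candidates(gm$gene_id, cn, expression, fdr_level)
  tab$region <- gm$region
  tab$cohort <- cohort
  out <- tab[tab$selected, c("gene_id", "region", "spearman_rho",
                             "p_value", "q_value", "cohort")]
  rownames(out) <- NULL
  out
}

#' Merge per-cohort candidate lists
#'
#' Set union on `gene_id` with per-cohort provenance retained
#' (comma-separated cohort labels), in deterministic gene_id order. An
#' intersection merge is available for sensitivity analyses.
#'
#' @param ... candidate data.frames from [select_candidates()].
#' @param mode `"union"` (default) or `"intersection"`.
#' @return data.frame with `gene_id` and `cohorts`.
#' @export
merge_cohort_candidates <- function(..., mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  lists <- list(...)
  if (!length(lists)) stop("no candidate lists supplied")
  ids <- lapply(lists, function(x) unique(x$gene_id))
  genes <- if (mode == "union") Reduce(union, ids) else Reduce(intersect, ids)
  genes <- sort(genes)
  prov <- vapply(genes, function(g) {
    lab <- vapply(lists, function(x)
      if (g %in% x$gene_id) unique(x$cohort)[1] else NA_character_,
      character(1))
    paste(lab[!is.na(lab)], collapse = ",")
  }, character(1))
  data.frame(gene_id = genes, cohorts = unname(prov),
             stringsAsFactors = FALSE)
}
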