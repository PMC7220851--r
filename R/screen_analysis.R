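# siRNA loss-of-function screen analytics: plate normalization against
# non-targeting controls, hit calling on percent proliferation, replicate
# concordance, copy-number-gain frequency filtering, and single-siRNA
# deconvolution validation.

#' Normalize plate readouts to percent proliferation
#'
#' `percent = 100 * raw / mean(control raws)`, computed within each
#' (cell line, replicate) plate. Control wells therefore average 100% by
#' construction, and the normalization is invariant to rescaling a plate's
#' readouts. Replicates are kept separate; averaging happens at hit
#' calling.
#'
#' @param plates long data.frame with columns `cell_line`, `replicate`,
#'   `gene_id`, `raw`, `is_control` (see [simulate_screen()]).
#' @param control_wells optional character vector of well ids to use as
#'   controls, overriding the `is_control` column.
#' @return the input with an added `percent_proliferation` column.
#' @export
normalize_proliferation <- function(plates, control_wells = NULL) {
  need <- c("cell_line", "replicate", "raw", "is_control")
  stopifnot(all(need %in% names(plates)))
  if (!is.null(control_wells))
    plates$is_control <- plates$well %in% control_wells
  key <- paste(plates$cell_line, plates$replicate, sep = "\r")
  plates$percent_proliferation <- NA_real_
  for (k in unique(key)) {
    idx <- key == k
    ctrl <- plates$raw[idx & plates$is_control]
    if (!length(ctrl)) stop("plate without control wells: ", k)
    cm <- mean(ctrl)
    if (cm <= 0)
      stop("plate rejected: control mean <= 0 for ",
           sub("\r", " replicate ", k))
    plates$percent_proliferation[idx] <- 100 * plates$raw[idx] / cm
  }
  plates
}

#' Pearson concordance of duplicate screens
#'
#' @param rep1,rep2 paired raw readouts of the two replicates.
#' @return Pearson product-moment correlation.
#' @export
replicate_concordance <- function(rep1, rep2) {
  if (length(rep1) != length(rep2)) stop("replicates of unequal length")
  cor(rep1, rep2)
}

#' Call primary proliferation hits
#'
#' A gene is a hit when its replicate-mean percent proliferation is
#' strictly below `threshold` (default 60%, i.e. more than 40% inhibition).
#' Exactly 60% is not a hit. Both replicates must be present.
#'
#' @param percents normalized table from [normalize_proliferation()].
#' @param threshold percent-proliferation cutoff (default 60).
#' @param per_replicate if `TRUE`, require every replicate below the
#'   threshold instead of the replicate mean (default `FALSE`).
#' @return data.frame per (cell_line, gene): `cell_line`, `gene_id`,
#'   `percent_proliferation` (replicate mean), `hit`.
#' @export
call_primary_hits <- function(percents, threshold = 60,
                              per_replicate = FALSE) {
  d <- percents[!percents$is_control & !is.na(percents$gene_id), ,
                drop = FALSE]
  agg <- aggregate(percent_proliferation ~ cell_line + gene_id, d, mean)
  if (per_replicate) {
    mx <- aggregate(percent_proliferation ~ cell_line + gene_id, d, max)
    agg$hit <- mx$percent_proliferation < threshold
  } else {
    agg$hit <- agg$percent_proliferation < threshold
  }
  agg[order(agg$cell_line, agg$gene_id), , drop = FALSE]
}

#' Union and intersection of per-cell-line hit sets
#'
#' @param hit_sets named list of character vectors (hit gene ids per cell
#'   line).
#' @return list: `union` (hit in at least one line), `intersection` (hit in
#'   all lines), `n_union`, `n_intersection`, `n_per_line`.
#' @export
merge_hits <- function(hit_sets) {
  stopifnot(is.list(hit_sets), length(hit_sets) >= 1)
  u <- sort(Reduce(union, hit_sets))
  i <- sort(Reduce(intersect, hit_sets))
  list(union = u, intersection = i, n_union = length(u),
       n_intersection = length(i),
       n_per_line = vapply(hit_sets, length, integer(1)))
}

#' Filter hits by copy-number-gain frequency across a cell-line panel
#'
#' Keeps genes whose copy-number status is gain (`+`) or high gain (`++`)
#' in at least `min_lines` cell lines of the panel.
#'
#' @param cna_status genes x cell-lines character matrix with values `++`
#'   (high gain), `+` (gain), `/` (neutral), `-` (loss).
#' @param min_lines minimum number of gained lines (default 8).
#' @return character vector of retained gene ids.
#' @export
cng_frequency_filter <- function(cna_status, min_lines = 8) {
  if (!all(cna_status %in% c("++", "+", "/", "-")))
    stop("cna status values must be '++', '+', '/' or '-'")
  freq <- rowSums(cna_status == "+" | cna_status == "++")
  rownames(cna_status)[freq >= min_lines]
}

#' Deconvolution validation of a pooled-siRNA hit
#'
#' A hit is validated when the SMARTpool inhibition exceeds
#' `pool_threshold` and at least `min_singles` of the four single siRNAs
#' each achieve inhibition above `single_threshold`
#' (inhibition = 100 - percent proliferation). This rules out off-target
#' pool effects.
#'
#' @param pool_percent pool percent proliferation.
#' @param single_percents numeric vector of 4 single-siRNA percent
#'   proliferation values.
#' @param single_threshold,pool_threshold inhibition cutoffs (default 50).
#' @param min_singles singles required to pass (default 2).
#' @return logical validated flag.
#' @export
deconvolution_validate <- function(pool_percent, single_percents,
                                   single_threshold = 50,
                                   pool_threshold = 50, min_singles = 2) {
  if (length(single_percents) != 4) stop("expected 4 single-siRNA values")
  (100 - pool_percent) > pool_threshold &&
    sum((100 - single_percents) > single_threshold) >= min_singles
}

#' Validated-driver calls from pooled and deconvolution screens
#'
#' Labels a gene a validated driver when its pooled silencing inhibits
#' proliferation by more than `pool_threshold` percent in every tested cell
#' line and the deconvolution rule ([deconvolution_validate()]) passes in
#' at least `min_deconv_lines` lines.
#'
#' @param pool_percents data.frame `cell_line`, `gene_id`,
#'   `percent_proliferation` for the pooled validation screen.
#' @param deconv normalized deconvolution table (`cell_line`, `gene_id`,
#'   `sirna` in pool/s1..s4, `percent_proliferation`).
#' @param single_threshold,pool_threshold,min_singles passed through to
#'   [deconvolution_validate()].
#' @param min_deconv_lines lines in which deconvolution must confirm
#'   (default 2).
#' @return data.frame: `gene_id`, `all_lines_inhibited`, `deconv_lines`,
#'   `validated`.
#' @export
validated_drivers <- function(pool_percents, deconv, single_threshold = 50,
                              pool_threshold = 50, min_singles = 2,
                              min_deconv_lines = 2) {
  genes <- sort(unique(pool_percents$gene_id))
  res <- lapply(genes, function(g) {
    pp <- pool_percents$percent_proliferation[pool_percents$gene_id == g]
    all_inh <- length(pp) > 0 && all((100 - pp) > pool_threshold)
    dl <- 0L
    for (cl in unique(deconv$cell_line)) {
      d <- deconv[deconv$cell_line == cl & deconv$gene_id %in% g, ,
                  drop = FALSE]
      if (!nrow(d)) next
      pool <- d$percent_proliferation[d$sirna == "pool"]
      singles <- d$percent_proliferation[d$sirna %in%
                                         c("s1", "s2", "s3", "s4")]
      if (length(pool) == 1 && length(singles) == 4 &&
          deconvolution_validate(pool, singles, single_threshold,
                                 pool_threshold, min_singles))
        dl <- dl + 1L
    }
    data.frame(gene_id = g, all_lines_inhibited = all_inh,
               deconv_lines = dl,
               validated = all_inh && dl >= min_deconv_lines,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
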