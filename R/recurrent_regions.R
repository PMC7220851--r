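# Multi-scale recurrent copy-number-event caller. The statistic is the
# cohort aggregate of rectified log2 ratios; significance is assessed with a
# cyclic-shift permutation null and an exceedance-run-count FDR estimator,
# and calls at several smoothing scales are organised into a containment
# forest whose leaves are the most focal recurrent events.

#' Aggregate copy-number profile of a binned cohort
#'
#' Per-bin sum across samples of the rectified log2 ratios:
#' `sum(max(x, 0))` for gains, `sum(max(-x, 0))` for losses. This is the
#' continuous recurrence statistic that the region caller thresholds.
#'
#' @param binned a `binned_cohort` from [segments_to_bins()].
#' @param direction `"gain"` or `"loss"`.
#' @return list with `bins`, `direction` and numeric `values` (one per bin).
#' @export
aggregate_profile <- function(binned, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (nrow(binned$matrix) == 0) stop("empty cohort")
  sgn <- if (direction == "gain") 1 else -1
  list(bins = binned$bins, direction = direction,
       values = colSums(pmax(sgn * binned$matrix, 0)))
}

# 0-based inclusive [start, end] bin index ranges per chromosome, in grid
# order. Smoothing and run extraction never cross these boundaries.
chrom_ranges <- function(bins) {
  r <- rle(bins$chrom)
  ends <- cumsum(r$lengths)
  data.frame(chrom = r$values, start = c(0L, ends[-length(ends)]),
             end = ends - 1L, stringsAsFactors = FALSE)
}

# Count of sorted values >= t for each t (exact on ties).
count_ge <- function(sorted_vals, t) {
  length(sorted_vals) - findInterval(t, sorted_vals, left.open = TRUE)
}

#' Call recurrent copy-number regions with permutation FDR control
#'
#' Reconstruction of a multi-scale recurrent-event caller. The aggregate
#' profile is smoothed with a centered box kernel at each half-width in
#' `scales`; a null distribution is built by cyclically shifting every
#' sample's binned profile within each chromosome by an independent uniform
#' offset and re-aggregating, `n_permutations` times. At each scale the
#' caller picks the smallest threshold `t` whose estimated FDR -- mean null
#' count of exceedance runs above `t` divided by the observed run count --
#' fits within that scale's share of the budget (`fdr_level` split evenly
#' across scales, so the union of calls over the whole scale space keeps
#' the configured level), and reports the maximal above-threshold runs as
#' regions (a run whose peak equals `t` exactly is called); the reported
#' `q` is the scale-count-adjusted FDR estimate. Identical intervals
#' re-found at several scales are collapsed to the most focal call.
#' Finally calls from all scales are assembled into a containment forest
#' and nesting levels assigned; higher levels are more focal.
#'
#' The cyclic-shift null preserves each sample's per-chromosome value
#' multiset and its serial autocorrelation, which is the key property of
#' segmented copy-number noise.
#'
#' @param binned a `binned_cohort`.
#' @param direction `"gain"` or `"loss"`; the two directions are called in
#'   separate passes.
#' @param fdr_level target false discovery rate for called regions,
#'   in (0, 1).
#' @param scales increasing integer half-widths (bins) of the box kernel;
#'   0 means no smoothing.
#' @param n_permutations number of cyclic-shift permutations (values below
#'   100 trigger a warning: the FDR estimate becomes unstable).
#' @param seed integer seed for the permutation offsets.
#' @return data.frame of regions: `chrom`, `start`, `end` (bin-aligned bp),
#'   `direction`, `scale`, `peak_stat`, `q`, `nesting_level`, `parent`
#'   (row index of the smallest strictly containing region or `NA`),
#'   `is_leaf`. Zero rows when nothing is called.
#' @export
call_recurrent_regions <- function(binned, direction = c("gain", "loss"),
                                   fdr_level = 0.01,
                                   scales = c(0, 1, 2, 4, 8, 16),
                                   n_permutations = 500, seed = 1) {
  direction <- match.arg(direction)
  stopifnot(fdr_level > 0, fdr_level < 1, length(scales) >= 1)
  scales <- as.integer(scales)
  if (is.unsorted(scales, strictly = TRUE))
    stop("scales must be strictly increasing")
  if (n_permutations < 100)
    warning("n_permutations < 100: FDR estimate will be unstable")

  sgn <- if (direction == "gain") 1 else -1
  Rm <- pmax(sgn * binned$matrix, 0)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      scale = integer(), peak_stat = numeric(),
                      q = numeric(), nesting_level = integer(),
                      parent = integer(), is_leaf = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(Rm) == 0 || all(Rm == 0)) return(empty)

  cr <- chrom_ranges(binned$bins)
  n_samples <- nrow(Rm)
  n_chrom <- nrow(cr)
  lens <- cr$end - cr$start + 1L

  set.seed(seed)
  # offsets[p, (s-1)*n_chrom + c] ~ Uniform{0, ..., len_c - 1}
  offsets <- matrix(0L, nrow = n_permutations, ncol = n_samples * n_chrom)
  for (s in seq_len(n_samples)) {
    for (cc in seq_len(n_chrom)) {
      offsets[, (s - 1L) * n_chrom + cc] <-
        sample.int(lens[cc], n_permutations, replace = TRUE) - 1L
    }
  }

  A <- colSums(Rm)
  null_ex <- perm_null_extrema_cpp(t(Rm), cr$start, cr$end, scales, offsets)

  # the per-scale budget splits the level across the scale space, so the
  # union of calls over all scales keeps the configured FDR
  alpha_scale <- fdr_level / length(scales)
  regions <- list()
  for (k in seq_along(scales)) {
    S <- box_smooth_cpp(A, cr$start, cr$end, scales[k])
    obs <- profile_extrema_cpp(S, cr$start, cr$end)
    cand <- sort(unique(S[S > 0]))
    if (!length(cand)) next
    obs_runs <- count_ge(obs$max, cand) - count_ge(obs$min, cand)
    null_runs <- (count_ge(null_ex[[k]]$max, cand) -
                  count_ge(null_ex[[k]]$min, cand)) / n_permutations
    fdr_hat <- null_runs / pmax(obs_runs, 1)
    ok <- obs_runs >= 1 & fdr_hat <= alpha_scale
    if (!any(ok)) next
    t_star <- cand[which(ok)[1]]
    q_star <- min(1, fdr_hat[which(ok)[1]] * length(scales))
    for (cc in seq_len(n_chrom)) {
      idx <- (cr$start[cc] + 1L):(cr$end[cc] + 1L)
      r <- rle(S[idx] >= t_star)
      pos <- cumsum(c(1L, r$lengths))
      for (j in which(r$values)) {
        b0 <- idx[pos[j]]               # first bin (1-based, grid)
        b1 <- idx[pos[j + 1L] - 1L]     # last bin
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = cr$chrom[cc],
          start = binned$bins$start[b0], end = binned$bins$end[b1],
          direction = direction, scale = scales[k],
          peak_stat = max(S[b0:b1]), q = q_star,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(regions)) return(empty)
  out <- do.call(rbind, regions)
  # identical intervals re-found at several scales collapse to the most
  # focal (smallest-scale) call
  out <- out[order(out$chrom, out$start, out$end, out$scale), , drop = FALSE]
  out <- out[!duplicated(out[c("chrom", "start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  nesting_forest(out)
}

#' Assemble the containment forest of called regions
#'
#' Populates `parent` (row index of the smallest strictly containing
#' region, or `NA` for roots), `nesting_level` (number of strictly
#' containing regions), and `is_leaf` (no called region strictly inside;
#' leaves are the most focal calls).
#'
#' @param regions data.frame of regions from a single
#'   [call_recurrent_regions()] pass, with `chrom`, `start`, `end`.
#' @return the same data.frame with `parent`, `nesting_level`, `is_leaf`
#'   filled in.
#' @export
nesting_forest <- function(regions) {
  n <- nrow(regions)
  parent <- rep(NA_integer_, n)
  level <- integer(n)
  leaf <- rep(TRUE, n)
  if (n > 1) {
    width <- regions$end - regions$start
    for (i in seq_len(n)) {
      # regions strictly containing region i
      cont <- which(regions$chrom == regions$chrom[i] &
                    regions$start <= regions$start[i] &
                    regions$end >= regions$end[i] &
                    width > width[i])
      level[i] <- length(cont)
      if (length(cont)) {
        parent[i] <- cont[which.min(width[cont])]
        leaf[cont] <- FALSE
      }
    }
  }
  regions$nesting_level <- level
  regions$parent <- parent
  regions$is_leaf <- leaf
  regions
}

#' Write called regions as BED plus a q-value TSV
#'
#' BED name field is `direction:scale:level`, score is the peak statistic.
#'
#' @param regions region data.frame.
#' @param bed_path output BED path.
#' @param tsv_path optional TSV with all columns including `q`.
#' @export
write_regions_bed <- function(regions, bed_path, tsv_path = NULL) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end,
                    name = sprintf("%s:%d:%d", regions$direction,
                                   regions$scale, regions$nesting_level),
                    score = regions$peak_stat)
  write.table(bed, bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  if (!is.null(tsv_path))
    write.table(regions, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(bed_path)
}

#' Overlap of called regions with a set of true loci
#'
#' Utility for simulation-based FDR scoring: a region is counted true if it
#' overlaps any locus in `loci` (same chromosome, intervals intersect).
#'
#' @param regions region data.frame (`chrom`, `start`, `end`).
#' @param loci data.frame of true loci (`chrom`, `start`, `end`).
#' @return logical vector, one per region.
#' @export
region_truth_overlap <- function(regions, loci) {
  vapply(seq_len(nrow(regions)), function(i) {
    any(loci$chrom == regions$chrom[i] &
        loci$start < regions$end[i] &
        loci$end > regions$start[i])
  }, logical(1))
}
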