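# Genome model: chromosome grid, gene annotation, segmented copy-number
# profiles. All internal coordinates are 0-based half-open; the SEG dialect
# on disk is 1-based inclusive and is converted at the IO boundary.

#' Construct a genome annotation
#'
#' Bundles an ordered chromosome table with a gene table and validates the
#' basic contracts every downstream step relies on: unique gene identifiers,
#' gene intervals within their chromosome, 0-based half-open coordinates.
#'
#' @param chromosomes data.frame with columns `chrom` (character) and
#'   `length` (bp). Order defines genome order.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open bp) and `strand` (`"+"` or `"-"`). Strand is carried
#'   through but ignored by all computations: copy number and expression are
#'   strand-agnostic.
#' @return An object of class `genome_annotation`: a list with elements
#'   `chromosomes` and `genes`.
#' @export
genome_annotation <- function(chromosomes, genes) {
  stopifnot(is.data.frame(chromosomes), all(c("chrom", "length") %in% names(chromosomes)))
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  genes$chrom <- as.character(genes$chrom)
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome names in annotation")
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_ids in annotation")
  if (!all(genes$chrom %in% chromosomes$chrom))
    stop("gene on unannotated chromosome: ",
         paste(setdiff(genes$chrom, chromosomes$chrom), collapse = ", "))
  if (any(genes$start < 0) || any(genes$end <= genes$start))
    stop("gene intervals must satisfy 0 <= start < end")
  len <- chromosomes$length[match(genes$chrom, chromosomes$chrom)]
  if (any(genes$end > len))
    stop("gene interval exceeds chromosome length: ",
         paste(genes$gene_id[genes$end > len], collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosomes (%.1f Mb), %d genes\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$genes)))
  invisible(x)
}

# Validate one cohort of segmented profiles: a data.frame with columns
# sample, chrom, start, end, log2_ratio; per sample & chromosome the
# segments must be sorted and non-overlapping.
validate_seg_cohort <- function(cohort) {
  need <- c("sample", "chrom", "start", "end", "log2_ratio")
  stopifnot(is.data.frame(cohort), all(need %in% names(cohort)))
  if (nrow(cohort) == 0) return(invisible(cohort))
  if (any(!is.finite(cohort$log2_ratio)))
    stop("non-finite log2_ratio in segmented cohort")
  if (any(cohort$end <= cohort$start))
    stop("segment with end <= start")
  key <- paste(cohort$sample, cohort$chrom, sep = "\r")
  for (k in unique(key)) {
    seg <- cohort[key == k, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)])) {
      i <- which(seg$start[-1] < seg$end[-nrow(seg)])[1]
      stop(sprintf("overlapping segments for sample %s at %s:%d-%d / %d-%d",
                   seg$sample[1], seg$chrom[1],
                   seg$start[i], seg$end[i], seg$start[i + 1], seg$end[i + 1]))
    }
  }
  invisible(cohort)
}

#' Read segmented copy-number profiles
#'
#' Reads a SEG-style tab-separated file with header columns `sample`,
#' `chromosome`, `start`, `end`, `log2_ratio`. On disk coordinates are
#' 1-based inclusive (the common SEG dialect); they are converted to the
#' package's internal 0-based half-open convention. Rows are grouped by
#' sample and sorted by chromosome and start so the result is deterministic
#' regardless of input row order.
#'
#' @param path path to the SEG file.
#' @return data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `log2_ratio` (0-based half-open).
#' @export
read_seg <- function(path) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("sample", "chromosome", "start", "end", "log2_ratio")
  if (!all(need %in% names(raw)))
    stop("SEG file must have header columns: ", paste(need, collapse = ", "))
  if (nrow(raw) == 0) {
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      log2_ratio = numeric(), stringsAsFactors = FALSE))
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' value at line %d of %s: '%s'",
                   col, bad[1] + 1L, path, raw[[col]][bad[1]]))
    x
  }
  cohort <- data.frame(sample = raw$sample, chrom = raw$chromosome,
                       start = num("start") - 1, end = num("end"),
                       log2_ratio = num("log2_ratio"),
                       stringsAsFactors = FALSE)
  cohort <- cohort[order(cohort$sample, cohort$chrom, cohort$start), ,
                   drop = FALSE]
  rownames(cohort) <- NULL
  validate_seg_cohort(cohort)
  cohort
}

#' Write segmented profiles as a SEG-style file
#'
#' Inverse of [read_seg()]: converts internal 0-based half-open coordinates
#' back to the 1-based inclusive on-disk dialect.
#'
#' @param cohort segmented cohort data.frame.
#' @param path output path.
#' @export
write_seg <- function(cohort, path) {
  validate_seg_cohort(cohort)
  out <- data.frame(sample = cohort$sample, chromosome = cohort$chrom,
                    start = cohort$start + 1, end = cohort$end,
                    log2_ratio = cohort$log2_ratio)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene annotation
#'
#' Gene tables travel as BED-like TSV (0-based half-open on disk, no
#' conversion) with columns `gene_id`, `chrom`, `start`, `end`, `strand`;
#' chromosome tables as TSV with `chrom`, `length`.
#'
#' @param genes_path path to the gene TSV.
#' @param chrom_path path to the chromosome TSV.
#' @return a [genome_annotation()].
#' @export
read_annotation <- function(genes_path, chrom_path) {
  genome_annotation(read.delim(chrom_path, stringsAsFactors = FALSE),
                    read.delim(genes_path, stringsAsFactors = FALSE))
}

#' @rdname read_annotation
#' @param annotation a `genome_annotation`.
#' @export
write_annotation <- function(annotation, genes_path, chrom_path) {
  write.table(annotation$genes, genes_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(annotation$chromosomes, chrom_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Read / write a genes-by-samples matrix as TSV
#'
#' The first column (`gene_id`) is the row index; remaining columns are
#' samples. Used for expression and count matrices.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d[[1]]
  m
}

#' @rdname read_matrix_tsv
#' @param m matrix with gene rownames.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Piecewise-constant integral of a sorted, non-overlapping segment list.
# Returns F(x) = integral over [0, x) of the segment value (0 where
# uncovered) evaluated at each x in xs. The workhorse behind binning and
# gene-level copy number: weighted means become differences of F.
seg_integral <- function(start, end, value, xs) {
  if (length(start) == 0) return(numeric(length(xs)))
  knots <- c(0, as.vector(rbind(start, end)))
  vals <- c(0, as.vector(rbind(value, numeric(length(value)))))
  widths <- diff(knots)
  cum <- c(0, cumsum(vals[-length(vals)] * widths))
  j <- findInterval(xs, knots)
  cum[j] + vals[j] * (xs - knots[j])
}

#' Bin grid for a genome
#'
#' Fixed-width bins per chromosome (last bin truncated at the chromosome
#' end), in genome order.
#'
#' @param annotation a [genome_annotation()].
#' @param bin_size bin width in bp.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
bin_grid <- function(annotation, bin_size) {
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop("bin_size must be a positive number")
  out <- lapply(seq_len(nrow(annotation$chromosomes)), function(i) {
    len <- annotation$chromosomes$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = annotation$chromosomes$chrom[i], start = starts,
               end = pmin(starts + bin_size, len), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Discretize a segmented cohort onto a fixed bin grid
#'
#' Each bin value is the length-weighted mean log2 ratio over the bin, with
#' uncovered genome counting as diploid (log2 ratio 0). Fully uncovered bins
#' are therefore 0. The total (value x width) mass of the profile is
#' conserved exactly.
#'
#' @param cohort segmented cohort data.frame (see [read_seg()]).
#' @param annotation a [genome_annotation()].
#' @param bin_size bin width in bp; must be positive.
#' @return An object of class `binned_cohort`: list with `bins` (the grid),
#'   `samples`, and `matrix` (samples x bins log2 ratios).
#' @export
segments_to_bins <- function(cohort, annotation, bin_size) {
  validate_seg_cohort(cohort)
  if (nrow(cohort) > 0 &&
      !all(cohort$chrom %in% annotation$chromosomes$chrom))
    stop("segment on unannotated chromosome")
  bins <- bin_grid(annotation, bin_size)
  samples <- sort(unique(cohort$sample))
  mat <- matrix(0, nrow = length(samples), ncol = nrow(bins),
                dimnames = list(samples, NULL))
  for (s in samples) {
    for (cn in unique(cohort$chrom[cohort$sample == s])) {
      seg <- cohort[cohort$sample == s & cohort$chrom == cn, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      idx <- which(bins$chrom == cn)
      Fe <- seg_integral(seg$start, seg$end, seg$log2_ratio, bins$end[idx])
      Fs <- seg_integral(seg$start, seg$end, seg$log2_ratio, bins$start[idx])
      mat[s, idx] <- (Fe - Fs) / (bins$end[idx] - bins$start[idx])
    }
  }
  structure(list(bins = bins, samples = samples, matrix = mat),
            class = "binned_cohort")
}

#' @export
print.binned_cohort <- function(x, ...) {
  cat(sprintf("binned_cohort: %d samples x %d bins on %d chromosomes\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$bins$chrom))))
  invisible(x)
}

#' Gene-level copy number from segmented profiles
#'
#' Length-weighted mean log2 ratio of the segments overlapping each gene
#' body, with uncovered gene territory counting as diploid (0). Robust to
#' breakpoints falling inside genes, and invariant to splitting a segment
#' into adjacent pieces with equal log2 ratio.
#'
#' @param cohort segmented cohort data.frame.
#' @param annotation a [genome_annotation()]; must contain genes.
#' @return genes x samples numeric matrix of log2 copy-number ratios.
#' @export
gene_level_cn <- function(cohort, annotation) {
  validate_seg_cohort(cohort)
  genes <- annotation$genes
  if (nrow(genes) == 0) stop("annotation contains no genes")
  samples <- sort(unique(cohort$sample))
  mat <- matrix(0, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$gene_id, samples))
  for (s in samples) {
    sub <- cohort[cohort$sample == s, , drop = FALSE]
    for (cn in unique(sub$chrom)) {
      gi <- which(genes$chrom == cn)
      if (!length(gi)) next
      seg <- sub[sub$chrom == cn, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      Fe <- seg_integral(seg$start, seg$end, seg$log2_ratio, genes$end[gi])
      Fs <- seg_integral(seg$start, seg$end, seg$log2_ratio, genes$start[gi])
      mat[gi, s] <- (Fe - Fs) / (genes$end[gi] - genes$start[gi])
    }
  }
  mat
}
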