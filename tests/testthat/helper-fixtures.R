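# Small fixtures built in code.

# A toy genome: one or more chromosomes with evenly spaced genes.
toy_annotation <- function(chrom_lengths = c(chr1 = 1e6),
                           genes = NULL) {
  chroms <- data.frame(chrom = names(chrom_lengths),
                       length = unname(chrom_lengths),
                       stringsAsFactors = FALSE)
  if (is.null(genes))
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character(), stringsAsFactors = FALSE)
  genome_annotation(chroms, genes)
}

toy_genes <- function(chrom, starts, width = 1e3,
                      ids = sprintf("g%03d", seq_along(starts))) {
  data.frame(gene_id = ids, chrom = chrom, start = starts,
             end = starts + width,
             strand = rep(c("+", "-"), length.out = length(starts)),
             stringsAsFactors = FALSE)
}

seg_row <- function(sample, chrom, start, end, log2) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             log2_ratio = log2, stringsAsFactors = FALSE)
}

# Write a SEG file (1-based inclusive on disk) from 1-based rows.
write_seg_text <- function(path, rows) {
  writeLines(c("sample\tchromosome\tstart\tend\tlog2_ratio", rows), path)
}

# A binned cohort built directly from a samples x bins matrix on a single
# chromosome grid (bin size 100 bp), bypassing segmentation.
toy_binned <- function(mat, bin_size = 100, chrom = "chr1") {
  if (is.character(chrom) && length(chrom) == 1)
    chrom <- rep(chrom, ncol(mat))
  stopifnot(length(chrom) == ncol(mat))
  pos <- unlist(lapply(rle(chrom)$lengths, seq_len)) - 1L
  bins <- data.frame(chrom = chrom, start = pos * bin_size,
                     end = (pos + 1L) * bin_size, stringsAsFactors = FALSE)
  rownames(mat) <- sprintf("S%02d", seq_len(nrow(mat)))
  structure(list(bins = bins, samples = rownames(mat), matrix = mat),
            class = "binned_cohort")
}

# Random non-overlapping segment cohort for property tests.
random_cohort <- function(seed, n_samples = 3, chrom_len = 1e5) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_samples)) {
    cuts <- sort(sample(seq(0, chrom_len, by = 100), 8))
    cuts <- unique(c(0, cuts, chrom_len))
    rows[[s]] <- data.frame(sample = sprintf("S%d", s), chrom = "chr1",
                            start = cuts[-length(cuts)], end = cuts[-1],
                            log2_ratio = round(rnorm(length(cuts) - 1), 3),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
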