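# Fixture builders shared across test files.

iv <- function(chrom, start, end, strand = ".") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

# random stranded intervals on a couple of chromosomes
rand_intervals <- function(n, max_pos = 10000, chroms = c("chr1", "chr2"),
                           strands = c("+", "-")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(500, n, replace = TRUE)
  iv(sample(chroms, n, replace = TRUE), start, start + len,
     sample(strands, n, replace = TRUE))
}

# tiny deterministic annotation used by classification tests
toy_annotation <- function() {
  transcript_table(
    id = c("m1", "m2", "mi1", "sn1", "r1", "l1"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(100, 400, 150, 2000, 50, 500),
    end = c(300, 700, 220, 2100, 200, 1500),
    strand = c("+", "+", "+", "-", "+", "-"),
    rna_class = c("mRNA", "mRNA", "miRNA", "snRNA", "rRNA", "lncRNA"))
}

# scaled-down simulation used by unit tests (the acceptance suite runs the
# full defaults)
small_sim_config <- function(seed = 11L, ...) {
  sim_config(seed = seed,
             n_chroms = 3L, chrom_length = 400000L,
             class_counts = c(mRNA = 40L, lncRNA = 20L, miRNA = 8L,
                              snRNA = 6L, tRNA = 6L, piwiRNA = 6L),
             frac_hif_targets = 1, hif_target_min_lfc = 0.8,
             n_novel_intergenic = 5L, n_novel_antisense = 3L,
             novel_length_range = c(500, 4000),
             ...)
}

# uniform-value coverage track over one tiny chromosome
flat_track <- function(value, len = 10000L, chrom = "chr1",
                       mark = "RNApol2", condition = "normoxia") {
  coverage_track(setNames(list(rep(value, len)), chrom), mark, condition)
}
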