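# shared fixtures and small oracles for the test suite

table1 <- function() {
  read_region_table(qtlcoloc_example("table1_regions.csv"))
}

table1_overlap <- function(rt = table1()) overlap_regions(rt)

loci_by_trait <- function(rt, trait) rt$loci[rt$loci$trait == trait, ]

synthetic_map <- function() {
  read_marker_map(qtlcoloc_example("marker_map_synthetic.csv"))
}

synthetic_regions <- function() {
  read_region_set(qtlcoloc_example("segregating_regions_synthetic.csv"))
}

sluc_anchors <- function() {
  read_locus_table(qtlcoloc_example("sluc_anchors_synthetic.csv"))
}

fig6_loci <- function() {
  read_locus_table(qtlcoloc_example("fig6_loci_synthetic.csv"))
}

ocb_tested <- function() {
  read_region_set(qtlcoloc_example("ocb_tested_synthetic.csv"))
}

# textbook one-way ANOVA F from group sums of squares (independent oracle)
oneway_F_oracle <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# exact null distribution of the concordance chi-square for a handful of
# regions by full enumeration of the per-region multinomial patterns
concordance_exact_p <- function(obs_stat, probs, expected) {
  n <- nrow(probs)
  grids <- rep(list(1:4), n)
  combos <- as.matrix(expand.grid(grids))
  p_tail <- 0
  for (i in seq_len(nrow(combos))) {
    pat <- combos[i, ]
    pr <- prod(probs[cbind(seq_len(n), pat)])
    counts <- tabulate(pat, nbins = 4)
    stat <- sum((counts - expected)^2 / expected)
    if (stat >= obs_stat - 1e-12) p_tail <- p_tail + pr
  }
  p_tail
}

# tiny two-marker map on one chromosome, d cM apart
two_marker_map <- function(d, chrom = "1", start = 10) {
  genome_map(data.frame(marker = c("mA", "mB"), chrom = chrom,
                        pos_cM = c(start, start + d)),
             chromosomes = data.frame(chrom = chrom,
                                      length_cM = start + d + 10))
}
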