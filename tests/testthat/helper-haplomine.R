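# Shared fixtures: published group summaries (used as *inputs*), tiny
# in-code VCF/GFF3 builders, and an independent brute-force oracle for the
# stepwise range test.

# Plant-height group summaries per haplotype of the causal dwarfing gene
# (four major haplotypes; n = 25/91/28/46 and 26/92/28/56).
table1_sd1 <- function(location = c("Guangzhou", "Yangjiang")) {
  location <- match.arg(location)
  if (location == "Guangzhou")
    data.frame(label = paste0("Hap", 1:4), n = c(25, 91, 28, 46),
               mean = c(91.8, 120.7, 136.8, 137.2), sd = c(10.1, 24.2, 18.2, 21.3))
  else
    data.frame(label = paste0("Hap", 1:4), n = c(26, 92, 28, 56),
               mean = c(90.1, 125.1, 142.9, 142.9), sd = c(8.9, 19.1, 19.2, 18.0))
}

# Two-haplotype gene summaries (t-test worked example)
table1_two_hap <- function(location = c("Guangzhou", "Yangjiang")) {
  location <- match.arg(location)
  if (location == "Guangzhou")
    list(h1 = list(n = 174, mean = 122.6, sd = 26.7),
         h2 = list(n = 88, mean = 141.0, sd = 17.8))
  else
    list(h1 = list(n = 154, mean = 124.8, sd = 24.0),
         h2 = list(n = 85, mean = 143.4, sd = 17.0))
}

# Six two-gene haplotype combinations with per-column printed summaries
# (3 shoot-length environments, 2 plant-height locations).
table3_combos <- function() {
  data.frame(combo = paste0("C", 1:6),
             hapA = c("Hap1", "Hap2", "Hap3", "Hap3", "Hap4", "Hap4"),
             hapB = c("Hap1", "Hap1", "Hap1", "Hap2", "Hap1", "Hap2"))
}

table3_summaries <- function() {
  lab <- paste0("C", 1:6)
  list(
    `SL:GST` = data.frame(label = lab, n = c(19, 74, 8, 15, 14, 29),
                          mean = c(27.7, 30.9, 36.5, 36.3, 40.2, 38.0),
                          sd = c(2.3, 3.7, 4.6, 3.9, 5.0, 4.9)),
    `SL:GSF` = data.frame(label = lab, n = c(20, 74, 8, 15, 14, 29),
                          mean = c(24.0, 27.6, 27.9, 27.4, 31.9, 31.5),
                          sd = c(2.5, 3.3, 3.7, 4.2, 3.4, 4.3)),
    `SL:DST` = data.frame(label = lab, n = c(20, 74, 8, 15, 14, 29),
                          mean = c(18.6, 22.0, 22.9, 23.3, 25.4, 25.4),
                          sd = c(2.2, 2.7, 3.5, 3.2, 3.3, 3.3)),
    `PH:Guangzhou` = data.frame(label = lab, n = c(20, 74, 8, 15, 14, 29),
                                mean = c(91.6, 122.7, 130.6, 140.6, 141.7, 134.9),
                                sd = c(9.8, 23.6, 19.5, 16.9, 19.3, 22.3)),
    `PH:Yangjiang` = data.frame(label = lab, n = c(16, 67, 8, 15, 13, 26),
                                mean = c(91.9, 121.9, 138.0, 146.0, 141.7, 138.8),
                                sd = c(10.0, 18.0, 20.9, 19.1, 18.7, 20.7)))
}

write_mini_vcf <- function(lines, samples = c("s1", "s2", "s3")) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts), collapse = "\t")
}

write_mini_gff3 <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

# Independent oracle for Duncan's protected range procedure: a pair of
# mean-sorted groups is non-significant iff SOME range containing it
# (including itself) fails its own least-significant-range test. This is the
# closed-form unfolding of the stepwise sweep, computed here by direct
# enumeration of all containing ranges -- no absorb bookkeeping shared with
# the implementation.
oracle_duncan_nonsig <- function(n, mean, sd, alpha = 0.05) {
  o <- order(-mean)
  n <- n[o]; m <- mean[o]; s <- sd[o]
  k <- length(m)
  mse <- sum((n - 1) * s^2) / sum(n - 1)
  dfe <- sum(n) - k
  fails <- function(a, b) {
    span <- b - a + 1
    alpha_p <- 1 - (1 - alpha)^(span - 1)
    nh <- 2 / (1 / n[a] + 1 / n[b])
    (m[a] - m[b]) < qtukey(1 - alpha_p, span, dfe) * sqrt(mse / nh)
  }
  nonsig <- diag(TRUE, k)
  for (i in 1:k) for (j in i:k) {
    if (i == j) next
    hit <- FALSE
    for (a in 1:i) for (b in j:k) if (fails(a, b)) hit <- TRUE
    nonsig[i, j] <- nonsig[j, i] <- hit
  }
  list(nonsig = nonsig, labels_sorted = o)
}

random_summary_groups <- function(k, rng_mean = c(0, 30), rng_sd = c(2, 20),
                                  rng_n = c(5, 100)) {
  data.frame(label = paste0("g", seq_len(k)),
             n = sample(rng_n[1]:rng_n[2], k, replace = TRUE),
             mean = round(runif(k, rng_mean[1], rng_mean[2]), 2),
             sd = round(runif(k, rng_sd[1], rng_sd[2]), 2))
}
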