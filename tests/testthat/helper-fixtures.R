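# Small constructors used across the test files.

variant_row <- function(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                        qual = 100, mq = 60, qd = 25, fs = 1,
                        sample = "s1", ad_ref = 10L, ad_alt = 10L,
                        masked = FALSE) {
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 qual = qual, mq = mq, qd = qd, fs = fs, sample = sample,
                 ad_ref = ad_ref, ad_alt = ad_alt, dp = ad_ref + ad_alt,
                 masked = masked)
}

# Independent brute-force Weir-Cockerham variance components on explicit
# per-population frequencies and sample sizes: literal textbook formulas,
# one locus at a time, no shared code with the package implementation.
bruteforce_wc <- function(p_mat, n_mat) {
  A <- 0
  B <- 0
  for (l in seq_len(ncol(p_mat))) {
    p <- p_mat[, l]
    n <- n_mat[, l]
    r <- length(p)
    nbar <- mean(n)
    pbar <- sum(n * p) / sum(n)
    S2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    MSG <- sum(n * p * (1 - p)) / sum(n - 1)
    MSP <- nbar * S2
    A <- A + (MSP - MSG) / nc
    B <- B + MSG
  }
  A / (A + B)
}

# Independent diploid Weir-Cockerham (1984) theta from genotype counts of
# two populations: n_i individuals, genotype counts per population
# (hom ref, het, hom alt). Ratio of averages over loci.
wc84_theta_genotypes <- function(geno_a, geno_b) {
  # geno_*: matrices loci x 3
  num <- 0
  den <- 0
  for (l in seq_len(nrow(geno_a))) {
    n1 <- sum(geno_a[l, ])
    n2 <- sum(geno_b[l, ])
    p1 <- (2 * geno_a[l, 3] + geno_a[l, 2]) / (2 * n1)
    p2 <- (2 * geno_b[l, 3] + geno_b[l, 2]) / (2 * n2)
    h1 <- geno_a[l, 2] / n1
    h2 <- geno_b[l, 2] / n2
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# A tiny two-gene reference + annotation written to temp files.
write_toy_annotation <- function(dir = file.path(tempdir(), "toy_annot")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # gene1: + strand, two exons; gene2: - strand, one exon
  # chromosome: 60 bp
  chrom <- paste0(
    "ATGGCTGCTAAAGGT", # 1-15
    "TTTTT",           # 16-20 intron
    "GCTGCTGCTTGA",    # 21-32 exon2 of gene1
    "AAAA",            # 33-36 spacer
    "TCACATCATCATCATCATCAT", # 37-57 gene2 (- strand CDS)
    "AAA"
  )
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chr1 toy", chrom), fa)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tmRNA\t1\t32\t.\t+\t.\tID=t1",
    "chr1\ttoy\tCDS\t1\t15\t.\t+\t0\tID=c1;Parent=t1",
    "chr1\ttoy\tCDS\t21\t32\t.\t+\t0\tID=c2;Parent=t1",
    "chr1\ttoy\tmRNA\t37\t57\t.\t-\t.\tID=t2",
    "chr1\ttoy\tCDS\t37\t57\t.\t-\t0\tID=c3;Parent=t2"
  ), gff)
  list(fasta = fa, gff = gff, chrom = chrom)
}
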