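# Independent oracle: enumerate the nine single-base mutants of a codon
# against the standard code directly.
enumerate_counts <- function(codon, stop_nonsyn = TRUE) {
  code <- as.vector(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  aa <- code[[codon]]
  syn <- 0
  for (p in 1:3) {
    n_syn <- 0
    n_all <- 0
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      m <- codon
      substr(m, p, p) <- b
      if (code[[m]] == "*" && !stop_nonsyn) next
      n_all <- n_all + 1
      if (code[[m]] == aa) n_syn <- n_syn + 1
    }
    if (n_all > 0) syn <- syn + n_syn / n_all
  }
  c(syn = syn, nonsyn = 3 - ifelse(stop_nonsyn, 0, 0) - syn)
}

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

test_that("site counts match exhaustive enumeration for all 61 sense codons", {
  codons <- sense_codons()
  got <- codon_site_counts(codons)
  for (i in seq_along(codons)) {
    exp_i <- enumerate_counts(codons[i])
    expect_equal(got$syn_sites[i], unname(exp_i["syn"]),
                 info = codons[i])
  }
  # per-codon sites always sum to exactly 3
  expect_equal(got$syn_sites + got$nonsyn_sites, rep(3, 61))
})

test_that("worked site-count examples hold", {
  got <- codon_site_counts(c("TGG", "GGG", "TTT"))
  expect_equal(got$syn_sites, c(0, 1, 1 / 3))
  expect_equal(got$nonsyn_sites, c(3, 2, 8 / 3))
})

test_that("stop and ambiguous codons are flagged with NA", {
  expect_warning(got <- codon_site_counts(c("TAA", "ANG", "GGG")),
                 "flagged")
  expect_true(is.na(got$syn_sites[1]))
  expect_true(is.na(got$syn_sites[2]))
  expect_equal(got$syn_sites[3], 1)
})

test_that("variant classification distinguishes syn/nonsyn/nonsense/noncoding", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ATGGGGTGGTAAAAA"))
  cds <- cds_model("g", "chr1", 1, 12)
  expect_equal(classify_variant(cds, ref, 6, "G", "A"), "synonymous")
  expect_equal(classify_variant(cds, ref, 5, "G", "A"), "nonsynonymous")
  expect_equal(classify_variant(cds, ref, 9, "G", "A"), "nonsense") # TGG->TGA
  expect_equal(classify_variant(cds, ref, 14, "A", "G"), "noncoding")
  expect_error(classify_variant(cds, ref, 6, "C", "A"), "mismatch")
})

test_that("classification agrees with brute-force translation over all codons", {
  codons <- sense_codons()
  seq <- paste(codons, collapse = "")
  ref <- Biostrings::DNAStringSet(c(chr1 = seq))
  cds <- cds_model("all61", "chr1", 1, nchar(seq))
  code <- as.vector(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  for (pos in seq_len(nchar(seq))) {
    refb <- substr(seq, pos, pos)
    ci <- (pos - 1) %/% 3
    codon <- substr(seq, ci * 3 + 1, ci * 3 + 3)
    for (alt in setdiff(c("A", "C", "G", "T"), refb)) {
      mut <- codon
      substr(mut, (pos - 1) %% 3 + 1, (pos - 1) %% 3 + 1) <- alt
      want <- if (code[[mut]] == "*") "nonsense"
              else if (code[[mut]] == code[[codon]]) "synonymous"
              else "nonsynonymous"
      expect_equal(classify_variant(cds, ref, pos, refb, alt), want,
                   info = paste(codon, pos, alt))
    }
  }
})

test_that("minus-strand classification equals plus-strand on the reverse complement", {
  codons <- sense_codons()
  seq <- paste(codons, collapse = "")
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  ref_plus <- Biostrings::DNAStringSet(c(chr1 = seq))
  ref_minus <- Biostrings::DNAStringSet(c(chr1 = rc))
  cds_plus <- cds_model("g+", "chr1", 1, L, strand = "+")
  cds_minus <- cds_model("g-", "chr1", 1, L, strand = "-")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(5)
  for (pos in sample.int(L, 60)) {
    refb <- substr(seq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    plus_call <- classify_variant(cds_plus, ref_plus, pos, refb, alt)
    minus_call <- classify_variant(cds_minus, ref_minus, L - pos + 1,
                                   comp[[refb]], comp[[alt]])
    expect_equal(minus_call, plus_call, info = paste(pos, refb, alt))
  }
})

test_that("CDS site totals sum codons and respect exon splitting", {
  seq10 <- strrep("GGG", 10)
  ref <- Biostrings::DNAStringSet(c(chr1 = seq10))
  whole <- cds_model("g", "chr1", 1, 30)
  tot <- cds_site_totals(whole, ref)
  expect_equal(tot$s_syn, 10)
  expect_equal(tot$s_nonsyn, 20)
  # splitting exons without changing the concatenated CDS changes nothing
  split <- cds_model("g", "chr1", c(1, 8, 21), c(7, 20, 30))
  expect_equal(cds_site_totals(split, ref)[, c("s_syn", "s_nonsyn")],
               tot[, c("s_syn", "s_nonsyn")])
  # empty annotation
  empty <- cds_site_totals(list(), ref)
  expect_equal(nrow(empty), 0)
  # frame violation names the offending gene
  expect_error(cds_site_totals(cds_model("bad", "chr1", 1, 10), ref), "bad")
})

test_that("internal stops are skipped and tallied", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste0("GGG", "TAA", "GGG")))
  tot <- cds_site_totals(cds_model("g", "chr1", 1, 9), ref)
  expect_equal(tot$n_skipped, 1L)
  expect_equal(tot$s_syn, 2)
  expect_equal(tot$s_nonsyn, 4)
})

test_that("FASTA + GFF3 round trip drives classification end to end", {
  toy <- write_toy_annotation()
  ref <- read_reference_fasta(toy$fasta)
  models <- read_cds_models(toy$gff)
  expect_setequal(names(models), c("t1", "t2"))
  expect_equal(models[["t2"]]$strand, "-")
  tot <- cds_site_totals(models, ref)
  expect_equal(nrow(tot), 2)
  # t1: ATG GCT GCT AAA GGT GCT GCT GCT TGA (9 codons, terminal stop kept
  # out of the totals)
  expect_equal(tot$n_codons[tot$gene == "t1"], 9L)
  expect_equal(tot$n_skipped[tot$gene == "t1"], 1L)
  # minus-strand gene reads ATG x 6 + TGA
  expect_equal(tot$n_codons[tot$gene == "t2"], 7L)
  # position 6 is codon 2 (GCT), third position: T->A gives GCA (Ala)
  v <- variant_row(pos = 6L, ref = "T", alt = "A")
  cls <- classify_variants(v, models, ref)
  expect_equal(cls$class, "synonymous")
})
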