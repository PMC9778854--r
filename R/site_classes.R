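#' The standard genetic code
#'
#' @return Named character vector mapping the 64 codons to one-letter amino
#'   acids, with `"*"` for the three stop codons (from
#'   `Biostrings::GENETIC_CODE`).
#' @export
genetic_code <- function() {
  as.vector(Biostrings::GENETIC_CODE) |>
    setNames(names(Biostrings::GENETIC_CODE))
}

translate_codon <- function(codon, code = genetic_code()) {
  unname(code[codon])
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for codons
#'
#' For each of the nine single-base changes of a codon, a change is
#' synonymous iff the encoded amino acid is unchanged. Each codon position
#' contributes `(synonymous changes) / (changes considered)` synonymous sites
#' (and the complement nonsynonymous), so with the default handling
#' `syn_sites + nonsyn_sites = 3` exactly. All three changes per position are
#' weighted equally (classic Nei-Gojobori, no transition/transversion
#' weighting).
#'
#' @param codon Character vector of 3-mers over `ACGT`.
#' @param stop_handling `"nonsynonymous"` (default): changes that create a
#'   stop codon count as nonsynonymous. `"exclude"`: such changes are dropped
#'   from both numerator and denominator.
#' @return A tibble with columns `codon`, `syn_sites`, `nonsyn_sites`.
#'   Stop codons and codons with characters outside `ACGT` get `NA` counts
#'   with a warning (they are excluded from totals downstream).
#' @examples
#' codon_site_counts(c("TGG", "GGG", "TTT"))
#' @export
codon_site_counts <- function(codon,
                              stop_handling = c("nonsynonymous", "exclude")) {
  stop_handling <- match.arg(stop_handling)
  code <- genetic_code()
  bases <- c("A", "C", "G", "T")
  one <- function(cd) {
    if (is.na(cd) || !grepl("^[ACGT]{3}$", cd)) return(c(NA_real_, NA_real_))
    aa <- translate_codon(cd, code)
    if (aa == "*") return(c(NA_real_, NA_real_))
    syn <- 0
    nonsyn <- 0
    for (p in 1:3) {
      n_syn <- 0L
      n_cons <- 0L
      for (b in setdiff(bases, substr(cd, p, p))) {
        mut <- cd
        substr(mut, p, p) <- b
        aa2 <- translate_codon(mut, code)
        if (aa2 == "*" && stop_handling == "exclude") next
        n_cons <- n_cons + 1L
        if (aa2 == aa) n_syn <- n_syn + 1L
      }
      if (n_cons > 0) {
        syn <- syn + n_syn / n_cons
        nonsyn <- nonsyn + 1 - n_syn / n_cons
      }
    }
    c(syn, nonsyn)
  }
  cd <- toupper(codon)
  m <- vapply(cd, one, numeric(2))
  out <- tibble::tibble(codon = codon, syn_sites = unname(m[1, ]),
                        nonsyn_sites = unname(m[2, ]))
  if (anyNA(out$syn_sites))
    warn(paste0(sum(is.na(out$syn_sites)),
                " stop or ambiguous codon(s) flagged with NA site counts."))
  out
}

#' Define a CDS model
#'
#' Exon intervals follow the GFF3 convention: 1-based, inclusive, given on
#' the forward strand and sorted by start; for minus-strand CDS the intervals
#' are concatenated in reverse order and reverse-complemented. `phase` bases
#' are trimmed from the 5' end of the concatenated CDS before codons are
#' formed (bases in the trimmed prefix are not classifiable).
#'
#' @param gene_id Gene/transcript identifier.
#' @param chrom Sequence (contig) name the intervals refer to.
#' @param starts,ends Integer vectors of 1-based inclusive exon bounds.
#' @param strand `"+"` or `"-"`.
#' @param phase Reading-frame offset of the first CDS segment in
#'   transcription order (0, 1, or 2).
#' @return An object of class `cds_model`.
#' @export
cds_model <- function(gene_id, chrom, starts, ends, strand = "+", phase = 0) {
  if (length(starts) != length(ends) || any(ends < starts))
    abort("Exon intervals must satisfy start <= end.")
  o <- order(starts)
  starts <- as.integer(starts[o])
  ends <- as.integer(ends[o])
  if (length(starts) > 1 && any(starts[-1] <= ends[-length(ends)]))
    abort(paste0("Overlapping exon intervals in ", gene_id, "."))
  if (!strand %in% c("+", "-")) abort("`strand` must be \"+\" or \"-\".")
  structure(list(gene_id = gene_id, chrom = chrom, starts = starts,
                 ends = ends, strand = strand, phase = as.integer(phase)),
            class = "cds_model")
}

# Concatenated CDS sequence (5'->3' in transcription order), phase applied.
cds_sequence <- function(cds, ref_seq) {
  chrom_seq <- ref_seq[[cds$chrom]]
  parts <- mapply(function(s, e) as.character(Biostrings::subseq(chrom_seq, s, e)),
                  cds$starts, cds$ends)
  seq <- paste(parts, collapse = "")
  if (cds$strand == "-") {
    seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  if (cds$phase > 0) seq <- substr(seq, cds$phase + 1, nchar(seq))
  seq
}

# 1-based position within the concatenated, phase-trimmed CDS; NA if outside.
cds_position <- function(cds, pos) {
  inside <- which(pos >= cds$starts & pos <= cds$ends)
  if (length(inside) != 1) return(NA_integer_)
  lens <- cds$ends - cds$starts + 1L
  if (cds$strand == "+") {
    before <- if (inside > 1) sum(lens[seq_len(inside - 1)]) else 0L
    raw <- before + (pos - cds$starts[inside]) + 1L
  } else {
    n <- length(lens)
    after <- if (inside < n) sum(lens[seq(inside + 1, n)]) else 0L
    raw <- after + (cds$ends[inside] - pos) + 1L
  }
  raw <- raw - cds$phase
  if (raw < 1) NA_integer_ else as.integer(raw)
}

#' Classify a biallelic SNP against a CDS model
#'
#' @param cds A [cds_model()].
#' @param ref_seq A named `DNAStringSet` (or named character vector) holding
#'   the reference sequence of `cds$chrom`.
#' @param pos 1-based genomic position of the variant.
#' @param ref,alt Reference and alternate bases (forward strand).
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"nonsense"`,
#'   `"noncoding"`.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ATGGGGTGA"))
#' cds <- cds_model("g1", "chr1", 1, 9)
#' classify_variant(cds, ref, 6, "G", "A")
#' @export
classify_variant <- function(cds, ref_seq, pos, ref, alt) {
  stopifnot(inherits(cds, "cds_model"))
  if (is.character(ref_seq)) ref_seq <- Biostrings::DNAStringSet(ref_seq)
  chrom_seq <- ref_seq[[cds$chrom]]
  genome_base <- as.character(Biostrings::subseq(chrom_seq, pos, pos))
  if (genome_base != toupper(ref))
    abort(sprintf("Reference mismatch at %s:%d: VCF says %s, FASTA says %s.",
                  cds$chrom, pos, ref, genome_base))
  cpos <- cds_position(cds, pos)
  if (is.na(cpos)) return("noncoding")
  seq <- cds_sequence(cds, ref_seq)
  if (cpos > nchar(seq)) return("noncoding")
  codon_i <- (cpos - 1) %/% 3
  if ((codon_i + 1) * 3 > nchar(seq)) return("noncoding") # trailing partial codon
  within <- (cpos - 1) %% 3 + 1
  codon <- substr(seq, codon_i * 3 + 1, codon_i * 3 + 3)
  alt_t <- toupper(alt)
  if (cds$strand == "-") {
    alt_t <- chartr("ACGT", "TGCA", alt_t)
  }
  mut <- codon
  substr(mut, within, within) <- alt_t
  code <- genetic_code()
  aa_ref <- translate_codon(codon, code)
  aa_alt <- translate_codon(mut, code)
  if (is.na(aa_ref) || is.na(aa_alt)) return("noncoding")
  if (aa_alt == "*" && aa_ref != "*") return("nonsense")
  if (aa_alt == aa_ref) "synonymous" else "nonsynonymous"
}

#' Synonymous/nonsynonymous site totals for a set of CDS models
#'
#' Sums [codon_site_counts()] over all codons of each CDS. Codons containing
#' ambiguous bases or internal stops are skipped (and counted). Transcripts
#' are counted separately; overlapping CDS on opposite strands each
#' contribute their own sites.
#'
#' @param cds_list A list of [cds_model()] objects (a single model is
#'   accepted).
#' @param ref_seq A named `DNAStringSet` or named character vector of
#'   reference sequences.
#' @param stop_handling Passed to [codon_site_counts()].
#' @return A tibble with one row per gene (`gene`, `s_syn`, `s_nonsyn`,
#'   `n_codons`, `n_skipped`). Totals are `colSums` of the count columns;
#'   see [site_totals()].
#' @export
cds_site_totals <- function(cds_list, ref_seq,
                            stop_handling = c("nonsynonymous", "exclude")) {
  stop_handling <- match.arg(stop_handling)
  if (inherits(cds_list, "cds_model")) cds_list <- list(cds_list)
  if (is.character(ref_seq)) ref_seq <- Biostrings::DNAStringSet(ref_seq)
  if (length(cds_list) == 0)
    return(tibble::tibble(gene = character(), s_syn = numeric(),
                          s_nonsyn = numeric(), n_codons = integer(),
                          n_skipped = integer()))
  purrr::map_dfr(cds_list, function(cds) {
    seq <- cds_sequence(cds, ref_seq)
    n_keep <- (nchar(seq) %/% 3) * 3
    if (nchar(seq) %% 3 != 0) {
      full_len <- nchar(seq) + cds$phase
      if (full_len %% 3 != 0)
        abort(paste0("CDS length not divisible by 3 for gene ", cds$gene_id,
                     " (", full_len, " bp)."))
      seq <- substr(seq, 1, n_keep) # phase-trimmed tail
    }
    codons <- substring(seq, seq(1, n_keep, 3), seq(3, n_keep, 3))
    # terminal stop codon is expected; only internal stops are anomalies
    counts <- suppressWarnings(codon_site_counts(codons, stop_handling))
    skipped <- is.na(counts$syn_sites)
    tibble::tibble(gene = cds$gene_id,
                   s_syn = sum(counts$syn_sites[!skipped]),
                   s_nonsyn = sum(counts$nonsyn_sites[!skipped]),
                   n_codons = length(codons),
                   n_skipped = sum(skipped))
  })
}

#' Genome-wide site totals
#'
#' @param site_table Per-gene table from [cds_site_totals()].
#' @return A one-row tibble with `s_syn` and `s_nonsyn` totals.
#' @export
site_totals <- function(site_table) {
  tibble::tibble(s_syn = sum(site_table$s_syn),
                 s_nonsyn = sum(site_table$s_nonsyn))
}

#' Read CDS models from a GFF3/GTF annotation
#'
#' Imports `CDS` features (via \pkg{rtracklayer}), groups them by parent
#' transcript, and returns a list of [cds_model()] objects. The `phase` of
#' the first CDS segment in transcription order is honored.
#'
#' @param path Path to a GFF3 or GTF file.
#' @return A named list of `cds_model` objects.
#' @export
read_cds_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) return(list())
  md <- as.data.frame(gr)
  id <- if ("Parent" %in% names(md) &&
            any(lengths(gr$Parent) > 0)) {
    vapply(gr$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
  } else if ("transcript_id" %in% names(md)) {
    md$transcript_id
  } else if ("ID" %in% names(md)) {
    md$ID
  } else {
    abort("Cannot determine CDS grouping: no Parent/transcript_id/ID attribute.")
  }
  phase_col <- if ("phase" %in% names(md)) {
    suppressWarnings(as.integer(as.character(md$phase)))
  } else rep(0L, nrow(md))
  phase_col[is.na(phase_col)] <- 0L
  groups <- split(seq_len(nrow(md)), id)
  models <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    strand <- as.character(md$strand[idx[1]])
    if (!strand %in% c("+", "-")) strand <- "+"
    o <- order(md$start[idx])
    idx <- idx[o]
    first <- if (strand == "+") idx[1] else idx[length(idx)]
    cds_model(gene_id = g, chrom = as.character(md$seqnames[idx[1]]),
              starts = md$start[idx], ends = md$end[idx],
              strand = strand, phase = phase_col[first])
  })
  names(models) <- names(groups)
  models
}

#' Read a reference genome FASTA
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A named `DNAStringSet`. Names are truncated at the first space.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Classify every variant record against a set of CDS models
#'
#' Adds a `class` column to a long variant table. A variant falling in no CDS
#' is `"noncoding"`; a variant inside several transcripts is classified by
#' the first transcript containing it (per-transcript assignment).
#'
#' @param variants Long variant tibble (needs `chrom`, `pos`, `ref`, `alt`).
#' @param cds_list List of [cds_model()] objects.
#' @param ref_seq Named `DNAStringSet` reference.
#' @return `variants` with a `class` column.
#' @export
classify_variants <- function(variants, cds_list, ref_seq) {
  if (inherits(cds_list, "cds_model")) cds_list <- list(cds_list)
  if (is.character(ref_seq)) ref_seq <- Biostrings::DNAStringSet(ref_seq)
  sites <- dplyr::distinct(variants, .data$chrom, .data$pos, .data$ref,
                           .data$alt)
  cls <- vapply(seq_len(nrow(sites)), function(i) {
    for (cds in cds_list) {
      if (cds$chrom != sites$chrom[i]) next
      k <- classify_variant(cds, ref_seq, sites$pos[i], sites$ref[i],
                            sites$alt[i])
      if (k != "noncoding") return(k)
    }
    "noncoding"
  }, character(1))
  sites$class <- cls
  dplyr::left_join(variants, sites, by = c("chrom", "pos", "ref", "alt"))
}
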