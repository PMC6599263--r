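# Mutant-peptide enumeration and neoantigen calling. The MHC binding model
# itself is pluggable: any function(peptide, allele) -> percentile rank can
# be used; a deterministic mock is bundled so the pipeline is testable
# without an external predictor.

AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"

#' Fetch one transcript from a reference
#'
#' @param reference list with `gene_model` and `transcripts`
#'   (see [annotate_catalog()]).
#' @param id transcript id.
#' @return list with `id`, `gene`, `cdna`, `cds_start`, `cds_end`.
#' @export
get_transcript <- function(reference, id) {
  gm <- reference$gene_model
  i <- match(id, gm$transcript)
  if (is.na(i)) stopf("transcript %s absent from gene model", id)
  list(id = id, gene = gm$gene[i],
       cdna = reference$transcripts[[id]],
       cds_start = gm$cds_start[i], cds_end = gm$cds_end[i])
}

#' Apply a variant to a transcript cDNA
#'
#' Substitutes (SNV) or inserts/deletes (indel, VCF anchor convention) at
#' the given cDNA position; the output length is the input length plus or
#' minus the indel length.
#'
#' @param tx a transcript (see [get_transcript()]).
#' @param ref,alt alleles.
#' @param cds_pos 1-based position of the first ref base within the cDNA.
#' @return mutant cDNA string.
#' @export
mutate_cdna <- function(tx, ref, alt, cds_pos) {
  if (identical(ref, alt)) stopf("identity edit (ref == alt) is invalid")
  cdna <- tx$cdna
  have <- substr(cdna, cds_pos, cds_pos + nchar(ref) - 1L)
  if (!identical(have, ref))
    stopf("ref allele %s does not match transcript %s sequence %s at pos %d",
          ref, tx$id, have, cds_pos)
  paste0(substr(cdna, 1, cds_pos - 1L), alt,
         substr(cdna, cds_pos + nchar(ref), nchar(cdna)))
}

#' Translate a CDS, halting at the first stop codon
#'
#' The reading frame starts at `cds_start`; trailing bases that do not fill
#' a codon (frameshifted sequence) are dropped; translation stops at the
#' first stop codon, which is not included (no readthrough).
#'
#' @param cdna cDNA string.
#' @param cds_start 1-based start of the reading frame.
#' @return amino-acid string.
#' @export
translate_cds <- function(cdna, cds_start = 1L) {
  s <- substr(cdna, cds_start, nchar(cdna))
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons]) # standard genetic code
  aa[is.na(aa)] <- "X"
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  paste(aa, collapse = "")
}

#' Enumerate mutant peptides for a variant
#'
#' Translates the wild-type and mutant transcript and returns every 8-11-mer
#' (configurable) of the mutant protein that covers an altered residue and
#' does not occur verbatim in the wild-type protein. For missense SNVs these
#' are the k-windows over the single altered residue (at most 8+9+10+11 = 38
#' peptides); for frameshifts, every peptide overlapping the novel frame
#' from the variant codon to the first stop. Synonymous variants yield an
#' empty set; so do nonsense variants (the truncated protein contains no
#' novel sequence).
#'
#' @param tx a transcript (see [get_transcript()]).
#' @param ref,alt,cds_pos the variant on the transcript.
#' @param kmin,kmax peptide length bounds (defaults 8 and 11, the lengths
#'   with which a putative antigen can bind HLA class I).
#' @return character vector of unique mutant peptides (sorted).
#' @export
enumerate_mutant_peptides <- function(tx, ref, alt, cds_pos,
                                      kmin = 8, kmax = 11) {
  if (cds_pos < tx$cds_start || cds_pos > tx$cds_end)
    stopf("variant at cDNA pos %d is outside the CDS of %s", cds_pos, tx$id)
  wt <- translate_cds(tx$cdna, tx$cds_start)
  mut_cdna <- mutate_cdna(tx, ref, alt, cds_pos)
  mut <- translate_cds(mut_cdna, tx$cds_start)
  la <- nchar(wt)
  lb <- nchar(mut)
  if (identical(wt, mut) || lb == 0) return(character(0))
  aw <- strsplit(wt, "")[[1]]
  bm <- strsplit(mut, "")[[1]]
  # first differing residue
  nmin <- min(la, lb)
  pre <- which(aw[seq_len(nmin)] != bm[seq_len(nmin)])
  d_start <- if (length(pre)) pre[1] else nmin + 1L
  if (d_start > lb) return(character(0)) # pure truncation, nothing novel
  frameshift <- abs(nchar(ref) - nchar(alt)) %% 3 != 0
  if (frameshift) {
    d_end <- lb
  } else {
    # longest common suffix not eating into the novel region
    suf <- 0L
    while (suf < nmin - d_start + 1L && aw[la - suf] == bm[lb - suf])
      suf <- suf + 1L
    d_end <- lb - suf
    if (d_end < d_start) { # clean in-frame deletion: junction only
      d_start <- max(1L, d_start - 1L)
      d_end <- min(lb, d_start + 1L)
    }
  }
  out <- character(0)
  for (k in kmin:kmax) {
    if (lb < k) next
    starts <- max(1L, d_start - k + 1L):min(lb - k + 1L, d_end)
    starts <- starts[starts >= 1]
    if (length(starts))
      out <- c(out, substring(mut, starts, starts + k - 1L))
  }
  wt_set <- unlist(lapply(kmin:kmax, function(k) kmers(wt, k)))
  sort(unique(setdiff(out, wt_set)))
}

#' Deterministic mock MHC binding predictor
#'
#' Returns a pluggable predictor `function(peptide, allele) -> rank` whose
#' percentile ranks (0-100) come from a seeded hash of (peptide, allele,
#' seed): identical inputs always give identical ranks, so tests are
#' reproducible without NetMHC-style software. A real predictor wrapper can
#' be dropped in anywhere a `predictor` argument is taken; the contract is
#' simply a vector-safe `function(peptide, allele)` returning nonnegative
#' percentile ranks.
#'
#' @param seed integer mixed into the hash.
#' @return a predictor function.
#' @export
mock_predictor <- function(seed = 1L) {
  force(seed)
  seed2 <- string_hash(paste0("mock", seed), 65521)
  function(peptide, allele) {
    s <- paste(peptide, allele, sep = "|")
    # position-weighted char sum scrambled by a MINSTD multiplier:
    # deterministic, vector-fast, approximately uniform on [0, 100)
    h1 <- vapply(s, function(x) {
      v <- utf8ToInt(x)
      sum(v * (seq_along(v) * 131 + 7)) %% 65521
    }, numeric(1), USE.NAMES = FALSE)
    (((h1 + seed2) * 48271) %% 100000) / 1000
  }
}

#' Score peptide/allele pairs through a predictor
#'
#' One prediction per (peptide, allele) pair (cartesian product).
#'
#' @param peptides character vector of peptides (amino-acid strings).
#' @param alleles character vector of HLA allele names.
#' @param predictor `function(peptide, allele) -> percentile rank`.
#' @return data.frame with columns `peptide`, `hla`, `rank`.
#' @export
predict_binding <- function(peptides, alleles, predictor = mock_predictor()) {
  bad <- !grepl(paste0("^[", AA_ALPHABET, "]+$"), peptides)
  if (any(bad))
    stopf("peptide contains non-amino-acid characters: %s",
          peptides[which(bad)[1]])
  if (length(peptides) == 0 || length(alleles) == 0)
    return(data.frame(peptide = character(0), hla = character(0),
                      rank = numeric(0), stringsAsFactors = FALSE))
  grid <- expand.grid(peptide = peptides, hla = alleles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rank <- as.numeric(predictor(grid$peptide, grid$hla))
  if (any(grid$rank < 0)) stopf("predictor returned a negative rank")
  grid
}

#' Call neoantigen candidates from gained variants
#'
#' The full candidate pipeline: for every gained variant with a
#' protein-altering consequence, enumerate mutant peptides, score each
#' (peptide, HLA) pair through the predictor, and keep candidates with a
#' strong predicted binding (`rank < rank_cutoff`, strict; default 0.5) in a
#' gene that is expressed (`FPKM > fpkm_cutoff`, strict; default 10).
#' Variants whose gene is missing from the expression table are dropped and
#' tallied in a warning. Identical peptides arising from different variants
#' are reported once per (peptide, allele, variant); the per-class summary
#' attribute counts unique (peptide, allele) pairs.
#'
#' @param gained a consequence-annotated `variant_catalog` of gained
#'   variants.
#' @param reference gene model + transcripts (see [annotate_catalog()]).
#' @param expression data.frame with columns `gene`, `fpkm` (one row per
#'   gene).
#' @param alleles HLA class I allele names of the sample.
#' @param predictor binding predictor (see [mock_predictor()]).
#' @param rank_cutoff,fpkm_cutoff strict thresholds (defaults 0.5 and 10).
#' @param kmin,kmax peptide length bounds.
#' @return data.frame (class `neoantigen_calls`) with columns `peptide`,
#'   `length`, `hla`, `rank`, `variant_key`, `gene`, `fpkm`, `source_class`;
#'   attributes `class_counts` (unique (peptide, allele) pairs per source
#'   class) and `dropped_no_expression`.
#' @export
call_neoantigens <- function(gained, reference, expression, alleles,
                             predictor = mock_predictor(),
                             rank_cutoff = 0.5, fpkm_cutoff = 10,
                             kmin = 8, kmax = 11) {
  v <- gained$variants
  if (nrow(v) > 0 && anyNA(v$consequence))
    stopf("catalog is not consequence-annotated; run annotate_catalog() first")
  rows <- list()
  dropped <- 0L
  idx <- which(v$consequence %in% c("missense", "frameshift",
                                    "inframe_indel"))
  for (i in idx) {
    fpkm <- expression$fpkm[match(v$gene[i], expression$gene)]
    if (is.na(fpkm)) {
      dropped <- dropped + 1L
      next
    }
    tx <- get_transcript(reference, v$transcript[i])
    peps <- enumerate_mutant_peptides(tx, v$ref[i], v$alt[i], v$cds_pos[i],
                                      kmin = kmin, kmax = kmax)
    if (length(peps) == 0) next
    pred <- predict_binding(peps, alleles, predictor)
    pred <- pred[pred$rank < rank_cutoff, , drop = FALSE]
    if (nrow(pred) == 0 || fpkm <= fpkm_cutoff) next
    src <- switch(v$consequence[i],
                  missense = "SNV",
                  frameshift = "frameshift",
                  inframe_indel = "inframe_indel")
    pred$length <- nchar(pred$peptide)
    pred$variant_key <- v$key[i]
    pred$gene <- v$gene[i]
    pred$fpkm <- fpkm
    pred$source_class <- src
    rows[[length(rows) + 1L]] <- pred
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(0), hla = character(0), rank = numeric(0),
               length = integer(0), variant_key = character(0),
               gene = character(0), fpkm = numeric(0),
               source_class = character(0), stringsAsFactors = FALSE)
  out <- out[, c("peptide", "length", "hla", "rank", "variant_key", "gene",
                 "fpkm", "source_class")]
  out <- out[!duplicated(out[, c("peptide", "hla", "variant_key")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (dropped > 0)
    warnf("%d variant(s) dropped: gene missing from expression table",
          dropped)
  counts <- vapply(split(out, out$source_class), function(d)
    nrow(unique(d[, c("peptide", "hla")])), integer(1))
  structure(out, class = c("neoantigen_calls", "data.frame"),
            class_counts = counts, dropped_no_expression = dropped)
}
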