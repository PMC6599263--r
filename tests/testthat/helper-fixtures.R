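# Fixtures are built in code; nothing is read from disk except the printed
# growth table shipped in inst/extdata.

# catalog from a compact spec, filling plausible read support
toy_catalog <- function(df, sample_id = "S", timepoint = "T0") {
  variant_catalog(df, sample_id = sample_id, timepoint = timepoint)
}

# n random variants with full read support at distinct positions
random_catalog <- function(n, seed, sample_id = "S", timepoint = "T0") {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    depth <- sample(5:300, n, replace = TRUE)
    alt_count <- vapply(depth, function(d) sample(0:d, 1), integer(1))
    usable <- vapply(alt_count, function(a) sample(0:a, 1), integer(1))
    fwd <- vapply(usable, function(u) sample(0:u, 1), integer(1))
    toy_catalog(data.frame(
      chrom = "chr1", pos = sample(1:1e6, n), ref = ref, alt = alt,
      depth = depth, alt_count = alt_count, alt_fwd = fwd,
      alt_rev = usable - fwd), sample_id, timepoint)
  })
}

# transcript with a 20-amino-acid-period protein: any single residue change
# breaks the period, so no mutant k-mer covering it can match a wild-type
# k-mer (k >= 2)
periodic_transcript <- function(n_aa = 50) {
  codon_of <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
                M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  aa <- rep(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
            length.out = n_aa)
  cdna <- paste0("ATG", paste(codon_of[aa], collapse = ""), "TAA")
  list(id = "toy.t1", gene = "toy", cdna = cdna, cds_start = 1L,
       cds_end = nchar(cdna))
}

# independent k-mer oracle (plain substring loop, no package code)
oracle_kmers <- function(s, kmin = 8, kmax = 11) {
  out <- character(0)
  for (k in kmin:kmax) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) out <- c(out, substr(s, i, i + k - 1))
  }
  unique(out)
}

# independent translation oracle for toy sequences
oracle_translate <- function(cdna) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(cdna) - nchar(cdna) %% 3
  aa <- character(0)
  for (i in seq(1, n, 3)) {
    a <- unname(gc[substr(cdna, i, i + 2)])
    if (is.na(a) || a == "*") break
    aa <- c(aa, a)
  }
  paste(aa, collapse = "")
}

growth_table <- function() {
  read.delim(system.file("extdata", "cell_line_growth.tsv",
                         package = "crcevo"), stringsAsFactors = FALSE)
}
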