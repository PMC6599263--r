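test_that("mutate_cdna edits sequences and validates the ref allele", {
  tx <- list(id = "t", gene = "g", cdna = "ATGGAACCC", cds_start = 1L,
             cds_end = 9L)
  # SNV at cDNA pos 4, G -> T introduces a stop codon (TAA)
  expect_equal(mutate_cdna(tx, "G", "T", 4), "ATGTAACCC")
  expect_error(mutate_cdna(tx, "G", "G", 4), "identity")
  expect_error(mutate_cdna(tx, "C", "T", 4), "does not match")
  # 2 bp deletion: length bookkeeping
  expect_equal(nchar(mutate_cdna(tx, "GGA", "G", 3)), 9 - 2)
  # insertion
  expect_equal(nchar(mutate_cdna(tx, "G", "GTT", 4)), 9 + 2)
})

test_that("translate_cds matches the independent oracle and halts at stops", {
  withr::with_seed(31, {
    codons <- setdiff(as.vector(outer(outer(c("A", "C", "G", "T"),
                                            c("A", "C", "G", "T"), paste0),
                                      c("A", "C", "G", "T"), paste0)),
                      character(0))
    for (rep in 1:5) {
      cdna <- paste(sample(codons, 40, replace = TRUE), collapse = "")
      expect_equal(translate_cds(cdna), oracle_translate(cdna))
    }
  })
  expect_equal(translate_cds("ATGTAACCC"), "M")
  expect_equal(translate_cds("AT"), "")
})

test_that("interior missense yields exactly 38 peptides, N-terminal 4", {
  tx <- periodic_transcript(50) # protein M + 50 residues = 51 aa
  # residue 26 (interior, >= 11 residues from both ends): codon starts at
  # cDNA position 3*25 + 1 = 76; make a missense edit at its first base
  wt <- translate_cds(tx$cdna)
  expect_equal(nchar(wt), 51)
  cds_pos <- 76L
  ref <- substr(tx$cdna, cds_pos, cds_pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  stopifnot(annotate_consequence(tx$cdna, 1, nchar(tx$cdna), cds_pos, ref,
                                 alt) == "missense")
  peps <- enumerate_mutant_peptides(tx, ref, alt, cds_pos)
  expect_length(peps, 38)
  expect_true(all(nchar(peps) %in% 8:11))

  # missense at residue 1: one window per k, anchored at the N terminus
  peps1 <- enumerate_mutant_peptides(tx, "A", "C", 1) # ATG -> CTG (M -> L)
  expect_length(peps1, 4)
  expect_equal(sort(nchar(peps1)), 8:11)
})

test_that("synonymous and nonsense variants yield no peptides", {
  tx <- periodic_transcript(50)
  # GCT -> GCA at residue 2 is synonymous (both Ala): third codon base
  expect_equal(substr(tx$cdna, 4, 6), "GCT")
  expect_length(enumerate_mutant_peptides(tx, "T", "A", 6), 0)
  # TGG (Trp, residue 20) -> TGA introduces a stop: pure truncation
  w_codon_start <- 3 * 19 + 1 # residue 20 of the protein (M + cycle)
  expect_equal(substr(tx$cdna, w_codon_start, w_codon_start + 2), "TGG")
  expect_length(enumerate_mutant_peptides(tx, "G", "A", w_codon_start + 2),
                0)
  expect_error(enumerate_mutant_peptides(tx, "A", "C", nchar(tx$cdna) + 3),
               "outside the CDS")
})

test_that("frameshift peptides equal the exhaustive two-set difference", {
  tx <- periodic_transcript(50)
  wt <- translate_cds(tx$cdna)
  # several 1-2 bp indels at assorted CDS positions
  cases <- list(c(10, 1), c(31, 2), c(76, 1), c(100, 2), c(130, 1))
  for (cs in cases) {
    pos <- cs[1]
    len <- cs[2]
    ref <- substr(tx$cdna, pos, pos + len)
    alt <- substr(tx$cdna, pos, pos)
    peps <- enumerate_mutant_peptides(tx, ref, alt, pos)
    mut <- oracle_translate(mutate_cdna(tx, ref, alt, pos))
    oracle <- setdiff(oracle_kmers(mut), oracle_kmers(wt))
    expect_setequal(peps, oracle)
  }
  # insertions too
  for (pos in c(22, 61, 91)) {
    ref <- substr(tx$cdna, pos, pos)
    alt <- paste0(ref, "AC")
    peps <- enumerate_mutant_peptides(tx, ref, alt, pos)
    mut <- oracle_translate(mutate_cdna(tx, ref, alt, pos))
    oracle <- setdiff(oracle_kmers(mut), oracle_kmers(wt))
    expect_setequal(peps, oracle)
  }
})

test_that("missense/inframe peptides equal the oracle on simulated variants", {
  cfg <- sim_config("msi", seed = 9)
  ref <- make_reference(cfg)
  tc <- simulate_timecourse(cfg, ref)
  g <- annotate_catalog(tc$catalogs$T90, ref)
  v <- g$variants
  v <- v[v$consequence %in% c("missense", "frameshift", "inframe_indel"), ]
  v <- head(v, 60)
  for (i in seq_len(nrow(v))) {
    tx <- get_transcript(ref, v$transcript[i])
    peps <- enumerate_mutant_peptides(tx, v$ref[i], v$alt[i], v$cds_pos[i])
    wt <- oracle_translate(substr(tx$cdna, tx$cds_start, nchar(tx$cdna)))
    mut <- oracle_translate(mutate_cdna(tx, v$ref[i], v$alt[i], v$cds_pos[i]))
    oracle <- setdiff(oracle_kmers(mut), oracle_kmers(wt))
    # implementation restricts to windows over altered residues; anything
    # else is wild-type-identical, so the sets must coincide
    expect_setequal(peps, oracle)
  }
  # invariant: missense never exceeds 38 peptides
  ms <- v[v$consequence == "missense", ]
  for (i in seq_len(min(nrow(ms), 20))) {
    tx <- get_transcript(ref, ms$transcript[i])
    expect_lte(length(enumerate_mutant_peptides(tx, ms$ref[i], ms$alt[i],
                                                ms$cds_pos[i])), 38)
  }
})

test_that("predict_binding: cartesian contract, determinism, validation", {
  stub <- function(peptide, allele) rep(0.4, length(peptide))
  out <- predict_binding(c("AAAAAAAA", "CCCCCCCC", "DDDDDDDD"),
                         c("HLA-A*02:01", "HLA-B*07:02"), stub)
  expect_equal(nrow(out), 6)
  expect_true(all(out$rank == 0.4))
  expect_error(predict_binding("AAAAXB12", "HLA-A*02:01", stub),
               "non-amino-acid")

  p <- mock_predictor(7)
  r1 <- p("SIINFEKL", "HLA-A*02:01")
  r2 <- p("SIINFEKL", "HLA-A*02:01")
  expect_identical(r1, r2)
  expect_true(r1 >= 0 && r1 < 100)
  # different seed, peptide or allele moves the rank
  expect_false(isTRUE(all.equal(r1, mock_predictor(8)("SIINFEKL",
                                                      "HLA-A*02:01"))))
  expect_false(isTRUE(all.equal(r1, p("SIINFEKM", "HLA-A*02:01"))))
})

test_that("call_neoantigens applies strict rank and FPKM bounds", {
  tx <- periodic_transcript(50)
  ref <- list(gene_model = data.frame(transcript = "toy.t1", gene = "toy",
                                      chrom = "chr1", start = 1,
                                      end = nchar(tx$cdna), cds_start = 1,
                                      cds_end = nchar(tx$cdna)),
              transcripts = setNames(tx$cdna, "toy.t1"))
  gained <- annotate_catalog(
    toy_catalog(data.frame(chrom = "chr1", pos = 76,
                           ref = substr(tx$cdna, 76, 76), alt = "C")), ref)
  stub <- function(rank) function(peptide, allele) rep(rank, length(peptide))
  # rank 0.4, fpkm 15 -> kept
  out <- call_neoantigens(gained, ref, data.frame(gene = "toy", fpkm = 15),
                          "HLA-A*02:01", stub(0.4))
  expect_equal(nrow(out), 38)
  expect_equal(unique(out$source_class), "SNV")
  # rank exactly 0.5 -> dropped (strict)
  expect_equal(nrow(call_neoantigens(gained, ref,
                                     data.frame(gene = "toy", fpkm = 15),
                                     "HLA-A*02:01", stub(0.5))), 0)
  # fpkm exactly 10 -> dropped (strict)
  expect_equal(nrow(call_neoantigens(gained, ref,
                                     data.frame(gene = "toy", fpkm = 10),
                                     "HLA-A*02:01", stub(0.4))), 0)
  # gene missing from the expression table -> dropped with warning tally
  expect_warning(
    out2 <- call_neoantigens(gained, ref,
                             data.frame(gene = "other", fpkm = 50),
                             "HLA-A*02:01", stub(0.4)),
    "missing from expression")
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "dropped_no_expression"), 1L)
})

test_that("frameshifts out-yield SNVs per variant on MMR-deficient catalogs", {
  cfg <- sim_config("msi", seed = 12)
  ref <- make_reference(cfg)
  tc <- simulate_timecourse(cfg, ref)
  gained <- subtract_catalogs(tc$catalogs$T90, tc$catalogs$T0)$gained
  gained <- annotate_catalog(gained, ref)
  expr <- simulate_expression(ref, cfg)
  res <- suppressWarnings(
    call_neoantigens(gained, ref, expr, cfg$hla_alleles, mock_predictor(12)))
  v <- gained$variants
  n_fs_var <- sum(v$consequence == "frameshift")
  n_ms_var <- sum(v$consequence == "missense")
  counts <- attr(res, "class_counts")
  cnt <- function(x) if (x %in% names(counts)) counts[[x]] else 0L
  per_fs <- cnt("frameshift") / max(n_fs_var, 1)
  per_snv <- cnt("SNV") / max(n_ms_var, 1)
  expect_gt(per_fs, per_snv)
})
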