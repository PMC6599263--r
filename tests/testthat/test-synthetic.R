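test_that("sim_config validates its domain", {
  expect_error(sim_config("mss", depth_mean = 0), "depth_mean")
  expect_error(sim_config("mss", snv_rate = -1), "rates")
  expect_error(sim_config("mss", clonal_fraction = 1.5), "clonal")
  expect_error(sim_config("mss", signature_mix = c(nope = 1)),
               "unknown signature")
  expect_error(sim_config("mss", gene_codons = c(2L, 5L)), "infeasible")
  expect_error(sim_config("mss",
                          ploidy_profile = data.frame(chrom = "chr1",
                                                      from = 1, to = 5,
                                                      cn = 2.5)),
               "integers")
  cfg <- sim_config("msi", seed = 2)
  expect_equal(sum(cfg$signature_mix), 1)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config("msi", seed = 77, n_genes = 12)
  r1 <- make_reference(cfg)
  r2 <- make_reference(cfg)
  expect_identical(r1, r2)
  t1 <- simulate_timecourse(cfg, r1)
  t2 <- simulate_timecourse(cfg, r1)
  expect_identical(t1$catalogs$T90$variants, t2$catalogs$T90$variants)
  expect_identical(simulate_counts(t1$catalogs$T90, cfg, r1)$variants,
                   simulate_counts(t2$catalogs$T90, cfg, r1)$variants)
  expect_identical(simulate_expression(r1, cfg), simulate_expression(r1, cfg))
  expect_identical(simulate_depth_profile(cfg, r1),
                   simulate_depth_profile(cfg, r1))
  # and emitted files are byte-identical
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(r1$genome, f1)
  write_fasta(r2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reference construction honours the transcript invariants", {
  cfg <- sim_config("mss", seed = 3, n_genes = 20)
  ref <- make_reference(cfg)
  expect_length(ref$transcripts, 20)
  cds_len <- ref$gene_model$cds_end - ref$gene_model$cds_start + 1
  expect_true(all(cds_len %% 3 == 0))
  expect_true(all(startsWith(unname(ref$transcripts), "ATG")))
  # translation contains no internal stop (it runs to the final stop codon)
  aa_len <- unname(nchar(vapply(ref$transcripts, translate_cds, "")))
  expect_equal(aa_len, unname(cds_len / 3 - 1))
  # genomic slice equals the cDNA
  gm <- ref$gene_model[3, ]
  expect_equal(substr(ref$genome[[gm$chrom]], gm$start, gm$end),
               unname(ref$transcripts[gm$transcript]))
})

test_that("MMR-deficient references embed homopolymer runs in every CDS", {
  ref <- make_reference(sim_config("msi", seed = 5, n_genes = 15))
  expect_true(all(grepl("A{6}|C{6}|G{6}|T{6}", ref$transcripts)))
})

test_that("zero rates give an unchanged catalog at T90", {
  cfg <- sim_config("msi", seed = 6, snv_rate = 0, indel_rate = 0,
                    lost_fraction = 0)
  ref <- make_reference(cfg)
  tc <- simulate_timecourse(cfg, ref)
  expect_identical(catalog_keys(tc$catalogs$T0), catalog_keys(tc$catalogs$T90))
})

test_that("event counts track the generating Poisson rates per process", {
  # MMR-deficient: indel-rich
  cfg <- sim_config("msi", seed = 8)
  tc <- simulate_timecourse(cfg, make_reference(cfg))
  tr <- tc$truth$intervals$T90
  expect_lt(abs(tr$n_snv - 90 * cfg$snv_rate), 3 * sqrt(90 * cfg$snv_rate))
  expect_lt(abs(tr$n_indel - 90 * cfg$indel_rate),
            3 * sqrt(90 * cfg$indel_rate))
  gained <- subtract_catalogs(tc$catalogs$T90, tc$catalogs$T0)$gained
  vc <- table(gained$variants$vclass)
  expect_gt((vc["INS"] + vc["DEL"]) / vc["SNV"], 1)

  # POLE-mutant: SNV-rich (ratio > 5)
  cfgp <- sim_config("pole", seed = 9)
  tcp <- simulate_timecourse(cfgp, make_reference(cfgp))
  gp <- subtract_catalogs(tcp$catalogs$T90, tcp$catalogs$T0)$gained
  vcp <- table(factor(gp$variants$vclass, c("SNV", "INS", "DEL")))
  expect_gt(vcp["SNV"] / max(vcp["INS"] + vcp["DEL"], 1), 5)
})

test_that("simulated SNV contexts reproduce the signature mixture", {
  cfg <- sim_config("pole", seed = 18, n_days = 90)
  ref <- make_reference(cfg)
  tc <- simulate_timecourse(cfg, ref)
  spec <- suppressWarnings(build_spectrum(tc$catalogs$T90, ref$genome))
  M <- synthetic_signatures()
  mix <- setNames(numeric(ncol(M)), colnames(M))
  mix[names(cfg$signature_mix)] <- cfg$signature_mix
  expected <- as.numeric(M %*% mix)
  cossim <- sum(spec * expected) /
    sqrt(sum(as.numeric(spec)^2) * sum(expected^2))
  expect_gte(cossim, 0.95)
})

test_that("read-count layer: binomial AFs, artifacts removed by the cascade", {
  cfg <- sim_config("mss", seed = 10)
  ref <- make_reference(cfg)
  pos <- 31:530
  refb <- vapply(pos, function(p) substr(ref$genome[["chr1"]], p, p), "")
  altb <- vapply(refb, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  clonal <- toy_catalog(data.frame(chrom = "chr1", pos = pos, ref = refb,
                                   alt = altb, af = 0.5), "S", "T0")
  cfg2 <- sim_config("mss", seed = 10, depth_mean = 200,
                     artifact_fraction = 0)
  cc <- simulate_counts(clonal, cfg2, ref)
  expect_equal(mean(cc$variants$af), 0.5, tolerance = 0.02)
  expect_true(all(cc$variants$alt_fwd + cc$variants$alt_rev <=
                    cc$variants$alt_count))

  # injected artifacts sit at AF ~ 0.02 and are >= 95% removed
  tc <- simulate_timecourse(cfg, ref)
  cc2 <- simulate_counts(tc$catalogs$T90, cfg, ref)
  art <- attr(cc2, "artifact_keys")
  expect_gt(length(art), 0)
  kept <- catalog_keys(apply_filters(cc2, filter_config()))
  expect_lte(mean(art %in% kept), 0.05)
})

test_that("depth profiles and AFs are consistent with the CN landscape", {
  ref <- make_reference(sim_config("mss", seed = 11))
  cfg <- sim_config("mss", seed = 11) # diploid everywhere
  dp <- simulate_depth_profile(cfg, ref)
  rg <- relative_gcn(dp$profile)
  expect_equal(mean(rg$relative_gcn), 2, tolerance = 0.05)
  expect_true(all(dp$truth$cn == 2))

  cfg3 <- sim_config("mss", seed = 11,
                     ploidy_profile = data.frame(chrom = "chr2", from = 1,
                                                 to = 20, cn = 3))
  dp3 <- simulate_depth_profile(cfg3, ref)
  arc_genes <- dp3$truth$gene[dp3$truth$cn == 3]
  m <- af_density_modes(dp3$afs$af[dp3$afs$gene %in% arc_genes])
  expect_equal(nrow(m), 2)
  expect_lt(abs(m$af[1] - 1 / 3), 0.04)
  expect_lt(abs(m$af[2] - 2 / 3), 0.04)
})

test_that("expression tables are deterministic with forced low expressors", {
  ref <- make_reference(sim_config("mss", seed = 12))
  cfg <- sim_config("mss", seed = 12)
  e <- simulate_expression(ref, cfg)
  expect_true(all(e$fpkm >= 0))
  low <- attr(e, "low_genes")
  expect_length(low, round(0.2 * nrow(e)))
  expect_true(all(e$fpkm[e$gene %in% low] < 10))
})
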