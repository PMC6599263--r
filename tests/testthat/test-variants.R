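test_that("catalog construction enforces invariants", {
  expect_error(toy_catalog(data.frame(chrom = "1", pos = 5, ref = "A",
                                      alt = "C", depth = 10,
                                      alt_count = 12)),
               "alt_count")
  expect_error(toy_catalog(data.frame(chrom = "1", pos = 5, ref = "A",
                                      alt = "C", depth = 10, alt_count = 6,
                                      alt_fwd = 4, alt_rev = 3)),
               "strand")
  expect_error(toy_catalog(data.frame(chrom = "1", pos = 0, ref = "A",
                                      alt = "C")), "pos")
  expect_error(toy_catalog(data.frame(chrom = "1", pos = c(2, 2),
                                      ref = "A", alt = "C")), "duplicate")
  cat <- toy_catalog(data.frame(chrom = "1", pos = 5, ref = "A", alt = "AC",
                                depth = 100, alt_count = 40))
  expect_equal(cat$variants$vclass, "INS")
  expect_equal(cat$variants$af, 0.4)
  expect_equal(n_variants(toy_catalog(NULL)), 0)
})

test_that("strand filter keeps only dual-strand support and demands counts", {
  cat <- toy_catalog(data.frame(
    chrom = "1", pos = 1:3, ref = "A", alt = "C",
    depth = 100, alt_count = c(10, 10, 0),
    alt_fwd = c(5, 8, 0), alt_rev = c(3, 0, 0)))
  expect_identical(strand_filter(cat), c(TRUE, FALSE, FALSE))
  nocounts <- toy_catalog(data.frame(chrom = "1", pos = 1, ref = "A",
                                     alt = "C", depth = 10, alt_count = 5))
  expect_error(strand_filter(nocounts), "strand counts")
})

test_that("AF/binomial filter applies both closed bounds exactly", {
  cfg <- filter_config()
  cat <- toy_catalog(data.frame(
    chrom = "1", pos = 1:2, ref = "A", alt = "C", depth = 100,
    alt_count = c(20, 5), alt_fwd = c(8, 2), alt_rev = c(8, 2)))
  # af 0.20 with exact tail P(X>=20 | n=100, p=0.01) << 0.05; af 0.05 < 0.10
  expect_identical(af_binomial_filter(cat, cfg), c(TRUE, FALSE))
  # af exactly at the bound but p = 1 - 0.95^10 ~ 0.401 > 0.05
  cfg5 <- filter_config(error_rate = 0.05)
  one <- toy_catalog(data.frame(chrom = "1", pos = 1, ref = "A", alt = "C",
                                depth = 10, alt_count = 1, alt_fwd = 1,
                                alt_rev = 0))
  expect_equal(binom_upper_tail(1, 10, 0.05), 1 - 0.95^10)
  expect_false(af_binomial_filter(one, cfg5))
  zero <- toy_catalog(data.frame(chrom = "1", pos = 1, ref = "A", alt = "C",
                                 depth = 0, alt_count = 0))
  expect_error(af_binomial_filter(zero, cfg), "depth")
})

test_that("exact binomial tail equals naive pmf summation (depth <= 500)", {
  for (depth in c(1, 10, 97, 500)) {
    for (er in c(0.01, 0.05)) {
      alts <- unique(pmin(depth, c(0, 1, 2, 5, round(depth / 2), depth)))
      naive <- vapply(alts, function(a) sum(dbinom(a:depth, depth, er)),
                      numeric(1))
      expect_equal(binom_upper_tail(alts, depth, er), naive,
                   tolerance = 1e-12)
    }
  }
})

test_that("database filter removes dbSNP and panel-of-normal keys", {
  cat <- toy_catalog(data.frame(chrom = "1", pos = 1:3, ref = "A",
                                alt = "C"))
  k <- catalog_keys(cat)
  cfg <- filter_config(dbsnp_keys = k[1], pon_keys = k[2])
  expect_identical(database_filter(cat, cfg), c(FALSE, FALSE, TRUE))
})

test_that("filter_config validates its domain", {
  expect_error(filter_config(min_af = 0), "min_af")
  expect_error(filter_config(alpha = 1), "alpha")
  expect_error(filter_config(error_rate = 0.2), "error_rate")
})

test_that("apply_filters: empty input, idempotence, order invariance, oracle", {
  cfg <- filter_config()
  expect_equal(n_variants(apply_filters(toy_catalog(NULL), cfg)), 0)

  cat <- random_catalog(200, seed = 42)
  keys <- catalog_keys(cat)
  cfg <- filter_config(dbsnp_keys = sample(keys, 20),
                       pon_keys = sample(keys, 20))
  out <- apply_filters(cat, cfg)
  # output subset of input, idempotent
  expect_true(all(catalog_keys(out) %in% keys))
  expect_identical(apply_filters(out, cfg)$variants, out$variants)

  # brute-force conjunction of the three predicates, per variant
  v <- cat$variants
  oracle_keep <- vapply(seq_len(nrow(v)), function(i) {
    p <- sum(dbinom(v$alt_count[i]:v$depth[i], v$depth[i], cfg$error_rate))
    v$alt_fwd[i] >= 1 && v$alt_rev[i] >= 1 &&
      v$alt_count[i] / v$depth[i] >= cfg$min_af && p <= cfg$alpha &&
      !(v$key[i] %in% c(cfg$dbsnp_keys, cfg$pon_keys))
  }, logical(1))
  expect_setequal(catalog_keys(out), v$key[oracle_keep])

  # input order does not matter
  perm <- withr::with_seed(1, sample(nrow(v)))
  cat2 <- toy_catalog(v[perm, setdiff(names(v), c("af", "key", "vclass"))])
  expect_setequal(catalog_keys(apply_filters(cat2, cfg)), catalog_keys(out))

  # failure reasons recorded for every removed variant
  log <- attr(out, "filter_log")
  expect_setequal(log$key, setdiff(keys, catalog_keys(out)))
  expect_true(all(nzchar(log$filter)))
})

test_that("subtract_catalogs: examples and set-conservation identities", {
  a <- random_catalog(60, seed = 1, timepoint = "T0")
  same <- subtract_catalogs(a, a)
  expect_equal(n_variants(same$gained), 0)
  expect_equal(n_variants(same$lost), 0)
  expect_equal(nrow(same$shared), 60)

  b <- random_catalog(40, seed = 99, timepoint = "T90")
  expect_length(intersect(catalog_keys(a), catalog_keys(b)), 0)
  disj <- subtract_catalogs(b, a)
  expect_setequal(catalog_keys(disj$gained), catalog_keys(b))
  expect_setequal(catalog_keys(disj$lost), catalog_keys(a))

  # overlap of 3 keys out of 5 (earlier) / 6 (later)
  earlier <- toy_catalog(data.frame(chrom = "1", pos = 1:5, ref = "A",
                                    alt = "C"), timepoint = "T0")
  later <- toy_catalog(data.frame(chrom = "1", pos = 3:8, ref = "A",
                                  alt = "C"), timepoint = "T90")
  s <- subtract_catalogs(later, earlier)
  expect_equal(n_variants(s$gained), 3)
  expect_equal(n_variants(s$lost), 2)
  expect_equal(nrow(s$shared), 3)

  # conservation on random overlapping catalogs
  for (seed in 1:5) {
    x <- random_catalog(80, seed = seed)
    y0 <- random_catalog(80, seed = seed + 100)
    mix <- rbind(x$variants[1:40, 1:9], y0$variants[, 1:9])
    mix <- mix[!duplicated(variant_key(mix$chrom, mix$pos, mix$ref,
                                       mix$alt)), ]
    y <- toy_catalog(mix, timepoint = "T90")
    s <- subtract_catalogs(y, x)
    expect_length(intersect(catalog_keys(s$gained), catalog_keys(s$lost)), 0)
    expect_setequal(c(catalog_keys(s$gained), s$shared$key),
                    catalog_keys(y))
    expect_setequal(c(catalog_keys(s$lost), s$shared$key), catalog_keys(x))
  }
})

test_that("lineage trees validate structure", {
  cats <- list(F1 = random_catalog(10, 1), F2 = random_catalog(10, 2))
  expect_error(lineage_tree(c(F1 = NA, F2 = "F3"), cats), "unknown parent")
  expect_error(lineage_tree(c(F1 = "F2", F2 = "F1"), cats), "root")
  expect_error(lineage_tree(c(F1 = NA), cats["F2"]), "missing catalog")
})

test_that("lineage_subtract compares each generation to its parent", {
  f1 <- random_catalog(30, seed = 5, timepoint = "F1")
  # F2 identical to F1 -> nothing gained
  tr <- lineage_tree(c(F1 = NA, F2 = "F1"), list(F1 = f1, F2 = f1))
  res <- lineage_subtract(tr)
  expect_true(res$F1$baseline)
  expect_equal(n_variants(res$F1$gained), 30)
  expect_equal(n_variants(res$F2$gained), 0)

  # branching: two children with disjoint private sets
  extra <- random_catalog(20, seed = 6)$variants
  c1 <- toy_catalog(rbind(f1$variants[, 1:9], extra[1:10, 1:9]), "S", "F2a")
  c2 <- toy_catalog(rbind(f1$variants[, 1:9], extra[11:20, 1:9]), "S", "F2b")
  tr2 <- lineage_tree(c(F1 = NA, F2a = "F1", F2b = "F1"),
                      list(F1 = f1, F2a = c1, F2b = c2))
  res2 <- lineage_subtract(tr2)
  expect_setequal(catalog_keys(res2$F2a$gained), extra$key[1:10])
  expect_setequal(catalog_keys(res2$F2b$gained), extra$key[11:20])

  # a mutation appearing at F2 and persisting is gained only at F2
  f2 <- toy_catalog(rbind(f1$variants[, 1:9], extra[1, 1:9]), "S", "F2")
  f3 <- f2
  f3$timepoint <- "F3"
  tr3 <- lineage_tree(c(F1 = NA, F2 = "F1", F3 = "F2"),
                      list(F1 = f1, F2 = f2, F3 = f3))
  res3 <- lineage_subtract(tr3)
  expect_setequal(catalog_keys(res3$F2$gained), extra$key[1])
  expect_equal(n_variants(res3$F3$gained), 0)
})

test_that("lineage subtraction telescopes along a chain", {
  withr::with_seed(11, {
    pool <- random_catalog(200, seed = 7)$variants
    cur <- pool[1:80, ]
    cats <- list(F1 = toy_catalog(cur[, 1:9], "S", "F1"))
    used <- 80
    for (g in c("F2", "F3", "F4")) {
      drop <- runif(nrow(cur)) < 0.15
      add <- pool[(used + 1):(used + 25), ]
      used <- used + 25
      cur <- rbind(cur[!drop, ], add)
      cats[[g]] <- toy_catalog(cur[, 1:9], "S", g)
    }
    tr <- lineage_tree(c(F1 = NA, F2 = "F1", F3 = "F2", F4 = "F3"), cats)
    res <- lineage_subtract(tr)
    # replay gains/losses from the root: must reconstruct the leaf
    keys <- catalog_keys(cats$F1)
    for (g in c("F2", "F3", "F4")) {
      keys <- setdiff(keys, catalog_keys(res[[g]]$lost))
      keys <- union(keys, catalog_keys(res[[g]]$gained))
    }
    expect_setequal(keys, catalog_keys(cats$F4))
  })
})

test_that("tmb counts coding variants per megabase", {
  cat <- toy_catalog(data.frame(
    chrom = "1", pos = 1:8, ref = "A", alt = "C",
    consequence = c(rep("missense", 3), "synonymous", "frameshift",
                    rep("noncoding", 3))))
  expect_equal(tmb(cat, coding_mb = 1), 5)
  expect_equal(tmb(cat, coding_mb = 38), 5 / 38)
  expect_equal(tmb(toy_catalog(NULL), coding_mb = 38), 0)
  expect_error(tmb(cat, coding_mb = 0), "coding_mb")
  unann <- toy_catalog(data.frame(chrom = "1", pos = 1, ref = "A",
                                  alt = "C"))
  expect_error(tmb(unann), "annotate")
})

test_that("annotate_consequence follows the standard genetic code", {
  # cDNA: ATG GAA TAA ; codon GAA at cds offset 4..6
  cdna <- "ATGGAATAA"
  expect_equal(annotate_consequence(cdna, 1, 9, 6, "A", "G"), "synonymous")
  expect_equal(annotate_consequence(cdna, 1, 9, 5, "A", "T"), "missense")
  expect_equal(annotate_consequence(cdna, 1, 9, 4, "G", "T"), "nonsense")
  expect_equal(annotate_consequence(cdna, 1, 9, 4, "GA", "G"), "frameshift")
  expect_equal(annotate_consequence("ATGGAAGAATAA", 1, 12, 3, "GGAA", "G"),
               "inframe_indel")
  expect_error(annotate_consequence(cdna, 1, 9, 4, "C", "T"),
               "does not match")
  expect_error(annotate_consequence(cdna, 1, 9, 4, "G", "G"), "identity")
})

test_that("ns_s_ratio: arithmetic, degenerate case, exhaustive-SNV oracle", {
  mk <- function(ns, s) {
    toy_catalog(data.frame(chrom = "1", pos = seq_len(ns + s), ref = "A",
                           alt = "C",
                           consequence = c(rep("missense", ns),
                                           rep("synonymous", s))))
  }
  expect_equal(ns_s_ratio(mk(30, 10))$ratio, 3)
  r0 <- ns_s_ratio(mk(4, 0))
  expect_false(r0$defined)
  expect_true(is.na(r0$ratio))

  # all possible SNVs across one toy CDS vs. codon-table enumeration
  ref <- make_reference(sim_config("mss", seed = 3, n_genes = 2,
                                   n_chrom = 1, gene_codons = c(20L, 20L)))
  gm <- ref$gene_model[1, ]
  cdna <- ref$transcripts[[gm$transcript]]
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (p in seq_len(nchar(cdna))) {
    b <- substr(cdna, p, p)
    for (a in setdiff(bases, b)) {
      rows[[length(rows) + 1]] <- data.frame(chrom = gm$chrom,
                                             pos = gm$start + p - 1,
                                             ref = b, alt = a)
    }
  }
  all_snvs <- annotate_catalog(toy_catalog(do.call(rbind, rows)), ref)
  got <- ns_s_ratio(all_snvs)

  gc <- Biostrings::GENETIC_CODE
  ns <- s <- 0
  for (ci in seq_len(nchar(cdna) / 3)) {
    codon <- substr(cdna, 3 * ci - 2, 3 * ci)
    for (off in 1:3) {
      for (a in setdiff(bases, substr(codon, off, off))) {
        mut <- codon
        substr(mut, off, off) <- a
        if (gc[[mut]] == gc[[codon]]) s <- s + 1 else ns <- ns + 1
      }
    }
  }
  expect_equal(got$ns, ns)
  expect_equal(got$s, s)
  expect_equal(got$ratio, ns / s)
})
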