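# Seeded synthetic-data generator. From a single master seed it produces
# every input the pipeline consumes: a toy genome/transcriptome, mutation
# accrual over time or lineage with signature-specific trinucleotide
# contexts, read counts, depth profiles consistent with an integer
# copy-number landscape, and FPKM expression. One derived RNG stream per
# stage, so stages can be regenerated independently.

SIM_PRESETS <- list(
  # events/day and signature mixtures chosen to emulate the four
  # DNA-repair states: microsatellite-stable (slow, clock-like),
  # mismatch-repair-deficient (indel-rich, fast), POLE proofreading-mutant
  # (SNV-rich ultramutator), MUTYH-mutant (C>A-rich, fast), and a
  # PDX-style serially passaged MMR-deficient lineage.
  mss   = list(process = "MSS", snv_rate = 0.8, indel_rate = 0.1,
               signature_mix = c(clock_ct = 0.7, flat = 0.3),
               homopolymers = FALSE),
  msi   = list(process = "MMRd", snv_rate = 5, indel_rate = 10,
               signature_mix = c(mmr_ct = 0.8, clock_ct = 0.2),
               homopolymers = TRUE),
  pole  = list(process = "POLEmut", snv_rate = 16, indel_rate = 0.5,
               signature_mix = c(pole_ca = 0.85, clock_ct = 0.15),
               homopolymers = FALSE),
  mutyh = list(process = "MUTYHmut", snv_rate = 14, indel_rate = 0.7,
               signature_mix = c(mutyh_ca = 0.8, clock_ct = 0.2),
               homopolymers = FALSE),
  pdx   = list(process = "MMRd", snv_rate = 5, indel_rate = 10,
               signature_mix = c(mmr_ct = 0.8, clock_ct = 0.2),
               homopolymers = TRUE,
               lineage = c(F1 = NA, F2 = "F1", F3 = "F2", F4 = "F3"),
               clonal_fraction = 0.3, lost_clonal = TRUE)
)

#' Simulation configuration
#'
#' The stated world of the generator. Presets encode the four mutational
#' processes studied: `mss` (slow, ~0.9 events/day), `msi`
#' (mismatch-repair-deficient: 10 indels + 5 SNVs/day, indels targeted at
#' homopolymer runs), `pole` (16 SNVs + 0.5 indels/day), `mutyh` (C>A-rich,
#' 14 SNVs/day), and `pdx` (an MSI-like lineage F1 -> F4, 60 days per
#' generation, where clonal variants may also emerge and be lost). In-vitro
#' presets follow the T0/T90 design (90 days, losses restricted to
#' subclonal variants); newly gained in-vitro events are mostly subclonal.
#'
#' @param preset one of `"mss"`, `"msi"`, `"pole"`, `"mutyh"`, `"pdx"`.
#' @param seed master seed; every stage derives its own stream from it.
#' @param ... overrides for any configuration field: `n_genes` (80),
#'   `n_chrom` (4), `gene_codons` (c(120, 280)), `snv_rate`, `indel_rate`
#'   (events/day), `signature_mix` (named weights over
#'   [synthetic_signatures()] columns), `baseline_n` (300),
#'   `baseline_clonal_fraction` (0.8), `clonal_fraction` (0.1 in vitro),
#'   `subclonal_af` (c(0.05, 0.25)), `lost_fraction` (0.1), `lost_clonal`
#'   (FALSE in vitro), `depth_mean` (100), `depth_dispersion` (NB size, 50),
#'   `depth_noise_sd` (0.05), `error_rate` (0.01), `artifact_fraction`
#'   (0.2), `terminal_loss` (0.08), `ploidy_profile` (data.frame chrom,
#'   from, to, cn; NULL = diploid everywhere), `timepoints` (c(0, 90)),
#'   `lineage` (named parent vector, pdx preset only), `n_days` (days per
#'   lineage generation, 60), `hla_alleles`, `n_het_per_gene` (25),
#'   `expression_meanlog`/`expression_sdlog` (log(30), 1),
#'   `low_expression_fraction` (0.2), `homopolymers`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(preset = c("mss", "msi", "pole", "mutyh", "pdx"),
                       seed = 1L, ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset, seed = as.integer(seed),
    n_genes = 80L, n_chrom = 4L, gene_codons = c(120L, 280L),
    baseline_n = 300L, baseline_clonal_fraction = 0.8,
    clonal_fraction = 0.1, subclonal_af = c(0.05, 0.25),
    lost_fraction = 0.1, lost_clonal = FALSE,
    depth_mean = 100, depth_dispersion = 50, depth_noise_sd = 0.05,
    error_rate = 0.01, artifact_fraction = 0.2, terminal_loss = 0.08,
    ploidy_profile = NULL, timepoints = c(0, 90), lineage = NULL,
    n_days = 60,
    hla_alleles = c("HLA-A*02:01", "HLA-B*07:02"),
    n_het_per_gene = 25L,
    expression_meanlog = log(30), expression_sdlog = 1,
    low_expression_fraction = 0.2)
  cfg <- utils::modifyList(cfg, SIM_PRESETS[[preset]])
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg), "process"))
  if (length(unknown)) stopf("unknown sim_config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, dots)
  # validation
  if (cfg$snv_rate < 0 || cfg$indel_rate < 0) stopf("rates must be >= 0")
  if (cfg$depth_mean <= 0) stopf("depth_mean must be > 0")
  if (cfg$clonal_fraction < 0 || cfg$clonal_fraction > 1 ||
      cfg$baseline_clonal_fraction < 0 || cfg$baseline_clonal_fraction > 1)
    stopf("clonal fractions must lie in [0, 1]")
  if (cfg$n_genes < 1 || cfg$gene_codons[1] < 10 ||
      cfg$gene_codons[2] < cfg$gene_codons[1])
    stopf("infeasible reference configuration")
  sig <- synthetic_signatures()
  bad <- setdiff(names(cfg$signature_mix), colnames(sig))
  if (length(bad)) stopf("unknown signature(s) in mixture: %s",
                         paste(bad, collapse = ", "))
  if (any(cfg$signature_mix < 0) || sum(cfg$signature_mix) <= 0)
    stopf("signature mixture weights must be nonnegative, not all zero")
  cfg$signature_mix <- cfg$signature_mix / sum(cfg$signature_mix)
  if (!is.null(cfg$ploidy_profile)) {
    pp <- cfg$ploidy_profile
    if (any(pp$cn < 0) || any(pp$cn != floor(pp$cn)))
      stopf("ploidy profile copy numbers must be integers >= 0")
  }
  structure(cfg, class = "sim_config")
}

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' Build a toy reference (genome, transcripts, gene model)
#'
#' Deterministic under the config seed. Each gene is a complete CDS (starts
#' ATG, ends with a stop codon, no internal stop), laid plus-strand on one
#' of `n_chrom` contigs with short intergenic spacers; the transcript cDNA
#' equals the genomic gene sequence. Mismatch-repair-deficient configs embed
#' a >= 6 bp homopolymer run inside every CDS to host slippage indels.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_reference`: list with `genome` (named
#'   character), `transcripts` (named character), `gene_model` (data.frame
#'   transcript, gene, chrom, start, end, cds_start, cds_end).
#' @export
make_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "reference"), {
    codons <- sense_codons()
    genes <- sprintf("g%03d", seq_len(cfg$n_genes))
    gene_seq <- character(cfg$n_genes)
    for (i in seq_len(cfg$n_genes)) {
      nc <- sample(cfg$gene_codons[1]:cfg$gene_codons[2], 1)
      body <- sample(codons, nc - 2L, replace = TRUE)
      if (isTRUE(cfg$homopolymers)) {
        at <- sample(seq_len(nc - 4L), 1) # codon slot inside the body
        body[at] <- "AAA"
        body[at + 1L] <- "AAA"
      }
      gene_seq[i] <- paste0("ATG", paste(body, collapse = ""), "TAA")
    }
    chrom_of <- paste0("chr", rep_len(seq_len(cfg$n_chrom), cfg$n_genes))
    chrom_of <- sort(chrom_of) # contiguous blocks per contig
    genome <- character(0)
    gm <- list()
    for (ch in unique(chrom_of)) {
      idx <- which(chrom_of == ch)
      seq_parts <- character(0)
      cursor <- 0L
      rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                             replace = TRUE), collapse = "")
      for (i in idx) {
        spacer <- rand_bases(30L)
        seq_parts <- c(seq_parts, spacer)
        cursor <- cursor + 30L
        start <- cursor + 1L
        seq_parts <- c(seq_parts, gene_seq[i])
        cursor <- cursor + nchar(gene_seq[i])
        gm[[length(gm) + 1L]] <- data.frame(
          transcript = paste0(genes[i], ".t1"), gene = genes[i],
          chrom = ch, start = start, end = cursor,
          cds_start = 1L, cds_end = nchar(gene_seq[i]),
          stringsAsFactors = FALSE)
      }
      seq_parts <- c(seq_parts, rand_bases(30L))
      genome[[ch]] <- paste(seq_parts, collapse = "")
    }
    gene_model <- do.call(rbind, gm)
    transcripts <- setNames(gene_seq[match(gene_model$gene, genes)],
                            gene_model$transcript)
    structure(list(genome = genome, transcripts = transcripts,
                   gene_model = gene_model, cfg = cfg),
              class = "sim_reference")
  })
}

# per-position pyrimidine-strand trinucleotide index of the genome
build_context_index <- function(genome) {
  out <- list()
  for (ch in names(genome)) {
    s <- strsplit(genome[[ch]], "")[[1]]
    n <- length(s)
    pos <- 2:(n - 1)
    ctx <- paste0(s[pos - 1], s[pos], s[pos + 1])
    pyr <- s[pos] %in% c("C", "T")
    ctx[!pyr] <- revcomp(ctx[!pyr])
    out[[ch]] <- data.frame(chrom = ch, pos = pos, ref = s[pos],
                            pyr_ctx = ctx, stringsAsFactors = FALSE)
  }
  idx <- do.call(rbind, out)
  rownames(idx) <- NULL
  idx
}

# homopolymer runs (>= min_len of the same base) across the genome
find_homopolymer_runs <- function(genome, min_len = 4L) {
  out <- list()
  for (ch in names(genome)) {
    r <- rle(strsplit(genome[[ch]], "")[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= min_len & starts > 1L
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              len = r$lengths[keep], base = r$values[keep],
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      len = integer(0), base = character(0)))
  do.call(rbind, out)
}

# state shared by the event samplers during one simulation run
new_sim_state <- function(cfg, ref) {
  idx <- build_context_index(ref$genome)
  runs <- find_homopolymer_runs(ref$genome)
  # keep only runs whose slippage events stay inside one CDS
  gm <- ref$gene_model
  inside <- vapply(seq_len(nrow(runs)), function(i) {
    any(gm$chrom == runs$chrom[i] & gm$start < runs$start[i] - 1L &
          gm$end > runs$start[i] + runs$len[i])
  }, logical(1))
  list(cfg = cfg, ref = ref, idx = idx,
       runs = runs[inside, , drop = FALSE],
       M = synthetic_signatures(),
       used_idx = rep(FALSE, nrow(idx)),
       used_keys = character(0))
}

base_at <- function(genome, chrom, pos) substr(genome[[chrom]], pos, pos)

# draw n SNVs with trinucleotide contexts following the signature mixture
draw_snvs <- function(state, n) {
  if (n == 0) return(list(state = state,
                          v = data.frame(chrom = character(0),
                                         pos = integer(0),
                                         ref = character(0),
                                         alt = character(0))))
  cfg <- state$cfg
  mix <- setNames(numeric(ncol(state$M)), colnames(state$M))
  mix[names(cfg$signature_mix)] <- cfg$signature_mix
  p96 <- as.numeric(state$M %*% mix)
  channels <- sbs96_channels()
  picks <- sample(96, n, replace = TRUE, prob = p96)
  rows <- integer(n)
  alts <- character(n)
  free <- !state$used_idx
  for (k in seq_len(n)) {
    ch <- channels[picks[k]]
    ctx <- paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7))
    target <- substr(ch, 5, 5)
    cand <- which(free & state$idx$pyr_ctx == ctx)
    if (!length(cand)) # context exhausted: any free site, same pyrimidine
      cand <- which(free & substr(state$idx$pyr_ctx, 2, 2) ==
                      substr(ch, 3, 3))
    if (!length(cand)) cand <- which(free)
    if (!length(cand)) stopf("genome exhausted: too many SNVs requested")
    i <- if (length(cand) == 1) cand else sample(cand, 1)
    free[i] <- FALSE
    rows[k] <- i
    alts[k] <- if (state$idx$ref[i] %in% c("C", "T")) target
    else dna_complement(target)
  }
  state$used_idx <- !free
  list(state = state,
       v = data.frame(chrom = state$idx$chrom[rows],
                      pos = state$idx$pos[rows],
                      ref = state$idx$ref[rows], alt = alts,
                      stringsAsFactors = FALSE))
}

# draw n indels; MMR-deficient processes slip preferentially at
# homopolymer runs (1 bp insertions/deletions of the run base)
draw_indels <- function(state, n) {
  if (n == 0) return(list(state = state,
                          v = data.frame(chrom = character(0),
                                         pos = integer(0),
                                         ref = character(0),
                                         alt = character(0))))
  cfg <- state$cfg
  ref <- state$ref
  gm <- ref$gene_model
  mmr <- identical(cfg$process, "MMRd")
  rows <- list()
  tries <- 0L
  while (length(rows) < n && tries < 60L * n) {
    tries <- tries + 1L
    if (mmr && nrow(state$runs) > 0 && runif(1) < 0.7) {
      r <- state$runs[sample(nrow(state$runs), 1), ]
      anchor <- r$start - 1L
      a <- base_at(ref$genome, r$chrom, anchor)
      if (runif(1) < 0.5) { # 1 bp deletion of the first run base
        v <- data.frame(chrom = r$chrom, pos = anchor,
                        ref = paste0(a, r$base), alt = a,
                        stringsAsFactors = FALSE)
      } else {            # 1 bp insertion of the run base
        v <- data.frame(chrom = r$chrom, pos = anchor, ref = a,
                        alt = paste0(a, r$base), stringsAsFactors = FALSE)
      }
    } else {
      g <- gm[sample(nrow(gm), 1), ]
      len <- sample(c(1L, 1L, 2L, 3L), 1)
      anchor <- sample((g$start + 1L):(g$end - len - 1L), 1)
      a <- base_at(ref$genome, g$chrom, anchor)
      if (runif(1) < 0.5) {
        del <- substr(ref$genome[[g$chrom]], anchor, anchor + len)
        v <- data.frame(chrom = g$chrom, pos = anchor, ref = del, alt = a,
                        stringsAsFactors = FALSE)
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        v <- data.frame(chrom = g$chrom, pos = anchor, ref = a,
                        alt = paste0(a, ins), stringsAsFactors = FALSE)
      }
    }
    key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
    if (key %in% state$used_keys) next
    state$used_keys <- c(state$used_keys, key)
    rows[[length(rows) + 1L]] <- v
  }
  if (length(rows) < n)
    warnf("indel sampler placed %d of %d requested events", length(rows), n)
  list(state = state, v = do.call(rbind, rows))
}

assign_af <- function(n, clonal_fraction, cfg) {
  clonal <- runif(n) < clonal_fraction
  af <- numeric(n)
  af[clonal] <- 0.5
  af[!clonal] <- runif(sum(!clonal), cfg$subclonal_af[1],
                       cfg$subclonal_af[2])
  list(af = af, clonal = clonal)
}

draw_events <- function(state, n_snv, n_indel, clonal_fraction) {
  s <- draw_snvs(state, n_snv)
  state <- s$state
  # register SNV keys so indels cannot collide
  if (nrow(s$v))
    state$used_keys <- c(state$used_keys,
                         variant_key(s$v$chrom, s$v$pos, s$v$ref, s$v$alt))
  d <- draw_indels(state, n_indel)
  state <- d$state
  v <- rbind(s$v, d$v)
  a <- assign_af(nrow(v), clonal_fraction, state$cfg)
  v$af <- a$af
  v$clonal <- a$clonal
  list(state = state, v = v)
}

#' Simulate mutation accrual over timepoints or a lineage
#'
#' Events accrue as Poisson(days x rate) per interval, with SNV contexts
#' drawn from the configured signature mixture (mismatch-repair-deficient
#' configs slip indels preferentially at homopolymer runs). Newly gained
#' events are clonal (allele fraction 0.5) with probability
#' `clonal_fraction`, otherwise subclonal (allele fraction uniform on
#' `subclonal_af`). At each later timepoint a `lost_fraction` of inherited
#' subclonal variants is dropped (clonal variants may also be lost in
#' lineage configs, mirroring in-vivo selection). Catalogs carry true allele
#' fractions; read counts are layered on by [simulate_counts()].
#'
#' @param cfg a [sim_config()].
#' @param ref the matching [make_reference()] output.
#' @param sample_id sample label for the emitted catalogs.
#' @return list with `catalogs` (named by timepoint/node label) and `truth`
#'   (per-interval gained/lost keys, event counts and the generating
#'   parameters).
#' @export
simulate_timecourse <- function(cfg, ref, sample_id = cfg$preset) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ref, "sim_reference"))
  with_seed(derive_seed(cfg$seed, "timecourse"), {
    state <- new_sim_state(cfg, ref)
    n_b_ind <- round(cfg$baseline_n *
                       cfg$indel_rate / max(cfg$snv_rate + cfg$indel_rate,
                                            1e-9))
    base <- draw_events(state, cfg$baseline_n - n_b_ind, n_b_ind,
                        cfg$baseline_clonal_fraction)
    state <- base$state
    edges <- if (!is.null(cfg$lineage)) {
      nodes <- names(cfg$lineage)
      data.frame(node = nodes, parent = as.character(cfg$lineage),
                 days = ifelse(is.na(cfg$lineage), 0, cfg$n_days),
                 stringsAsFactors = FALSE)
    } else {
      tp <- sort(cfg$timepoints)
      data.frame(node = paste0("T", tp),
                 parent = c(NA, paste0("T", head(tp, -1))),
                 days = c(0, diff(tp)), stringsAsFactors = FALSE)
    }
    tables <- list()
    truth <- list(params = list(snv_rate = cfg$snv_rate,
                                indel_rate = cfg$indel_rate,
                                lost_fraction = cfg$lost_fraction),
                  intervals = list())
    for (r in seq_len(nrow(edges))) {
      node <- edges$node[r]
      if (is.na(edges$parent[r])) {
        tables[[node]] <- base$v
        next
      }
      parent <- tables[[edges$parent[r]]]
      n_snv <- rpois(1, edges$days[r] * cfg$snv_rate)
      n_indel <- rpois(1, edges$days[r] * cfg$indel_rate)
      ev <- draw_events(state, n_snv, n_indel, cfg$clonal_fraction)
      state <- ev$state
      eligible <- if (cfg$lost_clonal) rep(TRUE, nrow(parent))
      else !parent$clonal
      drop <- eligible & runif(nrow(parent)) < cfg$lost_fraction
      kept <- parent[!drop, , drop = FALSE]
      tables[[node]] <- rbind(kept, ev$v)
      truth$intervals[[node]] <- list(
        parent = edges$parent[r], days = edges$days[r],
        n_snv = n_snv, n_indel = n_indel,
        gained_keys = variant_key(ev$v$chrom, ev$v$pos, ev$v$ref, ev$v$alt),
        lost_keys = variant_key(parent$chrom[drop], parent$pos[drop],
                                parent$ref[drop], parent$alt[drop]))
    }
    catalogs <- lapply(names(tables), function(node) {
      t <- tables[[node]]
      variant_catalog(t[order(t$chrom, t$pos, t$ref, t$alt),
                        c("chrom", "pos", "ref", "alt", "af")],
                      sample_id = sample_id, timepoint = node)
    })
    names(catalogs) <- names(tables)
    list(catalogs = catalogs, truth = truth)
  })
}

#' Layer read counts onto a catalog of true allele fractions
#'
#' Depth is negative-binomial around `depth_mean`; alt reads are binomial at
#' the true allele fraction; the strand split is binomial(1/2) after a small
#' deduction for reads supporting the allele only at terminal positions
#' (excluded from strand counting). Background artifact variants are
#' injected at low allele fraction (2 x `error_rate`) at a rate of
#' `artifact_fraction` per true variant — one third of them strand-biased —
#' to exercise the filter cascade.
#'
#' @param cat a `variant_catalog` whose `af` column holds true allele
#'   fractions (from [simulate_timecourse()]).
#' @param cfg the [sim_config()].
#' @param ref the [make_reference()] output (artifact site source).
#' @return the catalog with depth/alt/strand counts and recomputed observed
#'   `af`; attribute `artifact_keys` lists the injected artifacts.
#' @export
simulate_counts <- function(cat, cfg, ref) {
  stage <- paste("counts", cat$sample_id, cat$timepoint)
  with_seed(derive_seed(cfg$seed, stage), {
    v <- cat$variants
    n_art <- round(cfg$artifact_fraction * max(nrow(v), 1))
    if (n_art > 0) {
      chroms <- sample(names(ref$genome), n_art, replace = TRUE)
      pos <- vapply(chroms, function(ch)
        sample(2:(nchar(ref$genome[[ch]]) - 1L), 1), integer(1))
      refb <- mapply(base_at, list(ref$genome), chroms, pos)
      altb <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      art <- data.frame(chrom = chroms, pos = pos, ref = refb, alt = altb,
                        af = 2 * cfg$error_rate, stringsAsFactors = FALSE)
      art$key <- variant_key(art$chrom, art$pos, art$ref, art$alt)
      art <- art[!duplicated(art$key) & !(art$key %in% v$key), ]
      biased <- seq_len(nrow(art)) <= nrow(art) / 3
    } else {
      art <- data.frame()
      biased <- logical(0)
    }
    af_true <- c(v$af, art$af)
    n <- length(af_true)
    depth <- pmax(rnbinom(n, mu = cfg$depth_mean,
                          size = cfg$depth_dispersion), 2L)
    alt <- rbinom(n, depth, af_true)
    terminal <- rbinom(n, alt, cfg$terminal_loss)
    usable <- alt - terminal
    fwd <- rbinom(n, usable, 0.5)
    rev <- usable - fwd
    if (nrow(art) > 0) { # strand-biased artifacts
      bi <- which(c(rep(FALSE, nrow(v)), biased))
      fwd[bi] <- usable[bi]
      rev[bi] <- 0L
    }
    all_v <- rbind(v[, c("chrom", "pos", "ref", "alt")],
                   if (nrow(art)) art[, c("chrom", "pos", "ref", "alt")])
    all_v$depth <- depth
    all_v$alt_count <- alt
    all_v$alt_fwd <- fwd
    all_v$alt_rev <- rev
    out <- variant_catalog(all_v, cat$sample_id, cat$timepoint)
    attr(out, "artifact_keys") <- if (nrow(art)) art$key else character(0)
    out
  })
}

gene_cn <- function(cfg, gene_model) {
  gm <- gene_model
  cn <- rep(2L, nrow(gm))
  ord <- stats::ave(seq_len(nrow(gm)), gm$chrom, FUN = seq_along)
  if (!is.null(cfg$ploidy_profile)) {
    pp <- cfg$ploidy_profile
    for (r in seq_len(nrow(pp))) {
      hit <- gm$chrom == pp$chrom[r] & ord >= pp$from[r] & ord <= pp$to[r]
      cn[hit] <- as.integer(pp$cn[r])
    }
  }
  list(cn = cn, ordinal = as.integer(ord))
}

#' Simulate a per-gene depth profile consistent with a ploidy landscape
#'
#' Per-gene median depth is proportional to CN/2 times `depth_mean` with
#' multiplicative log-normal noise; per-gene heterozygous-variant allele
#' fractions are binomially sampled around k/N for the gene's copy number N
#' (k uniform on 1..N-1). The generating segmentation is returned as truth
#' for recovery tests.
#'
#' @param cfg a [sim_config()] (its `ploidy_profile` sets the landscape;
#'   NULL means diploid everywhere).
#' @param ref the [make_reference()] output.
#' @return list with `profile` (a [depth_profile()]), `afs` (data.frame
#'   gene, af), and `truth` (data.frame chrom, ordinal, gene, cn).
#' @export
simulate_depth_profile <- function(cfg, ref) {
  with_seed(derive_seed(cfg$seed, "depth_profile"), {
    gm <- ref$gene_model
    g <- gene_cn(cfg, gm)
    md <- ifelse(g$cn == 0, cfg$depth_mean * 0.02,
                 cfg$depth_mean * g$cn / 2) *
      rlnorm(nrow(gm), 0, cfg$depth_noise_sd)
    prof <- depth_profile(data.frame(chrom = gm$chrom, ordinal = g$ordinal,
                                     gene = gm$gene, median_depth = md,
                                     stringsAsFactors = FALSE))
    afs <- list()
    for (i in seq_len(nrow(gm))) {
      if (g$cn[i] < 1) next
      k <- if (g$cn[i] == 1) rep(1L, cfg$n_het_per_gene)
      else sample(seq_len(g$cn[i] - 1L), cfg$n_het_per_gene, replace = TRUE)
      p <- k / max(g$cn[i], 1L)
      d <- pmax(rnbinom(cfg$n_het_per_gene, mu = md[i],
                        size = cfg$depth_dispersion), 10L)
      afs[[length(afs) + 1L]] <- data.frame(
        gene = gm$gene[i], af = rbinom(cfg$n_het_per_gene, d, p) / d,
        stringsAsFactors = FALSE)
    }
    list(profile = prof,
         afs = if (length(afs)) do.call(rbind, afs)
               else data.frame(gene = character(0), af = numeric(0)),
         truth = data.frame(chrom = gm$chrom, ordinal = g$ordinal,
                            gene = gm$gene, cn = g$cn,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate an FPKM expression table
#'
#' Log-normal FPKM per gene, with a configured fraction of genes forced
#' below the FPKM > 10 expression filter to exercise it.
#'
#' @param ref the [make_reference()] output.
#' @param cfg a [sim_config()].
#' @return data.frame with columns `gene`, `fpkm`; attribute `low_genes`.
#' @export
simulate_expression <- function(ref, cfg) {
  with_seed(derive_seed(cfg$seed, "expression"), {
    genes <- unique(ref$gene_model$gene)
    fpkm <- rlnorm(length(genes), cfg$expression_meanlog,
                   cfg$expression_sdlog)
    n_low <- round(cfg$low_expression_fraction * length(genes))
    low <- sample(length(genes), n_low)
    fpkm[low] <- runif(n_low, 0.1, 9)
    structure(data.frame(gene = genes, fpkm = fpkm,
                         stringsAsFactors = FALSE),
              low_genes = genes[low])
  })
}
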