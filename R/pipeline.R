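# Umbrella pipeline and command-line entry point.

#' Run the full pipeline on a simulated preset
#'
#' simulate -> filter -> subtract -> TMB -> spectrum/exposures ->
#' neoantigens -> ploidy -> evolvability, writing one TSV/VCF/JSON per stage
#' plus a machine-readable summary. Deterministic for a fixed seed. An
#' optional differential-expression table is passed through [filter_deg()].
#'
#' @param out_dir output directory (created if needed).
#' @param preset simulation preset, see [sim_config()].
#' @param seed master seed.
#' @param cfg optional pre-built [sim_config()] (overrides preset/seed).
#' @param de_table optional DE table for [filter_deg()].
#' @param predictor binding predictor (default [mock_predictor()] seeded
#'   from `seed`).
#' @param coding_mb TMB denominator (default 38).
#' @param threshold evolvability bound in alterations/day (default 10).
#' @return the summary list, invisibly; also written to
#'   `<out_dir>/summary.json`.
#' @export
run_all <- function(out_dir, preset = "msi", seed = 1L, cfg = NULL,
                    de_table = NULL, predictor = NULL, coding_mb = 38,
                    threshold = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- cfg %||% sim_config(preset, seed = seed)
  predictor <- predictor %||% mock_predictor(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  message(sprintf("run_all: preset=%s seed=%d out=%s", cfg$preset, cfg$seed,
                  out_dir))
  ref <- stage("reference", make_reference(cfg))
  write_fasta(ref$genome, file.path(out_dir, "genome.fa"))
  write_fasta(ref$transcripts, file.path(out_dir, "transcripts.fa"))
  write_gene_model(ref$gene_model, file.path(out_dir, "gene_model.tsv"))

  tc <- stage("timecourse", simulate_timecourse(cfg, ref))
  labels <- names(tc$catalogs)
  first <- labels[1]
  last <- labels[length(labels)]
  counted <- stage("counts", lapply(tc$catalogs, simulate_counts, cfg = cfg,
                                    ref = ref))
  fcfg <- filter_config(error_rate = cfg$error_rate)
  filtered <- stage("filter", lapply(counted, apply_filters, cfg = fcfg))
  for (l in labels)
    write_vcf(filtered[[l]], file.path(out_dir, paste0(l, ".vcf")))

  sub <- stage("subtract",
               subtract_catalogs(filtered[[last]], filtered[[first]]))
  gained <- stage("annotate", annotate_catalog(sub$gained, ref))
  lost <- annotate_catalog(sub$lost, ref)
  write_vcf(gained, file.path(out_dir, "gained.vcf"))
  write_vcf(lost, file.path(out_dir, "lost.vcf"))

  burden <- stage("tmb", tmb(gained, coding_mb = coding_mb))

  spec <- stage("spectrum", build_spectrum(gained, ref$genome))
  write_spectrum(spec, file.path(out_dir, "spectrum.tsv"))
  fit <- NULL
  if (sum(spec) >= 10) {
    fit <- stage("fit-signatures", fit_exposures(spec,
                                                 synthetic_signatures()))
    write_exposures(fit, file.path(out_dir, "exposures.tsv"))
  } else {
    message("fit-signatures: skipped (fewer than 10 mutations)")
  }

  expr_tab <- stage("expression", simulate_expression(ref, cfg))
  write_expression(expr_tab, file.path(out_dir, "expression.tsv"))
  neo <- stage("neoantigens",
               suppressWarnings(call_neoantigens(gained, ref, expr_tab,
                                                 cfg$hla_alleles, predictor)))
  write.table(as.data.frame(neo), file.path(out_dir, "neoantigens.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  dp <- stage("depth-profile", simulate_depth_profile(cfg, ref))
  write_depth_profile(dp$profile, file.path(out_dir, "depth_profile.tsv"))
  pl <- stage("ploidy", estimate_ploidy(dp$afs, dp$profile,
                                        seed = derive_seed(cfg$seed,
                                                           "ploidy")))
  write.table(pl$segments, file.path(out_dir, "segments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(pl$summary, file.path(out_dir, "ploidy_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  elapsed <- if (!is.null(cfg$lineage)) cfg$n_days else diff(range(cfg$timepoints))
  call <- stage("evolvability",
                evolvability_call(cfg$preset, n_variants(sub$gained),
                                  n_variants(sub$lost), elapsed,
                                  threshold = threshold))
  write.table(call, file.path(out_dir, "evolvability.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  deg <- NULL
  if (!is.null(de_table)) {
    deg <- stage("de-filter", filter_deg(de_table))
    write.table(deg, file.path(out_dir, "de_significant.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    preset = cfg$preset, seed = cfg$seed,
    thresholds = list(min_af = fcfg$min_af, alpha = fcfg$alpha,
                      error_rate = fcfg$error_rate, rank_cutoff = 0.5,
                      fpkm_cutoff = 10, evolvability = threshold),
    timepoints = labels,
    n_variants = lapply(filtered, n_variants),
    gained = n_variants(sub$gained), lost = n_variants(sub$lost),
    tmb = burden,
    ns_s = ns_s_ratio(gained)[c("ns", "s", "ratio")],
    spectrum_total = sum(spec),
    exposures = if (!is.null(fit)) as.list(round(fit$normalized, 6)),
    n_neoantigens = nrow(neo),
    neoantigens_by_class = as.list(attr(neo, "class_counts")),
    ploidy = setNames(as.list(pl$summary$fraction),
                      paste0("CN", pl$summary$cn)),
    rate_per_day = call$rate_per_day, label = call$label,
    n_de_genes = if (!is.null(deg)) nrow(deg))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}

# --- command-line interface ------------------------------------------------

parse_cli_args <- function(argv) {
  opts <- list()
  pos <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(argv) && !startsWith(argv[i + 1L], "--")) {
        opts[[key]] <- argv[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

req_opt <- function(args, key) {
  if (is.null(args$opts[[key]])) stopf("missing required option --%s", key)
  args$opts[[key]]
}

opt_num <- function(args, key, default) {
  v <- args$opts[[key]]
  if (is.null(v)) default else as.numeric(v)
}

cli_filter_config <- function(args) {
  filter_config(
    min_af = opt_num(args, "min-af", 0.10),
    alpha = opt_num(args, "alpha", 0.05),
    error_rate = opt_num(args, "error-rate", 0.01),
    dbsnp_keys = if (!is.null(args$opts$dbsnp))
      read_key_list(args$opts$dbsnp) else character(0),
    pon_keys = if (!is.null(args$opts$pon))
      read_key_list(args$opts$pon) else character(0))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `filter`, `subtract`,
#' `lineage-subtract`, `tmb`, `spectrum`, `fit-signatures`,
#' `cluster-exposures`, `neoantigens`, `ploidy`, `evolvability`,
#' `de-filter` and `run-all`. Options are `--key value` pairs; every
#' threshold defaults to the pipeline's stated value. Logs (including seeds
#' and thresholds) go to stderr; the exit status is nonzero on error. The
#' installed script lives at `system.file("cli", "crcevo", package =
#' "crcevo")`.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 on success).
#' @export
cli_main <- function(argv) {
  if (length(argv) == 0) {
    message("usage: crcevo <subcommand> [--options]; subcommands: ",
            "simulate filter subtract lineage-subtract tmb spectrum ",
            "fit-signatures cluster-exposures neoantigens ploidy ",
            "evolvability de-filter run-all")
    return(1L)
  }
  cmd <- argv[1]
  args <- parse_cli_args(argv[-1])
  seed <- as.integer(opt_num(args, "seed", 1))
  handler <- switch(
    cmd,
    "simulate" = function() {
      out <- req_opt(args, "out")
      preset <- args$opts$preset %||% "msi"
      message(sprintf("simulate: preset=%s seed=%d", preset, seed))
      cfg <- sim_config(preset, seed = seed)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      ref <- make_reference(cfg)
      write_fasta(ref$genome, file.path(out, "genome.fa"))
      write_fasta(ref$transcripts, file.path(out, "transcripts.fa"))
      write_gene_model(ref$gene_model, file.path(out, "gene_model.tsv"))
      tc <- simulate_timecourse(cfg, ref)
      for (l in names(tc$catalogs))
        write_vcf(annotate_catalog(simulate_counts(tc$catalogs[[l]], cfg,
                                                   ref), ref),
                  file.path(out, paste0(l, ".vcf")))
      dp <- simulate_depth_profile(cfg, ref)
      write_depth_profile(dp$profile, file.path(out, "depth_profile.tsv"))
      write_expression(simulate_expression(ref, cfg),
                       file.path(out, "expression.tsv"))
      jsonlite::write_json(tc$truth, file.path(out, "truth.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    },
    "filter" = function() {
      catalog <- read_vcf(req_opt(args, "vcf"))
      cfg <- cli_filter_config(args)
      message(sprintf("filter: min_af=%g alpha=%g error_rate=%g",
                      cfg$min_af, cfg$alpha, cfg$error_rate))
      out <- apply_filters(catalog, cfg)
      write_vcf(out, req_opt(args, "out"))
      message(sprintf("kept %d of %d variants", n_variants(out),
                      n_variants(catalog)))
    },
    "subtract" = function() {
      later <- read_vcf(req_opt(args, "later"))
      earlier <- read_vcf(req_opt(args, "earlier"))
      s <- subtract_catalogs(later, earlier)
      write_vcf(s$gained, req_opt(args, "gained"))
      write_vcf(s$lost, req_opt(args, "lost"))
      message(sprintf("gained %d, lost %d, shared %d",
                      n_variants(s$gained), n_variants(s$lost),
                      nrow(s$shared)))
    },
    "lineage-subtract" = function() {
      tree <- read_lineage(req_opt(args, "lineage"))
      out <- req_opt(args, "out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      res <- lineage_subtract(tree)
      for (n in names(res)) {
        write_vcf(res[[n]]$gained, file.path(out, paste0(n, ".gained.vcf")))
        write_vcf(res[[n]]$lost, file.path(out, paste0(n, ".lost.vcf")))
      }
    },
    "tmb" = function() {
      catalog <- read_vcf(req_opt(args, "vcf"))
      val <- tmb(catalog, coding_mb = opt_num(args, "coding-mb", 38))
      cat(sprintf("%g\n", val))
    },
    "spectrum" = function() {
      catg <- read_vcf(req_opt(args, "vcf"))
      genome <- read_fasta(req_opt(args, "genome"))
      write_spectrum(build_spectrum(catg, genome), req_opt(args, "out"))
    },
    "fit-signatures" = function() {
      spec <- read_spectrum(req_opt(args, "spectrum"))
      M <- if (!is.null(args$opts$signatures))
        read_signature_matrix(args$opts$signatures) else
          synthetic_signatures()
      write_exposures(fit_exposures(spec, M), req_opt(args, "out"))
    },
    "cluster-exposures" = function() {
      df <- read.delim(req_opt(args, "exposures"), check.names = FALSE)
      X <- as.matrix(df[, -1, drop = FALSE])
      rownames(X) <- df[[1]]
      linkage_to_json(cluster_exposures(X), req_opt(args, "out"))
    },
    "neoantigens" = function() {
      gained <- read_vcf(req_opt(args, "vcf"))
      ref <- list(transcripts = read_fasta(req_opt(args, "transcripts")),
                  gene_model = read_gene_model(req_opt(args, "gene-model")))
      gained <- annotate_catalog(gained, ref)
      expr <- read_expression(req_opt(args, "expression"))
      alleles <- strsplit(req_opt(args, "alleles"), ",", fixed = TRUE)[[1]]
      message(sprintf(
        "neoantigens: seed=%d rank<%g fpkm>%g kmer %d-%d", seed,
        opt_num(args, "rank-cutoff", 0.5), opt_num(args, "fpkm-cutoff", 10),
        opt_num(args, "kmin", 8), opt_num(args, "kmax", 11)))
      res <- call_neoantigens(
        gained, ref, expr, alleles, predictor = mock_predictor(seed),
        rank_cutoff = opt_num(args, "rank-cutoff", 0.5),
        fpkm_cutoff = opt_num(args, "fpkm-cutoff", 10),
        kmin = opt_num(args, "kmin", 8), kmax = opt_num(args, "kmax", 11))
      write.table(as.data.frame(res), req_opt(args, "out"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    },
    "ploidy" = function() {
      prof <- read_depth_profile(req_opt(args, "depth-profile"))
      catg <- read_vcf(req_opt(args, "vcf"))
      message(sprintf("ploidy: seed=%d alpha=%g n_perm=%d", seed,
                      opt_num(args, "alpha", 0.01),
                      as.integer(opt_num(args, "n-perm", 1000))))
      pl <- estimate_ploidy(catg, prof,
                            alpha = opt_num(args, "alpha", 0.01),
                            n_perm = as.integer(opt_num(args, "n-perm",
                                                        1000)),
                            seed = seed)
      write.table(pl$segments, req_opt(args, "out"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(pl$summary, paste0(req_opt(args, "out"), ".summary"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    },
    "evolvability" = function() {
      gained <- read_vcf(req_opt(args, "gained"))
      lost <- read_vcf(req_opt(args, "lost"))
      days <- opt_num(args, "days", 90)
      call <- evolvability_call(gained$sample_id, n_variants(gained),
                                n_variants(lost), days,
                                threshold = opt_num(args, "threshold", 10))
      write.table(call, req_opt(args, "out"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      message(sprintf("%s: %.2f alterations/day -> %s", call$sample,
                      call$rate_per_day, call$label))
    },
    "de-filter" = function() {
      df <- read.delim(req_opt(args, "table"), stringsAsFactors = FALSE)
      out <- filter_deg(df)
      write.table(out, req_opt(args, "out"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      message(sprintf("%d of %d genes significant", nrow(out), nrow(df)))
    },
    "run-all" = function() {
      run_all(req_opt(args, "out"), preset = args$opts$preset %||% "msi",
              seed = seed)
    },
    stopf("unknown subcommand '%s'", cmd))
  handler()
  0L
}
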