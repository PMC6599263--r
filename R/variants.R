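# Variant data model, filter cascade, subtraction, TMB, consequence
# annotation and NS:S ratio.

CONSEQUENCE_LEVELS <- c("synonymous", "missense", "nonsense", "frameshift",
                        "inframe_indel", "noncoding")
CODING_CONSEQUENCES <- setdiff(CONSEQUENCE_LEVELS, "noncoding")

#' Variant identity key
#'
#' Variants are identified by exact (chrom, pos, ref, alt) match, VCF-style
#' 1-based coordinates. Indels are assumed left-anchored and consistently
#' represented (one calling pipeline), so no re-normalisation is applied.
#'
#' @param chrom,pos,ref,alt vectors describing one variant per element.
#' @return character vector of keys `chrom:pos:ref:alt`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

infer_vclass <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
         ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
}

empty_variants <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vclass = character(0), depth = integer(0),
             alt_count = integer(0), alt_fwd = integer(0),
             alt_rev = integer(0), af = numeric(0), gene = character(0),
             transcript = character(0), cds_pos = integer(0),
             consequence = character(0), key = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a variant catalog
#'
#' A variant catalog holds every somatic alteration called for one sample at
#' one timepoint or lineage node. Required columns of `variants` are `chrom`,
#' `pos`, `ref`, `alt`; read-support columns (`depth`, `alt_count`,
#' `alt_fwd`, `alt_rev`) and annotation columns (`gene`, `transcript`,
#' `cds_pos`, `consequence`) are optional and filled with `NA` when absent.
#' `alt_fwd`/`alt_rev` are the alt-supporting reads per strand counted
#' excluding read-terminal positions, so `alt_fwd + alt_rev <= alt_count`.
#' The allelic frequency `af` is `alt_count / depth`; when read counts are
#' absent a pre-supplied `af` column (e.g. a simulated true allele fraction)
#' is carried through unchanged.
#'
#' @param variants data.frame of variant records.
#' @param sample_id sample label.
#' @param timepoint timepoint/generation label (e.g. "T0", "T90", "F2").
#' @return an object of class `variant_catalog`.
#' @export
variant_catalog <- function(variants, sample_id, timepoint = NA_character_) {
  if (is.null(variants) || nrow(as.data.frame(variants)) == 0) {
    variants <- empty_variants()
  }
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(v))
  if (length(miss)) stopf("variant table lacks columns: %s",
                          paste(miss, collapse = ", "))
  v$chrom <- as.character(v$chrom)
  v$pos <- as.integer(v$pos)
  v$ref <- toupper(as.character(v$ref))
  v$alt <- toupper(as.character(v$alt))
  for (col in c("depth", "alt_count", "alt_fwd", "alt_rev", "cds_pos")) {
    v[[col]] <- if (col %in% names(v)) as.integer(v[[col]]) else
      rep(NA_integer_, nrow(v))
  }
  for (col in c("gene", "transcript", "consequence")) {
    v[[col]] <- if (col %in% names(v)) as.character(v[[col]]) else
      rep(NA_character_, nrow(v))
  }
  v$vclass <- infer_vclass(v$ref, v$alt)
  af_obs <- ifelse(!is.na(v$alt_count) & !is.na(v$depth) & v$depth > 0,
                   v$alt_count / v$depth, NA_real_)
  if (!"af" %in% names(v)) v$af <- af_obs
  else v$af <- ifelse(is.na(af_obs), as.numeric(v$af), af_obs)
  v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  v <- v[, names(empty_variants())]
  rownames(v) <- NULL
  out <- structure(list(sample_id = as.character(sample_id),
                        timepoint = as.character(timepoint),
                        variants = v),
                   class = "variant_catalog")
  validate_catalog(out)
  out
}

#' Validate variant-catalog invariants
#'
#' Checks key uniqueness, coordinate and read-count invariants
#' (`0 <= alt_count <= depth`, `alt_fwd + alt_rev <= alt_count`,
#' `af` in \[0, 1\], `pos >= 1`, ref/alt consistent with the variant class).
#' @param cat a `variant_catalog`.
#' @return the catalog, invisibly; errors on violation.
#' @export
validate_catalog <- function(cat) {
  stopifnot(inherits(cat, "variant_catalog"))
  v <- cat$variants
  if (anyDuplicated(v$key))
    stopf("duplicate variant keys: %s",
          paste(unique(v$key[duplicated(v$key)]), collapse = ", "))
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) stopf("invalid variant %s: %s", v$key[i[1]], what)
  }
  bad(!is.na(v$pos) & v$pos < 1, "pos must be >= 1")
  bad(is.na(v$pos), "pos is required")
  bad(!grepl("^[ACGTN]+$", v$ref) | !grepl("^[ACGTN]+$", v$alt),
      "alleles must be ACGTN strings")
  bad(v$ref == v$alt, "ref and alt are identical")
  bad(!is.na(v$alt_count) & !is.na(v$depth) &
        (v$alt_count < 0 | v$alt_count > v$depth),
      "alt_count must satisfy 0 <= alt_count <= depth")
  bad(!is.na(v$alt_fwd) & !is.na(v$alt_rev) & !is.na(v$alt_count) &
        (v$alt_fwd < 0 | v$alt_rev < 0 | v$alt_fwd + v$alt_rev > v$alt_count),
      "strand counts must satisfy alt_fwd + alt_rev <= alt_count")
  bad(!is.na(v$af) & (v$af < 0 | v$af > 1), "af must lie in [0, 1]")
  invisible(cat)
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat(sprintf("<variant_catalog> sample %s, timepoint %s: %d variants\n",
              x$sample_id, x$timepoint, nrow(x$variants)))
  invisible(x)
}

#' Number of variants in a catalog
#' @param cat a `variant_catalog`.
#' @export
n_variants <- function(cat) nrow(cat$variants)

#' Variant keys of a catalog
#' @param cat a `variant_catalog`.
#' @export
catalog_keys <- function(cat) cat$variants$key

subset_catalog <- function(cat, keep) {
  v <- cat$variants[keep, , drop = FALSE]
  rownames(v) <- NULL
  cat$variants <- v
  cat
}

#' Filter-cascade configuration
#'
#' Defaults follow the pipeline's stated thresholds: variants with allelic
#' frequency below 10% or with a binomial read-support p-value above 0.05
#' are excluded, and variants found in a common-SNP database or a panel of
#' normals are removed as germline/artifacts. The binomial null is a
#' configurable per-read error rate (default 1%); the test is the exact
#' upper tail P(X >= alt_count) for X ~ Binomial(depth, error_rate).
#'
#' @param min_af minimum allelic frequency kept (closed bound, default 0.10).
#' @param alpha maximum binomial p-value kept (closed bound, default 0.05).
#' @param error_rate per-read error probability of the binomial null
#'   (default 0.01; must be below `min_af`).
#' @param dbsnp_keys,pon_keys character vectors of variant keys
#'   (see [variant_key()]) to remove.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_af = 0.10, alpha = 0.05, error_rate = 0.01,
                          dbsnp_keys = character(0),
                          pon_keys = character(0)) {
  if (!(min_af > 0 && min_af < 1)) stopf("min_af must be in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must be in (0, 1)")
  if (!(error_rate > 0 && error_rate < min_af))
    stopf("error_rate must be in (0, min_af)")
  structure(list(min_af = min_af, alpha = alpha, error_rate = error_rate,
                 dbsnp_keys = as.character(dbsnp_keys),
                 pon_keys = as.character(pon_keys)),
            class = "filter_config")
}

#' Exact binomial upper-tail probability
#'
#' P(X >= alt_count) for X ~ Binomial(depth, error_rate), the probability of
#' observing at least the seen alt-read support under sequencing noise alone.
#' @param alt_count,depth read counts.
#' @param error_rate per-read error probability.
#' @export
binom_upper_tail <- function(alt_count, depth, error_rate) {
  pbinom(alt_count - 1, depth, error_rate, lower.tail = FALSE)
}

#' Strand-support filter
#'
#' Alleles supported by only reads with the same strand (counting excludes
#' read-terminal positions) are discarded: a variant is kept iff
#' `alt_fwd >= 1` and `alt_rev >= 1`.
#'
#' @param cat a `variant_catalog` with populated strand counts.
#' @return logical keep-flag per variant.
#' @export
strand_filter <- function(cat) {
  v <- cat$variants
  if (nrow(v) == 0) return(logical(0))
  if (anyNA(v$alt_fwd) || anyNA(v$alt_rev)) {
    i <- which(is.na(v$alt_fwd) | is.na(v$alt_rev))[1]
    stopf("variant %s: strand counts (alt_fwd/alt_rev) are missing",
          v$key[i])
  }
  v$alt_fwd >= 1 & v$alt_rev >= 1
}

#' Allelic-frequency and binomial read-support filter
#'
#' A variant is kept iff its allelic frequency is at least `min_af` and the
#' exact binomial upper-tail p-value (alt reads vs. the per-read error null)
#' is at most `alpha`.
#'
#' @param cat a `variant_catalog` with depth/alt_count populated.
#' @param cfg a [filter_config()].
#' @return logical keep-flag per variant.
#' @export
af_binomial_filter <- function(cat, cfg = filter_config()) {
  v <- cat$variants
  if (nrow(v) == 0) return(logical(0))
  if (anyNA(v$depth) || anyNA(v$alt_count)) {
    i <- which(is.na(v$depth) | is.na(v$alt_count))[1]
    stopf("variant %s: depth/alt_count are missing", v$key[i])
  }
  if (any(v$depth < 1)) {
    stopf("variant %s: depth must be >= 1", v$key[which(v$depth < 1)[1]])
  }
  af <- v$alt_count / v$depth
  p <- binom_upper_tail(v$alt_count, v$depth, cfg$error_rate)
  af >= cfg$min_af & p <= cfg$alpha
}

#' Germline/artifact key-list filter
#'
#' Removes variants whose key occurs in a common-SNP database or panel of
#' normals.
#' @inheritParams af_binomial_filter
#' @return logical keep-flag per variant.
#' @export
database_filter <- function(cat, cfg = filter_config()) {
  k <- cat$variants$key
  !(k %in% cfg$dbsnp_keys) & !(k %in% cfg$pon_keys)
}

#' Apply the somatic filter cascade
#'
#' Order: strand support, then allelic-frequency/binomial test, then
#' database key lists. The output is a subset of the input and the cascade
#' is idempotent. Per-variant failure reasons are recorded in the
#' `filter_log` attribute (reasons: `strand_bias`, `low_af`, `binom_p`,
#' `dbsnp`, `pon`), which is what the VCF writer places in FILTER.
#'
#' @inheritParams af_binomial_filter
#' @return the filtered `variant_catalog`, with attribute `filter_log`
#'   (data.frame of key and semicolon-joined failure reasons).
#' @export
apply_filters <- function(cat, cfg = filter_config()) {
  v <- cat$variants
  if (nrow(v) == 0) {
    out <- cat
    attr(out, "filter_log") <- data.frame(key = character(0),
                                          filter = character(0),
                                          stringsAsFactors = FALSE)
    return(out)
  }
  strand_ok <- strand_filter(cat)
  af <- v$alt_count / v$depth
  p <- binom_upper_tail(v$alt_count, v$depth, cfg$error_rate)
  if (any(v$depth < 1, na.rm = TRUE) || anyNA(v$depth) || anyNA(v$alt_count))
    af_binomial_filter(cat, cfg) # raise the per-variant error
  reasons <- mapply(function(s, a, pp, k) {
    r <- character(0)
    if (!s) r <- c(r, "strand_bias")
    if (a < cfg$min_af) r <- c(r, "low_af")
    if (pp > cfg$alpha) r <- c(r, "binom_p")
    if (k %in% cfg$dbsnp_keys) r <- c(r, "dbsnp")
    if (k %in% cfg$pon_keys) r <- c(r, "pon")
    paste(r, collapse = ";")
  }, strand_ok, af, p, v$key, USE.NAMES = FALSE)
  keep <- reasons == ""
  out <- subset_catalog(cat, keep)
  attr(out, "filter_log") <- data.frame(key = v$key[!keep],
                                        filter = reasons[!keep],
                                        stringsAsFactors = FALSE)
  out
}

#' Subtract two variant catalogs (timepoint comparison)
#'
#' Compares a later catalog of the same lineage against an earlier one:
#' gained variants are present only later, lost variants only earlier, and
#' shared variants retain both allelic frequencies so trunk (clonal) vs.
#' subclonal status can be reported.
#'
#' @param later,earlier `variant_catalog`s of the same sample lineage.
#' @return list with elements `gained` and `lost` (catalogs) and `shared`
#'   (data.frame of key, af_later, af_earlier).
#' @export
subtract_catalogs <- function(later, earlier) {
  stopifnot(inherits(later, "variant_catalog"),
            inherits(earlier, "variant_catalog"))
  kl <- catalog_keys(later)
  ke <- catalog_keys(earlier)
  gained <- subset_catalog(later, !(kl %in% ke))
  lost <- subset_catalog(earlier, !(ke %in% kl))
  shared_keys <- intersect(kl, ke)
  shared <- data.frame(
    key = shared_keys,
    af_later = later$variants$af[match(shared_keys, kl)],
    af_earlier = earlier$variants$af[match(shared_keys, ke)],
    stringsAsFactors = FALSE)
  list(gained = gained, lost = lost, shared = shared)
}

#' Build a lineage tree of catalogs
#'
#' @param parents named character vector: `parents["F2"] == "F1"`; the root
#'   has parent `NA`. Must be acyclic with a single root.
#' @param catalogs named list of `variant_catalog`s, one per node.
#' @return an object of class `lineage_tree`.
#' @export
lineage_tree <- function(parents, catalogs) {
  nodes <- names(parents)
  if (is.null(nodes) || anyDuplicated(nodes))
    stopf("parents must be a uniquely named vector of node ids")
  roots <- nodes[is.na(parents)]
  if (length(roots) != 1)
    stopf("lineage tree must have exactly one root, found %d", length(roots))
  unknown <- setdiff(parents[!is.na(parents)], nodes)
  if (length(unknown)) stopf("unknown parent node(s): %s",
                             paste(unknown, collapse = ", "))
  # cycle check: walk up from every node, must reach the root
  for (n in nodes) {
    seen <- character(0)
    cur <- n
    while (!is.na(parents[[cur]])) {
      if (cur %in% seen) stopf("lineage tree contains a cycle through %s", cur)
      seen <- c(seen, cur)
      cur <- parents[[cur]]
    }
  }
  miss <- setdiff(nodes, names(catalogs))
  if (length(miss)) stopf("missing catalog for node(s): %s",
                          paste(miss, collapse = ", "))
  structure(list(parents = parents, catalogs = catalogs[nodes], root = roots),
            class = "lineage_tree")
}

#' Generation-wise subtraction over a lineage tree
#'
#' Each non-root node (e.g. xenograft generation F2) is compared with its
#' immediate parent (F1): second-generation samples against the first, third
#' against the second, and so on. The root is reported as the baseline, its
#' full catalog flagged `baseline = TRUE` (it was called against the
#' reference, nothing is subtracted).
#'
#' @param tree a [lineage_tree()].
#' @return named list per node: `gained`, `lost`, `shared`, `baseline` flag.
#' @export
lineage_subtract <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  out <- list()
  for (n in names(tree$parents)) {
    p <- tree$parents[[n]]
    if (is.na(p)) {
      out[[n]] <- list(gained = tree$catalogs[[n]],
                       lost = subset_catalog(tree$catalogs[[n]], FALSE),
                       shared = data.frame(key = character(0),
                                           af_later = numeric(0),
                                           af_earlier = numeric(0)),
                       baseline = TRUE)
    } else {
      s <- subtract_catalogs(tree$catalogs[[n]], tree$catalogs[[p]])
      out[[n]] <- c(s, list(baseline = FALSE))
    }
  }
  out
}

#' Tumor mutational burden
#'
#' Coding variants per megabase. Only variants whose annotated consequence
#' is coding (anything but `noncoding`) are counted; the denominator is the
#' coding footprint in Mb (default 38 Mb, a typical exome).
#'
#' @param cat a consequence-annotated `variant_catalog`.
#' @param coding_mb coding footprint in megabases (> 0).
#' @return alterations per Mb (numeric scalar).
#' @export
tmb <- function(cat, coding_mb = 38) {
  if (!is.numeric(coding_mb) || length(coding_mb) != 1 || coding_mb <= 0)
    stopf("coding_mb must be a positive number")
  v <- cat$variants
  if (nrow(v) > 0 && anyNA(v$consequence))
    stopf("catalog is not consequence-annotated; run annotate_catalog() first")
  sum(v$consequence %in% CODING_CONSEQUENCES) / coding_mb
}

#' Consequence of a variant on a coding sequence
#'
#' Classifies a variant given the cDNA of its transcript and the CDS bounds
#' (1-based, closed, within the cDNA). SNVs are translated through the
#' standard genetic code (synonymous / missense / nonsense); indels whose
#' length is not a multiple of 3 are frameshifts, otherwise inframe indels;
#' positions outside the CDS are noncoding.
#'
#' @param cdna transcript cDNA sequence (character scalar).
#' @param cds_start,cds_end CDS bounds within the cDNA.
#' @param cds_pos 1-based position of the first ref base within the cDNA.
#' @param ref,alt alleles (VCF-style; indels carry the anchor base).
#' @return one of `r paste(CONSEQUENCE_LEVELS, collapse = ", ")`.
#' @export
annotate_consequence <- function(cdna, cds_start, cds_end, cds_pos, ref, alt) {
  if (ref == alt) stopf("identity edit (ref == alt) is not a variant")
  if (cds_pos < 1 || cds_pos + nchar(ref) - 1L > nchar(cdna))
    return("noncoding") # spans the transcript boundary
  have <- substr(cdna, cds_pos, cds_pos + nchar(ref) - 1L)
  if (!identical(have, ref))
    stopf("ref allele %s does not match transcript sequence %s at cDNA pos %d",
          ref, have, cds_pos)
  if (cds_pos < cds_start || cds_pos > cds_end) return("noncoding")
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    off <- cds_pos - cds_start # 0-based offset into CDS
    codon_i <- off %/% 3
    codon_start <- cds_start + 3 * codon_i
    wt_codon <- substr(cdna, codon_start, codon_start + 2)
    mt_codon <- wt_codon
    substr(mt_codon, off %% 3 + 1, off %% 3 + 1) <- alt
    wt_aa <- translate_codon(wt_codon)
    mt_aa <- translate_codon(mt_codon)
    if (wt_aa == mt_aa) return("synonymous")
    if (mt_aa == "*") return("nonsense")
    return("missense")
  }
  if (abs(nchar(ref) - nchar(alt)) %% 3 != 0) "frameshift" else "inframe_indel"
}

translate_codon <- function(codon) {
  as.character(Biostrings::GENETIC_CODE[[codon]])
}

#' Annotate a catalog with gene, CDS position and consequence
#'
#' Maps every variant onto the gene model of a reference (see
#' [make_reference()] for the synthetic one, or [read_gene_model()]):
#' variants falling inside a gene get the gene/transcript labels, the cDNA
#' position and a consequence; variants between genes are `noncoding`.
#'
#' @param cat a `variant_catalog`.
#' @param reference list with elements `gene_model` (data.frame with columns
#'   transcript, gene, chrom, start, end, cds_start, cds_end) and
#'   `transcripts` (named character vector of cDNA sequences).
#' @return the annotated catalog.
#' @export
annotate_catalog <- function(cat, reference) {
  gm <- reference$gene_model
  v <- cat$variants
  if (nrow(v) == 0) return(cat)
  for (i in seq_len(nrow(v))) {
    hit <- which(gm$chrom == v$chrom[i] & gm$start <= v$pos[i] &
                   gm$end >= v$pos[i])
    if (length(hit) == 0) {
      v$consequence[i] <- "noncoding"
      next
    }
    hit <- hit[1]
    cds_pos <- v$pos[i] - gm$start[hit] + 1L
    v$gene[i] <- gm$gene[hit]
    v$transcript[i] <- gm$transcript[hit]
    v$cds_pos[i] <- cds_pos
    v$consequence[i] <- annotate_consequence(
      reference$transcripts[[gm$transcript[hit]]],
      gm$cds_start[hit], gm$cds_end[hit], cds_pos, v$ref[i], v$alt[i])
  }
  cat$variants <- v
  cat
}

#' Nonsynonymous-to-synonymous mutation ratio
#'
#' (missense + nonsense + frameshift) / synonymous, the selection readout
#' used to contrast in-vitro and in-vivo passaging. With zero synonymous
#' mutations the ratio is flagged undefined instead of raising a division
#' error.
#'
#' @param cat a consequence-annotated `variant_catalog`.
#' @return list with `ns` and `s` counts, `ratio` (NA when undefined) and a
#'   `defined` flag.
#' @export
ns_s_ratio <- function(cat) {
  v <- cat$variants
  if (nrow(v) > 0 && anyNA(v$consequence))
    stopf("catalog is not consequence-annotated; run annotate_catalog() first")
  ns <- sum(v$consequence %in% c("missense", "nonsense", "frameshift"))
  s <- sum(v$consequence == "synonymous")
  if (s == 0) list(ns = ns, s = 0L, ratio = NA_real_, defined = FALSE)
  else list(ns = ns, s = s, ratio = ns / s, defined = TRUE)
}
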