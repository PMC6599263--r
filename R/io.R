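# File formats. The variant dialect is a minimal VCF v4.2: read support is
# carried as FORMAT AD (ref,alt) and DP, the non-terminal strand split as
# INFO SAF/SAR, annotations as INFO GENE/TX/CDSPOS/CSQ, and filter-cascade
# failure reasons in FILTER. All other tables are plain TSV; lineage
# descriptions are JSON.

VCF_HEADER <- c(
  "##fileformat=VCFv4.2",
  "##source=crcevo",
  "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt reads, forward strand, read-terminal positions excluded\">",
  "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reads, reverse strand, read-terminal positions excluded\">",
  "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
  "##INFO=<ID=TX,Number=1,Type=String,Description=\"Transcript id\">",
  "##INFO=<ID=CDSPOS,Number=1,Type=Integer,Description=\"Position of the first ref base in the cDNA\">",
  "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
  "##FILTER=<ID=strand_bias,Description=\"Alt reads on one strand only\">",
  "##FILTER=<ID=low_af,Description=\"Allelic frequency below threshold\">",
  "##FILTER=<ID=binom_p,Description=\"Binomial read-support p-value above threshold\">",
  "##FILTER=<ID=dbsnp,Description=\"Key present in SNP database\">",
  "##FILTER=<ID=pon,Description=\"Key present in panel of normals\">",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depths\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">")

KNOWN_INFO_KEYS <- c("SAF", "SAR", "GENE", "TX", "CDSPOS", "CSQ")

#' Write a variant catalog as minimal VCF
#'
#' @param cat a `variant_catalog`; a `filter_log` attribute (from
#'   [apply_filters()]) populates FILTER for failing records written via
#'   `filter_log`.
#' @param path output file.
#' @param filter_log optional data.frame (key, filter) of failure reasons;
#'   records not listed get `PASS` (or `.` when read support is absent).
#' @export
write_vcf <- function(cat, path, filter_log = attr(cat, "filter_log")) {
  v <- cat$variants
  info <- vapply(seq_len(nrow(v)), function(i) {
    parts <- character(0)
    if (!is.na(v$alt_fwd[i])) parts <- c(parts, paste0("SAF=", v$alt_fwd[i]))
    if (!is.na(v$alt_rev[i])) parts <- c(parts, paste0("SAR=", v$alt_rev[i]))
    if (!is.na(v$gene[i])) parts <- c(parts, paste0("GENE=", v$gene[i]))
    if (!is.na(v$transcript[i])) parts <- c(parts, paste0("TX=", v$transcript[i]))
    if (!is.na(v$cds_pos[i])) parts <- c(parts, paste0("CDSPOS=", v$cds_pos[i]))
    if (!is.na(v$consequence[i])) parts <- c(parts, paste0("CSQ=", v$consequence[i]))
    if (!length(parts)) "." else paste(parts, collapse = ";")
  }, character(1))
  filt <- rep(NA_character_, nrow(v))
  if (!is.null(filter_log) && nrow(filter_log) > 0) {
    m <- match(v$key, filter_log$key)
    filt <- filter_log$filter[m]
  }
  filt[is.na(filt)] <- ifelse(is.na(v$depth[is.na(filt)]), ".", "PASS")
  gt <- ifelse(is.na(v$depth) | is.na(v$alt_count), ".:.",
               paste0(v$depth - v$alt_count, ",", v$alt_count, ":", v$depth))
  lines <- c(VCF_HEADER,
             paste0("##sample=", cat$sample_id),
             paste0("##timepoint=", cat$timepoint),
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cat$sample_id, sep = "\t"))
  if (nrow(v) > 0)
    lines <- c(lines, paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", filt,
                            info, "AD:DP", gt, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

parse_info <- function(s) {
  if (s == ".") return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  setNames(lapply(kv, function(x) if (length(x) > 1) x[2] else TRUE),
           vapply(kv, `[`, character(1), 1))
}

#' Read a minimal VCF into a variant catalog
#'
#' Malformed records raise an error naming the offending line number;
#' unknown INFO keys produce a warning. Invariants (alt_count <= depth,
#' valid alleles) are enforced on read.
#'
#' @param path VCF file path.
#' @param sample_id,timepoint optional overrides; defaults come from the
#'   `##sample=` / `##timepoint=` header lines or the genotype column name.
#' @return a `variant_catalog`.
#' @export
read_vcf <- function(path, sample_id = NULL, timepoint = NULL) {
  lines <- readLines(path)
  hdr <- grepl("^##", lines)
  chrom_line <- which(grepl("^#CHROM", lines))
  if (length(chrom_line) != 1) stopf("%s: missing #CHROM header line", path)
  meta <- lines[hdr]
  get_meta <- function(key) {
    m <- grep(paste0("^##", key, "="), meta, value = TRUE)
    if (length(m)) sub(paste0("^##", key, "="), "", m[1]) else NULL
  }
  cols <- strsplit(lines[chrom_line], "\t", fixed = TRUE)[[1]]
  sample_id <- sample_id %||% get_meta("sample") %||%
    (if (length(cols) >= 10) cols[10] else "sample")
  timepoint <- timepoint %||% get_meta("timepoint") %||% NA_character_
  body_idx <- setdiff(seq_along(lines), c(which(hdr), chrom_line))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  rows <- vector("list", length(body_idx))
  unknown_info <- character(0)
  for (k in seq_along(body_idx)) {
    ln <- body_idx[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stopf("%s line %d: expected >= 8 tab-separated fields",
                             path, ln)
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1) stopf("%s line %d: bad POS '%s'", path, ln, f[2])
    if (grepl(",", f[5], fixed = TRUE))
      stopf("%s line %d: multi-allelic records must be decomposed", path, ln)
    if (!grepl("^[ACGTNacgtn]+$", f[4]) || !grepl("^[ACGTNacgtn]+$", f[5]))
      stopf("%s line %d: bad REF/ALT alleles", path, ln)
    info <- parse_info(f[8])
    unknown_info <- union(unknown_info,
                          setdiff(names(info), KNOWN_INFO_KEYS))
    depth <- alt_count <- NA_integer_
    if (length(f) >= 10 && f[9] != "." && f[10] != ".:.") {
      fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      val <- strsplit(f[10], ":", fixed = TRUE)[[1]]
      ad <- val[match("AD", fmt)]
      dp <- val[match("DP", fmt)]
      if (!is.na(ad)) {
        adv <- suppressWarnings(as.integer(strsplit(ad, ",")[[1]]))
        if (length(adv) != 2 || anyNA(adv))
          stopf("%s line %d: bad AD field '%s'", path, ln, ad)
        alt_count <- adv[2]
      }
      if (!is.na(dp)) depth <- suppressWarnings(as.integer(dp))
      if (!is.na(depth) && !is.na(alt_count) &&
          (alt_count < 0 || alt_count > depth))
        stopf("%s line %d: alt_count %d exceeds depth %d",
              path, ln, alt_count, depth)
    }
    as_int <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
    as_chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
    rows[[k]] <- data.frame(
      chrom = f[1], pos = pos, ref = toupper(f[4]), alt = toupper(f[5]),
      depth = depth, alt_count = alt_count,
      alt_fwd = as_int(info$SAF), alt_rev = as_int(info$SAR),
      gene = as_chr(info$GENE), transcript = as_chr(info$TX),
      cds_pos = as_int(info$CDSPOS), consequence = as_chr(info$CSQ),
      stringsAsFactors = FALSE)
  }
  if (length(unknown_info))
    warnf("%s: unknown INFO key(s) ignored: %s", path,
          paste(unknown_info, collapse = ", "))
  df <- if (length(rows)) do.call(rbind, rows) else NULL
  variant_catalog(df, sample_id = sample_id, timepoint = timepoint)
}

#' Read variant keys from a VCF or 4-column TSV key list
#'
#' For database filters (dbSNP-like, panel of normals): either a VCF (keys
#' taken from CHROM/POS/REF/ALT) or a headerless 4-column TSV
#' (chrom, pos, ref, alt).
#' @param path file path.
#' @return character vector of variant keys.
#' @export
read_key_list <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##") || startsWith(first, "#CHROM")) {
    cat <- read_vcf(path)
    return(catalog_keys(cat))
  }
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stopf("%s: key list needs 4 columns (chrom,pos,ref,alt)",
                          path)
  variant_key(df[[1]], df[[2]], toupper(df[[3]]), toupper(df[[4]]))
}

#' Read / write FASTA (wrapper around Biostrings)
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)), path)
  invisible(path)
}

#' Read / write the gene-model TSV
#'
#' Columns: transcript, gene, chrom, start, end, cds_start, cds_end
#' (1-based, closed; CDS bounds within the cDNA). CDS lengths must be
#' divisible by 3.
#' @param path file path.
#' @export
read_gene_model <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("transcript", "gene", "chrom", "start", "end", "cds_start",
           "cds_end")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("%s: gene model lacks columns: %s", path,
                          paste(miss, collapse = ", "))
  badlen <- which((df$cds_end - df$cds_start + 1) %% 3 != 0)
  if (length(badlen))
    stopf("%s: CDS length of %s is not divisible by 3", path,
          df$transcript[badlen[1]])
  df
}

#' @rdname read_gene_model
#' @param gene_model data.frame in gene-model layout.
#' @export
write_gene_model <- function(gene_model, path) {
  write.table(gene_model, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a 2-column expression TSV (gene, fpkm)
#' @param path file path.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "fpkm") %in% names(df)))
    stopf("%s: expression table needs columns gene, fpkm", path)
  if (anyDuplicated(df$gene)) stopf("%s: duplicate gene symbols", path)
  df
}

#' @rdname read_expression
#' @param expression data.frame (gene, fpkm).
#' @export
write_expression <- function(expression, path) {
  write.table(expression, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a depth-profile TSV (chrom, ordinal, gene, median_depth)
#' @param path file path.
#' @export
read_depth_profile <- function(path) {
  depth_profile(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_depth_profile
#' @param profile a [depth_profile()].
#' @export
write_depth_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read growth records (sample, n, t, split_ratio TSV)
#' @param path file path.
#' @return data.frame with the doubling time and growth rate appended.
#' @export
read_growth_records <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "n", "t")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("%s: growth records lack columns: %s", path,
                          paste(miss, collapse = ", "))
  df$dt <- doubling_time(df$n, df$t)
  df$gr <- growth_rate(df$dt)
  df
}

#' Write / read a lineage description as JSON
#'
#' Layout: `{"nodes": [{"id": "F1", "parent": null, "vcf": "F1.vcf"}, ...]}`.
#' VCF paths are interpreted relative to the JSON file.
#'
#' @param tree a [lineage_tree()].
#' @param path output JSON path; per-node VCFs are written next to it.
#' @export
write_lineage <- function(tree, path) {
  dir <- dirname(path)
  nodes <- lapply(names(tree$parents), function(n) {
    vcf <- paste0(n, ".vcf")
    write_vcf(tree$catalogs[[n]], file.path(dir, vcf))
    p <- tree$parents[[n]]
    list(id = n, parent = if (is.na(p)) NULL else p, vcf = vcf)
  })
  jsonlite::write_json(list(nodes = nodes), path, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_lineage
#' @export
read_lineage <- function(path) {
  js <- jsonlite::read_json(path)
  dir <- dirname(path)
  ids <- vapply(js$nodes, function(n) n$id, character(1))
  parents <- setNames(vapply(js$nodes, function(n)
    if (is.null(n$parent)) NA_character_ else n$parent, character(1)), ids)
  catalogs <- setNames(lapply(js$nodes, function(n)
    read_vcf(file.path(dir, n$vcf), timepoint = n$id)), ids)
  lineage_tree(parents, catalogs)
}
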