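# 96-channel trinucleotide spectra, NNLS signature refitting, and
# average-linkage clustering of exposure profiles.

#' Canonical 96-channel order
#'
#' Six pyrimidine-centric substitution subtypes (C>A, C>G, C>T, T>A, T>C,
#' T>G) times 16 flanking contexts; within each subtype the 5' base varies
#' slowest and both flanks run alphabetically (A, C, G, T). Channel labels
#' look like `"A[C>T]G"`. All spectrum and signature-matrix files use this
#' exact row order.
#' @return character vector of 96 channel labels.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  b <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    paste0(rep(b, each = 4), "[", s, "]", rep(b, times = 4))))
}

#' Build the 96-channel mutation spectrum of a catalog
#'
#' Every SNV is binned by its substitution subtype and immediate 5'/3'
#' context. Substitutions are referred to by the pyrimidine of the mutated
#' Watson-Crick pair: SNVs with a purine reference are reverse-complemented
#' (allele and flanks) before binning. Indels are ignored. SNVs whose
#' context is unavailable (contig edge) are skipped with a warning and
#' counted in the `skipped` attribute, so
#' `sum(spectrum) + skipped == number of SNVs`.
#'
#' @param cat a `variant_catalog`.
#' @param genome named character vector of contig sequences.
#' @return integer vector of 96 counts (class `spectrum96`) with attributes
#'   `skipped` and `total_snvs`.
#' @export
build_spectrum <- function(cat, genome) {
  channels <- sbs96_channels()
  counts <- setNames(integer(96), channels)
  v <- cat$variants[cat$variants$vclass == "SNV", , drop = FALSE]
  skipped <- 0L
  for (i in seq_len(nrow(v))) {
    seqi <- genome[[v$chrom[i]]]
    if (is.null(seqi) || is.na(seqi))
      stopf("contig %s absent from genome", v$chrom[i])
    pos <- v$pos[i]
    if (pos < 2 || pos > nchar(seqi) - 1) {
      skipped <- skipped + 1L
      next
    }
    ref_g <- substr(seqi, pos, pos)
    if (ref_g != v$ref[i])
      stopf("variant %s: ref %s does not match genome base %s",
            v$key[i], v$ref[i], ref_g)
    l <- substr(seqi, pos - 1, pos - 1)
    r <- substr(seqi, pos + 1, pos + 1)
    if (v$ref[i] %in% c("C", "T")) {
      ch <- paste0(l, "[", v$ref[i], ">", v$alt[i], "]", r)
    } else {
      ch <- paste0(dna_complement(r), "[", dna_complement(v$ref[i]), ">",
                   dna_complement(v$alt[i]), "]", dna_complement(l))
    }
    if (!ch %in% channels) { # ambiguous base in allele or context
      skipped <- skipped + 1L
      next
    }
    counts[ch] <- counts[ch] + 1L
  }
  if (skipped > 0)
    warnf("%d SNV(s) skipped (context unavailable)", skipped)
  structure(counts, class = "spectrum96", skipped = skipped,
            total_snvs = nrow(v))
}

validate_signature_matrix <- function(M, tol = 1e-9) {
  if (!is.matrix(M) || nrow(M) != 96)
    stopf("signature matrix must have 96 rows")
  if (any(M < 0)) stopf("signature matrix entries must be nonnegative")
  cs <- colSums(M)
  if (any(abs(cs - 1) > tol))
    stopf("signature column(s) do not sum to 1: %s",
          paste(colnames(M)[abs(cs - 1) > tol], collapse = ", "))
  if (!is.null(rownames(M)) && !identical(rownames(M), sbs96_channels()))
    stopf("signature matrix rows are not in canonical 96-channel order")
  invisible(M)
}

#' Nonnegative least squares (Lawson-Hanson active set)
#'
#' Solves `argmin_{x >= 0} ||A x - b||_2`. Used for signature refitting;
#' exposed because it is generally useful and easy to test against a
#' brute-force active-set oracle.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector (length m).
#' @return list with `x` (the nonnegative solution) and `residual`
#'   (Euclidean norm of `A x - b`).
#' @export
nnls <- function(A, b) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  tol <- 1e-10 * max(1, max(abs(crossprod(A, b))))
  w <- drop(crossprod(A, b - A %*% x))
  outer_it <- 0L
  while (any(!passive) && any(w[!passive] > tol) && outer_it < 30L * n) {
    outer_it <- outer_it + 1L
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) {
        x <- s
        break
      }
      q <- passive & s <= tol
      alpha <- min(x[q] / (x[q] - s[q]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
      if (!any(passive)) break
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x[x < 0] <- 0
  list(x = x, residual = sqrt(sum((A %*% x - b)^2)))
}

#' Refit signature exposures to a spectrum
#'
#' Nonnegative least squares of the raw 96-channel counts on the signature
#' matrix: exposures = argmin over e >= 0 of ||M e - spectrum||. Samples
#' with fewer than 10 mutations are refused outright (too little signal for
#' a stable refit).
#'
#' @param spec a `spectrum96` (or plain 96-vector of counts).
#' @param M signature matrix: 96 rows in canonical channel order, one column
#'   per signature, columns summing to 1.
#' @param min_mutations refusal threshold (default 10).
#' @return object of class `exposure_fit`: list with `exposures` (raw,
#'   mutation-count scale), `normalized` (sums to 1), `residual`, `total`.
#' @export
fit_exposures <- function(spec, M, min_mutations = 10) {
  spec <- as.numeric(spec)
  if (length(spec) != 96) stopf("spectrum must have 96 channels")
  if (any(spec < 0)) stopf("spectrum counts must be nonnegative")
  validate_signature_matrix(M)
  total <- sum(spec)
  if (total < min_mutations)
    stopf("insufficient mutations: spectrum has %d, need at least %d",
          total, min_mutations)
  fit <- nnls(M, spec)
  e <- setNames(fit$x, colnames(M))
  norm <- if (sum(e) > 0) e / sum(e) else e
  structure(list(exposures = e, normalized = norm, residual = fit$residual,
                 total = total),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat(sprintf("<exposure_fit> %d mutations, residual %.3f\n",
              x$total, x$residual))
  print(round(x$normalized, 3))
  invisible(x)
}

#' Cluster exposure profiles (Euclidean, average linkage)
#'
#' Agglomerative clustering of per-sample signature contribution vectors
#' with the Euclidean metric and average linkage. `stats::hclust` breaks
#' ties by merging the lowest-index pair first, so the tree is deterministic
#' under a fixed input order.
#'
#' @param X numeric matrix, one row per sample (>= 2 rows).
#' @return an `hclust` merge tree.
#' @export
cluster_exposures <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("clustering needs at least 2 exposure profiles")
  hclust(dist(X, method = "euclidean"), method = "average")
}

#' Export a merge tree as nested JSON
#'
#' @param hc an `hclust` object.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
linkage_to_json <- function(hc, path = NULL) {
  labels <- hc$labels %||% as.character(seq_along(hc$order))
  build <- function(i) {
    if (i < 0) return(list(leaf = labels[-i]))
    list(height = hc$height[i],
         children = list(build(hc$merge[i, 1]), build(hc$merge[i, 2])))
  }
  js <- jsonlite::toJSON(build(nrow(hc$merge)), auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Bundled synthetic signature set
#'
#' Six deterministic, well-separated 96-channel profiles used by the
#' synthetic-data generator and the test suite (no external signature data
#' is ever downloaded). They mimic the shapes relevant to DNA-repair
#' deficiency without being the canonical catalog: `clock_ct` (C>T at CpG,
#' ageing-like), `mmr_ct` (broad C>T plus T>C, mismatch-repair-like),
#' `pole_ca` (C>A at TpCpT plus C>T at TpCpG and T>G at TpTpT, polymerase
#' epsilon proofreading-like), `mutyh_ca` (broad C>A, base-excision-repair
#' like), `apobec` (C>T/C>G at TpCpW), and `flat` (uniform background).
#' Real signature matrices in the same TSV layout are accepted as input by
#' [read_signature_matrix()].
#'
#' @return 96 x 6 probability matrix in canonical channel order.
#' @export
synthetic_signatures <- function() {
  ch <- sbs96_channels()
  sub <- substr(ch, 3, 5)
  f5 <- substr(ch, 1, 1)
  f3 <- substr(ch, 7, 7)
  M <- matrix(0, 96, 6,
              dimnames = list(ch, c("clock_ct", "mmr_ct", "pole_ca",
                                    "mutyh_ca", "apobec", "flat")))
  M[sub == "C>T" & f3 == "G", "clock_ct"] <- 1
  M[sub == "C>T" & f3 != "G", "clock_ct"] <- 0.05
  M[sub == "C>T", "mmr_ct"] <- 1
  M[sub == "T>C", "mmr_ct"] <- 0.5
  M["T[C>A]T", "pole_ca"] <- 8
  M["T[C>T]G", "pole_ca"] <- 5
  M["T[T>G]T", "pole_ca"] <- 3
  M[, "pole_ca"] <- M[, "pole_ca"] + 0.02
  M[sub == "C>A", "mutyh_ca"] <- 1
  M[sub %in% c("C>T", "C>G") & f5 == "T" & f3 %in% c("A", "T"), "apobec"] <- 1
  M[, "flat"] <- 1
  sweep(M, 2, colSums(M), "/")
}

#' Write / read a 96-channel spectrum as TSV
#'
#' Two columns (`channel`, `count`); the channel column is mandatory and
#' must list the canonical order.
#' @param spec a `spectrum96` or 96-vector.
#' @param path file path.
#' @export
write_spectrum <- function(spec, path) {
  df <- data.frame(channel = sbs96_channels(), count = as.integer(spec))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "count") %in% names(df)))
    stopf("%s: spectrum TSV needs columns channel, count", path)
  if (!identical(df$channel, sbs96_channels()))
    stopf("%s: channel column is not in canonical 96-channel order", path)
  structure(setNames(as.integer(df$count), df$channel), class = "spectrum96",
            skipped = 0L, total_snvs = sum(df$count))
}

#' Write / read a signature matrix as TSV
#'
#' First column `channel` (canonical order), one column per signature.
#' @param M 96 x S probability matrix.
#' @param path file path.
#' @export
write_signature_matrix <- function(M, path) {
  validate_signature_matrix(M)
  df <- data.frame(channel = sbs96_channels(),
                   format(M, digits = 15, scientific = FALSE, trim = TRUE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_matrix
#' @export
read_signature_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "channel")
    stopf("%s: first column must be 'channel'", path)
  if (!identical(df$channel, sbs96_channels()))
    stopf("%s: channel column is not in canonical 96-channel order", path)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$channel
  # re-normalise away the rounding incurred by the text representation
  M <- sweep(M, 2, colSums(M), "/")
  validate_signature_matrix(M)
  M
}

#' Write exposures (raw, normalized, residual) as TSV
#' @param fit an `exposure_fit`.
#' @param path file path.
#' @export
write_exposures <- function(fit, path) {
  df <- data.frame(signature = names(fit$exposures),
                   exposure = as.numeric(fit$exposures),
                   normalized = as.numeric(fit$normalized))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_mutations=%d residual=%.6g",
                     fit$total, fit$residual), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
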