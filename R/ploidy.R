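# Two-step ploidy estimation: relative gene copy number from depth ratios,
# circular binary segmentation in gene-ordinal space, and absolute integer
# copy number from allelic-frequency peak matching.

#' Construct a per-gene depth profile
#'
#' Ordered per-gene records in gene-ordinal coordinates (genes numbered
#' along each chromosome), the native coordinate space of the ploidy
#' estimator.
#'
#' @param df data.frame with columns `chrom`, `ordinal`, `gene`,
#'   `median_depth`.
#' @return a `depth_profile` data.frame, ordered by (chrom, ordinal).
#' @export
depth_profile <- function(df) {
  req <- c("chrom", "ordinal", "gene", "median_depth")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("depth profile lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (any(df$median_depth < 0)) stopf("median depths must be >= 0")
  df <- df[order(df$chrom, df$ordinal), req]
  for (ch in unique(df$chrom)) {
    o <- df$ordinal[df$chrom == ch]
    if (!identical(as.integer(o), seq_along(o)))
      stopf("ordinals of %s must be 1..n without gaps", ch)
  }
  rownames(df) <- NULL
  structure(df, class = c("depth_profile", "data.frame"))
}

#' Relative gene copy number from depth ratios
#'
#' The sample is treated as diploid overall: the median read depth across
#' all coding regions is the 2N level, and each gene's relative GCN is twice
#' the ratio of its median depth to the overall median (so 2 = diploid).
#'
#' @param profile a [depth_profile()].
#' @return the profile with an added `relative_gcn` column and attribute
#'   `overall_median`.
#' @export
relative_gcn <- function(profile) {
  overall <- median(profile$median_depth)
  if (!is.finite(overall) || overall <= 0)
    stopf("overall median depth is zero; cannot estimate ploidy")
  profile$relative_gcn <- 2 * profile$median_depth / overall
  attr(profile, "overall_median") <- overall
  profile
}

# maximal circular two-sample statistic over all arcs of x.
# Arcs are x[(i+1)..j] vs the rest; both parts must span >= min_width
# points. The statistic is |mean(arc) - mean(rest)| / sqrt(1/L + 1/(n-L)):
# the scale factor common to all permutations cancels in the permutation
# test, so no variance estimate is needed.
max_arc_stat <- function(x, min_width) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  tot <- cs[n + 1]
  best <- list(stat = -Inf, i = 0L, j = 0L)
  for (L in min_width:(n - min_width)) {
    starts <- 0:(n - L) # arc = (start+1)..(start+L)
    arc <- cs[starts + L + 1] - cs[starts + 1]
    stat <- abs(arc / L - (tot - arc) / (n - L)) / sqrt(1 / L + 1 / (n - L))
    k <- which.max(stat)
    if (stat[k] > best$stat)
      best <- list(stat = stat[k], i = starts[k], j = starts[k] + L)
  }
  best
}

#' Circular binary segmentation
#'
#' Recursive changepoint search on an ordered vector of log2 depth ratios:
#' for every candidate arc the maximal two-sample statistic between in-arc
#' and out-of-arc means is compared against a permutation null (`n_perm`
#' shuffles of the values); the split is accepted iff the permutation
#' p-value is at most `alpha`, and the algorithm recurses on the resulting
#' pieces. Segments shorter than `2 * min_width` are never split. With
#' fewer than 2 values, a single trivial segment is returned.
#'
#' @param x numeric vector of ordered log2 ratios (one chromosome).
#' @param alpha permutation p-value threshold for accepting a split
#'   (default 0.01). As `alpha` goes to 0 no split is ever accepted.
#' @param n_perm number of permutations (default 1000).
#' @param min_width minimum segment length in ordinals (default 3).
#' @param seed RNG seed for the permutation null (restored afterwards).
#' @return data.frame with columns `start`, `end`, `mean` (1-based, closed,
#'   contiguous, covering 1..length(x)).
#' @export
cbs_segment <- function(x, alpha = 0.01, n_perm = 1000, min_width = 3,
                        seed = NULL) {
  n <- length(x)
  if (n < 2)
    return(data.frame(start = 1L, end = n, mean = if (n) mean(x) else NA_real_))
  with_seed(seed, {
    bounds <- cbs_recurse(x, 1L, n, alpha, n_perm, min_width)
    starts <- c(1L, head(bounds, -1) + 1L)
    data.frame(start = starts, end = bounds,
               mean = mapply(function(s, e) mean(x[s:e]), starts, bounds))
  })
}

# returns sorted segment end positions within [lo, hi]
cbs_recurse <- function(x, lo, hi, alpha, n_perm, min_width) {
  m <- hi - lo + 1L
  if (m < 2L * min_width) return(hi)
  seg <- x[lo:hi]
  obs <- max_arc_stat(seg, min_width)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (max_arc_stat(sample(seg), min_width)$stat >= obs$stat)
      exceed <- exceed + 1L
  }
  p <- (exceed + 1) / (n_perm + 1)
  if (p > alpha) return(hi)
  cuts <- sort(unique(c(obs$i, obs$j)))
  cuts <- cuts[cuts > 0 & cuts < m]
  if (length(cuts) == 0) return(hi)
  pieces <- cbind(c(1L, cuts + 1L), c(cuts, m))
  out <- integer(0)
  for (r in seq_len(nrow(pieces))) {
    out <- c(out, cbs_recurse(x, lo + pieces[r, 1] - 1L,
                              lo + pieces[r, 2] - 1L,
                              alpha, n_perm, min_width))
  }
  sort(unique(out))
}

#' Modes of a smoothed allelic-frequency density
#'
#' Gaussian kernel density of the AFs on \[0, 1\] (default bandwidth 0.03)
#' followed by local-maximum detection; minor wiggles below
#' `min_height_frac` of the tallest mode are discarded.
#'
#' @param afs numeric vector of allelic frequencies.
#' @param bw smoothing bandwidth (default 0.03).
#' @param min_height_frac relative height cutoff for reported modes
#'   (default 0.1).
#' @return data.frame with columns `af` (mode position) and `height`.
#' @export
af_density_modes <- function(afs, bw = 0.03, min_height_frac = 0.1) {
  if (length(afs) == 0)
    return(data.frame(af = numeric(0), height = numeric(0)))
  d <- density(afs, bw = bw, from = 0, to = 1, n = 512)
  y <- d$y
  is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  # plateau-safe endpoints
  if (y[1] > y[2]) is_max[1] <- TRUE
  if (y[length(y)] > y[length(y) - 1]) is_max[length(y)] <- TRUE
  i <- which(is_max & y >= min_height_frac * max(y))
  data.frame(af = d$x[i], height = y[i])
}

# mismatch between observed AF modes and the heterozygous peak grid of
# copy number N ({k/N, k=1..N-1}; {1} for N=1). Earth-mover-flavoured:
# height-weighted distance from each mode to its nearest grid peak, plus a
# fixed penalty per grid peak with no mode nearby.
af_grid_score <- function(modes, n_cn, bw = 0.03,
                          unmatched_penalty = 0.05) {
  grid <- if (n_cn == 1) 1 else seq_len(n_cn - 1) / n_cn
  d_mode <- vapply(modes$af, function(m) min(abs(m - grid)), numeric(1))
  w <- modes$height / sum(modes$height)
  tol <- max(2 * bw, 0.25 / n_cn)
  unmatched <- sum(vapply(grid, function(g)
    all(abs(modes$af - g) > tol), logical(1)))
  sum(w * d_mode) + unmatched_penalty * unmatched
}

#' Absolute copy number of a segment from its allelic frequencies
#'
#' Heterozygous variants on a segment of absolute copy number N sit at
#' allele fractions k/N (2N: one bell at 50%; 3N: two peaks at 33% and 66%;
#' 4N: 25/50/75; ...). Candidate copy numbers 1..`max_cn` are scored by
#' matching the modes of the smoothed AF density against the k/N grid and
#' the minimal-mismatch N is returned, ties broken toward the candidate
#' closest to the depth-derived relative GCN. Homozygous deletions are
#' called from the depth alone (`rel_gcn < 0.5`), since no AF grid exists at
#' N = 0; segments with fewer than `min_afs` AFs fall back to rounding the
#' relative GCN (flagged in `method`).
#'
#' @param rel_gcn the segment's mean relative gene copy number.
#' @param afs allelic frequencies of the segment's member variants.
#' @param max_cn largest candidate copy number (default 8).
#' @param bw AF density bandwidth (default 0.03).
#' @param min_afs minimum AFs required for peak matching (default 10).
#' @return list with `cn` (integer), `method` (`af_peaks`, `fallback` or
#'   `low_gcn`) and `score` (NA unless `af_peaks`).
#' @export
absolute_cn <- function(rel_gcn, afs, max_cn = 8, bw = 0.03, min_afs = 10) {
  afs <- afs[!is.na(afs)]
  if (rel_gcn < 0.5)
    return(list(cn = 0L, method = "low_gcn", score = NA_real_))
  if (length(afs) < min_afs)
    return(list(cn = max(0L, as.integer(round(rel_gcn))), method = "fallback",
                score = NA_real_))
  modes <- af_density_modes(afs, bw = bw)
  scores <- vapply(seq_len(max_cn), function(n)
    af_grid_score(modes, n, bw = bw), numeric(1))
  ord <- order(scores, abs(seq_len(max_cn) - rel_gcn))
  list(cn = as.integer(ord[1]), method = "af_peaks", score = scores[ord[1]])
}

#' Estimate the ploidy landscape of a sample
#'
#' The full two-step estimator: per-gene relative GCN from the depth
#' profile, circular binary segmentation of the log2 GCN ratios per
#' chromosome, and per-segment absolute copy number from the allelic
#' frequencies of the variants falling in the segment (matched by gene).
#' The genome summary reports the fraction of gene ordinals at each integer
#' copy number (sums to 1).
#'
#' @param cat a `variant_catalog` with `gene` and `af` populated, or a
#'   data.frame with columns `gene`, `af`.
#' @param profile a [depth_profile()].
#' @param alpha,n_perm,min_width,seed segmentation controls, see
#'   [cbs_segment()].
#' @param max_cn,bw,min_afs peak-matching controls, see [absolute_cn()].
#' @return list with `segments` (one row per segment: chrom, start, end,
#'   log2_ratio, relative_gcn, n_afs, absolute_cn, method, score) and
#'   `summary` (data.frame cn, fraction).
#' @export
estimate_ploidy <- function(cat, profile, alpha = 0.01, n_perm = 1000,
                            min_width = 3, seed = NULL, max_cn = 8,
                            bw = 0.03, min_afs = 10) {
  afs <- if (inherits(cat, "variant_catalog"))
    data.frame(gene = cat$variants$gene, af = cat$variants$af)
  else as.data.frame(cat)[, c("gene", "af")]
  prof <- relative_gcn(profile)
  segs <- list()
  for (ch in unique(prof$chrom)) {
    p <- prof[prof$chrom == ch, ]
    x <- log2(pmax(p$relative_gcn, 0.05) / 2)
    s <- cbs_segment(x, alpha = alpha, n_perm = n_perm,
                     min_width = min_width,
                     seed = if (is.null(seed)) NULL
                            else derive_seed(seed, paste0("cbs_", ch)))
    for (r in seq_len(nrow(s))) {
      genes <- p$gene[s$start[r]:s$end[r]]
      seg_afs <- afs$af[afs$gene %in% genes]
      rg <- mean(p$relative_gcn[s$start[r]:s$end[r]])
      ac <- absolute_cn(rg, seg_afs, max_cn = max_cn, bw = bw,
                        min_afs = min_afs)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = s$start[r], end = s$end[r],
        log2_ratio = s$mean[r], relative_gcn = rg,
        n_afs = length(seg_afs[!is.na(seg_afs)]),
        absolute_cn = ac$cn, method = ac$method, score = ac$score,
        stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  widths <- segments$end - segments$start + 1L
  tab <- tapply(widths, segments$absolute_cn, sum)
  summary <- data.frame(cn = as.integer(names(tab)),
                        fraction = as.numeric(tab) / sum(widths))
  list(segments = segments, summary = summary)
}
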