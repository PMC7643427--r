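#' Distance-band z-score map
#'
#' For every intra-arm bin pair separated by at least `min_separation`
#' bins (default 2: self and nearest-neighbour pairs carry mostly
#' digestion/religation signal and are never considered), the contact
#' value is standardized against the other pairs at the same genomic
#' separation: `z = (v - mean_band) / sd_band`.  Bands with fewer than
#' `min_band_pairs` pairs are excluded entirely, as are bands with zero
#' spread.  Band statistics are computed per arm by default
#' (`pool = "genome"` pools all arms at each separation).
#'
#' @param cm a `contact_matrix`, normally vc_sqrt-normalized (any
#'   normalization is accepted and recorded).
#' @param min_separation smallest pair separation in bins (default 2).
#' @param min_band_pairs minimum pairs a band needs to be scored
#'   (default 15).
#' @param pool `"arm"` (default) or `"genome"`.
#' @return object of class `"zscore_map"`: the z matrix (`$z`, NA where
#'   masked), the layout, and the parameters used.
#' @export
zscore_map <- function(cm, min_separation = 2L, min_band_pairs = 15L,
                       pool = c("arm", "genome")) {
  stopifnot(inherits(cm, "contact_matrix"))
  pool <- match.arg(pool)
  B <- cm$layout$n_bins
  z <- matrix(NA_real_, B, B)
  pairs <- intra_arm_pairs(cm, min_sep = min_separation)
  if (nrow(pairs) == 0L) stop("no eligible intra-arm pairs")
  bins <- cm$layout$bins
  grp <- if (pool == "arm")
    paste(bins$chrom[pairs$bin1], bins$arm[pairs$bin1], pairs$sep)
  else as.character(pairs$sep)
  dropped <- 0L
  for (g in split(seq_len(nrow(pairs)), grp)) {
    if (length(g) < min_band_pairs) next
    v <- pairs$value[g]
    mu <- mean(v); sdev <- stats::sd(v)
    if (!is.finite(sdev) || sdev == 0) { dropped <- dropped + 1L; next }
    zv <- (v - mu) / sdev
    i <- pairs$bin1[g]; j <- pairs$bin2[g]
    z[cbind(i, j)] <- zv
    z[cbind(j, i)] <- zv
  }
  if (dropped > 0L)
    warning(dropped, " band(s) with zero spread were masked")
  structure(list(z = z, layout = cm$layout, norm = cm$norm,
                 min_separation = min_separation,
                 min_band_pairs = min_band_pairs, pool = pool,
                 resolution = cm$resolution),
            class = "zscore_map")
}

#' Call high z-score interactions
#'
#' All unmasked intra-arm bin pairs with z strictly greater than the
#' threshold.
#'
#' @param zmap a [zscore_map()].
#' @param threshold z cutoff (default 2; strict inequality).
#' @param condition optional condition label.
#' @return data.frame of class `"interaction_set"`: `bin1 < bin2`
#'   (global 1-based ids), `chrom`, `start1`, `start2`, `distance` (bp),
#'   `z`, `condition`; attributes `resolution`, `layout`.
#' @export
call_interactions <- function(zmap, threshold = 2, condition = NA_character_) {
  stopifnot(inherits(zmap, "zscore_map"))
  idx <- which(upper.tri(zmap$z) & !is.na(zmap$z) & zmap$z > threshold,
               arr.ind = TRUE)
  bins <- zmap$layout$bins
  condition <- rep(condition, nrow(idx))
  out <- data.frame(bin1 = idx[, 1], bin2 = idx[, 2],
                    chrom = bins$chrom[idx[, 1]],
                    start1 = bins$start[idx[, 1]],
                    start2 = bins$start[idx[, 2]],
                    distance = (idx[, 2] - idx[, 1]) * zmap$resolution,
                    z = zmap$z[idx],
                    condition = condition,
                    stringsAsFactors = FALSE)
  out <- out[order(out$bin1, out$bin2), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("interaction_set", "data.frame"),
            resolution = zmap$resolution, layout = zmap$layout)
}

#' Partition two interaction sets into common and specific calls
#'
#' Exact bin-pair identity: an interaction is common when the same
#' (bin1, bin2) pair is called in both conditions.
#'
#' @param set_a,set_b `interaction_set`s at the same resolution.
#' @return list with data.frames `common`, `a_specific`, `b_specific`
#'   and the integer vector `counts`.
#' @export
compare_sets <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "interaction_set"),
            inherits(set_b, "interaction_set"))
  if (!identical(attr(set_a, "resolution"), attr(set_b, "resolution")))
    stop("interaction sets have different resolutions")
  ka <- paste(set_a$bin1, set_a$bin2)
  kb <- paste(set_b$bin1, set_b$bin2)
  list(common = set_a[ka %in% kb, , drop = FALSE],
       a_specific = set_a[!ka %in% kb, , drop = FALSE],
       b_specific = set_b[!kb %in% ka, , drop = FALSE],
       counts = c(common = sum(ka %in% kb),
                  a_specific = sum(!ka %in% kb),
                  b_specific = sum(!kb %in% ka)))
}

#' Aggregate contact map around called interactions
#'
#' For each interaction, the square window of half-width `half_window`
#' genomic distance centered on the pair (a 9 x 9 window at 2 kb bins
#' and the default 8 kb half-window) is extracted, divided by its own
#' mean, and the normalized windows are averaged element-wise.  Windows
#' truncated by an arm edge are dropped.  A centre enrichment above the
#' window border indicates point-like (loop) contacts.
#'
#' @param cm a `contact_matrix` (typically KR-normalized).
#' @param interactions an `interaction_set` at the same resolution.
#' @param half_window half window size in bp (default 8000).
#' @return list: `profile` (mean normalized window), `n_used`,
#'   `offsets` (bp offsets of window rows/cols).
#' @export
aggregate_matrix <- function(cm, interactions, half_window = 8000) {
  stopifnot(inherits(cm, "contact_matrix"),
            inherits(interactions, "interaction_set"))
  if (!identical(cm$resolution, attr(interactions, "resolution")))
    stop("matrix and interactions are at different resolutions")
  w <- as.integer(round(half_window / cm$resolution))
  bins <- cm$layout$bins
  size <- 2L * w + 1L
  acc <- matrix(0, size, size)
  n_used <- 0L
  for (r in seq_len(nrow(interactions))) {
    i <- interactions$bin1[r]; j <- interactions$bin2[r]
    ri <- (i - w):(i + w); rj <- (j - w):(j + w)
    if (min(ri) < 1L || min(rj) < 1L ||
        max(ri) > cm$layout$n_bins || max(rj) > cm$layout$n_bins) next
    # whole window must stay on the pair's arm
    if (length(unique(bins$chrom[c(ri, rj)])) > 1L ||
        length(unique(bins$arm[c(ri, rj)])) > 1L) next
    sub <- cm$mat[ri, rj, drop = FALSE]
    mu <- mean(sub, na.rm = TRUE)
    if (!is.finite(mu) || mu <= 0) next
    sub[is.na(sub)] <- mu  # masked cells do not pull the mean window
    acc <- acc + sub / mu
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no interaction window fits inside an arm")
  offs <- seq(-w, w) * cm$resolution
  list(profile = acc / n_used, n_used = n_used, offsets = offs)
}

#' Read and write interaction pairs as BEDPE
#'
#' Tab-separated BEDPE (0-based half-open intervals, `start1 <= start2`)
#' with a `z` score column and an optional condition.
#' @param x an `interaction_set`.
#' @param path file path.
#' @export
write_bedpe <- function(x, path) {
  stopifnot(inherits(x, "interaction_set"))
  res <- attr(x, "resolution")
  df <- data.frame(chrom1 = x$chrom, start1 = x$start1,
                   end1 = x$start1 + res,
                   chrom2 = x$chrom, start2 = x$start2,
                   end2 = x$start2 + res,
                   name = ".", z = x$z)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @param layout a `genome_layout` giving the bin coordinates.
#' @export
read_bedpe <- function(path, layout) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  z <- if (ncol(df) >= 8L) as.numeric(df[[8L]]) else NA_real_
  bins <- layout$bins
  key <- paste(bins$chrom, bins$start)
  b1 <- match(paste(df$chrom1, df$start1), key)
  b2 <- match(paste(df$chrom2, df$start2), key)
  if (anyNA(b1) || anyNA(b2)) stop("BEDPE coordinates not on bin grid")
  swap <- b1 > b2
  tmp <- b1[swap]; b1[swap] <- b2[swap]; b2[swap] <- tmp
  out <- data.frame(bin1 = b1, bin2 = b2, chrom = bins$chrom[b1],
                    start1 = bins$start[b1], start2 = bins$start[b2],
                    distance = (b2 - b1) * layout$binsize, z = z,
                    condition = NA_character_, stringsAsFactors = FALSE)
  structure(out, class = c("interaction_set", "data.frame"),
            resolution = layout$binsize, layout = layout)
}
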