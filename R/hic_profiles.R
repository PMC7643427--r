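#' Insulation vectors at fixed offsets
#'
#' Aggregates a fine-binned contact map into coarse 1D interaction
#' vectors: for each coarse genomic position and each offset `o`, the
#' mean contact value over intra-chromosomal bin pairs separated by
#' exactly `o` whose genomic midpoint falls in that coarse bin.
#' Positions spanning a domain border score low at every offset because
#' pairs bridging the border are depleted.  Coarse bins at chromosome
#' edges that lack the full complement of midpoints for an offset are
#' masked (NA) rather than partially averaged.
#'
#' @param cm a `contact_matrix` (typically KR-normalized 2 kb bins).
#' @param agg_bin coarse bin size in bp (default 10000).
#' @param offsets genomic offsets in bp (default 10-100 kb in 10 kb
#'   steps, giving exactly 10 vectors).
#' @return data.frame: `chrom`, `pos` (coarse bin start), one column
#'   `o<offset>` per offset.
#' @export
insulation_vectors <- function(cm, agg_bin = 10000,
                               offsets = seq(10000, 100000, by = 10000)) {
  stopifnot(inherits(cm, "contact_matrix"))
  bs <- cm$resolution
  if (any(offsets %% bs != 0)) stop("offsets must be multiples of the bin size")
  if (agg_bin %% bs != 0) stop("agg_bin must be a multiple of the bin size")
  bins <- cm$layout$bins
  per_coarse <- agg_bin / bs
  out <- list()
  for (cn in cm$layout$chroms$chrom) {
    ids <- bins$id[bins$chrom == cn]
    clen <- cm$layout$chroms$length[cm$layout$chroms$chrom == cn]
    pos <- seq(0, clen - 1, by = agg_bin)
    block <- data.frame(chrom = cn, pos = pos, stringsAsFactors = FALSE)
    for (o in offsets) {
      k <- o / bs
      val <- rep(NA_real_, length(pos))
      if (length(ids) > k) {
        i <- ids[seq_len(length(ids) - k)]
        j <- i + k
        v <- cm$mat[cbind(i, j)]
        mid <- (bins$start[i] + bins$start[j] + bs) / 2
        cb <- floor(mid / agg_bin) + 1L
        cnt <- tapply(rep(1L, length(cb)), cb, sum)
        mn <- tapply(v, cb, mean)        # NA if any pair masked
        full <- as.integer(names(cnt))[cnt == per_coarse]
        full <- full[full <= length(pos)]
        val[full] <- mn[as.character(full)]
      }
      block[[paste0("o", o)]] <- val
    }
    out[[cn]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "agg_bin") <- agg_bin
  attr(res, "offsets") <- offsets
  res
}

#' Mean log2 interaction profile across domain borders
#'
#' For each border and each offset vector, the window of insulation
#' values within `window` bp of the border is normalized by its own
#' mean and log2-transformed; profiles are then averaged across borders
#' per offset.  A dip at position zero reflects contact insulation at
#' the borders.
#'
#' @param vectors output of [insulation_vectors()].
#' @param borders data.frame with columns `chrom`, `start` (bp; BED-style
#'   0-based positions; `end` optional and ignored beyond the midpoint).
#' @param window half-window in bp (default 1e5).
#' @return data.frame: `offset`, `rel_pos` (bp relative to border),
#'   `log2_score`, `n_borders`.
#' @export
border_profile <- function(vectors, borders, window = 1e5) {
  agg_bin <- attr(vectors, "agg_bin")
  offsets <- attr(vectors, "offsets")
  stopifnot(!is.null(agg_bin), !is.null(offsets))
  w <- as.integer(window / agg_bin)
  rel <- seq(-w, w)
  used <- 0L
  acc <- matrix(0, length(offsets), length(rel),
                dimnames = list(paste0("o", offsets), NULL))
  cnt <- matrix(0L, length(offsets), length(rel))
  for (b in seq_len(nrow(borders))) {
    cn <- borders$chrom[b]
    bpos <- if ("end" %in% names(borders))
      (borders$start[b] + borders$end[b]) / 2 else borders$start[b]
    vv <- vectors[vectors$chrom == cn, , drop = FALSE]
    if (nrow(vv) == 0L) next
    ctr <- which.min(abs(vv$pos - bpos))
    idx <- ctr + rel
    if (min(idx) < 1L || max(idx) > nrow(vv)) next
    used <- used + 1L
    for (oi in seq_along(offsets)) {
      vals <- vv[[paste0("o", offsets[oi])]][idx]
      mu <- mean(vals, na.rm = TRUE)
      if (!is.finite(mu) || mu <= 0) next
      lg <- log2(vals / mu)
      okv <- is.finite(lg)
      acc[oi, okv] <- acc[oi, okv] + lg[okv]
      cnt[oi, okv] <- cnt[oi, okv] + 1L
    }
  }
  if (used == 0L) stop("no borders fall within the insulation vectors")
  prof <- acc / pmax(cnt, 1L)
  prof[cnt == 0L] <- NA_real_
  data.frame(offset = rep(offsets, each = length(rel)),
             rel_pos = rep(rel * agg_bin, times = length(offsets)),
             log2_score = as.vector(t(prof)),
             n_borders = used)
}

#' Virtual 4C viewpoint profile
#'
#' Extracts one matrix row — the contact profile of a viewpoint bin
#' along a region — and smooths it by local polynomial regression
#' (loess, tricube weights, degree 2) with a pointwise 95% confidence
#' band from the local fit's standard errors.
#'
#' @param cm a `contact_matrix` (typically KR-normalized 1 kb bins).
#' @param chrom chromosome of the viewpoint.
#' @param viewpoint viewpoint position in bp.
#' @param region numeric `c(start, end)` in bp (default: whole
#'   chromosome).
#' @param span loess span (default 0.3).
#' @param level confidence level (default 0.95).
#' @return data.frame: `pos` (bin start), `raw`, `fit`, `lower`,
#'   `upper`.
#' @export
virtual_4c <- function(cm, chrom, viewpoint, region = NULL, span = 0.3,
                       level = 0.95) {
  stopifnot(inherits(cm, "contact_matrix"))
  bins <- cm$layout$bins
  vp <- which(bins$chrom == chrom & bins$start <= viewpoint &
                viewpoint < bins$start + cm$resolution)
  if (length(vp) != 1L) stop("viewpoint not on the bin grid")
  if (cm$mask[vp]) stop("viewpoint bin is masked")
  if (is.null(region)) {
    clen <- cm$layout$chroms$length[cm$layout$chroms$chrom == chrom]
    region <- c(0, clen)
  }
  sel <- which(bins$chrom == chrom & bins$start >= region[1] &
                 bins$start < region[2])
  prof <- data.frame(pos = bins$start[sel], raw = cm$mat[vp, sel])
  dat <- prof[is.finite(prof$raw), , drop = FALSE]
  if (nrow(dat) < 10L) stop("too few unmasked bins in region")
  lo <- stats::loess(raw ~ pos, data = dat, span = span, degree = 2,
                     family = "gaussian",
                     control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(lo, newdata = data.frame(pos = prof$pos), se = TRUE)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  prof$fit <- as.numeric(pr$fit)
  prof$lower <- prof$fit - zq * as.numeric(pr$se.fit)
  prof$upper <- prof$fit + zq * as.numeric(pr$se.fit)
  prof
}

#' Per-bin median interaction distance
#'
#' For each genomic bin, the contact-value-weighted median of the
#' genomic distances to all its unmasked intra-chromosomal partners.
#' A genome-wide shortening of these medians indicates loss of
#' long-range contacts.  Bins with zero total weight get NA.
#'
#' @param cm a `contact_matrix`.
#' @param min_separation smallest partner separation in bins
#'   (default 1).
#' @return data.frame: `chrom`, `start`, `median_distance` (bp).
#' @export
median_interaction_distance <- function(cm, min_separation = 1L) {
  stopifnot(inherits(cm, "contact_matrix"))
  bins <- cm$layout$bins
  res <- rep(NA_real_, nrow(bins))
  for (cn in cm$layout$chroms$chrom) {
    ids <- bins$id[bins$chrom == cn]
    for (i in ids) {
      j <- ids[abs(ids - i) >= min_separation]
      v <- cm$mat[i, j]
      okv <- is.finite(v) & v > 0
      if (!any(okv)) next
      d <- abs(j[okv] - i) * cm$resolution
      res[i] <- weighted_median(d, v[okv])
    }
  }
  data.frame(chrom = bins$chrom, start = bins$start, median_distance = res)
}

# weighted median: smallest x with cumulative weight >= half the total
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1]
  if (cw[i] == 0.5 && i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

#' Read a BED file of domain borders
#'
#' Three or more tab-separated columns `chrom start end`, 0-based
#' half-open.
#' @param path file path.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df[, 1:3]
}

#' @rdname read_bed
#' @param borders data.frame with `chrom`, `start`, `end`.
#' @export
write_bed <- function(borders, path) {
  utils::write.table(borders[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
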