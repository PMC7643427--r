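#' Genome layout for binned contact maps
#'
#' Chromosome names, lengths and centromere positions, plus the bin
#' size, define the coordinate system of a contact matrix: bins are
#' 0-based half-open `[start, start + binsize)` intervals, numbered
#' consecutively along the genome, and each bin belongs to the left or
#' right arm of its chromosome according to which side of the centromere
#' its midpoint falls.
#'
#' @param chroms data.frame with columns `chrom`, `length`, `centromere`
#'   (bp).
#' @param binsize bin size in bp.
#' @return object of class `"genome_layout"` with a precomputed bin
#'   table (`$bins`: `chrom`, `start`, `arm`, `id`).
#' @export
genome_layout <- function(chroms, binsize) {
  stopifnot(all(c("chrom", "length", "centromere") %in% names(chroms)),
            binsize > 0)
  if (any(chroms$centromere <= 0 | chroms$centromere >= chroms$length))
    stop("centromere must lie inside its chromosome")
  if (anyDuplicated(chroms$chrom)) stop("duplicated chromosome names")
  bins <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    starts <- seq(0, chroms$length[i] - 1, by = binsize)
    mid <- starts + binsize / 2
    data.frame(chrom = chroms$chrom[i], start = starts,
               arm = ifelse(mid < chroms$centromere[i], "L", "R"),
               stringsAsFactors = FALSE)
  }))
  bins$id <- seq_len(nrow(bins))
  structure(list(chroms = chroms, binsize = binsize, bins = bins,
                 n_bins = nrow(bins)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout: %d chromosome(s), %d bins of %g bp>\n",
              nrow(x$chroms), x$n_bins, x$binsize))
  invisible(x)
}

#' Read or write a genome layout file
#'
#' Whitespace-delimited text with a header line and columns
#' `chrom length centromere`.
#' @param path file path.
#' @param binsize bin size in bp.
#' @export
read_layout <- function(path, binsize) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  genome_layout(df, binsize)
}

#' A binned, symmetric chromatin contact matrix
#'
#' Stores the dense symmetric matrix of contact values together with its
#' layout, normalization state (`raw`, `KR`, `vc_sqrt` or `zscore`) and
#' the logical mask of unusable bins.  Masked bins propagate: their rows
#' and columns are NA and they are excluded from all statistics.
#'
#' @param layout a [genome_layout()].
#' @param mat numeric symmetric matrix, `n_bins` square.
#' @param norm normalization state.
#' @param mask logical vector of masked bins (default: none).
#' @export
contact_matrix <- function(layout, mat, norm = "raw", mask = NULL) {
  stopifnot(inherits(layout, "genome_layout"),
            is.matrix(mat), nrow(mat) == layout$n_bins,
            ncol(mat) == layout$n_bins)
  if (max(abs(mat - t(mat)), na.rm = TRUE) > 1e-8 * (1 + max(abs(mat), na.rm = TRUE)))
    stop("matrix is not symmetric")
  if (is.null(mask)) mask <- rep(FALSE, layout$n_bins)
  mat[mask, ] <- NA_real_
  mat[, mask] <- NA_real_
  structure(list(layout = layout, mat = mat, norm = norm, mask = mask,
                 resolution = layout$binsize),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix: %d bins at %g bp, %s-normalized, %d masked>\n",
              x$layout$n_bins, x$resolution, x$norm, sum(x$mask)))
  invisible(x)
}

#' Read a contact matrix from triplet text
#'
#' Whitespace- or comma-delimited text with a header and columns
#' `bin1 bin2 value`, where `bin1`/`bin2` are 0-based global bin indices
#' in the layout's bin order.  Entries appearing as both (i, j) and
#' (j, i) are summed; negative values are an error.
#'
#' @param path triplet file.
#' @param layout a [genome_layout()].
#' @return a raw `contact_matrix`.
#' @export
read_contacts <- function(path, layout) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          sep = "", comment.char = "#")
  names(df)[1:3] <- c("bin1", "bin2", "value")
  if (any(df$value < 0)) stop("negative contact values")
  B <- layout$n_bins
  if (any(df$bin1 < 0 | df$bin1 >= B | df$bin2 < 0 | df$bin2 >= B))
    stop("bin index out of range for layout (", B, " bins)")
  m <- matrix(0, B, B)
  for (r in seq_len(nrow(df))) {
    i <- df$bin1[r] + 1L; j <- df$bin2[r] + 1L
    m[i, j] <- m[i, j] + df$value[r]
    if (i != j) m[j, i] <- m[j, i] + df$value[r]
  }
  contact_matrix(layout, m, norm = "raw")
}

#' @rdname read_contacts
#' @param cm a `contact_matrix`.
#' @export
write_contacts <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  idx <- which(upper.tri(cm$mat, diag = TRUE) & cm$mat != 0 &
                 !is.na(cm$mat), arr.ind = TRUE)
  df <- data.frame(bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                   value = cm$mat[idx])
  utils::write.table(df[order(df$bin1, df$bin2), ], path,
                     row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Knight-Ruiz-style matrix balancing
#'
#' Computes the symmetric balancing vector x such that
#' `diag(x) M diag(x)` has equal row sums on all unmasked bins, by the
#' symmetric fixed-point iteration `x <- x / sqrt(rowsum)` (normalized
#' each sweep).  This converges to the same balancing vector as the
#' Knight-Ruiz Newton scheme.  Bins with zero coverage are masked first.
#'
#' @param cm a raw `contact_matrix`.
#' @param tol relative row-sum tolerance (default 1e-8, comfortably
#'   inside the 1e-6 contract).
#' @param max_iter iteration cap; non-convergence is an error.
#' @return a `contact_matrix` with `norm = "KR"`; unmasked row sums
#'   equal 1.
#' @export
kr_balance <- function(cm, tol = 1e-8, max_iter = 3000L) {
  stopifnot(inherits(cm, "contact_matrix"))
  mask <- cm$mask | apply(cm$mat, 1L, function(r) all(is.na(r) | r == 0))
  keep <- which(!mask)
  if (length(keep) < 2L) stop("fewer than two unmasked bins")
  M <- cm$mat[keep, keep, drop = FALSE]
  x <- rep(1, length(keep))
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    s <- as.numeric(M %*% x) * x   # row sums of diag(x) M diag(x)
    if (any(s <= 0)) stop("balancing broke down: zero row sum")
    if (max(abs(s / mean(s) - 1)) < tol) { ok <- TRUE; break }
    x <- x / sqrt(s)
    x <- x / mean(x)
  }
  if (!ok) stop("KR balancing did not converge in ", max_iter, " iterations")
  s <- as.numeric(M %*% x) * x
  x <- x / sqrt(mean(s))           # scale row sums to 1
  out <- matrix(NA_real_, cm$layout$n_bins, cm$layout$n_bins)
  out[keep, keep] <- M * tcrossprod(x)
  res <- contact_matrix(cm$layout, out, norm = "KR", mask = mask)
  res$balancing <- replace(rep(NA_real_, cm$layout$n_bins), keep, x)
  res
}

#' Vanilla-coverage square-root normalization
#'
#' `M'[i, j] = M[i, j] / sqrt(c_i * c_j)` with `c_k` the coverage (row
#' sum) of bin k.  Zero-coverage bins are masked.
#'
#' @param cm a raw `contact_matrix`.
#' @return a `contact_matrix` with `norm = "vc_sqrt"`.
#' @export
vc_sqrt_balance <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  cov <- rowSums(cm$mat, na.rm = TRUE)
  mask <- cm$mask | cov <= 0
  m <- cm$mat / sqrt(outer(cov, cov))
  m[mask, ] <- NA_real_
  m[, mask] <- NA_real_
  contact_matrix(cm$layout, m, norm = "vc_sqrt", mask = mask)
}

#' Classify contacts as intra-arm, inter-arm or trans
#'
#' Value-weighted proportions of contacts within one chromosome arm,
#' between the two arms of one chromosome, and between different
#' chromosomes.  Each unordered bin pair counts once; arm membership is
#' decided by bin midpoint relative to the centromere.
#'
#' @param cm a `contact_matrix` (any normalization; note that balanced
#'   and raw maps weight pairs differently).
#' @return named numeric vector `c(intra_arm, inter_arm, trans)` summing
#'   to 1.
#' @export
classify_contacts <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  bins <- cm$layout$bins
  ut <- upper.tri(cm$mat, diag = TRUE)
  idx <- which(ut & !is.na(cm$mat) & cm$mat > 0, arr.ind = TRUE)
  v <- cm$mat[idx]
  same_chrom <- bins$chrom[idx[, 1]] == bins$chrom[idx[, 2]]
  same_arm <- same_chrom & bins$arm[idx[, 1]] == bins$arm[idx[, 2]]
  tot <- sum(v)
  c(intra_arm = sum(v[same_arm]) / tot,
    inter_arm = sum(v[same_chrom & !same_arm]) / tot,
    trans = sum(v[!same_chrom]) / tot)
}

#' Contact probability versus genomic distance
#'
#' Mean normalized contact value of intra-arm bin pairs as a function of
#' genomic separation, averaged within log-spaced distance bands; bands
#' without pairs are omitted.
#'
#' @param cm a `contact_matrix`.
#' @param chrom,arm restrict to one chromosome arm (default: all arms
#'   pooled).
#' @param n_bands number of log-spaced distance bands.
#' @param min_separation smallest separation in bins (default 1).
#' @return data.frame `distance` (geometric band midpoint, bp), `prob`
#'   (mean value), `n_pairs`.
#' @export
contact_decay <- function(cm, chrom = NULL, arm = NULL, n_bands = 25L,
                          min_separation = 1L) {
  stopifnot(inherits(cm, "contact_matrix"))
  bins <- cm$layout$bins
  sel <- rep(TRUE, nrow(bins))
  if (!is.null(chrom)) sel <- sel & bins$chrom == chrom
  if (!is.null(arm)) sel <- sel & bins$arm == arm
  ids <- bins$id[sel]
  pairs <- intra_arm_pairs(cm, ids, min_separation)
  if (nrow(pairs) == 0L) stop("no intra-arm pairs selected")
  d <- pairs$sep * cm$layout$binsize
  br <- exp(seq(log(min(d)), log(max(d) + 1), length.out = n_bands + 1L))
  band <- cut(d, br, include.lowest = TRUE)
  agg <- tapply(pairs$value, band, mean)
  npair <- tapply(pairs$value, band, length)
  keep <- !is.na(agg)
  mids <- sqrt(br[-1] * br[-length(br)])
  data.frame(distance = mids[keep], prob = as.numeric(agg[keep]),
             n_pairs = as.integer(npair[keep]))
}

# all unmasked intra-arm pairs among bin ids, separation >= min_sep bins
intra_arm_pairs <- function(cm, ids = NULL, min_sep = 1L) {
  bins <- cm$layout$bins
  if (is.null(ids)) ids <- bins$id
  out <- list()
  groups <- split(ids, list(bins$chrom[ids], bins$arm[ids]), drop = TRUE)
  for (g in groups) {
    g <- sort(g)
    if (length(g) <= min_sep) next
    for (k in seq.int(min_sep, length(g) - 1L)) {
      i <- g[seq_len(length(g) - k)]
      j <- g[seq_len(length(g) - k) + k]
      contig <- (j - i) == k  # global ids are consecutive within an arm
      v <- cm$mat[cbind(i, j)]
      okv <- !is.na(v) & contig
      if (any(okv))
        out[[length(out) + 1L]] <- data.frame(
          bin1 = i[okv], bin2 = j[okv], sep = k, value = v[okv])
    }
  }
  if (length(out) == 0L)
    return(data.frame(bin1 = integer(0), bin2 = integer(0),
                      sep = integer(0), value = numeric(0)))
  do.call(rbind, out)
}

#' Difference of two contact matrices
#'
#' Element-wise `a - b` on the shared mask, for difference-map displays.
#' @param a,b `contact_matrix` objects on the same layout and
#'   normalization.
#' @export
subtract_matrices <- function(a, b) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (a$layout$n_bins != b$layout$n_bins || a$resolution != b$resolution)
    stop("layouts do not match")
  if (a$norm != b$norm) stop("normalization states differ")
  mask <- a$mask | b$mask
  contact_matrix(a$layout, a$mat - b$mat, norm = paste0(a$norm, "_diff"),
                 mask = mask)
}
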