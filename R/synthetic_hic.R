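#' Recipe for synthetic contact maps
#'
#' Expected contact counts follow a power-law distance decay,
#' `mu[i, j] = depth * |i - j|^gamma` (separation in bins) for
#' intra-chromosomal pairs and a flat `depth * trans_level` for
#' trans pairs, multiplied by block-domain enrichments for pairs with
#' both ends inside a domain and by fold enrichments at planted loop
#' pairs.  Observed counts are Poisson draws, symmetrized.
#'
#' @param layout a [genome_layout()]; default: one 2 Mb chromosome with
#'   a centromere at 1 Mb, 10 kb bins.
#' @param depth count scale at one-bin separation.
#' @param gamma decay exponent (must be negative; default -1).
#' @param trans_level relative level of trans contacts (default 0.01).
#' @param blocks optional data.frame `chrom`, `start`, `end`,
#'   `enrichment` (bp intervals; pairs wholly inside get multiplied).
#' @param loops optional data.frame `bin1`, `bin2` (1-based global bin
#'   ids, bin1 < bin2) and `fold` (> 1).
#' @param seed integer seed.
#' @return list of class `"map_recipe"`.
#' @export
map_recipe <- function(layout = NULL, depth = 200, gamma = -1,
                       trans_level = 0.01, blocks = NULL, loops = NULL,
                       seed = 1L) {
  if (is.null(layout))
    layout <- genome_layout(data.frame(chrom = "chrI", length = 2e6,
                                       centromere = 1e6), binsize = 1e4)
  if (gamma >= 0) stop("decay exponent gamma must be negative")
  if (!is.null(loops)) {
    stopifnot(all(c("bin1", "bin2", "fold") %in% names(loops)))
    if (any(loops$fold <= 1)) stop("loop fold enrichment must exceed 1")
    if (any(loops$bin1 >= loops$bin2)) stop("loops need bin1 < bin2")
  }
  structure(list(layout = layout, depth = depth, gamma = gamma,
                 trans_level = trans_level, blocks = blocks,
                 loops = loops, seed = as.integer(seed)),
            class = "map_recipe")
}

expected_map <- function(recipe) {
  lay <- recipe$layout
  bins <- lay$bins
  B <- lay$n_bins
  mu <- matrix(recipe$depth * recipe$trans_level, B, B)
  for (cn in lay$chroms$chrom) {
    ids <- bins$id[bins$chrom == cn]
    sep <- abs(outer(ids, ids, "-"))
    dec <- recipe$depth * pmax(sep, 1)^recipe$gamma
    mu[ids, ids] <- dec
  }
  if (!is.null(recipe$blocks)) {
    for (b in seq_len(nrow(recipe$blocks))) {
      blk <- recipe$blocks[b, ]
      ids <- bins$id[bins$chrom == blk$chrom & bins$start >= blk$start &
                       bins$start + lay$binsize <= blk$end]
      mu[ids, ids] <- mu[ids, ids] * blk$enrichment
    }
  }
  if (!is.null(recipe$loops)) {
    for (l in seq_len(nrow(recipe$loops))) {
      i <- recipe$loops$bin1[l]; j <- recipe$loops$bin2[l]
      mu[i, j] <- mu[i, j] * recipe$loops$fold[l]
      mu[j, i] <- mu[i, j]
    }
  }
  mu
}

#' Generate a synthetic contact map with known ground truth
#'
#' @param recipe a [map_recipe()].
#' @return a raw [contact_matrix()] with attributes `truth_loops`
#'   (data.frame of planted loop pairs) and `truth_borders`
#'   (data.frame of block boundaries, BED-style).
#' @export
generate_contact_map <- function(recipe) {
  stopifnot(inherits(recipe, "map_recipe"))
  set.seed(recipe$seed)
  mu <- expected_map(recipe)
  B <- nrow(mu)
  ut <- upper.tri(mu, diag = TRUE)
  counts <- matrix(0, B, B)
  counts[ut] <- stats::rpois(sum(ut), mu[ut])
  counts <- counts + t(counts) - diag(diag(counts))
  cmat <- contact_matrix(recipe$layout, counts, norm = "raw")
  attr(cmat, "truth_loops") <- recipe$loops
  if (!is.null(recipe$blocks)) {
    brd <- unique(data.frame(chrom = rep(recipe$blocks$chrom, 2),
                             start = c(recipe$blocks$start,
                                       recipe$blocks$end)))
    brd$end <- brd$start + recipe$layout$binsize
    attr(cmat, "truth_borders") <- brd[order(brd$chrom, brd$start), ]
  }
  cmat
}

#' Sample random intra-arm loop positions
#'
#' Distinct intra-arm bin pairs with separations in `[min_sep, max_sep]`
#' bins, avoiding pairs in `exclude`.
#'
#' @param layout a `genome_layout`.
#' @param n number of pairs.
#' @param min_sep,max_sep separation range in bins.
#' @param exclude optional data.frame with `bin1`, `bin2` to avoid.
#' @return data.frame `bin1`, `bin2`.
#' @export
sample_loop_pairs <- function(layout, n, min_sep = 4L, max_sep = 40L,
                              exclude = NULL) {
  bins <- layout$bins
  cand <- list()
  for (g in split(bins$id, list(bins$chrom, bins$arm), drop = TRUE)) {
    g <- sort(g)
    for (k in seq.int(min_sep, min(max_sep, length(g) - 1L))) {
      i <- g[seq_len(length(g) - k)]
      cand[[length(cand) + 1L]] <- data.frame(bin1 = i, bin2 = i + k)
    }
  }
  cand <- do.call(rbind, cand)
  if (!is.null(exclude))
    cand <- cand[!paste(cand$bin1, cand$bin2) %in%
                   paste(exclude$bin1, exclude$bin2), , drop = FALSE]
  if (nrow(cand) < n) stop("not enough eligible pairs")
  cand[sample.int(nrow(cand), n), , drop = FALSE]
}

#' Generate a pair of condition maps with shared and specific loops
#'
#' Two contact maps built on one decay/domain background, sharing
#' `shared` planted loops, with `a_only` loops present only in map A
#' and `b_only` only in map B.  Counts may be given (pairs are then
#' sampled under the recipe seed) or explicit `bin1`/`bin2`
#' data.frames; pair lists must be disjoint.
#'
#' @param shared,a_only,b_only integer counts or data.frames of loop
#'   pairs.
#' @param recipe a [map_recipe()] supplying the background (its own
#'   `loops` must be NULL).
#' @param fold fold enrichment for every planted loop (default 10).
#' @return list `a`, `b` (contact matrices) and `truth` (list of the
#'   three pair data.frames).
#' @export
generate_condition_pair <- function(shared, a_only, b_only, recipe,
                                    fold = 10) {
  stopifnot(inherits(recipe, "map_recipe"), is.null(recipe$loops))
  set.seed(recipe$seed)
  lay <- recipe$layout
  as_pairs <- function(x, exclude) {
    if (is.data.frame(x)) x[, c("bin1", "bin2"), drop = FALSE]
    else if (x > 0) sample_loop_pairs(lay, x, exclude = exclude)
    else data.frame(bin1 = integer(0), bin2 = integer(0))
  }
  sh <- as_pairs(shared, NULL)
  ao <- as_pairs(a_only, sh)
  bo <- as_pairs(b_only, rbind(sh, ao))
  keys <- c(paste(sh$bin1, sh$bin2), paste(ao$bin1, ao$bin2),
            paste(bo$bin1, bo$bin2))
  if (anyDuplicated(keys)) stop("shared and specific loop lists overlap")
  with_fold <- function(p) if (nrow(p)) cbind(p, fold = fold) else NULL
  ra <- recipe; ra$loops <- with_fold(rbind(sh, ao)); ra$seed <- recipe$seed + 1L
  rb <- recipe; rb$loops <- with_fold(rbind(sh, bo)); rb$seed <- recipe$seed + 2L
  list(a = generate_contact_map(ra), b = generate_contact_map(rb),
       truth = list(shared = sh, a_only = ao, b_only = bo))
}
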