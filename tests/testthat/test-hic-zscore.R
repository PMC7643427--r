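test_that("band z-scores standardize each separation band", {
  set.seed(9)
  lay <- toy_layout(arm_bins = 40L, binsize = 2000)
  m <- matrix(rpois(80 * 80, 30), 80, 80)
  m <- m + t(m)
  cm <- contact_matrix(lay, m)
  zm <- zscore_map(cm, min_separation = 2L, min_band_pairs = 15L)

  # within every retained band: mean 0, sd 1; shorter separations masked
  bins <- lay$bins
  expect_true(all(is.na(diag(zm$z))))
  expect_true(all(is.na(zm$z[cbind(1:79, 2:80)])))
  for (arm in c("L", "R")) {
    ids <- bins$id[bins$arm == arm]
    for (k in c(2L, 5L, 20L)) {
      i <- ids[seq_len(length(ids) - k)]
      zv <- zm$z[cbind(i, i + k)]
      if (all(is.na(zv))) next
      v <- cm$mat[cbind(i, i + k)]
      expect_equal(mean(zv), 0, tolerance = 1e-9)
      expect_equal(sd(zv), 1, tolerance = 1e-9)
      # hand-computed (x - mu) / sigma for the band
      expect_equal(zv, (v - mean(v)) / sd(v))
    }
    # band at separation length(ids) - 1 has a single pair -> masked
    expect_true(is.na(zm$z[ids[1], ids[length(ids)]]))
  }
})

test_that("bands with fewer than 15 pairs are masked entirely", {
  set.seed(2)
  # left arm 10 bins (at most 8 pairs per band), right arm 30 bins
  lay <- genome_layout(data.frame(chrom = "c", length = 40 * 2000,
                                  centromere = 10 * 2000), 2000)
  m <- matrix(rpois(40 * 40, 25), 40, 40)
  m <- m + t(m)
  zm <- zscore_map(contact_matrix(lay, m))
  left <- lay$bins$id[lay$bins$arm == "L"]
  expect_true(all(is.na(zm$z[left, left])))
  right <- lay$bins$id[lay$bins$arm == "R"]
  expect_false(all(is.na(zm$z[right, right])))
  # a 16-pair band on the right arm (separation 14) is retained
  i <- right[seq_len(16)]
  expect_false(anyNA(zm$z[cbind(i, i + 14L)]))
})

test_that("constant bands give z = 0 and zero-spread bands warn", {
  lay <- toy_layout(arm_bins = 30L, binsize = 2000)
  m <- matrix(0, 60, 60)
  for (k in 2:5) {
    ids <- lay$bins$id[lay$bins$arm == "L"]
    i <- ids[seq_len(length(ids) - k)]
    m[cbind(i, i + k)] <- 7   # constant within each band
    m[cbind(i + k, i)] <- 7
  }
  m[1, 4] <- m[4, 1] <- 9     # one band gets spread
  expect_warning(zm <- zscore_map(contact_matrix(lay, m)), "zero spread")
  ids <- lay$bins$id[lay$bins$arm == "L"]
  i2 <- ids[seq_len(length(ids) - 2)]
  expect_true(all(is.na(zm$z[cbind(i2, i2 + 2)])))  # constant -> masked
  i3 <- ids[seq_len(length(ids) - 3)]
  zb <- zm$z[cbind(i3, i3 + 3)]
  v <- m[cbind(i3, i3 + 3)]
  expect_equal(zb, (v - mean(v)) / sd(v))           # the spread band scores
})

test_that("interaction calling is strict and empty maps give empty sets", {
  lay <- toy_layout(arm_bins = 30L, binsize = 2000)
  set.seed(5)
  m <- matrix(rpois(60 * 60, 30), 60, 60); m <- m + t(m)
  zm <- zscore_map(contact_matrix(lay, m))
  # force a band to known z values: pick entries and check the boundary
  calls <- call_interactions(zm, threshold = 2)
  expect_true(all(calls$z > 2))
  expect_false(any(abs(calls$z - 2) < 1e-12))
  at2 <- which(abs(zm$z - 2) < 1e-12, arr.ind = TRUE)
  if (nrow(at2)) expect_false(any(paste(at2[, 1], at2[, 2]) %in%
                                    paste(calls$bin1, calls$bin2)))
  # threshold above every z -> empty set
  none <- call_interactions(zm, threshold = max(zm$z, na.rm = TRUE) + 1)
  expect_equal(nrow(none), 0L)
})

test_that("planted loops are recovered with few false positives", {
  lay <- toy_layout(arm_bins = 100L)
  set.seed(3)
  loops <- sample_loop_pairs(lay, 20L, min_sep = 4L, max_sep = 40L)
  rec <- map_recipe(layout = lay, depth = 500, gamma = -1,
                    loops = cbind(loops, fold = 10), seed = 8)
  cm <- generate_contact_map(rec)
  zm <- zscore_map(vc_sqrt_balance(cm))
  calls <- call_interactions(zm)
  keys <- paste(calls$bin1, calls$bin2)
  truth <- paste(loops$bin1, loops$bin2)
  recall <- mean(truth %in% keys)
  expect_gte(recall, 0.95)
  n_scored <- sum(!is.na(zm$z[upper.tri(zm$z)]))
  fp <- sum(!keys %in% truth)
  # Gaussian z > 2 tail is ~2.3%; Poisson maps run close to it
  expect_lt(fp / n_scored, 2.5 * pnorm(2, lower.tail = FALSE))
})

test_that("condition comparison partitions exactly by bin pair", {
  lay <- toy_layout(arm_bins = 30L, binsize = 2000)
  set.seed(6)
  m <- matrix(rpois(60 * 60, 30), 60, 60); m <- m + t(m)
  zm <- zscore_map(contact_matrix(lay, m))
  calls <- call_interactions(zm)
  same <- compare_sets(calls, calls)
  expect_equal(unname(same$counts),
               c(nrow(calls), 0L, 0L))
  # disjoint sets share nothing
  half1 <- calls[seq_len(floor(nrow(calls) / 2)), ]
  half2 <- calls[-seq_len(floor(nrow(calls) / 2)), ]
  attr(half1, "resolution") <- attr(calls, "resolution")
  attr(half2, "resolution") <- attr(calls, "resolution")
  class(half1) <- class(half2) <- class(calls)
  cmp <- compare_sets(half1, half2)
  expect_equal(unname(cmp$counts["common"]), 0L)
  expect_error(compare_sets(calls, structure(calls, resolution = 999)),
               "resolution")
})

test_that("shared and specific planted loops are recovered as a partition", {
  pairs <- generate_condition_pair(50L, 10L, 5L,
                                   map_recipe(layout = toy_layout(100L),
                                              depth = 500, seed = 21))
  call_map <- function(cm) call_interactions(zscore_map(vc_sqrt_balance(cm)))
  cmp <- compare_sets(call_map(pairs$a), call_map(pairs$b))
  truth <- pairs$truth
  key <- function(p) paste(p$bin1, p$bin2)
  expect_gte(sum(key(truth$shared) %in% key(cmp$common)), 48)
  expect_gte(sum(key(truth$a_only) %in% key(rbind(cmp$a_specific,
                                                  cmp$common))), 9)
  expect_gte(sum(key(truth$b_only) %in% key(rbind(cmp$b_specific,
                                                  cmp$common))), 4)

  none <- generate_condition_pair(0L, 0L, 0L,
                                  map_recipe(layout = toy_layout(50L),
                                             depth = 300, seed = 4))
  expect_null(attr(none$a, "truth_loops"))
  sh <- data.frame(bin1 = c(5L, 8L), bin2 = c(15L, 20L))
  expect_error(generate_condition_pair(sh, sh[1, ], 0L,
                                       map_recipe(layout = toy_layout(50L),
                                                  seed = 1)),
               "overlap")
})

test_that("aggregate windows normalize to one on flat maps and enrich at
          planted loops", {
  lay <- toy_layout(arm_bins = 100L, binsize = 2000)
  flat <- uniform_matrix(lay, 5)
  iset <- structure(data.frame(bin1 = 40L, bin2 = 60L, chrom = "chrI",
                               start1 = lay$bins$start[40],
                               start2 = lay$bins$start[60],
                               distance = 20 * 2000, z = 3,
                               condition = NA_character_),
                    class = c("interaction_set", "data.frame"),
                    resolution = 2000, layout = lay)
  agg <- aggregate_matrix(flat, iset, half_window = 8000)
  expect_equal(dim(agg$profile), c(9L, 9L))
  expect_true(all(abs(agg$profile - 1) < 1e-12))

  # windows truncated by the arm edge are dropped
  edge <- iset; edge$bin1 <- 2L; edge$bin2 <- 22L
  expect_error(aggregate_matrix(flat, edge), "no interaction window")

  loops <- data.frame(bin1 = c(30L, 50L), bin2 = c(50L, 75L))
  rec <- map_recipe(layout = lay, depth = 800, gamma = -1,
                    loops = cbind(loops, fold = 8), seed = 13)
  cm <- generate_contact_map(rec)
  kr <- kr_balance(cm)
  iset2 <- structure(data.frame(bin1 = loops$bin1, bin2 = loops$bin2,
                                chrom = "chrI",
                                start1 = lay$bins$start[loops$bin1],
                                start2 = lay$bins$start[loops$bin2],
                                distance = (loops$bin2 - loops$bin1) * 2000,
                                z = NA_real_, condition = NA_character_),
                     class = c("interaction_set", "data.frame"),
                     resolution = 2000, layout = lay)
  agg2 <- aggregate_matrix(kr, iset2)
  ctr <- agg2$profile[5, 5]
  border <- c(agg2$profile[1, ], agg2$profile[9, ],
              agg2$profile[, 1], agg2$profile[, 9])
  expect_gt(ctr, mean(border))
})
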