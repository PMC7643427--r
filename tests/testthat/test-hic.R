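make_iset <- function(layout, bin1, bin2) {
  bins <- layout$bins
  structure(data.frame(bin1 = bin1, bin2 = bin2,
                       chrom = bins$chrom[bin1],
                       start1 = bins$start[bin1],
                       start2 = bins$start[bin2],
                       distance = (bin2 - bin1) * layout$binsize,
                       z = NA_real_, condition = NA_character_,
                       stringsAsFactors = FALSE),
            class = c("interaction_set", "data.frame"),
            resolution = layout$binsize, layout = layout)
}

test_that("layouts assign bins to arms and validate centromeres", {
  lay <- toy_layout(arm_bins = 5L)
  expect_equal(lay$n_bins, 10L)
  expect_equal(lay$bins$arm, rep(c("L", "R"), each = 5))
  expect_error(genome_layout(data.frame(chrom = "c", length = 100,
                                        centromere = 200), 10),
               "inside its chromosome")
})

test_that("triplet files read symmetrically, summing duplicates", {
  lay <- toy_layout(arm_bins = 5L)
  f <- write_triplets(data.frame(bin1 = c(0, 1, 2), bin2 = c(2, 3, 0),
                                 value = c(5, 7, 3)))
  cm <- read_contacts(f, lay)
  expect_equal(cm$mat[1, 3], 8)  # (0,2) and (2,0) summed
  expect_equal(cm$mat[3, 1], 8)
  expect_equal(cm$mat[2, 4], 7)
  expect_equal(sum(cm$mat), 2 * (8 + 7))

  expect_error(read_contacts(write_triplets(
    data.frame(bin1 = 0, bin2 = 99, value = 1)), lay), "out of range")
  expect_error(read_contacts(write_triplets(
    data.frame(bin1 = 0, bin2 = 1, value = -2)), lay), "negative")
})

test_that("KR balancing equalizes row sums and matches a Sinkhorn oracle", {
  lay2 <- genome_layout(data.frame(chrom = "c", length = 2e4,
                                   centromere = 1e4), 1e4)
  M <- matrix(c(2, 1, 1, 2), 2, 2)
  bal <- kr_balance(contact_matrix(lay2, M))
  rs <- rowSums(bal$mat)
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-6)

  # brute-force alternating row/column scaling
  S <- M
  for (it in 1:500) {
    S <- S / rowSums(S)
    S <- t(t(S) / colSums(S))
  }
  S <- S / rowSums(S)[1]
  expect_equal(bal$mat / sum(bal$mat), S / sum(S), tolerance = 1e-5)

  # a bigger random map: row sums equal, and balancing is idempotent
  set.seed(4)
  lay <- toy_layout(arm_bins = 20L)
  R <- matrix(rpois(40 * 40, 20), 40, 40)
  R <- R + t(R)
  cm <- contact_matrix(lay, R)
  b1 <- kr_balance(cm)
  rs <- rowSums(b1$mat, na.rm = TRUE)
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-6)
  b2 <- kr_balance(contact_matrix(lay, b1$mat, mask = b1$mask))
  ratio <- b2$mat / b1$mat
  expect_lt(diff(range(ratio, na.rm = TRUE)), 1e-6)
  expect_equal(b1$norm, "KR")
})

test_that("vc_sqrt divides by the coverage geometric mean", {
  lay3 <- genome_layout(data.frame(chrom = "c", length = 3e4,
                                   centromere = 1.5e4), 1e4)
  M <- matrix(c(4, 2, 0,
                2, 1, 1,
                0, 1, 9), 3, 3, byrow = TRUE)
  vc <- vc_sqrt_balance(contact_matrix(lay3, M))
  cov <- c(6, 4, 10)
  expect_equal(vc$mat, M / sqrt(outer(cov, cov)))
  expect_equal(vc$norm, "vc_sqrt")

  # uniform in, uniform out; global count scaling cancels to a constant
  lay <- toy_layout(arm_bins = 10L)
  u <- vc_sqrt_balance(uniform_matrix(lay, 5))
  expect_equal(diff(range(u$mat)), 0)
  # global count scaling cancels: coverage scales with the counts
  a <- vc_sqrt_balance(contact_matrix(lay3, M))
  b <- vc_sqrt_balance(contact_matrix(lay3, 4 * M))
  expect_equal(b$mat, a$mat, tolerance = 1e-12)

  # zero-coverage bins become masked
  M0 <- M; M0[3, ] <- 0; M0[, 3] <- 0
  v0 <- vc_sqrt_balance(contact_matrix(lay3, M0))
  expect_true(v0$mask[3])
  expect_true(all(is.na(v0$mat[3, ])))
})

test_that("contact classification matches hand-placed counts", {
  # chrA: bins 1-2 (arm L), 3-4 (arm R); chrB: bins 5 (L), 6 (R)
  lay <- genome_layout(data.frame(chrom = c("chrA", "chrB"),
                                  length = c(4e4, 2e4),
                                  centromere = c(2e4, 1e4)), 1e4)
  m <- matrix(0, 6, 6)
  m[1, 2] <- m[2, 1] <- 4   # intra-arm
  m[1, 3] <- m[3, 1] <- 2   # inter-arm
  m[1, 5] <- m[5, 1] <- 3   # trans
  m[6, 6] <- 1              # intra-arm (self pair)
  pr <- classify_contacts(contact_matrix(lay, m))
  expect_equal(unname(pr), c(0.5, 0.2, 0.3))
  expect_equal(sum(pr), 1)

  # invariance under global scaling
  pr4 <- classify_contacts(contact_matrix(lay, 4 * m))
  expect_equal(pr, pr4)

  one_arm <- matrix(0, 6, 6); one_arm[1, 2] <- one_arm[2, 1] <- 7
  expect_equal(unname(classify_contacts(
    contact_matrix(lay, one_arm))["intra_arm"]), 1)
})

test_that("distance decay recovers the generator's exponent", {
  lay <- toy_layout(arm_bins = 100L)
  rec <- map_recipe(layout = lay, depth = 500, gamma = -1, seed = 2)
  cm <- generate_contact_map(rec)
  dc <- contact_decay(cm, n_bands = 20L)
  fitln <- lm(log(prob) ~ log(distance), data = dc)
  expect_lt(abs(coef(fitln)[2] - (-1)), 0.05)
  expect_equal(nrow(dc), sum(!is.na(dc$prob)))

  # contacts at a single separation: one band carries all the signal
  m <- matrix(0, lay$n_bins, lay$n_bins)
  for (i in 1:20) m[i, i + 5] <- m[i + 5, i] <- 3
  dc1 <- contact_decay(contact_matrix(lay, m), n_bands = 99L)
  expect_equal(sum(dc1$prob > 0), 1L)
  # 20 pairs of value 3 among the 190 sep-5 pairs of the two arms
  expect_equal(max(dc1$prob), 20 * 3 / 190)
})
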