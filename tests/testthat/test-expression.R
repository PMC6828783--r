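test_that("median-of-ratios size factors reproduce hand-computed values", {
  m <- matrix(c(2, 8, 4, 16), 2, 2,
              dimnames = list(c("h1", "h2"), c("L1", "L2")))
  sf <- size_factors(m)
  # geometric means sqrt(8) and sqrt(128); both rows give the same ratios
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
  expect_equal(unname(round(sf, 5)), c(0.70711, 1.41421))

  ident <- matrix(c(5, 9, 5, 9), 2, 2)
  expect_equal(unname(size_factors(ident)), c(1, 1))
})

test_that("size factors are scale-equivariant and row-permutation invariant", {
  set.seed(41)
  m <- matrix(rpois(60, 50) + 1, 20, 3)
  sf <- size_factors(m)
  m2 <- m
  m2[, 2] <- m2[, 2] * 3
  sf2 <- size_factors(m2)
  # factors are defined up to a common scale: scaling library 2 by 3
  # multiplies its factor by 3 relative to every other library
  expect_equal(sf2[2] / sf2[1], 3 * sf[2] / sf[1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sf2[2] / sf2[3], 3 * sf[2] / sf[3], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(size_factors(m[sample(nrow(m)), ]), sf, tolerance = 1e-12)
})

test_that("normalization inverts scaling and is a fixed point", {
  set.seed(42)
  m <- matrix(rpois(45, 80) + 1, 15, 3)
  sf <- size_factors(m)
  norm <- normalize_counts(m, sf)
  # factors of an already-normalized matrix are exactly 1
  expect_equal(unname(size_factors(norm)), rep(1, 3), tolerance = 1e-9)
  # doubling a column is undone by normalization up to the global scale
  # the geometric-mean-1 convention leaves free
  m2 <- m; m2[, 1] <- 2 * m[, 1]
  ratio <- normalize_counts(m2) / normalize_counts(m)
  expect_equal(max(ratio), min(ratio), tolerance = 1e-12)
  # all-ones factors are the identity
  expect_equal(normalize_counts(m, c(1, 1, 1)), m)
})

test_that("our size factors agree with the DESeq2 reference estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(43)
  m <- matrix(rnbinom(300, mu = 100, size = 3) + 1, 100, 3)
  ours <- unname(size_factors(m))
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(m))
  ref <- ref / exp(mean(log(ref)))     # same up-to-scale convention
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("all-zero-containing rows trigger the pseudo-count error", {
  m <- matrix(c(0, 5, 3, 0), 2, 2)
  expect_error(size_factors(m), "pseudo-count")
})

mk_classes <- function(c5, c3, lib = "L1", extra = NULL) {
  df <- data.frame(
    hairpin_id = "h", arm = c("5p", "3p"), label = "MATURE",
    seq = c("A", "B"), stringsAsFactors = FALSE)
  df[[lib]] <- c(c5, c3)
  if (!is.null(extra)) df <- rbind(df, extra)
  df
}

test_that("arm summary computes guide arm, dominance and co-expression", {
  s <- arm_summary(mk_classes(60, 40))
  expect_equal(s$guide_arm, "5p")
  expect_equal(s$guide_fraction, 60)
  expect_true(s$coexpressed)          # ratio 1.5 < 2

  s2 <- arm_summary(mk_classes(0, 100))
  expect_equal(s2$guide_arm, "3p")
  expect_equal(s2$guide_fraction, 100)
  expect_false(s2$coexpressed)

  # isomiRs count into arm totals, offset/loop reads do not
  extra <- data.frame(hairpin_id = "h", arm = c("5p", "5p", "none"),
                      label = c("ISO_3P_TEMPLATE", "MOR_5P", "LOR"),
                      seq = c("C", "D", "E"), L1 = c(15, 50, 50))
  s3 <- arm_summary(mk_classes(60, 40, extra = extra))
  expect_equal(s3$count_5p, 75)
  expect_equal(s3$count_3p, 40)

  # the printed 94.6% dominance case
  s4 <- arm_summary(mk_classes(946, 54))
  expect_equal(s4$guide_fraction, 94.6)
})

test_that("arm ties leave the guide undefined and ratio 2 is not co-expression", {
  s <- arm_summary(mk_classes(50, 50))
  expect_equal(s$guide_arm, "undefined")
  expect_true(s$coexpressed)          # ratio 1 < 2
  s2 <- arm_summary(mk_classes(100, 50))
  expect_false(s2$coexpressed)        # ratio exactly 2 is excluded
  s3 <- arm_summary(mk_classes(99, 50))
  expect_true(s3$coexpressed)
  # co-expression is symmetric in the arms
  s4 <- arm_summary(mk_classes(50, 99))
  expect_equal(s4$coexpressed, s3$coexpressed)
  s0 <- arm_summary(mk_classes(0, 0))
  expect_equal(s0$guide_arm, "undefined")
  expect_false(s0$coexpressed)
})

test_that("arm switching flags exactly the brute-force pairwise disagreements", {
  mk_sum <- function(guides) {
    data.frame(hairpin_id = "h", library = paste0("L", seq_along(guides)),
               count_5p = 0, count_3p = 0, guide_arm = guides,
               guide_fraction = NA, coexpressed = FALSE,
               stringsAsFactors = FALSE)
  }
  expect_true(detect_arm_switching(mk_sum(c("3p", "3p", "5p")))$switching)
  expect_false(detect_arm_switching(mk_sum(c("5p", "5p", "5p")))$switching)
  expect_false(detect_arm_switching(mk_sum(c("5p", "undefined", "5p")))$switching)

  set.seed(44)
  for (i in 1:30) {
    g <- sample(c("5p", "3p", "undefined"), 3, replace = TRUE)
    brute <- any(outer(g, g, function(a, b)
      a != b & a %in% c("5p", "3p") & b %in% c("5p", "3p")))
    expect_equal(detect_arm_switching(mk_sum(g))$switching, brute)
  }
})

test_that("isomiR fractions sum to 100 per hairpin and recover trivial cases", {
  cl <- mk_classes(70, 30)
  r <- isomir_ratios(cl)
  expect_equal(r$per_hairpin$fraction[r$per_hairpin$label == "MATURE"], 100)
  expect_equal(sum(r$per_hairpin$fraction), 100)

  extra <- data.frame(hairpin_id = "h", arm = "5p",
                      label = c("ISO_3P_TEMPLATE", "OTHER"),
                      seq = c("C", "D"), L1 = c(20, 10))
  r2 <- isomir_ratios(mk_classes(50, 20, extra = extra))
  ph <- r2$per_hairpin
  expect_equal(sum(ph$fraction), 100)
  expect_equal(ph$fraction[ph$label == "ISO_3P_TEMPLATE"], 20)
  expect_equal(ph$fraction[ph$label == "OTHER"], 10)
})

test_that("Pearson/average-linkage clustering matches a brute-force UPGMA oracle", {
  p <- rbind(a = c(1, 2, 3), b = c(1, 2, 3.1), c = c(3, 2, 1))
  out <- pearson_upgma(p)
  expect_lt(out$dist["a", "b"], 0.01)
  expect_gt(out$dist["a", "c"], 1.9)     # near-perfect anti-correlation
  expect_equal(out$hclust$merge[1, ], c(-1, -2))  # identical profiles first

  set.seed(45)
  for (i in 1:10) {
    m <- matrix(rnorm(15), 5, 3)
    rownames(m) <- letters[1:5]
    got <- pearson_upgma(m)
    coph_got <- as.matrix(stats::cophenetic(got$hclust))
    coph_oracle <- naive_upgma_cophenetic(got$dist)
    dimnames(coph_oracle) <- dimnames(got$dist)
    expect_equal(coph_got, coph_oracle[rownames(coph_got), colnames(coph_got)],
                 tolerance = 1e-9)
  }
})

test_that("Pearson distance is invariant to positive affine transforms", {
  set.seed(46)
  m <- matrix(rnorm(9), 3, 3)
  d1 <- pearson_upgma(m)$dist
  m2 <- m
  m2[1, ] <- 5 + 2.5 * m[1, ]
  d2 <- pearson_upgma(m2)$dist
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("constant profiles are flagged and fewer than two entities error", {
  m <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  out <- pearson_upgma(m)
  expect_equal(out$constant_rows, "a")
  expect_equal(out$dist["a", "b"], 2)
  expect_error(pearson_upgma(m[1, , drop = FALSE]), "two")
})
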