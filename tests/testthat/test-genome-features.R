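mk_loci <- function(starts, ends, scaffold = "s1") {
  n <- length(starts)
  hairpin_set(data.frame(
    hairpin_id = sprintf("hp%02d", seq_len(n)), scaffold = scaffold,
    strand = "+", start = as.integer(starts), end = as.integer(ends),
    arm5p_start = as.integer(starts), arm5p_end = as.integer(starts + 20),
    arm3p_start = as.integer(ends - 20), arm3p_end = as.integer(ends),
    stringsAsFactors = FALSE))
}

test_that("hairpins within the gap cluster, distant ones do not", {
  h <- mk_loci(c(0, 5100), c(100, 5200))       # 5-kb gap
  cl <- find_clusters(h)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 2L)
  expect_equal(cl$members, "hp01,hp02")

  h2 <- mk_loci(c(0, 15100), c(100, 15200))    # 15-kb gap
  expect_equal(nrow(find_clusters(h2)), 0L)

  # chaining: 0, 9 kb, 18 kb -> one cluster of three
  h3 <- mk_loci(c(0, 9000, 18000), c(100, 9100, 18100))
  cl3 <- find_clusters(h3)
  expect_equal(cl3$n_members, 3L)
})

test_that("cluster chaining equals the transitive-closure oracle and ignores order", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    starts <- sort(sample(0:60000, n))
    ends <- starts + sample(60:120, n, replace = TRUE)
    h <- mk_loci(starts, ends)
    cl <- find_clusters(h)
    comp <- naive_interval_components(starts, ends, 10000)
    big <- unname(table(comp)[table(comp) >= 2])
    expect_equal(sort(cl$n_members), as.integer(sort(big)))
    # membership agrees, not just sizes
    for (k in seq_len(nrow(cl))) {
      ids <- strsplit(cl$members[k], ",")[[1]]
      idx <- match(ids, h$hairpin_id)
      expect_equal(length(unique(comp[idx])), 1L)
    }
    # shuffled input gives identical output
    h_shuf <- h[sample(nrow(h)), ]
    expect_equal(find_clusters(hairpin_set(as.data.frame(h_shuf))), cl)
  }
})

test_that("clusters export as BED intervals", {
  h <- mk_loci(c(0, 5100), c(100, 5200))
  cl <- find_clusters(h)
  f <- withr::local_tempfile(fileext = ".bed")
  write_clusters_bed(cl, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(bed$V2, 0L)
  expect_equal(bed$V3, 5200L)
})

test_that("the surrogate folder scores a perfect GC stem as designed", {
  # 10-bp GC stem + 4-nt loop, padded to the length floor with unpairable
  # terminal A runs
  stem <- "GGGGGGGGGG"
  hp <- paste0(strrep("A", 15), stem, "TTTT",
               chartr("GC", "CG", paste(rev(strsplit(stem, "")[[1]]),
                                        collapse = "")),
               strrep("A", 15))
  out <- fold_hairpin(hp)
  expect_equal(out$dg, -30)
  expect_equal(sum(!is.na(out$partner)), 20L)

  # homopolymers have no stem
  none <- fold_hairpin(strrep("A", 60))
  expect_equal(none$dg, 0)
  expect_equal(none$structure, strrep(".", 60))

  # reverse complement leaves the energy unchanged
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(hp)))
  expect_equal(fold_hairpin(rc)$dg, out$dg)
})

test_that("fold_hairpin enforces length bounds and pairs AU/GU as configured", {
  expect_error(fold_hairpin("ACGT"), "40-400")
  expect_error(fold_hairpin(strrep("ACGT", 200)), "40-400")
  # an AT stem scores -2 per pair
  hp <- paste0(strrep("C", 15), strrep("A", 8), "TTTT", strrep("T", 8),
               strrep("C", 15))
  expect_equal(fold_hairpin(hp)$dg, -16)
})

test_that("the RNAfold backend returns a stable thermodynamic fold", {
  set.seed(52)
  arm <- rand_seq(25)
  hp <- paste0(arm, "TTCGTT",
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(arm))))
  out <- fold_hairpin(hp, backend = "rnafold")
  expect_lt(out$dg, -20)
  expect_match(out$structure, "^[.()]+$")
  expect_equal(nchar(out$structure), nchar(hp))
})

mk_stack <- function(locus_len, a5, a3, n5 = 50, n3 = 40, extra = NULL) {
  st <- data.frame(
    lstart = c(a5[1], a3[1]), lend = c(a5[2], a3[2]), count = c(n5, n3))
  if (!is.null(extra)) st <- rbind(st, extra)
  st
}

planted_candidate <- function(seed = 53, m = 22) {
  set.seed(seed)
  X <- rand_seq(m + 2)
  loop <- rand_seq(12)
  hp <- paste0(strrep("A", 10), X, loop,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(X))), strrep("A", 10))
  a5 <- c(10, 10 + m)
  a3 <- c(10 + m + 2 + 12, 10 + m + 2 + 12 + m)
  list(seq = hp, a5 = a5, a3 = a3)
}

test_that("a well-supported stem-loop passes the novel-candidate criteria", {
  pc <- planted_candidate()
  stack <- mk_stack(nchar(pc$seq), pc$a5, pc$a3)
  ev <- evaluate_novel_candidate(stack, pc$seq)
  expect_lt(ev$dg, -20)
  expect_true(ev$fold_pass)
  expect_true(ev$reads_pass)
  expect_true(ev$both_arms)
  expect_equal(ev$overhang, 2L)
  expect_true(ev$overhang_pass)
  expect_true(ev$homogeneity_pass)
  expect_equal(ev$verdict, "PASS")
})

test_that("one-arm candidates are PROVISIONAL and weak folds FAIL", {
  pc <- planted_candidate(54)
  one_arm <- data.frame(lstart = pc$a5[1], lend = pc$a5[2], count = 60)
  ev <- evaluate_novel_candidate(one_arm, pc$seq)
  expect_false(ev$both_arms)
  expect_equal(ev$verdict, "PROVISIONAL")
  ev2 <- evaluate_novel_candidate(one_arm, pc$seq,
                                  novel_params(require_both_arms = TRUE))
  expect_equal(ev2$verdict, "FAIL")

  # weak fold: same stack on an unstructured locus
  set.seed(55)
  flat <- paste0(strrep("A", 40), strrep("C", 40))
  evw <- evaluate_novel_candidate(mk_stack(80, c(5, 25), c(55, 75)), flat,
                                  novel_params())
  expect_false(evw$fold_pass)
  expect_equal(evw$verdict, "FAIL")

  # empty stack fails on reads
  eve <- evaluate_novel_candidate(data.frame(lstart = integer(0),
                                             lend = integer(0),
                                             count = numeric(0)), pc$seq)
  expect_false(eve$reads_pass)
  expect_equal(eve$verdict, "FAIL")
})

test_that("relaxing thresholds never turns PASS into FAIL (monotonicity)", {
  pc <- planted_candidate(56)
  # ragged stack: some reads shift the 5' ends
  extra <- data.frame(lstart = pc$a5[1] + 2, lend = pc$a5[2] + 2, count = 4)
  stack <- mk_stack(nchar(pc$seq), pc$a5, pc$a3, extra = extra)
  strict <- novel_params()
  relaxed <- novel_params(dg_threshold = -10, min_reads = 1,
                          overhang_tol = 3, five_prime_homogeneity_min = 0.5)
  v1 <- evaluate_novel_candidate(stack, pc$seq, strict)$verdict
  v2 <- evaluate_novel_candidate(stack, pc$seq, relaxed)$verdict
  rank <- c(FAIL = 0, PROVISIONAL = 1, PASS = 2)
  expect_gte(rank[v2], rank[v1])
})
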