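# All classify_read calls use locus coordinates of the toy hairpin:
# arm5p = [a5s, a5e), loop, arm3p = [a3s, a3e) within a padded locus.

lab <- function(t, lstart, seq, params = classifier_params()) {
  classify_read(lstart, seq, t$locus, params)
}

test_that("the decision tree labels the canonical cases", {
  t <- toy_hairpin(10)
  lc <- t$locus
  m5 <- lslice(lc, lc$a5s, lc$a5e)

  expect_equal(lab(t, lc$a5s, m5)$label, "MATURE")
  expect_equal(lab(t, lc$a5s, m5)$arm, "5p")
  # 3' deletion -> templated; 3' templated extension -> templated
  expect_equal(lab(t, lc$a5s, substr(m5, 1, nchar(m5) - 1))$label,
               "ISO_3P_TEMPLATE")
  ext <- lslice(lc, lc$a5s, lc$a5e + 2)
  expect_equal(lab(t, lc$a5s, ext)$label, "ISO_3P_TEMPLATE")
  # 3' addition disagreeing with the genome continuation
  cont <- substr(lc$seq, lc$a5e + 1, lc$a5e + 1)
  bad <- paste0(m5, setdiff(c("A", "T", "G", "C"), cont)[1])
  expect_equal(lab(t, lc$a5s, bad)$label, "ISO_3P_NONTEMPLATE")
  # 5' shortening -> templated; untemplated 5' head -> non-templated
  expect_equal(lab(t, lc$a5s + 3, substr(m5, 4, nchar(m5)))$label,
               "ISO_5P_TEMPLATE")
  up <- substr(lc$seq, lc$a5s, lc$a5s)       # genome base before the arm
  head <- setdiff(c("A", "C", "G", "T"), up)[1]
  expect_equal(lab(t, lc$a5s - 1, paste0(head, m5))$label,
               "ISO_5P_NONTEMPLATE")
  # and a templated 5' extension
  expect_equal(lab(t, lc$a5s - 2, lslice(lc, lc$a5s - 2, lc$a5e))$label,
               "ISO_5P_TEMPLATE")
})

test_that("SNP position relative to the seed decides the SNP group", {
  t <- toy_hairpin(11)
  lc <- t$locus
  m5 <- lslice(lc, lc$a5s, lc$a5e)
  snp_at <- function(pos) {
    ch <- strsplit(m5, "")[[1]]
    ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
    paste(ch, collapse = "")
  }
  expect_equal(lab(t, lc$a5s, snp_at(2))$label, "ISO_SNP_SEED")
  expect_equal(lab(t, lc$a5s, snp_at(7))$label, "ISO_SNP_SEED")
  expect_equal(lab(t, lc$a5s, snp_at(1))$label, "ISO_SNP_NONSEED")
  expect_equal(lab(t, lc$a5s, snp_at(8))$label, "ISO_SNP_NONSEED")
  # seed definition is parameterized
  p28 <- classifier_params(seed_start = 2, seed_end = 8)
  expect_equal(lab(t, lc$a5s, snp_at(8), p28)$label, "ISO_SNP_SEED")
})

test_that("offset reads obey the adjacency tolerance on both arms", {
  t <- toy_hairpin(12)
  lc <- t$locus
  mor5 <- function(gap) lslice(lc, lc$a5s - 18 - gap, lc$a5s - gap)
  expect_equal(lab(t, lc$a5s - 18, mor5(0))$label, "MOR_5P")
  expect_equal(lab(t, lc$a5s - 20, mor5(2))$label, "MOR_5P")
  expect_equal(lab(t, lc$a5s - 21, mor5(3))$label, "OTHER")
  p0 <- classifier_params(mor_max_start_offset = 0)
  expect_equal(lab(t, lc$a5s - 18, mor5(0), p0)$label, "MOR_5P")
  expect_equal(lab(t, lc$a5s - 19, mor5(1), p0)$label, "OTHER")

  mor3 <- function(gap) lslice(lc, lc$a3e + gap, lc$a3e + gap + 18)
  expect_equal(lab(t, lc$a3e, mor3(0))$label, "MOR_3P")
  expect_equal(lab(t, lc$a3e + 2, mor3(2))$label, "MOR_3P")
  expect_equal(lab(t, lc$a3e + 3, mor3(3))$label, "OTHER")
  # partial-overlap reads that cannot be isomiRs are offset reads too
  straddle5 <- lslice(lc, lc$a5s - 9, lc$a5s + 9)
  expect_equal(lab(t, lc$a5s - 9, straddle5)$label, "MOR_5P")
  straddle3 <- lslice(lc, lc$a3e - 9, lc$a3e + 9)
  expect_equal(lab(t, lc$a3e - 9, straddle3)$label, "MOR_3P")
})

test_that("loop reads are LOR with no arm attribution", {
  t <- toy_hairpin(13, loop_len = 20)
  lc <- t$locus
  whole <- lslice(lc, lc$loop_s, lc$loop_e)
  r <- lab(t, lc$loop_s, whole)
  expect_equal(r$label, "LOR")
  expect_equal(r$arm, "none")
  # straddling one boundary without matching mature ends
  strad <- lslice(lc, lc$a5e - 5, lc$a5e - 5 + 18)
  expect_equal(lab(t, lc$a5e - 5, strad)$label, "LOR")
})

test_that("reads shifted at both ends inside an arm are OTHER unless a seed SNP", {
  t <- toy_hairpin(14)
  lc <- t$locus
  inner <- lslice(lc, lc$a5s + 1, lc$a5e - 1)
  expect_equal(lab(t, lc$a5s + 1, inner)$label, "OTHER")
  # same span but with a mismatch inside the seed region (positions 2-7
  # of the mature; locus position a5s+2 is inside it)
  ch <- strsplit(inner, "")[[1]]
  ch[2] <- setdiff(c("A", "C", "G", "T"), ch[2])[1]   # locus pos a5s+2
  expect_equal(lab(t, lc$a5s + 1, paste(ch, collapse = ""))$label,
               "ISO_SNP_SEED")
})

test_that("template decisions equal a naive character comparison oracle", {
  set.seed(99)
  for (i in 1:25) {
    t <- toy_hairpin(i + 200)
    lc <- t$locus
    m5 <- lslice(lc, lc$a5s, lc$a5e)
    k <- sample(1:3, 1)
    tail <- rand_seq(k)
    read <- paste0(m5, tail)
    genome_cont <- lslice(lc, lc$a5e, lc$a5e + k)
    want <- if (identical(tail, genome_cont)) "ISO_3P_TEMPLATE"
            else "ISO_3P_NONTEMPLATE"
    expect_equal(lab(t, lc$a5s, read)$label, want)
  }
})

test_that("classification is invariant under strand flip of the locus", {
  t <- toy_hairpin(15)
  # re-plant the same hairpin on the minus strand of the reverse genome
  g <- t$genome
  L <- nchar(g[["s1"]])
  flipped <- as_genome(c(s1 = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(g[["s1"]])))))
  h <- t$hairpins
  h2 <- h
  h2$strand <- "-"
  h2$start <- L - h$end; h2$end <- L - h$start
  h2$arm5p_start <- L - h$arm5p_end; h2$arm5p_end <- L - h$arm5p_start
  h2$arm3p_start <- L - h$arm3p_end; h2$arm3p_end <- L - h$arm3p_start
  loci2 <- hairpin_loci(hairpin_set(as.data.frame(h2)), flipped, pad = 30)
  expect_identical(loci2$seq, t$locus$seq)
  expect_equal(c(loci2$a5s, loci2$a5e, loci2$a3s, loci2$a3e),
               c(t$locus$a5s, t$locus$a5e, t$locus$a3s, t$locus$a3e))
})

test_that("classify_assignments conserves counts and applies the strict >10 rule", {
  sim <- small_sim(21)
  out <- classify_sim(sim)
  libs <- sim$config$libraries
  for (lb in libs) {
    expect_equal(sum(out$classes$classes[[lb]]),
                 sum(out$assignments[[lb]]), tolerance = 1e-9)
  }
  # per-hairpin marginals conserved
  for (lb in libs) {
    got <- tapply(out$classes$classes[[lb]], out$classes$classes$hairpin_id, sum)
    want <- tapply(out$assignments[[lb]], out$assignments$hairpin_id, sum)
    expect_equal(as.numeric(got[names(want)]), as.numeric(want),
                 tolerance = 1e-9)
  }

  # strictly-greater threshold: exactly 10 reads is not eligible
  t <- toy_hairpin(16)
  read <- lslice(t$locus, t$locus$a5s, t$locus$a5e)
  for (cnt in c(10, 11)) {
    reads <- data.frame(read_id = "r1", seq = read, lib1 = cnt)
    al <- align_reads(reads, t$genome, t$hairpins)
    asg <- resolve_multimappers(al$alignments, reads, align_params())
    cls <- classify_assignments(asg, t$loci)
    expect_identical(unname(cls$eligible["hp1", "lib1"]), cnt > 10)
  }
})

test_that("each simulated read gets exactly one label (partition property)", {
  sim <- small_sim(22)
  out <- classify_sim(sim)
  # every assignment row got a label from the vocabulary
  expect_true(all(out$classes$labels$label %in% read_classes()))
  # labels per (read, hairpin) are unique
  key <- paste(out$classes$labels$read_id, out$classes$labels$hairpin_id)
  expect_false(any(duplicated(key)))
})

test_that("the aligner-fed classifier agrees with the position-based labeller", {
  sim <- small_sim(23)
  out <- classify_sim(sim)
  truth <- sim$truth
  pred <- out$classes$labels
  m <- merge(truth[c("seq", "label", "arm")], pred[c("seq", "label", "arm")],
             by = "seq", suffixes = c(".truth", ".pred"))
  expect_equal(m$label.pred, m$label.truth)
  expect_equal(m$arm.pred, m$arm.truth)
})

test_that("a hairpin without arms or an out-of-span read raises an error", {
  t <- toy_hairpin(17)
  lc <- t$locus
  lc$a5s <- NA_integer_; lc$a3s <- NA_integer_
  expect_error(classify_read(0, "ACGTACGTACGTACGTA", lc), "mature arm")
  expect_error(classify_read(-1, "ACGTACGTACGTACGTA", t$locus), "outside")
})
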