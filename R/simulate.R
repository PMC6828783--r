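# Synthetic miRNAome generator.  Plants stem-loop hairpins (near-perfect
# reverse-complementary stems with the canonical 2-nt 3' duplex
# overhangs) in a random toy genome and draws three stage-labelled read
# libraries from a configurable mixture over the eleven read classes,
# with per-sequence ground truth for recovery scoring.
#
# Ground-truth labels are derived from the generation coordinates by a
# direct character-comparison labeller that shares no code with the
# aligner/classifier path, so recovery tests exercise the full pipeline
# against an independent oracle.  Reads carrying a sequencing error are
# re-labelled to the class their final sequence represents: a substituted
# base is indistinguishable from a SNP isomiR, so the truth describes the
# emitted sequence, not the pre-error template.

#' Simulation configuration
#'
#' Defaults emulate a three-library (juvenile/subadult/adult) small-RNA
#' study design: 17-30-nt reads over planted hairpins, a class mixture
#' dominated by mature reads with 3' template variants as the most
#' common isomiR, 3' non-template A/U tails, seed/non-seed SNP variants,
#' rare 5' variants, and low levels of offset/loop reads; per-hairpin,
#' per-library negative-binomial counts with a per-hairpin arm bias.
#'
#' @param n_scaffolds,scaffold_len Toy genome dimensions.
#' @param n_hairpins Number of planted hairpins (spread over scaffolds).
#' @param mature_len Range of mature-arm lengths in nt.
#' @param loop_len Range of terminal-loop lengths in nt.
#' @param class_mixture Named probability vector over [read_classes()]
#'   (renormalized; must cover only known labels).
#' @param deletion_len Range of template-variant deletion lengths.
#' @param addition_len Range of template-variant addition lengths.
#' @param template_add_prob Probability a template variant is an addition
#'   rather than a deletion.
#' @param tail_len Range of non-template tail/head lengths (bases drawn
#'   from A/U and guaranteed to mismatch the genome continuation).
#' @param count_mean,count_dispersion Negative-binomial mean and size for
#'   per-hairpin, per-library read totals.
#' @param arm_bias Either `NULL` (drawn per hairpin from
#'   `arm_bias_range`) or a numeric vector/matrix of 5p fractions
#'   (hairpins x libraries for arm-switching scenarios).
#' @param arm_bias_range Range the per-hairpin 5p fraction is drawn from.
#' @param libraries Library (life-stage) names.
#' @param error_rate Per-base uniform substitution probability applied to
#'   every read copy (default 0).
#' @param pad Flank width used when extracting loci (matches the aligner
#'   default).
#' @param rng_seed Seed controlling all randomness.
#' @return List with class `sim_config`.
#' @export
sim_config <- function(n_scaffolds = 3L, scaffold_len = 30000L,
                       n_hairpins = 12L, mature_len = c(20L, 24L),
                       loop_len = c(8L, 20L),
                       class_mixture = default_class_mixture(),
                       deletion_len = c(1L, 3L), addition_len = c(1L, 2L),
                       template_add_prob = 0.25, tail_len = c(1L, 2L),
                       count_mean = 150, count_dispersion = 4,
                       arm_bias = NULL, arm_bias_range = c(0.15, 0.85),
                       libraries = c("juvenile", "subadult", "adult"),
                       error_rate = 0, pad = 30L, rng_seed = 1L) {
  mix <- class_mixture
  if (is.null(names(mix)) || !all(names(mix) %in% READ_CLASSES))
    stop("class_mixture must be named with read_classes() labels",
         call. = FALSE)
  if (any(mix < 0) || sum(mix) <= 0)
    stop("class_mixture must be non-negative with positive sum", call. = FALSE)
  mix <- mix / sum(mix)
  if (deletion_len[2] >= mature_len[1])
    stop("deletion_len exceeds the shortest mature length", call. = FALSE)
  if (mature_len[1] - deletion_len[2] < 17L)
    stop("deletions would push reads below the 17-nt window", call. = FALSE)
  stopifnot(error_rate >= 0, error_rate < 1, n_hairpins >= 1)
  structure(list(
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_len = as.integer(scaffold_len),
    n_hairpins = as.integer(n_hairpins),
    mature_len = as.integer(mature_len), loop_len = as.integer(loop_len),
    class_mixture = mix, deletion_len = as.integer(deletion_len),
    addition_len = as.integer(addition_len),
    template_add_prob = template_add_prob, tail_len = as.integer(tail_len),
    count_mean = count_mean, count_dispersion = count_dispersion,
    arm_bias = arm_bias, arm_bias_range = arm_bias_range,
    libraries = libraries, error_rate = error_rate, pad = as.integer(pad),
    rng_seed = as.integer(rng_seed)), class = "sim_config")
}

#' Default read-class mixture
#'
#' Mature reads dominate; 3' template variants are the largest isomiR
#' group, followed by 5' template variants, untemplated 3' A/U tails and
#' SNP variants, with 5' non-template additions rare; offset and loop
#' reads contribute a few percent.
#'
#' @return Named probability vector over all eleven classes (sums to 1).
#' @export
default_class_mixture <- function() {
  mix <- c(MATURE = 0.600, ISO_3P_TEMPLATE = 0.207,
           ISO_3P_NONTEMPLATE = 0.037, ISO_SNP_NONSEED = 0.022,
           ISO_5P_TEMPLATE = 0.042, ISO_5P_NONTEMPLATE = 0.008,
           ISO_SNP_SEED = 0.035, MOR_5P = 0.018, MOR_3P = 0.006,
           LOR = 0.015, OTHER = 0.010)
  mix / sum(mix)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

runif_int <- function(n, range) {
  if (range[1] >= range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a miRNAome study
#'
#' Generates the toy genome, hairpin annotations, three collapsed read
#' libraries and sequence-level ground truth.  Deterministic under
#' `rng_seed`.
#'
#' @param config [sim_config()].
#' @return List with class `mirnaome_sim`: `genome`, `hairpins`, `loci`,
#'   `reads` (merged collapsed table), `truth` (`seq`, `hairpin_id`,
#'   `arm`, `label` plus per-library true counts), `config`, and
#'   `n_dropped` (reads rejected for cross-hairpin sequence collisions).
#' @export
simulate_mirnaome <- function(config = sim_config()) {
  set.seed(config$rng_seed)
  libs <- config$libraries
  n_hp <- config$n_hairpins

  # --- plant hairpins -----------------------------------------------------
  # stem layout: X (m+2 nt) + loop + revcomp(X); mature 5p = X[1..m],
  # mature 3p = revcomp(X[3..m+2]) so the duplex carries 2-nt 3' overhangs
  hp_seqs <- vector("list", n_hp)
  for (i in seq_len(n_hp)) {
    m <- runif_int(1L, config$mature_len)
    L <- runif_int(1L, config$loop_len)
    X <- rand_dna(m + 2L)
    hp <- paste0(X, rand_dna(L), revcomp(X))
    hp_seqs[[i]] <- list(seq = hp, m = m, L = L,
                         a5 = c(0L, m),                       # local coords
                         a3 = c(m + 2L + L, 2L * m + 2L + L))
  }

  # --- assemble scaffolds -------------------------------------------------
  per_scaf <- split(seq_len(n_hp),
                    rep(seq_len(config$n_scaffolds), length.out = n_hp))
  genome <- character(0)
  hp_rows <- list()
  for (s in seq_len(config$n_scaffolds)) {
    idx <- per_scaf[[s]]
    parts <- character(0)
    cursor <- 0L
    for (i in idx) {
      gap <- runif_int(1L, c(400L, 9000L))
      parts <- c(parts, rand_dna(gap))
      cursor <- cursor + gap
      strand <- sample(c("+", "-"), 1L)
      h <- hp_seqs[[i]]
      len <- nchar(h$seq)
      ins <- if (strand == "+") h$seq else revcomp(h$seq)
      g0 <- cursor
      l2g <- function(lc) if (strand == "+") g0 + lc else g0 + len - rev(lc)
      a5g <- l2g(h$a5); a3g <- l2g(h$a3)
      hp_rows[[i]] <- data.frame(
        hairpin_id = sprintf("hp-%02d", i), scaffold = sprintf("scaf%d", s),
        strand = strand, start = g0, end = g0 + len,
        arm5p_start = a5g[1], arm5p_end = a5g[2],
        arm3p_start = a3g[1], arm3p_end = a3g[2],
        stringsAsFactors = FALSE)
      parts <- c(parts, ins)
      cursor <- cursor + len
    }
    tail_len <- max(100L, config$scaffold_len - cursor)
    parts <- c(parts, rand_dna(tail_len))
    genome[sprintf("scaf%d", s)] <- paste(parts, collapse = "")
  }
  hairpins <- hairpin_set(do.call(rbind, hp_rows))
  loci <- hairpin_loci(hairpins, genome, pad = config$pad)

  # arm bias (5p fraction), per hairpin x library
  bias <- config$arm_bias
  if (is.null(bias)) bias <- stats::runif(n_hp, config$arm_bias_range[1],
                                          config$arm_bias_range[2])
  if (is.null(dim(bias))) bias <- matrix(bias, n_hp, length(libs))

  # --- draw reads ---------------------------------------------------------
  recs <- list()
  for (i in seq_len(n_hp)) {
    locus <- loci[i, ]
    for (j in seq_along(libs)) {
      n <- rnbinom(1L, mu = config$count_mean, size = config$count_dispersion)
      if (n == 0L) next
      cls <- sample(names(config$class_mixture), n, replace = TRUE,
                    prob = config$class_mixture)
      for (k in seq_len(n)) {
        rd <- build_read(cls[k], locus, bias[i, j], config)
        if (is.null(rd)) next
        recs[[length(recs) + 1L]] <- data.frame(
          hairpin_id = locus$hairpin_id, library = libs[j],
          seq = rd$seq, lstart = rd$lstart, label = cls[k], arm = rd$arm,
          stringsAsFactors = FALSE)
      }
    }
  }
  reads_long <- do.call(rbind, recs)

  # --- sequencing error (per-copy, uniform substitution) ------------------
  # a substituted base is indistinguishable from a SNP isomiR, so altered
  # copies are re-labelled to the class their final sequence represents,
  # using the independent position-based labeller
  if (config$error_rate > 0) {
    newseq <- vapply(reads_long$seq, apply_seq_error, "",
                     rate = config$error_rate, USE.NAMES = FALSE)
    changed <- which(newseq != reads_long$seq)
    reads_long$seq <- newseq
    li <- match(reads_long$hairpin_id, loci$hairpin_id)
    for (r in changed) {
      tl <- position_label(reads_long$seq[r], reads_long$lstart[r],
                           loci[li[r], ])
      reads_long$label[r] <- tl$label
      reads_long$arm[r] <- tl$arm
    }
  }

  # --- collapse + collision rejection -------------------------------------
  key <- paste(reads_long$seq, reads_long$hairpin_id, reads_long$arm,
               reads_long$label, sep = "\r")
  seq_of <- sub("\r.*$", "", unique(key))
  conflict_seqs <- seq_of[duplicated(seq_of)]
  # also reject sequences occurring more than once across the padded loci
  # (they would multimap and have no unique truth)
  multi <- multi_locus_seqs(unique(reads_long$seq), loci)
  drop_seqs <- union(conflict_seqs, multi)
  n_dropped <- sum(reads_long$seq %in% drop_seqs)
  reads_long <- reads_long[!(reads_long$seq %in% drop_seqs), , drop = FALSE]

  collapsed <- lapply(libs, function(lb) {
    collapse_reads(reads_long$seq[reads_long$library == lb], lb)
  })
  reads <- merge_read_libraries(collapsed)

  truth <- unique(reads_long[c("seq", "hairpin_id", "arm", "label")])
  for (lb in libs) {
    t <- tapply(rep(1, sum(reads_long$library == lb)),
                reads_long$seq[reads_long$library == lb], sum)
    v <- setNames(rep(0, nrow(truth)), truth$seq)
    v[names(t)] <- t
    truth[[lb]] <- unname(v)
  }
  rownames(truth) <- NULL

  structure(list(genome = genome, hairpins = hairpins, loci = loci,
                 reads = reads, truth = truth, config = config,
                 n_dropped = n_dropped),
            class = "mirnaome_sim")
}

# sequences with >1 exact occurrence across the oriented padded loci
multi_locus_seqs <- function(seqs, loci) {
  big <- paste(loci$seq, collapse = strrep("N", 35L))
  hits <- vapply(seqs, function(s) {
    m <- gregexpr(s, big, fixed = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, 0L)
  seqs[hits > 1L]
}

apply_seq_error <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# build one read of a given class in locus coordinates; returns NULL when
# the class is infeasible for this hairpin geometry
build_read <- function(class, locus, bias5p, config) {
  ctx <- locus$seq
  a5 <- c(locus$a5s, locus$a5e); a3 <- c(locus$a3s, locus$a3e)
  arm <- if (class == "MOR_5P") "5p"
         else if (class == "MOR_3P") "3p"
         else if (class == "LOR") "none"
         else if (runif(1) < bias5p) "5p" else "3p"
  a <- if (arm == "3p") a3 else a5
  res <- build_read_impl(class, locus, ctx, a5, a3, a, config)
  if (is.null(res)) return(NULL)
  res$arm <- arm
  res
}

build_read_impl <- function(class, locus, ctx, a5, a3, a, config) {
  sl <- function(s, e) seq_slice(ctx, s, e)
  pick_nontpl <- function(pos) {
    g <- substr(ctx, pos + 1L, pos + 1L)
    cand <- setdiff(c("A", "T"), g)
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  switch(class,
    MATURE = list(seq = sl(a[1], a[2]), lstart = a[1]),
    ISO_3P_TEMPLATE = {
      if (runif(1) < config$template_add_prob) {
        d <- runif_int(1L, config$addition_len)
        list(seq = sl(a[1], a[2] + d), lstart = a[1])
      } else {
        d <- runif_int(1L, config$deletion_len)
        list(seq = sl(a[1], a[2] - d), lstart = a[1])
      }
    },
    ISO_3P_NONTEMPLATE = {
      t <- runif_int(1L, config$tail_len)
      tail <- vapply(seq_len(t) - 1L, function(o) pick_nontpl(a[2] + o), "")
      list(seq = paste0(sl(a[1], a[2]), paste(tail, collapse = "")),
           lstart = a[1])
    },
    ISO_SNP_NONSEED = snp_read(ctx, a, seed = FALSE),
    ISO_SNP_SEED = snp_read(ctx, a, seed = TRUE),
    ISO_5P_TEMPLATE = {
      if (runif(1) < config$template_add_prob && a[1] >= config$addition_len[2]) {
        d <- runif_int(1L, config$addition_len)
        list(seq = sl(a[1] - d, a[2]), lstart = a[1] - d)
      } else {
        d <- runif_int(1L, config$deletion_len)
        list(seq = sl(a[1] + d, a[2]), lstart = a[1] + d)
      }
    },
    ISO_5P_NONTEMPLATE = {
      t <- runif_int(1L, config$tail_len)
      if (a[1] < t) return(NULL)
      head <- vapply(rev(seq_len(t)), function(o) pick_nontpl(a[1] - o), "")
      list(seq = paste0(paste(head, collapse = ""), sl(a[1], a[2])),
           lstart = a[1] - t)
    },
    MOR_5P = {
      len <- min(runif_int(1L, c(18L, 22L)), a5[1])
      if (len < 17L) return(NULL)
      list(seq = sl(a5[1] - len, a5[1]), lstart = a5[1] - len)
    },
    MOR_3P = {
      len <- min(runif_int(1L, c(18L, 22L)), nchar(ctx) - a3[2])
      if (len < 17L) return(NULL)
      list(seq = sl(a3[2], a3[2] + len), lstart = a3[2])
    },
    LOR = {
      ls <- locus$loop_s; le <- locus$loop_e
      w <- le - ls
      if (w >= 17L) {
        len <- runif_int(1L, c(17L, min(w, 24L)))
        s0 <- ls + runif_int(1L, c(0L, w - len))
        list(seq = sl(s0, s0 + len), lstart = s0)
      } else {
        need <- 17L - w
        e5 <- ceiling(need / 2); e3 <- need - e5
        list(seq = sl(ls - e5, le + e3), lstart = ls - e5)
      }
    },
    OTHER = {
      if (a[2] - a[1] - 2L < 17L) return(NULL)
      list(seq = sl(a[1] + 1L, a[2] - 1L), lstart = a[1] + 1L)
    }
  )
}

snp_read <- function(ctx, a, seed) {
  m <- a[2] - a[1]
  pos <- if (seed) sample(2:7, 1L) else sample(c(1L, 8:m), 1L)
  s <- seq_slice(ctx, a[1], a[2])
  orig <- substr(s, pos, pos)
  substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
  list(seq = s, lstart = a[1])
}

# Independent position-based labeller used for ground truth of
# error-altered read copies (and as an oracle in tests).  It never sees
# an alignment: the read is compared base-by-base against the locus at
# its known generation offset and the ordered rules are re-implemented
# here against those strings.
position_label <- function(seq, lstart, locus, seed_pos = c(2L, 7L),
                           mor_tol = 2L) {
  lend <- lstart + nchar(seq)
  rb <- strsplit(seq, "")[[1]]
  fb <- strsplit(seq_slice(locus$seq, lstart, lend), "")[[1]]
  mm <- lstart + which(rb != fb) - 1L          # 0-based locus positions
  a5 <- c(locus$a5s, locus$a5e); a3 <- c(locus$a3s, locus$a3e)
  has5 <- !is.na(a5[1]); has3 <- !is.na(a3[1])

  # nearest arm by 5'-end distance, tie broken by overlap
  cand <- list()
  if (has5) cand$`5p` <- a5
  if (has3) cand$`3p` <- a3
  d <- vapply(cand, function(a) abs(lstart - a[1]), 0)
  ov <- vapply(cand, function(a) max(0, min(lend, a[2]) - max(lstart, a[1])), 0)
  ix <- which(d == min(d))
  if (length(ix) > 1L) ix <- ix[which.max(ov[ix])]
  armn <- names(cand)[ix[1]]
  a <- cand[[ix[1]]]
  in_seed <- function(p) p >= a[1] + seed_pos[1] - 1L & p < a[1] + seed_pos[2]
  seed_hit <- any(in_seed(mm))

  if (lstart == a[1] && lend == a[2] && length(mm) == 0L)
    return(list(label = "MATURE", arm = armn))
  if (lstart == a[1]) {
    if (lend < a[2]) return(list(label = "ISO_3P_TEMPLATE", arm = armn))
    if (lend > a[2]) {
      tail_ok <- !any(mm >= a[2])
      return(list(label = if (tail_ok) "ISO_3P_TEMPLATE"
                          else "ISO_3P_NONTEMPLATE", arm = armn))
    }
    return(list(label = if (seed_hit) "ISO_SNP_SEED" else "ISO_SNP_NONSEED",
                arm = armn))
  }
  if (lend == a[2]) {
    if (lstart > a[1]) return(list(label = "ISO_5P_TEMPLATE", arm = armn))
    head_ok <- !any(mm < a[1])
    return(list(label = if (head_ok) "ISO_5P_TEMPLATE"
                        else "ISO_5P_NONTEMPLATE", arm = armn))
  }
  if (has5 && ((lend <= a5[1] && a5[1] - lend <= mor_tol) ||
               (lstart < a5[1] && lend > a5[1] && lend < a5[2])))
    return(list(label = "MOR_5P", arm = "5p"))
  if (has3 && ((lstart >= a3[2] && lstart - a3[2] <= mor_tol) ||
               (lend > a3[2] && lstart > a3[1] && lstart < a3[2])))
    return(list(label = "MOR_3P", arm = "3p"))
  if (has5 && has3 && lstart < a3[1] && lend > a5[2])
    return(list(label = "LOR", arm = "none"))
  if (seed_hit) return(list(label = "ISO_SNP_SEED", arm = armn))
  list(label = "OTHER", arm = armn)
}

#' Score classification recovery against simulation truth
#'
#' Builds a count-weighted confusion matrix of true versus predicted
#' labels over the eleven classes (plus `UNASSIGNED` for reads the
#' pipeline did not place), and per-class recall/precision.
#'
#' @param predicted Per-read predictions: `data.frame` with `seq` and
#'   `label` (e.g. `$labels` from [classify_assignments()]).
#' @param truth Truth table from [simulate_mirnaome()] (`$truth`).
#' @return List with `confusion`, `recall`, `precision`, `accuracy`
#'   (percent of true read copies predicted correctly).
#' @export
score_recovery <- function(predicted, truth) {
  libs <- setdiff(names(truth), c("seq", "hairpin_id", "arm", "label"))
  if (!all(predicted$seq %in% truth$seq))
    stop("predicted sequences absent from truth", call. = FALSE)
  pred_lab <- tapply(predicted$label, predicted$seq, function(x) x[1])
  # flag sequences predicted with conflicting labels across placements
  n_lab <- tapply(predicted$label, predicted$seq, function(x)
    length(unique(x)))
  if (any(n_lab > 1L))
    pred_lab[names(n_lab)[n_lab > 1L]] <- "AMBIGUOUS"
  levels_all <- c(READ_CLASSES, "UNASSIGNED", "AMBIGUOUS")
  p <- pred_lab[truth$seq]
  p[is.na(p)] <- "UNASSIGNED"
  w <- rowSums(as.matrix(truth[libs]))
  conf <- matrix(0, length(READ_CLASSES), length(levels_all),
                 dimnames = list(READ_CLASSES, levels_all))
  for (i in seq_len(nrow(truth)))
    conf[truth$label[i], p[i]] <- conf[truth$label[i], p[i]] + w[i]
  recall <- 100 * diag(conf[, READ_CLASSES]) / rowSums(conf)
  prec_den <- colSums(conf)[READ_CLASSES]
  precision <- 100 * diag(conf[, READ_CLASSES]) / prec_den
  acc <- 100 * sum(diag(conf[, READ_CLASSES])) / sum(conf)
  list(confusion = conf, recall = recall, precision = precision,
       accuracy = acc)
}

#' Write simulation outputs to disk
#'
#' Emits `genome.fa`, `hairpins.gff3`, one collapsed
#' `reads_<library>.fa` per library, and `truth.tsv`.
#'
#' @param sim A [simulate_mirnaome()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gff3_hairpins(sim$hairpins, file.path(dir, "hairpins.gff3"))
  for (lb in sim$config$libraries) {
    sub <- sim$reads[sim$reads[[lb]] > 0, c("read_id", "seq", lb)]
    names(sub)[3] <- "count"
    write_collapsed_fasta(sub, file.path(dir, sprintf("reads_%s.fa", lb)))
  }
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
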