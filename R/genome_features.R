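# Genomic miRNA clusters and novel-hairpin candidate evaluation.

#' Genomic clustering parameters
#'
#' @param max_gap Maximum end-to-start gap in nt between consecutive
#'   hairpins in a cluster (default 10 kb).
#' @param min_members Minimum hairpins per reported cluster (default 2).
#' @return List with class `cluster_params`.
#' @export
cluster_params <- function(max_gap = 10000L, min_members = 2L) {
  stopifnot(max_gap > 0, min_members >= 1)
  structure(list(max_gap = as.integer(max_gap),
                 min_members = as.integer(min_members)),
            class = "cluster_params")
}

#' Find genomic miRNA clusters
#'
#' Per scaffold, hairpins are sorted by start and chained while the gap
#' (next start minus previous end) does not exceed `max_gap`
#' (single-linkage chaining, i.e. the transitive closure of the pairwise
#' within-gap relation); chains with at least `min_members` members are
#' reported.  Output is invariant to input row order.
#'
#' @param hairpins Hairpin annotation table.
#' @param params [cluster_params()].
#' @return `data.frame` with one row per cluster: `cluster_id`,
#'   `scaffold`, `start`, `end`, `n_members`, `members`
#'   (comma-separated hairpin ids in genomic order).
#' @export
find_clusters <- function(hairpins, params = cluster_params()) {
  out <- list()
  for (sc in sort(unique(hairpins$scaffold))) {
    h <- hairpins[hairpins$scaffold == sc, , drop = FALSE]
    h <- h[order(h$start, h$end, h$hairpin_id), , drop = FALSE]
    if (nrow(h) == 0L) next
    gap <- h$start[-1L] - cummax(h$end)[-nrow(h)]
    grp <- cumsum(c(1L, as.integer(gap > params$max_gap)))
    for (g in unique(grp)) {
      sub <- h[grp == g, , drop = FALSE]
      if (nrow(sub) < params$min_members) next
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, start = min(sub$start), end = max(sub$end),
        n_members = nrow(sub),
        members = paste(sub$hairpin_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(scaffold = character(0), start = integer(0), end = integer(0),
               n_members = integer(0), members = character(0))
  if (nrow(res)) res <- res[order(res$scaffold, res$start), , drop = FALSE]
  res$cluster_id <- if (nrow(res)) sprintf("cluster-%d", seq_len(nrow(res)))
                    else character(0)
  rownames(res) <- NULL
  res[c("cluster_id", "scaffold", "start", "end", "n_members", "members")]
}

#' Export clusters as BED
#'
#' @param clusters Output of [find_clusters()].
#' @param path Output path (BED: 0-based half-open, as used internally).
#' @export
write_clusters_bed <- function(clusters, path) {
  bed <- data.frame(clusters$scaffold, clusters$start, clusters$end,
                    clusters$cluster_id)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# per-pair energies of the surrogate stem model, kcal/mol
.pair_energy <- function(b1, b2) {
  key <- paste0(b1, b2)
  e <- c(GC = -3, CG = -3, AT = -2, TA = -2, GT = -1, TG = -1)
  v <- e[key]
  ifelse(is.na(v), 0, v)
}

#' Fold a hairpin candidate
#'
#' The built-in `"surrogate"` backend finds the maximum-scoring
#' contiguous stem-loop by complementary extension, with per-pair
#' energies GC = -3, AU = -2, GU = -1 kcal/mol and a terminal loop of at
#' least 3 nt.  It is a stem-counting surrogate for ranking candidate
#' hairpins, not a thermodynamic nearest-neighbour model; the
#' `"rnafold"` backend delegates to the RNAfold executable when a
#' thermodynamic minimum-free-energy structure is wanted.
#'
#' @param seq Nucleotide sequence (RNA or DNA alphabet), 40-400 nt.
#' @param backend `"surrogate"` (default) or `"rnafold"`.
#' @return List with `dg` (kcal/mol; 0 when no stem is found),
#'   `structure` (dot-bracket), and `partner` (integer vector: 1-based
#'   pairing partner per position, `NA` when unpaired).
#' @export
fold_hairpin <- function(seq, backend = c("surrogate", "rnafold")) {
  backend <- match.arg(backend)
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (n < 40L || n > 400L)
    stop("fold_hairpin expects sequences of 40-400 nt (got ", n, ")",
         call. = FALSE)
  if (backend == "rnafold") return(.fold_rnafold(seq))
  b <- strsplit(seq, "")[[1]]
  best <- list(dg = 0, i = NA, j = NA, k = 0L)
  # anti-diagonals: pairs (i, c - i), 0-based, innermost loop >= 3
  for (cc in seq(4L, 2L * n - 4L)) {
    i_max <- floor((cc - 4L) / 2L)
    i_lo <- max(0L, cc - (n - 1L))
    if (i_max < i_lo) next
    is <- i_lo:i_max
    js <- cc - is
    w <- .pair_energy(b[is + 1L], b[js + 1L])
    # maximal runs of complementary pairs along the diagonal
    r <- rle(w < 0)
    pos <- cumsum(c(1L, r$lengths))
    for (q in seq_along(r$values)) {
      if (!r$values[q]) next
      s0 <- pos[q]; s1 <- pos[q + 1L] - 1L
      dg <- sum(w[s0:s1])
      if (dg < best$dg) {
        best <- list(dg = dg, i = is[s0], j = js[s0], k = s1 - s0 + 1L)
      }
    }
  }
  struct <- rep(".", n)
  partner <- rep(NA_integer_, n)
  if (best$k > 0L) {
    ii <- best$i + seq_len(best$k) - 1L
    jj <- best$j - seq_len(best$k) + 1L
    struct[ii + 1L] <- "("
    struct[jj + 1L] <- ")"
    partner[ii + 1L] <- jj + 1L
    partner[jj + 1L] <- ii + 1L
  }
  list(dg = best$dg, structure = paste(struct, collapse = ""),
       partner = partner)
}

.fold_rnafold <- function(seq) {
  exe <- Sys.which("RNAfold")
  if (exe == "")
    stop("RNAfold executable not found on PATH", call. = FALSE)
  out <- system2(exe, args = "--noPS", input = dna_to_rna(seq),
                 stdout = TRUE)
  line <- out[2]
  db <- sub("\\s.*$", "", line)
  dg <- as.numeric(gsub("[()\\s]", "", sub("^[.()]+\\s+", "", line),
                        perl = TRUE))
  partner <- rep(NA_integer_, nchar(db))
  stack <- integer(0)
  ch <- strsplit(db, "")[[1]]
  for (p in seq_along(ch)) {
    if (ch[p] == "(") stack <- c(stack, p)
    else if (ch[p] == ")") {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[p] <- q; partner[q] <- p
    }
  }
  list(dg = dg, structure = db, partner = partner)
}

#' Novel-candidate parameters
#'
#' @param dg_threshold Folding free energy a candidate must fall below
#'   (default -20 kcal/mol, exposed as a parameter).
#' @param min_reads Minimum total read count at the locus (default 10).
#' @param require_both_arms When `FALSE` (default), candidates with reads
#'   on only one stem arm are labelled `PROVISIONAL` instead of failing.
#' @param duplex_overhang_nt Expected 3' duplex overhang in nt
#'   (default 2).
#' @param overhang_tol Tolerance on the overhang (default 1).
#' @param five_prime_homogeneity_min Minimum fraction of an arm's reads
#'   sharing the modal 5' end (default 0.9).
#' @return List with class `novel_params`.
#' @export
novel_params <- function(dg_threshold = -20, min_reads = 10,
                         require_both_arms = FALSE, duplex_overhang_nt = 2L,
                         overhang_tol = 1L,
                         five_prime_homogeneity_min = 0.9) {
  stopifnot(dg_threshold < 0, min_reads >= 0, overhang_tol >= 0)
  structure(list(dg_threshold = dg_threshold, min_reads = min_reads,
                 require_both_arms = require_both_arms,
                 duplex_overhang_nt = as.integer(duplex_overhang_nt),
                 overhang_tol = as.integer(overhang_tol),
                 five_prime_homogeneity_min = five_prime_homogeneity_min),
            class = "novel_params")
}

# count-weighted mode (smallest value on ties, for determinism)
.wmode <- function(x, w) {
  t <- tapply(w, x, sum)
  as.integer(names(t)[order(-t, as.numeric(names(t)))][1])
}

#' Evaluate a novel-hairpin candidate
#'
#' Screens a read stack at a candidate locus against the standard
#' annotation criteria: a stable fold (`dg < dg_threshold`), sufficient
#' reads, reads from both stem arms, homogeneous 5' ends per arm, and a
#' Dicer-like ~2-nt 3' duplex overhang measured between the modal 5p
#' read 3' end and the modal 3p read 5' end on the folded stem.  All
#' flags are computed independently; the verdict is `PASS` when all hold,
#' `PROVISIONAL` when only reads-on-both-arms is missing (unless
#' `require_both_arms`), `FAIL` otherwise.
#'
#' @param stack `data.frame` of reads at the locus: `lstart`, `lend`
#'   (0-based half-open locus coordinates) and `count`.
#' @param locus_seq Candidate locus sequence (hairpin orientation).
#' @param params [novel_params()].
#' @param backend Folding backend passed to [fold_hairpin()].
#' @return List: `dg`, flags (`fold_pass`, `reads_pass`, `both_arms`,
#'   `overhang_pass`, `homogeneity_pass`), `overhang`, and `verdict`.
#' @export
evaluate_novel_candidate <- function(stack, locus_seq,
                                     params = novel_params(),
                                     backend = "surrogate") {
  fold <- fold_hairpin(locus_seq, backend = backend)
  res <- list(dg = fold$dg, fold_pass = fold$dg < params$dg_threshold,
              reads_pass = FALSE, both_arms = FALSE, overhang_pass = FALSE,
              homogeneity_pass = FALSE, overhang = NA_integer_,
              verdict = "FAIL")
  if (is.null(stack) || nrow(stack) == 0L || sum(stack$count) == 0L)
    return(res)
  res$reads_pass <- sum(stack$count) >= params$min_reads

  paired <- which(!is.na(fold$partner))
  if (length(paired) == 0L) return(res)
  loop_mid <- mean(range(paired))
  side5 <- paired[paired < loop_mid]
  side3 <- paired[paired > loop_mid]
  mid <- (stack$lstart + stack$lend - 1) / 2 + 1   # 1-based midpoints
  on5 <- mid >= min(side5) & mid <= max(side5)
  on3 <- mid >= min(side3) & mid <= max(side3)
  c5 <- sum(stack$count[on5]); c3 <- sum(stack$count[on3])
  res$both_arms <- c5 > 0 && c3 > 0

  hom <- logical(0)
  for (side in list(on5, on3)) {
    if (!any(side) || sum(stack$count[side]) == 0) next
    st <- stack[side, , drop = FALSE]
    t <- tapply(st$count, st$lstart, sum)
    hom <- c(hom, max(t) / sum(t) >= params$five_prime_homogeneity_min)
  }
  res$homogeneity_pass <- length(hom) > 0L && all(hom)

  if (res$both_arms) {
    b_last <- .wmode(stack$lend[on5], stack$count[on5]) - 1L  # 0-based last
    c_start <- .wmode(stack$lstart[on3], stack$count[on3])    # 0-based start
    p <- fold$partner[b_last + 1L]                            # partner, 1-based
    if (!is.na(p)) {
      res$overhang <- (p - 1L) - c_start
      res$overhang_pass <-
        abs(res$overhang - params$duplex_overhang_nt) <= params$overhang_tol
    }
  } else {
    # overhang is not measurable with one expressed arm; it does not
    # count against a one-arm candidate
    res$overhang_pass <- TRUE
  }

  all_but_arms <- res$fold_pass && res$reads_pass && res$overhang_pass &&
    res$homogeneity_pass
  res$verdict <- if (all_but_arms && res$both_arms) "PASS"
                 else if (all_but_arms && !params$require_both_arms) "PROVISIONAL"
                 else "FAIL"
  res
}
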