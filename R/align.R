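# Assignment of collapsed reads to hairpin loci.  Alignment is restricted
# to padded hairpin loci (whole-genome mapping of real data is delegated
# to SAM input); each read is aligned in hairpin 5'->3' orientation with
# the cost scheme mismatch 2, insertion 3, deletion 3, and accepted when
# at least `length_fraction` of the read aligns with identity at least
# `similarity_fraction` over the aligned part.

#' Alignment parameters
#'
#' @param mismatch_cost,insertion_cost,deletion_cost Edit costs
#'   (defaults 2, 3, 3).
#' @param length_fraction Minimum aligned fraction of the read
#'   (default 0.85).
#' @param similarity_fraction Minimum identity over the aligned part
#'   (default 0.8).
#' @param multimap_policy `"split_equally"` divides a read's count
#'   equally across tied best placements (fractional counts allowed);
#'   `"random"` picks one placement uniformly with a seeded RNG.
#' @param rng_seed Seed for the `"random"` policy.
#' @param pad Flanking margin around hairpins in nt (default 30), so
#'   offset reads can land.
#' @param max_clip3 Maximum number of terminal 3' read bases retained as
#'   a candidate non-template tail when the full-length read fails the
#'   similarity filter (default 3).
#' @return List with class `align_params`.
#' @export
align_params <- function(mismatch_cost = 2, insertion_cost = 3,
                         deletion_cost = 3, length_fraction = 0.85,
                         similarity_fraction = 0.8,
                         multimap_policy = c("split_equally", "random"),
                         rng_seed = 1L, pad = 30L, max_clip3 = 3L) {
  stopifnot(mismatch_cost > 0, insertion_cost > 0, deletion_cost > 0,
            length_fraction > 0, length_fraction <= 1,
            similarity_fraction > 0, similarity_fraction <= 1)
  if (insertion_cost != deletion_cost)
    stop("the aligner uses a single gap-per-base cost; insertion_cost and ",
         "deletion_cost must be equal", call. = FALSE)
  structure(list(
    mismatch_cost = mismatch_cost, insertion_cost = insertion_cost,
    deletion_cost = deletion_cost, length_fraction = length_fraction,
    similarity_fraction = similarity_fraction,
    multimap_policy = match.arg(multimap_policy),
    rng_seed = as.integer(rng_seed), pad = as.integer(pad),
    max_clip3 = as.integer(max_clip3)), class = "align_params")
}

# substitution matrix shared by the aligner (match 0, mismatch -cost so
# that -score equals the placement cost)
.subst_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = 0, mismatch = -params$mismatch_cost, baseOnly = TRUE)
}

# semi-global alignment of a set of reads against one locus sequence;
# returns per-read placement details (locus coordinates, 0-based
# half-open)
.align_to_locus <- function(seqs, locus_seq, params, mat,
                            gap_cost = params$insertion_cost) {
  subj <- Biostrings::DNAString(locus_seq)
  pat <- Biostrings::DNAStringSet(seqs)
  aln <- Biostrings::pairwiseAlignment(
    pat, subj, type = "global-local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = gap_cost)
  mmt <- Biostrings::mismatchTable(aln)
  mm_by_read <- split(mmt$SubjectStart - 1L, factor(mmt$PatternId,
                                                    levels = seq_along(seqs)))
  ind <- Biostrings::indel(aln)
  ins_len <- sum(IRanges::width(ind@insertion))
  del_len <- sum(IRanges::width(ind@deletion))
  data.frame(
    lstart = Biostrings::start(Biostrings::subject(aln)) - 1L,
    lend = Biostrings::end(Biostrings::subject(aln)),
    cost = -Biostrings::score(aln),
    n_mm = vapply(mm_by_read, length, 0L),
    mm_lpos = vapply(mm_by_read, paste, "", collapse = ","),
    ins_len = ins_len, del_len = del_len,
    stringsAsFactors = FALSE
  )
}

# acceptance rule for one placement: aligned fraction of the read and
# identity over the aligned part
.placement_ok <- function(read_len, aligned_len, n_mm, ins_len, del_len,
                          params) {
  cols <- aligned_len + del_len
  matches <- aligned_len - n_mm - ins_len
  (aligned_len / read_len) >= params$length_fraction &
    (matches / cols) >= params$similarity_fraction
}

#' Align collapsed reads to hairpin loci
#'
#' Aligns every unique read sequence against every padded hairpin locus
#' and keeps, per read, all placements attaining the minimum cost that
#' pass the length/similarity filters.  The search is tiered: ungapped
#' placements are preferred (isomiR-defining events -- offset ends,
#' untemplated additions, SNPs -- are substitution/offset events, and a
#' gapped re-alignment of an untemplated tail or head would silently
#' shift the 5' anchor the classifier keys on); reads with no acceptable
#' ungapped placement are retried with up to `max_clip3` terminal 3'
#' bases set aside as a candidate non-template tail, and only then with
#' gaps under the full cost scheme.
#'
#' @param reads `data.frame` with columns `read_id`, `seq` and one or
#'   more library count columns (see [merge_read_libraries()]).
#' @param genome Genome (named character vector).
#' @param hairpins Hairpin annotation table.
#' @param params [align_params()].
#' @param loci Optional pre-computed [hairpin_loci()] table (must match
#'   `params$pad`).
#' @return List with `alignments` (one row per read x accepted placement:
#'   locus coordinates, cost, mismatch positions, clip) and `unaligned`
#'   (read ids with no accepted placement).
#' @export
align_reads <- function(reads, genome, hairpins, params = align_params(),
                        loci = NULL) {
  if (is.null(loci)) loci <- hairpin_loci(hairpins, genome, pad = params$pad)
  if (nrow(loci) == 0L || nrow(reads) == 0L) {
    return(list(alignments = empty_alignments(), unaligned = reads$read_id))
  }
  mat <- .subst_matrix(params)
  nr <- nrow(reads)
  nl <- nrow(loci)
  # tier 1: ungapped placements (gaps priced out), scoreOnly first
  costs <- matrix(NA_real_, nr, nl)
  for (j in seq_len(nl)) {
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(reads$seq), Biostrings::DNAString(loci$seq[j]),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = .NOGAP_COST, scoreOnly = TRUE)
    costs[, j] <- -sc
  }
  best <- apply(costs, 1L, min)
  rows <- list()
  for (j in seq_len(nl)) {
    idx <- which(abs(costs[, j] - best) < 1e-9 & best < .NOGAP_COST)
    if (!length(idx)) next
    d <- .align_to_locus(reads$seq[idx], loci$seq[j], params, mat,
                         gap_cost = .NOGAP_COST)
    m <- nchar(reads$seq[idx])
    ok <- .placement_ok(m, m, d$n_mm, d$ins_len, d$del_len, params)
    keep <- which(ok)
    if (length(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = reads$read_id[idx[keep]], seq = reads$seq[idx[keep]],
        hairpin_id = loci$hairpin_id[j], d[keep, , drop = FALSE],
        clip3 = "", stringsAsFactors = FALSE)
    }
  }
  aln <- if (length(rows)) do.call(rbind, rows) else empty_alignments()
  # tier 2: 3'-clip rescue; tier 3: gapped placements
  todo <- which(!(reads$read_id %in% unique(aln$read_id)))
  for (i in todo) {
    res <- .clip_rescue(reads$seq[i], reads$read_id[i], loci, params, mat)
    if (is.null(res))
      res <- .gapped_rescue(reads$seq[i], reads$read_id[i], loci, params, mat)
    if (!is.null(res)) aln <- rbind(aln, res)
  }
  rownames(aln) <- NULL
  list(alignments = aln,
       unaligned = setdiff(reads$read_id, unique(aln$read_id)))
}

# gap price that excludes gaps from a placement tier while keeping costs
# finite for the score pass
.NOGAP_COST <- 1e6

empty_alignments <- function() {
  data.frame(read_id = character(0), seq = character(0),
             hairpin_id = character(0), lstart = integer(0), lend = integer(0),
             cost = numeric(0), n_mm = integer(0), mm_lpos = character(0),
             ins_len = integer(0), del_len = integer(0), clip3 = character(0),
             stringsAsFactors = FALSE)
}

# retry a rejected read with 1..max_clip3 terminal 3' bases clipped
# (ungapped core); the clip must respect the length fraction
# ((m - c)/m >= length_fraction)
.clip_rescue <- function(seq, read_id, loci, params, mat) {
  m <- nchar(seq)
  max_c <- min(params$max_clip3, floor(m * (1 - params$length_fraction)))
  if (max_c < 1L) return(NULL)
  for (c in seq_len(max_c)) {
    core <- substr(seq, 1L, m - c)
    tail_seq <- substr(seq, m - c + 1L, m)
    cand <- list()
    for (j in seq_len(nrow(loci))) {
      d <- .align_to_locus(core, loci$seq[j], params, mat,
                           gap_cost = .NOGAP_COST)
      if (d$cost < .NOGAP_COST &&
          .placement_ok(m, m - c, d$n_mm, d$ins_len, d$del_len, params)) {
        cand[[length(cand) + 1L]] <- data.frame(
          read_id = read_id, seq = seq, hairpin_id = loci$hairpin_id[j],
          d, clip3 = tail_seq, stringsAsFactors = FALSE)
      }
    }
    if (length(cand)) {
      all <- do.call(rbind, cand)
      return(all[abs(all$cost - min(all$cost)) < 1e-9, , drop = FALSE])
    }
  }
  NULL
}

# last resort: gapped placements under the full cost scheme
.gapped_rescue <- function(seq, read_id, loci, params, mat) {
  m <- nchar(seq)
  cand <- list()
  for (j in seq_len(nrow(loci))) {
    d <- .align_to_locus(seq, loci$seq[j], params, mat)
    if (.placement_ok(m, m, d$n_mm, d$ins_len, d$del_len, params)) {
      cand[[length(cand) + 1L]] <- data.frame(
        read_id = read_id, seq = seq, hairpin_id = loci$hairpin_id[j],
        d, clip3 = "", stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(NULL)
  all <- do.call(rbind, cand)
  all[abs(all$cost - min(all$cost)) < 1e-9, , drop = FALSE]
}

#' Resolve multimapping reads into assignments
#'
#' Reads with several tied best placements are resolved per
#' `multimap_policy`: `"split_equally"` divides the read's per-library
#' counts equally across placements (mirroring the convention of halving
#' reads between hairpins that share an identical mature sequence);
#' `"random"` keeps one placement chosen uniformly with the seeded RNG.
#' Counts are conserved under both policies.
#'
#' @param alignments Accepted placements from [align_reads()].
#' @param reads Read table with library count columns.
#' @param params [align_params()].
#' @return `data.frame` of assignments: the placement columns plus one
#'   assigned-count column per library (possibly fractional).
#' @export
resolve_multimappers <- function(alignments, reads, params = align_params()) {
  libs <- setdiff(names(reads), c("read_id", "seq"))
  if (nrow(alignments) == 0L) {
    out <- alignments
    for (lib in libs) out[[lib]] <- numeric(0)
    return(out)
  }
  split_idx <- split(seq_len(nrow(alignments)), alignments$read_id)
  keep_rows <- integer(0)
  share <- numeric(0)
  if (params$multimap_policy == "random") {
    set.seed(params$rng_seed)
    for (idx in split_idx) {
      pick <- if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
      keep_rows <- c(keep_rows, pick)
      share <- c(share, 1)
    }
  } else {
    for (idx in split_idx) {
      keep_rows <- c(keep_rows, idx)
      share <- c(share, rep(1 / length(idx), length(idx)))
    }
  }
  out <- alignments[keep_rows, , drop = FALSE]
  cnt <- reads[match(out$read_id, reads$read_id), libs, drop = FALSE]
  for (lib in libs) out[[lib]] <- cnt[[lib]] * share
  rownames(out) <- NULL
  out
}
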