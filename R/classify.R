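# The read-classification decision tree.  Reads assigned to a hairpin are
# labelled as mature, one of six isomiR groups, offset RNA (moR), loop
# RNA (loR) or OTHER.  All comparisons are made in hairpin 5'->3'
# orientation (locus coordinates), so the rules below are strand-free.
#
# Group semantics:
#   ISO_3P_TEMPLATE     mature 5' end; 3' deletions, or additions that
#                       match the genome continuation
#   ISO_3P_NONTEMPLATE  mature 5' end; >=1 added 3' base disagreeing with
#                       the genome (untemplated tail, typically A/U)
#   ISO_SNP_NONSEED     both mature ends; internal SNP outside seed (2-7)
#   ISO_5P_TEMPLATE     mature 3' end; 5' deletions/templated additions
#   ISO_5P_NONTEMPLATE  mature 3' end; untemplated 5' additions
#   ISO_SNP_SEED        SNP inside the seed (positions 2-7 of the mature
#                       5' end); also the residual label for any read
#                       reaching the final step with a seed mismatch
#   MOR_5P / MOR_3P     offset reads flanking the 5p mature 5' end / the
#                       3p mature 3' end on the primary transcript
#   LOR                 reads from the terminal loop between the arms

#' Classifier parameters
#'
#' @param seed_start,seed_end Seed positions on the mature read, 1-based
#'   inclusive from the 5' end (defaults 2 and 7).
#' @param min_hairpin_reads Strictly-greater read-count threshold a
#'   hairpin must exceed in a library to enter isomiR ratio analysis
#'   (default 10).
#' @param mor_max_start_offset Adjacency tolerance in nt for offset reads
#'   (default 2; exact adjacency is recovered with 0).
#' @return List with class `classifier_params`.
#' @export
classifier_params <- function(seed_start = 2L, seed_end = 7L,
                              min_hairpin_reads = 10,
                              mor_max_start_offset = 2L) {
  stopifnot(seed_start > 1L, seed_start <= seed_end,
            mor_max_start_offset >= 0L, min_hairpin_reads >= 0)
  structure(list(seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 min_hairpin_reads = min_hairpin_reads,
                 mor_max_start_offset = as.integer(mor_max_start_offset)),
            class = "classifier_params")
}

#' Classify one aligned read against its hairpin
#'
#' Applies the ordered decision tree in locus coordinates.  The aligner
#' contributes only the anchor (`lstart`, the locus position of the
#' read's 5' end); all template/SNP decisions are made by naive
#' character-by-character comparison of the read against the locus
#' sequence at that anchor.  This deliberately ignores gapped
#' re-alignments of untemplated tails: a 3' addition that disagrees with
#' the genome continuation base-by-base is non-templated even where a
#' gap placement would be cheaper.
#'
#' @param lstart Locus position (0-based) of the read's 5' end.
#' @param seq Read sequence (hairpin orientation, DNA alphabet).
#' @param locus One row of the [hairpin_loci()] table.
#' @param params [classifier_params()].
#' @return List with `label` (one of [read_classes()]) and `arm`
#'   (`"5p"`, `"3p"` or `"none"`).
#' @export
classify_read <- function(lstart, seq, locus, params = classifier_params()) {
  a5 <- c(locus$a5s, locus$a5e)
  a3 <- c(locus$a3s, locus$a3e)
  has5 <- !is.na(a5[1]); has3 <- !is.na(a3[1])
  if (!has5 && !has3)
    stop("hairpin ", locus$hairpin_id, " has no annotated mature arm",
         call. = FALSE)
  L <- nchar(locus$seq)
  lend <- lstart + nchar(seq)
  if (lstart < 0L || lend > L || lend <= lstart)
    stop("alignment outside the padded hairpin span", call. = FALSE)
  # positional disagreement with the genome
  rb <- strsplit(seq, "")[[1]]
  fb <- strsplit(seq_slice(locus$seq, lstart, lend), "")[[1]]
  mm_lpos <- lstart + which(rb != fb) - 1L

  # nearest mature arm: smaller 5'-end distance, tie -> larger overlap
  arms <- list()
  if (has5) arms$`5p` <- a5
  if (has3) arms$`3p` <- a3
  d5 <- vapply(arms, function(a) abs(lstart - a[1]), 0)
  ov <- vapply(arms, function(a) max(0, min(lend, a[2]) - max(lstart, a[1])), 0)
  best <- which(d5 == min(d5))
  if (length(best) > 1L) best <- best[which.max(ov[best])]
  arm_name <- names(arms)[[best[1]]]
  arm <- arms[[best[1]]]
  seed_lo <- arm[1] + params$seed_start - 1L   # 0-based inclusive
  seed_hi <- arm[1] + params$seed_end          # 0-based exclusive
  seed_mm <- any(mm_lpos >= seed_lo & mm_lpos < seed_hi)

  # step 1: exact mature read
  if (lstart == arm[1] && lend == arm[2] && length(mm_lpos) == 0L)
    return(list(label = "MATURE", arm = arm_name))

  # step 2: mature 5' end
  if (lstart == arm[1]) {
    if (lend != arm[2]) {
      if (lend < arm[2]) {
        # pure 3' deletion is always templated
        return(list(label = "ISO_3P_TEMPLATE", arm = arm_name))
      }
      ext_mm <- any(mm_lpos >= arm[2])
      return(list(label = if (ext_mm) "ISO_3P_NONTEMPLATE"
                          else "ISO_3P_TEMPLATE",
                  arm = arm_name))
    }
    # same span, internal mismatches
    return(list(label = if (seed_mm) "ISO_SNP_SEED" else "ISO_SNP_NONSEED",
                arm = arm_name))
  }

  # step 3: mature 3' end
  if (lend == arm[2]) {
    if (lstart > arm[1]) {
      # 5' shortening removes templated bases
      return(list(label = "ISO_5P_TEMPLATE", arm = arm_name))
    }
    add_mm <- any(mm_lpos < arm[1])
    return(list(label = if (add_mm) "ISO_5P_NONTEMPLATE"
                        else "ISO_5P_TEMPLATE",
                arm = arm_name))
  }

  # step 4: offset reads
  if (has5) {
    if (lend <= a5[1] && (a5[1] - lend) <= params$mor_max_start_offset)
      return(list(label = "MOR_5P", arm = "5p"))
    if (lstart < a5[1] && lend > a5[1] && lend < a5[2])
      return(list(label = "MOR_5P", arm = "5p"))
  }
  if (has3) {
    if (lstart >= a3[2] && (lstart - a3[2]) <= params$mor_max_start_offset)
      return(list(label = "MOR_3P", arm = "3p"))
    if (lend > a3[2] && lstart > a3[1] && lstart < a3[2])
      return(list(label = "MOR_3P", arm = "3p"))
  }

  # step 5: loop reads (between the 3' end of the 5p mature and the 5'
  # start of the 3p mature, wholly or straddling a boundary)
  if (has5 && has3 && lstart < a3[1] && lend > a5[2])
    return(list(label = "LOR", arm = "none"))

  # step 6: residual; a seed mismatch overrides to the seed-SNP group
  if (seed_mm) return(list(label = "ISO_SNP_SEED", arm = arm_name))
  list(label = "OTHER", arm = arm_name)
}

#' Classify all assignments into a class count table
#'
#' Applies [classify_read()] to every assignment row and tallies counts
#' per (hairpin, arm, label, library).  Hairpins whose total assigned
#' count in a library does not exceed `min_hairpin_reads` are flagged
#' ineligible for isomiR ratio analysis in that library (strictly-greater
#' threshold) but stay in the table so expression totals are conserved.
#'
#' @param assignments Output of [resolve_multimappers()].
#' @param loci [hairpin_loci()] table matching the alignment run.
#' @param params [classifier_params()].
#' @return List with `classes` (long `data.frame`: `hairpin_id`, `arm`,
#'   `label`, `seq`, and one count column per library), `labels` (per
#'   assignment row), and `eligible` (hairpin x library logical matrix
#'   for the isomiR-ratio threshold).
#' @export
classify_assignments <- function(assignments, loci,
                                 params = classifier_params()) {
  libs <- setdiff(names(assignments),
                  c("read_id", "seq", "hairpin_id", "lstart", "lend", "cost",
                    "n_mm", "mm_lpos", "ins_len", "del_len", "clip3"))
  n <- nrow(assignments)
  label <- character(n); arm <- character(n)
  locus_idx <- match(assignments$hairpin_id, loci$hairpin_id)
  for (i in seq_len(n)) {
    cl <- classify_read(assignments$lstart[i], assignments$seq[i],
                        loci[locus_idx[i], ], params)
    label[i] <- cl$label; arm[i] <- cl$arm
  }
  classes <- data.frame(hairpin_id = assignments$hairpin_id,
                        arm = arm, label = label, seq = assignments$seq,
                        stringsAsFactors = FALSE)
  for (lib in libs) classes[[lib]] <- assignments[[lib]]

  # aggregate duplicate (hairpin, arm, label, seq) rows
  key <- paste(classes$hairpin_id, classes$arm, classes$label, classes$seq,
               sep = "\r")
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(classes[libs], by = list(key = key), FUN = sum)
    first <- classes[!duplicated(key), c("hairpin_id", "arm", "label", "seq")]
    first <- first[match(agg$key, unique(key)), ]
    classes <- cbind(first, agg[libs])
  }
  rownames(classes) <- NULL

  hp_ids <- sort(unique(classes$hairpin_id))
  eligible <- matrix(FALSE, length(hp_ids), length(libs),
                     dimnames = list(hp_ids, libs))
  for (lib in libs) {
    tot <- tapply(classes[[lib]], classes$hairpin_id, sum)
    eligible[names(tot), lib] <- tot > params$min_hairpin_reads
  }
  list(classes = classes, labels = data.frame(
    read_id = assignments$read_id, hairpin_id = assignments$hairpin_id,
    seq = assignments$seq, arm = arm, label = label,
    stringsAsFactors = FALSE), eligible = eligible)
}

#' Classify a mature/isomiR worked example
#'
#' Embeds a mature sequence in a small constructed genome, with the
#' genome continuation beyond the mature 3' end (and the context before
#' its 5' end) taken from the variant itself so that length variants are
#' templated unless `continuation` overrides the downstream genome
#' bases.  The variant read is then aligned and classified through the
#' regular pipeline path.
#'
#' @param mature_seq,variant_seq Mature and variant sequences (RNA or
#'   DNA alphabet).
#' @param arm Which arm the mature is annotated on (`"5p"`/`"3p"`).
#' @param continuation Optional genome bases immediately after the
#'   mature 3' end, overriding the variant-derived continuation (used to
#'   probe non-template calls).
#' @param params [classifier_params()].
#' @return The label assigned to the variant (character).
#' @export
classify_isomir_example <- function(mature_seq, variant_seq,
                                    arm = c("5p", "3p"),
                                    continuation = NULL,
                                    params = classifier_params()) {
  arm <- match.arg(arm)
  M <- normalize_seq(mature_seq)
  V <- normalize_seq(variant_seq)
  f5 <- "ACGCTGAACTCGTAGCTGCACGTCAACGGA"
  f3 <- "TCCAGCATGTTAGACGATCAGCGGAAGTCA"
  # context before the mature 5' end: templated when the variant extends
  # the 5' side (its extra head bases become genome)
  before <- ""
  after <- ""
  if (endsWith(V, M) && nchar(V) > nchar(M))
    before <- substr(V, 1L, nchar(V) - nchar(M))
  if (startsWith(V, M) && nchar(V) > nchar(M))
    after <- substr(V, nchar(M) + 1L, nchar(V))
  if (!is.null(continuation)) after <- normalize_seq(continuation)
  scaf <- paste0(f5, before, M, after, f3)
  ms <- nchar(f5) + nchar(before)          # 0-based mature start
  me <- ms + nchar(M)
  hp <- data.frame(
    hairpin_id = "example", scaffold = "s", strand = "+",
    start = max(0L, ms - 5L), end = min(nchar(scaf), me + 5L),
    arm5p_start = if (arm == "5p") ms else NA_integer_,
    arm5p_end = if (arm == "5p") me else NA_integer_,
    arm3p_start = if (arm == "3p") ms else NA_integer_,
    arm3p_end = if (arm == "3p") me else NA_integer_,
    stringsAsFactors = FALSE)
  hairpins <- hairpin_set(hp)
  genome <- as_genome(c(s = scaf))
  reads <- data.frame(read_id = "v", seq = V, lib = 1)
  al <- align_reads(reads, genome, hairpins)
  if (nrow(al$alignments) == 0L)
    stop("variant read did not align to the constructed locus",
         call. = FALSE)
  a <- al$alignments[1, ]
  loci <- hairpin_loci(hairpins, genome)
  cl <- classify_read(a$lstart, V, loci[1, ], params)
  cl$label
}
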