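# Standard-format I/O.  Genomes and reads go through Biostrings, hairpin
# annotations through rtracklayer (miRBase-style GFF3 dialect:
# `miRNA_primary_transcript` hairpins with `miRNA` mature arms linked by
# Parent), optional pre-computed alignments through Rsamtools.

#' Read a genome FASTA
#'
#' Loads scaffolds into a named character vector.  Sequences are
#' uppercased and U is normalized to T, so downstream comparisons are in
#' DNA space; report helpers convert back to RNA for display.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per scaffold.
#' @export
read_genome_fasta <- function(path) {
  # BStringSet so RNA (U) input survives until our own normalization
  ss <- Biostrings::readBStringSet(path)
  genome <- normalize_seq(as.character(ss))
  names(genome) <- sub("\\s.*$", "", names(ss))
  as_genome(genome)
}

#' Construct/validate a genome object
#'
#' @param scaffolds Named character vector of nucleotide sequences.
#' @return The validated genome (named character vector).
#' @export
as_genome <- function(scaffolds) {
  if (is.null(names(scaffolds)) || anyDuplicated(names(scaffolds)))
    stop("scaffold names must be present and unique", call. = FALSE)
  if (any(nchar(scaffolds) == 0L))
    stop("scaffold sequences must be non-empty", call. = FALSE)
  scaffolds <- normalize_seq(scaffolds)
  check_nucleotides(scaffolds, "genome")
  scaffolds
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of scaffolds.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# parse a collapsed-FASTA header count token: ">id_xN" or ">id count=N";
# absent token -> count 1
parse_header_count <- function(header) {
  m <- regmatches(header, regexec("count=([0-9]+)", header))
  cnt <- vapply(m, function(x) if (length(x) == 2L) as.numeric(x[2]) else NA_real_, 0)
  m2 <- regmatches(header, regexec("_x([0-9]+)(\\s|$)", header))
  cnt2 <- vapply(m2, function(x) if (length(x) >= 2L) as.numeric(x[2]) else NA_real_, 0)
  out <- ifelse(is.na(cnt), cnt2, cnt)
  ifelse(is.na(out), 1, out)
}

#' Read small-RNA reads from FASTA/FASTQ
#'
#' Collapsed-FASTA headers may carry a multiplicity as `>id_xN` or
#' `>id count=N`; reads without a token count once.  FASTQ qualities are
#' ignored.  Sequences are uppercased with U normalized to T.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return `data.frame` with columns `read_id`, `seq`, `count`.
#' @export
read_reads_fasta <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  ss <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop(sprintf("malformed %s file '%s': %s",
                                     format, path, conditionMessage(e)),
                             call. = FALSE))
  seqs <- normalize_seq(as.character(ss))
  check_nucleotides(seqs, sprintf("reads in '%s'", path))
  headers <- names(ss)
  data.frame(
    read_id = sub("\\s.*$", "", headers),
    seq = unname(seqs),
    count = parse_header_count(headers),
    stringsAsFactors = FALSE
  )
}

#' Write collapsed reads as FASTA
#'
#' One record per unique sequence with the count encoded in the header
#' (`>idx_xN` convention).
#'
#' @param reads `data.frame` with columns `seq` and `count` (and
#'   optionally `read_id`).
#' @param path Output path.
#' @export
write_collapsed_fasta <- function(reads, path) {
  ids <- if ("read_id" %in% names(reads)) reads$read_id else
    sprintf("r%d", seq_len(nrow(reads)))
  cnt <- if ("count" %in% names(reads)) reads$count else rep(1, nrow(reads))
  lines <- as.vector(rbind(sprintf(">%s_x%g", ids, cnt), reads$seq))
  writeLines(lines, path)
  invisible(path)
}

#' Read hairpin annotations from GFF3
#'
#' Expects `miRNA_primary_transcript` features for hairpins and `miRNA`
#' features for mature arms, linked by `Parent` (miRBase dialect, 1-based
#' inclusive coordinates).  Coordinates are converted to the internal
#' 0-based half-open convention and arms are assigned 5p/3p by their
#' position in hairpin 5'->3' orientation (strand-aware): on the minus
#' strand the higher-coordinate mature is the 5p arm.
#'
#' @param path Path to a GFF3 file.
#' @return A hairpin annotation `data.frame` (see [hairpin_set()]).
#' @export
read_gff3_hairpins <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  hp <- gr[type == "miRNA_primary_transcript"]
  mat <- gr[type == "miRNA"]
  if (length(hp) == 0L)
    stop("no miRNA_primary_transcript features in ", path, call. = FALSE)
  hp_id <- as.character(hp$ID)
  if (anyNA(hp_id) || anyDuplicated(hp_id))
    stop("hairpin features must carry unique ID attributes", call. = FALSE)

  df <- data.frame(
    hairpin_id = hp_id,
    scaffold = as.character(GenomicRanges::seqnames(hp)),
    strand = as.character(GenomicRanges::strand(hp)),
    start = GenomicRanges::start(hp) - 1L,   # 1-based incl -> 0-based half-open
    end = GenomicRanges::end(hp),
    arm5p_start = NA_integer_, arm5p_end = NA_integer_,
    arm3p_start = NA_integer_, arm3p_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (any(df$strand == "*"))
    stop("hairpin features must be stranded (+/-)", call. = FALSE)

  parents <- vapply(seq_along(mat), function(i) {
    p <- mat$Parent[[i]]
    if (length(p) != 1L || is.na(p))
      stop("mature miRNA feature without a single Parent hairpin (feature ",
           i, ")", call. = FALSE)
    as.character(p)
  }, "")
  if (!all(parents %in% hp_id))
    stop("mature miRNA feature with Parent not matching any hairpin: ",
         paste(unique(setdiff(parents, hp_id)), collapse = ", "),
         call. = FALSE)

  for (id in hp_id) {
    k <- which(parents == id)
    if (length(k) == 0L) next
    if (length(k) > 2L)
      stop("hairpin ", id, " has more than two mature arms", call. = FALSE)
    row <- which(df$hairpin_id == id)
    ms <- GenomicRanges::start(mat)[k] - 1L
    me <- GenomicRanges::end(mat)[k]
    if (length(k) == 2L) {
      o <- order(ms)
      if (ms[o[2]] < me[o[1]])
        stop("mature arms overlap within hairpin ", id, call. = FALSE)
      # genomic-left mature is 5p on '+', 3p on '-'
      if (df$strand[row] == "+") {
        df$arm5p_start[row] <- ms[o[1]]; df$arm5p_end[row] <- me[o[1]]
        df$arm3p_start[row] <- ms[o[2]]; df$arm3p_end[row] <- me[o[2]]
      } else {
        df$arm5p_start[row] <- ms[o[2]]; df$arm5p_end[row] <- me[o[2]]
        df$arm3p_start[row] <- ms[o[1]]; df$arm3p_end[row] <- me[o[1]]
      }
    } else {
      arm <- infer_single_arm(mat[k], df[row, ])
      df[[paste0("arm", arm, "_start")]][row] <- ms
      df[[paste0("arm", arm, "_end")]][row] <- me
    }
  }
  hairpin_set(df)
}

# one annotated mature: use a -5p/-3p Name suffix when present, else the
# hairpin-oriented midpoint rule
infer_single_arm <- function(m, hp_row) {
  nm <- if (!is.null(m$Name)) as.character(m$Name) else NA_character_
  if (!is.na(nm) && grepl("-5p$", nm)) return("5p")
  if (!is.na(nm) && grepl("-3p$", nm)) return("3p")
  mid_hp <- (hp_row$start + hp_row$end) / 2
  mid_m <- (GenomicRanges::start(m) - 1L + GenomicRanges::end(m)) / 2
  left <- mid_m < mid_hp
  if (hp_row$strand == "+") (if (left) "5p" else "3p") else (if (left) "3p" else "5p")
}

#' Construct/validate a hairpin annotation table
#'
#' Internal coordinates are 0-based half-open.  Invariants enforced: arms
#' lie within the hairpin span, the 5p arm strictly precedes the 3p arm in
#' hairpin 5'->3' orientation, arms do not overlap, and at least one arm
#' is present.
#'
#' @param df `data.frame` with columns `hairpin_id`, `scaffold`, `strand`,
#'   `start`, `end`, `arm5p_start`, `arm5p_end`, `arm3p_start`,
#'   `arm3p_end` (arm columns may be `NA` when an arm is absent).
#' @return The validated `data.frame`.
#' @export
hairpin_set <- function(df) {
  need <- c("hairpin_id", "scaffold", "strand", "start", "end",
            "arm5p_start", "arm5p_end", "arm3p_start", "arm3p_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(df$hairpin_id)) stop("hairpin_id must be unique", call. = FALSE)
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -", call. = FALSE)
  if (any(df$end <= df$start)) stop("hairpin span must be non-empty", call. = FALSE)
  has5 <- !is.na(df$arm5p_start)
  has3 <- !is.na(df$arm3p_start)
  if (any(!has5 & !has3))
    stop("every hairpin needs at least one mature arm", call. = FALSE)
  for (i in seq_len(nrow(df))) {
    for (arm in c("5p", "3p")) {
      s <- df[[paste0("arm", arm, "_start")]][i]
      e <- df[[paste0("arm", arm, "_end")]][i]
      if (is.na(s)) next
      if (e <= s || s < df$start[i] || e > df$end[i])
        stop("arm ", arm, " outside hairpin span for ", df$hairpin_id[i],
             call. = FALSE)
    }
    if (has5[i] && has3[i]) {
      # in hairpin orientation 5p must strictly precede 3p
      if (df$strand[i] == "+") {
        ok <- df$arm5p_end[i] <= df$arm3p_start[i]
      } else {
        ok <- df$arm3p_end[i] <= df$arm5p_start[i]
      }
      if (!ok) stop("arms overlap or are mis-ordered for ", df$hairpin_id[i],
                    call. = FALSE)
    }
  }
  class(df) <- c("hairpin_set", "data.frame")
  df
}

#' Write hairpin annotations as GFF3
#'
#' Inverse of [read_gff3_hairpins()]: internal 0-based half-open
#' coordinates are converted back to GFF3 1-based inclusive; arm features
#' are named `<hairpin_id>-5p`/`-3p` and linked to their hairpin via
#' `Parent`.
#'
#' @param hairpins Hairpin annotation table.
#' @param path Output path.
#' @export
write_gff3_hairpins <- function(hairpins, path) {
  rows <- list()
  for (i in seq_len(nrow(hairpins))) {
    h <- hairpins[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = h$scaffold, start = h$start + 1L, end = h$end,
      strand = h$strand, type = "miRNA_primary_transcript",
      ID = h$hairpin_id, Name = h$hairpin_id, Parent = NA_character_)
    for (arm in c("5p", "3p")) {
      s <- h[[paste0("arm", arm, "_start")]]
      if (is.na(s)) next
      e <- h[[paste0("arm", arm, "_end")]]
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = h$scaffold, start = s + 1L, end = e,
        strand = h$strand, type = "miRNA",
        ID = paste0(h$hairpin_id, "-", arm),
        Name = paste0(h$hairpin_id, "-", arm),
        Parent = h$hairpin_id)
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqnames,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand)
  gr$type <- tab$type
  gr$ID <- tab$ID
  gr$Name <- tab$Name
  gr$Parent <- S4Vectors::unname(IRanges::CharacterList(
    lapply(tab$Parent, function(p) if (is.na(p)) character(0) else p)))
  gr$source <- "mirnaome"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read pre-computed alignments from SAM
#'
#' Unmapped records are dropped (with a message giving the count) and
#' edits are reconstructed against the genome by walking the CIGAR.
#' Soft-clipped bases are preserved: a 3'-end clip is retained as a
#' candidate non-template tail for the classifier rather than discarded.
#'
#' @param path Path to a SAM file (with `@SQ` headers).
#' @param genome Genome as returned by [read_genome_fasta()].
#' @return `data.frame` with one row per mapped record: `read_id`, `seq`,
#'   `scaffold`, `strand`, `start`, `end` (0-based half-open genomic),
#'   `n_mismatch`, `edits` (semicolon-separated `pos0:op:base` tokens),
#'   `clip5`, `clip3` (clipped base strings, query orientation).
#' @export
read_sam_alignments <- function(path, genome) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "strand",
                                        "pos", "cigar", "seq"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  unmapped <- bitwAnd(rec$flag, 4L) != 0L
  if (any(unmapped))
    message(sum(unmapped), " unmapped record(s) dropped")
  keep <- which(!unmapped)
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    scaf <- as.character(rec$rname[i])
    if (is.na(scaf) || !scaf %in% names(genome))
      stop("alignment references absent scaffold: ", scaf, call. = FALSE)
    out[[k]] <- cigar_walk(
      qname = rec$qname[i], seq = as.character(rec$seq[i]),
      scaffold = scaf, strand = as.character(rec$strand[i]),
      pos1 = rec$pos[i], cigar = rec$cigar[i], ref = genome[[scaf]])
  }
  do.call(rbind, out)
}

# reconstruct edits from CIGAR + genome comparison (M/=/X compared
# base-by-base; MD tag not required)
cigar_walk <- function(qname, seq, scaffold, strand, pos1, cigar, ref) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("[0-9]+", "", ops)
  rpos <- pos1 - 1L  # 0-based ref cursor
  qpos <- 0L         # 0-based query cursor
  edits <- character(0)
  n_mm <- 0L
  clip5 <- ""; clip3 <- ""
  for (j in seq_along(op)) {
    len <- n[j]
    switch(op[j],
      "M" = , "=" = , "X" = {
        qb <- substring(seq, qpos + 1L, qpos + len)
        rb <- seq_slice(ref, rpos, rpos + len)
        d <- which(strsplit(qb, "")[[1]] != strsplit(rb, "")[[1]])
        for (x in d) {
          edits <- c(edits, sprintf("%d:mismatch:%s", rpos + x - 1L,
                                    substring(qb, x, x)))
        }
        n_mm <- n_mm + length(d)
        rpos <- rpos + len; qpos <- qpos + len
      },
      "I" = {
        edits <- c(edits, sprintf("%d:insertion:%s", rpos,
                                  substring(seq, qpos + 1L, qpos + len)))
        qpos <- qpos + len
      },
      "D" = , "N" = {
        edits <- c(edits, sprintf("%d:deletion:%s", rpos,
                                  seq_slice(ref, rpos, rpos + len)))
        rpos <- rpos + len
      },
      "S" = {
        if (qpos == 0L) clip5 <- substring(seq, 1L, len)
        else clip3 <- substring(seq, qpos + 1L, qpos + len)
        qpos <- qpos + len
      },
      "H" = NULL,
      "P" = NULL
    )
  }
  data.frame(read_id = qname, seq = seq, scaffold = scaffold, strand = strand,
             start = pos1 - 1L, end = rpos, n_mismatch = n_mm,
             edits = paste(edits, collapse = ";"),
             clip5 = clip5, clip3 = clip3, stringsAsFactors = FALSE)
}
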