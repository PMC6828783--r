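# Read preprocessing: the length window applied to adapter-clipped clean
# reads, and collapsing of duplicate sequences into per-library counts.

#' Preprocessing parameters
#'
#' @param min_len,max_len Length window in nt (defaults 17 and 30, the
#'   conventional small-RNA window retaining miRNA-sized reads).
#' @return List with class `preprocess_params`.
#' @export
preprocess_params <- function(min_len = 17L, max_len = 30L) {
  stopifnot(is_count(min_len), is_count(max_len),
            min_len >= 1, min_len <= max_len)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "preprocess_params")
}

#' Length-filter reads
#'
#' Keeps reads whose length lies within `[min_len, max_len]`.  Stats are
#' count-weighted: a collapsed read with count 12 contributes 12 to the
#' totals.
#'
#' @param reads `data.frame` with columns `seq` and `count`.
#' @param params [preprocess_params()].
#' @return List with `kept` (the filtered `data.frame`) and `stats`
#'   (`n_in`, `n_kept`, count-weighted).
#' @export
length_filter <- function(reads, params = preprocess_params()) {
  if (nrow(reads) == 0L) {
    return(list(kept = reads, stats = c(n_in = 0, n_kept = 0)))
  }
  len <- nchar(reads$seq)
  keep <- len >= params$min_len & len <= params$max_len
  list(
    kept = reads[keep, , drop = FALSE],
    stats = c(n_in = sum(reads$count), n_kept = sum(reads$count[keep]))
  )
}

#' Collapse raw reads into unique sequences with per-library counts
#'
#' @param sequences Character vector of (normalized) read sequences, or a
#'   `data.frame` with columns `seq` and `count`.
#' @param library Library identifier for this batch.
#' @return `data.frame` with columns `seq` and one count column named
#'   after the library.
#' @export
collapse_reads <- function(sequences, library) {
  stopifnot(is.character(library), length(library) == 1L)
  if (is.data.frame(sequences)) {
    seqs <- sequences$seq
    cnt <- sequences$count
  } else {
    seqs <- sequences
    cnt <- rep(1, length(sequences))
  }
  seqs <- normalize_seq(seqs)
  tot <- tapply(cnt, seqs, sum)
  out <- data.frame(seq = names(tot), stringsAsFactors = FALSE)
  out[[library]] <- as.numeric(tot)
  rownames(out) <- NULL
  out
}

#' Merge per-library collapsed reads into one table
#'
#' @param ... Collapsed-read `data.frame`s from [collapse_reads()], one
#'   per library (distinct library names).
#' @return `data.frame` with `read_id`, `seq` and one count column per
#'   library (0 where a sequence is absent from a library).
#' @export
merge_read_libraries <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))
    tabs <- tabs[[1]]
  libs <- unlist(lapply(tabs, function(t) setdiff(names(t), "seq")))
  if (anyDuplicated(libs)) stop("duplicate library names", call. = FALSE)
  seqs <- sort(unique(unlist(lapply(tabs, `[[`, "seq"))))
  out <- data.frame(read_id = sprintf("r%d", seq_along(seqs)), seq = seqs,
                    stringsAsFactors = FALSE)
  for (t in tabs) {
    lib <- setdiff(names(t), "seq")
    v <- setNames(rep(0, length(seqs)), seqs)
    v[t$seq] <- t[[lib]]
    out[[lib]] <- unname(v)
  }
  out
}
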