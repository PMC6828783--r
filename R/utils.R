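# Shared low-level helpers.  All internal coordinates in this package are
# 0-based half-open; GFF3 (1-based inclusive) is converted at the I/O
# boundary only.

# round half up to `digits` decimals (base round() is round-half-even,
# which does not reproduce the one-decimal percentages used in report
# tables)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# DNA -> RNA display (reports print U, computation uses T)
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

# RNA/DNA input normalization: uppercase, U -> T
normalize_seq <- function(x) chartr("Uu", "TT", toupper(x))

check_nucleotides <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT/U characters (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring by 0-based half-open interval
seq_slice <- function(seq, start0, end0) {
  substr(seq, start0 + 1L, end0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0
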