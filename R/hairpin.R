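# Hairpin locus extraction.  Every downstream computation (alignment,
# classification, folding) runs in "locus coordinates": 0-based positions
# along the padded hairpin sequence written in hairpin 5'->3' orientation.
# Minus-strand hairpins are reverse-complemented at extraction, which
# makes the classifier strand-agnostic by construction.

#' Extract padded, oriented hairpin loci
#'
#' For each annotated hairpin, extracts the genomic span padded by
#' `pad` nt on each side (clipped at scaffold boundaries) as a sequence in
#' hairpin 5'->3' orientation, and maps the mature-arm intervals into
#' locus coordinates.  The padding gives offset reads (moRs) room to land.
#'
#' @param hairpins Hairpin annotation table ([hairpin_set()]).
#' @param genome Genome (named character vector).
#' @param pad Flanking margin in nt (default 30).
#' @return `data.frame` with one row per hairpin: locus sequence `seq`,
#'   padded genomic interval `pstart`/`pend`, and arm/loop intervals
#'   `a5s`,`a5e`,`a3s`,`a3e`,`loop_s`,`loop_e` in locus coordinates
#'   (`NA` when an arm is absent).
#' @export
hairpin_loci <- function(hairpins, genome, pad = 30L) {
  stopifnot(pad >= 0L)
  n <- nrow(hairpins)
  if (n == 0L) {
    return(data.frame(hairpin_id = character(0), scaffold = character(0),
                      strand = character(0), pstart = integer(0),
                      pend = integer(0), seq = character(0),
                      a5s = integer(0), a5e = integer(0), a3s = integer(0),
                      a3e = integer(0), loop_s = integer(0),
                      loop_e = integer(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    hairpin_id = hairpins$hairpin_id,
    scaffold = hairpins$scaffold,
    strand = hairpins$strand,
    pstart = NA_integer_, pend = NA_integer_,
    seq = NA_character_,
    a5s = NA_integer_, a5e = NA_integer_,
    a3s = NA_integer_, a3e = NA_integer_,
    loop_s = NA_integer_, loop_e = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    h <- hairpins[i, ]
    if (!h$scaffold %in% names(genome))
      stop("hairpin ", h$hairpin_id, " on unknown scaffold ", h$scaffold,
           call. = FALSE)
    slen <- nchar(genome[[h$scaffold]])
    ps <- max(0L, h$start - pad)
    pe <- min(slen, h$end + pad)
    s <- seq_slice(genome[[h$scaffold]], ps, pe)
    if (h$strand == "-") s <- revcomp(s)
    out$pstart[i] <- ps; out$pend[i] <- pe; out$seq[i] <- s
    g2l <- function(gs, ge) {
      if (h$strand == "+") c(gs - ps, ge - ps) else c(pe - ge, pe - gs)
    }
    if (!is.na(h$arm5p_start)) {
      v <- g2l(h$arm5p_start, h$arm5p_end)
      out$a5s[i] <- v[1]; out$a5e[i] <- v[2]
    }
    if (!is.na(h$arm3p_start)) {
      v <- g2l(h$arm3p_start, h$arm3p_end)
      out$a3s[i] <- v[1]; out$a3e[i] <- v[2]
    }
    if (!is.na(out$a5e[i]) && !is.na(out$a3s[i])) {
      out$loop_s[i] <- out$a5e[i]
      out$loop_e[i] <- out$a3s[i]
    }
  }
  out
}

# locus coords -> genomic 0-based half-open interval
locus_to_genomic <- function(locus_row, lstart, lend) {
  if (locus_row$strand == "+") {
    c(locus_row$pstart + lstart, locus_row$pstart + lend)
  } else {
    c(locus_row$pend - lend, locus_row$pend - lstart)
  }
}
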