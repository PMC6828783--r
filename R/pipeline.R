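# End-to-end orchestration and the read-accounting summary.

#' Summarize read handling across pipeline stages
#'
#' Computes the stage-to-stage retention percentages of the standard
#' accounting table: trimming retention (% of clean reads), mapping rate
#' (% of trimmed reads) and annotation rate (% of mapped reads).
#' Percentages are reported to one decimal, round-half-up.
#'
#' @param stages `data.frame` with columns `library`, `raw_reads`,
#'   `clean_reads`, `trimmed_17_30`, `mapped`, `annotated` (counts,
#'   non-increasing along the chain).
#' @return The input with `pct_trimmed`, `pct_mapped`, `pct_annotated`
#'   columns appended.
#' @export
summarize_pipeline <- function(stages) {
  need <- c("library", "raw_reads", "clean_reads", "trimmed_17_30",
            "mapped", "annotated")
  miss <- setdiff(need, names(stages))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  chain <- c("raw_reads", "clean_reads", "trimmed_17_30", "mapped",
             "annotated")
  for (i in seq_len(length(chain) - 1L)) {
    bad <- stages[[chain[i + 1L]]] > stages[[chain[i]]]
    if (any(bad))
      stop(chain[i + 1L], " exceeds ", chain[i], " for library ",
           paste(stages$library[bad], collapse = ", "), call. = FALSE)
  }
  pct <- function(num, den) ifelse(den > 0, round_half_up(100 * num / den, 1),
                                   NA_real_)
  stages$pct_trimmed <- pct(stages$trimmed_17_30, stages$clean_reads)
  stages$pct_mapped <- pct(stages$mapped, stages$trimmed_17_30)
  stages$pct_annotated <- pct(stages$annotated, stages$mapped)
  stages
}

#' Run the whole pipeline
#'
#' Executes simulate (optional) -> length filter -> locus alignment ->
#' classification -> expression summaries -> normalization/clustering ->
#' genomic clusters -> novel-candidate screen, and optionally writes all
#' result tables plus a run manifest to `out_dir`.
#'
#' @param config List with either `simulate` (a [sim_config()]) or
#'   `genome`/`hairpins`/`reads` paths (`reads` = named list
#'   library -> FASTA); optional `preprocess`, `align`, `classifier`,
#'   `arm`, `cluster`, `novel` parameter objects, `cluster_profiles`
#'   (`"normalized"` or `"raw"`), and `out_dir`.
#' @param seed Seed recorded in the manifest and used for any policy
#'   randomness (overrides `align$rng_seed`).
#' @return Object of class `mirnaome_run` with all intermediate and
#'   final tables.
#' @export
run_pipeline <- function(config, seed = 1L) {
  t0 <- Sys.time()
  p_pre <- config$preprocess %||% preprocess_params()
  p_aln <- config$align %||% align_params()
  p_cls <- config$classifier %||% classifier_params()
  p_arm <- config$arm %||% arm_params()
  p_clu <- config$cluster %||% cluster_params()
  p_nov <- config$novel %||% novel_params()
  p_aln$rng_seed <- as.integer(seed)
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  sim <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_mirnaome(config$simulate)
    genome <- sim$genome
    hairpins <- sim$hairpins
    reads <- sim$reads
    say("simulate: %d hairpins, %d unique reads, %d dropped for collisions",
        nrow(hairpins), nrow(reads), sim$n_dropped)
  } else {
    if (is.null(config$genome) || is.null(config$hairpins) ||
        is.null(config$reads))
      stop("config needs either a 'simulate' block or genome/hairpins/reads",
           call. = FALSE)
    genome <- read_genome_fasta(config$genome)
    hairpins <- read_gff3_hairpins(config$hairpins)
    tabs <- lapply(names(config$reads), function(lib) {
      r <- read_reads_fasta(config$reads[[lib]])
      collapse_reads(r[c("seq", "count")], lib)
    })
    reads <- merge_read_libraries(tabs)
    say("load: %d hairpins, %d unique reads", nrow(hairpins), nrow(reads))
  }
  libs <- setdiff(names(reads), c("read_id", "seq"))

  # preprocess
  len <- nchar(reads$seq)
  keep <- len >= p_pre$min_len & len <= p_pre$max_len
  clean_tot <- colSums(as.matrix(reads[, libs, drop = FALSE]))
  trimmed_tot <- colSums(as.matrix(reads[keep, libs, drop = FALSE]))
  reads_f <- reads[keep, , drop = FALSE]
  say("length filter %d-%d nt: %d of %d unique reads kept",
      p_pre$min_len, p_pre$max_len, nrow(reads_f), nrow(reads))

  # align + assign
  loci <- hairpin_loci(hairpins, genome, pad = p_aln$pad)
  al <- align_reads(reads_f, genome, hairpins, p_aln, loci = loci)
  assignments <- resolve_multimappers(al$alignments, reads_f, p_aln)
  mapped_tot <- colSums(as.matrix(assignments[, libs, drop = FALSE]))
  say("align: %d reads placed, %d unaligned",
      length(unique(al$alignments$read_id)), length(al$unaligned))

  # classify
  cls <- classify_assignments(assignments, loci, p_cls)
  classes <- cls$classes
  annotated_tot <- vapply(libs, function(lb)
    sum(classes[[lb]][classes$label != "OTHER"]), 0)

  # expression
  counts <- hairpin_count_matrix(classes, libs)
  sf <- tryCatch(size_factors(counts), error = function(e) {
    say("size factors unavailable (%s); using 1.0", conditionMessage(e))
    setNames(rep(1, length(libs)), libs)
  })
  norm <- normalize_counts(counts, sf)
  arms <- arm_summary(classes, p_arm)
  switching <- detect_arm_switching(arms)
  ratios <- isomir_ratios(classes, cls$eligible)
  profiles <- if (identical(config$cluster_profiles, "raw")) counts else norm
  expr_clust <- if (nrow(profiles) >= 2L) pearson_upgma(profiles) else NULL

  # genome features
  gclusters <- find_clusters(hairpins, p_clu)
  novel <- novel_screen(assignments, loci, libs, p_nov)

  stages <- data.frame(
    library = libs,
    raw_reads = unname(clean_tot), clean_reads = unname(clean_tot),
    trimmed_17_30 = unname(trimmed_tot), mapped = unname(mapped_tot),
    annotated = unname(annotated_tot), stringsAsFactors = FALSE)
  summary_tab <- summarize_pipeline(stages)

  manifest <- list(
    package = "mirnaome",
    version = as.character(packageVersion("mirnaome")),
    seed = as.integer(seed),
    params = list(preprocess = unclass(p_pre), align = unclass(p_aln),
                  classifier = unclass(p_cls), arm = unclass(p_arm),
                  cluster = unclass(p_clu), novel = unclass(p_nov)),
    log = log_lines,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- structure(list(
    genome = genome, hairpins = hairpins, loci = loci, reads = reads_f,
    assignments = assignments, classes = classes, eligible = cls$eligible,
    labels = cls$labels, counts = counts, size_factors = sf,
    normalized = norm, arm_summary = arms, switching = switching,
    isomir_ratios = ratios, clustering = expr_clust,
    genomic_clusters = gclusters, novel = novel, summary = summary_tab,
    sim = sim, manifest = manifest), class = "mirnaome_run")

  if (!is.null(config$out_dir)) write_run(res, config$out_dir)
  res
}

# per-hairpin x library totals over all labels
hairpin_count_matrix <- function(classes, libs) {
  hp <- sort(unique(classes$hairpin_id))
  m <- matrix(0, length(hp), length(libs), dimnames = list(hp, libs))
  for (lib in libs) {
    t <- tapply(classes[[lib]], classes$hairpin_id, sum)
    m[names(t), lib] <- t
  }
  m
}

# evaluate every hairpin locus as a novel-style candidate
novel_screen <- function(assignments, loci, libs, params) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    sub <- assignments[assignments$hairpin_id == loci$hairpin_id[i], ,
                       drop = FALSE]
    stack <- data.frame(lstart = sub$lstart, lend = sub$lend,
                        count = rowSums(as.matrix(sub[, libs, drop = FALSE])))
    ev <- tryCatch(
      evaluate_novel_candidate(stack, loci$seq[i], params),
      error = function(e) NULL)
    if (is.null(ev)) next
    rows[[length(rows) + 1L]] <- data.frame(
      hairpin_id = loci$hairpin_id[i], dg = ev$dg,
      fold_pass = ev$fold_pass, reads_pass = ev$reads_pass,
      both_arms = ev$both_arms, overhang = ev$overhang,
      overhang_pass = ev$overhang_pass,
      homogeneity_pass = ev$homogeneity_pass, verdict = ev$verdict,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Write all result tables of a run
#'
#' @param run A `mirnaome_run` object.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name, rn = FALSE) {
    write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = rn, col.names = TRUE)
  }
  wt(run$classes, "classes.tsv")
  wt(run$arm_summary, "arm_summary.tsv")
  wt(run$switching, "switching.tsv")
  wt(run$isomir_ratios$per_hairpin, "isomir_ratios.tsv")
  wt(data.frame(library = names(run$size_factors),
                size_factor = unname(run$size_factors)), "size_factors.tsv")
  wt(run$counts, "counts.tsv", rn = TRUE)
  wt(run$normalized, "normalized_counts.tsv", rn = TRUE)
  wt(run$genomic_clusters, "clusters.tsv")
  write_clusters_bed(run$genomic_clusters, file.path(dir, "clusters.bed"))
  if (!is.null(run$novel)) wt(run$novel, "novel.tsv")
  wt(run$summary, "pipeline_summary.tsv")
  if (!is.null(run$clustering)) {
    hc <- run$clustering$hclust
    mrg <- hc$merge
    wt(data.frame(step = seq_len(nrow(mrg)), child1 = mrg[, 1],
                  child2 = mrg[, 2], height = hc$height), "linkage.tsv")
    wt(run$clustering$dist, "distance_matrix.tsv", rn = TRUE)
  }
  yaml::write_yaml(run$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.mirnaome_run <- function(x, ...) {
  cat("miRNAome pipeline run\n")
  cat(sprintf("  hairpins: %d   unique reads: %d   libraries: %s\n",
              nrow(x$hairpins), nrow(x$reads),
              paste(colnames(x$counts), collapse = ", ")))
  cat(sprintf("  genomic clusters: %d   novel verdicts: %s\n",
              nrow(x$genomic_clusters),
              if (is.null(x$novel)) "none" else
                paste(names(table(x$novel$verdict)),
                      table(x$novel$verdict), sep = ":", collapse = " ")))
  cat("read accounting:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mirnaome_run <- function(object, ...) {
  list(summary = object$summary,
       size_factors = object$size_factors,
       isomir_means = object$isomir_ratios$means,
       switching = object$switching[object$switching$switching, ,
                                    drop = FALSE])
}

#' Bundled example read-accounting table
#'
#' Read-processing totals for three life-stage libraries (juvenile,
#' subadult, adult) of a *Daphnia magna* small-RNA study: raw reads,
#' adapter-clean reads, reads retained by the 17-30-nt window, reads
#' mapped to the genome, and mapped reads annotated to miRNA loci.
#'
#' @return `data.frame` in the [summarize_pipeline()] input layout.
#' @export
dmagna_read_processing <- function() {
  read.delim(system.file("extdata", "dmagna_read_processing.tsv",
                         package = "mirnaome"), stringsAsFactors = FALSE)
}

#' Bundled mature/isomiR worked examples
#'
#' Curated *D. magna* mature-miRNA/isomiR sequence pairs (RNA alphabet)
#' with the expected template class of each variant, for classifier
#' validation: the variant is planted next to its mature sequence in a
#' constructed genome and must classify into the stated group.
#'
#' @return `data.frame` with `mirna`, `mature_seq`, `variant_seq`,
#'   `expected_class`.
#' @export
dmagna_isomir_examples <- function() {
  read.delim(system.file("extdata", "dmagna_isomir_examples.tsv",
                         package = "mirnaome"), stringsAsFactors = FALSE)
}

#' Bundled novel mature miRNA sequences
#'
#' Curated novel *D. magna* mature miRNA sequences (RNA alphabet) with
#' their published lengths in nt.
#'
#' @return `data.frame` with `mirna`, `mature_seq`, `length_nt`.
#' @export
dmagna_novel_mirnas <- function() {
  read.delim(system.file("extdata", "dmagna_novel_mirnas.tsv",
                         package = "mirnaome"), stringsAsFactors = FALSE)
}
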