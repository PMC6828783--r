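# Fixtures are built in code: a deterministic single-hairpin locus for
# classifier tests, plus naive re-implementations used as oracles.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one '+'-strand hairpin: 30-nt flank | arm5 (21) | loop (12) | arm3 (21)
# | 30-nt flank, with known locus coordinates
toy_hairpin <- function(seed = 42, arm5_len = 21, loop_len = 12,
                        arm3_len = 21, flank = 40) {
  set.seed(seed)
  scaf <- rand_seq(flank + arm5_len + loop_len + arm3_len + flank)
  hp <- hairpin_set(data.frame(
    hairpin_id = "hp1", scaffold = "s1", strand = "+",
    start = flank - 5L, end = flank + arm5_len + loop_len + arm3_len + 5L,
    arm5p_start = flank, arm5p_end = flank + arm5_len,
    arm3p_start = flank + arm5_len + loop_len,
    arm3p_end = flank + arm5_len + loop_len + arm3_len,
    stringsAsFactors = FALSE))
  genome <- as_genome(c(s1 = scaf))
  loci <- hairpin_loci(hp, genome, pad = 30L)
  list(genome = genome, hairpins = hp, loci = loci, locus = loci[1, ])
}

# slice of a locus sequence by 0-based half-open coordinates
lslice <- function(locus, s, e) substr(locus$seq, s + 1L, e)

# naive ungapped placement oracle: enumerate every offset, cost = 2 * mm,
# keep offsets passing the identity filter at minimum cost
naive_ungapped <- function(read, ctx, similarity = 0.8) {
  m <- nchar(read)
  L <- nchar(ctx)
  if (m > L) return(NULL)
  rb <- strsplit(read, "")[[1]]
  res <- data.frame(lstart = integer(0), cost = numeric(0))
  for (s in 0:(L - m)) {
    fb <- strsplit(substr(ctx, s + 1L, s + m), "")[[1]]
    mm <- sum(rb != fb)
    if ((m - mm) / m >= similarity)
      res <- rbind(res, data.frame(lstart = s, cost = 2 * mm))
  }
  if (nrow(res) == 0L) return(NULL)
  res[abs(res$cost - min(res$cost)) < 1e-9, , drop = FALSE]
}

# brute-force UPGMA returning the cophenetic distance matrix
naive_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  dm <- d
  coph <- matrix(0, n, n)
  while (length(active) > 1L) {
    k <- length(active)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      # unweighted average linkage over original members
      dd <- mean(d[active[[i]], active[[j]]])
      if (dd < best[1] - 1e-12) best <- c(dd, i, j)
    }
    i <- best[2]; j <- best[3]
    coph[active[[i]], active[[j]]] <- best[1]
    coph[active[[j]], active[[i]]] <- best[1]
    merged <- c(active[[i]], active[[j]])
    active <- active[-c(i, j)]
    active[[length(active) + 1L]] <- merged
  }
  coph
}

# connected components of the pairwise within-gap relation on intervals
naive_interval_components <- function(starts, ends, max_gap) {
  n <- length(starts)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    gap <- max(starts[i], starts[j]) - min(ends[i], ends[j])
    adj[i, j] <- gap <= max_gap
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# default small simulation shared by several tests
small_sim <- function(seed = 7, ...) {
  simulate_mirnaome(sim_config(n_hairpins = 5, count_mean = 80,
                               rng_seed = seed, ...))
}

# run the alignment+classification path on a simulation
classify_sim <- function(sim, params = align_params()) {
  al <- align_reads(sim$reads, sim$genome, sim$hairpins, params,
                    loci = sim$loci)
  asg <- resolve_multimappers(al$alignments, sim$reads, params)
  cls <- classify_assignments(asg, sim$loci)
  list(alignments = al, assignments = asg, classes = cls)
}
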