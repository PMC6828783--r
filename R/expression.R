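# Arm-level expression logic, median-of-ratios normalization, isomiR
# class ratios, and Pearson/average-linkage clustering of expression
# profiles.

#' Arm-dominance parameters
#'
#' @param guide_majority_fraction Fraction of the 5p+3p total an arm must
#'   strictly exceed to be called the guide arm (default 0.5).
#' @param coexpression_ratio_max Arms count as co-expressed when
#'   dominant/minor count ratio is strictly below this (default 2).
#' @return List with class `arm_params`.
#' @export
arm_params <- function(guide_majority_fraction = 0.5,
                       coexpression_ratio_max = 2) {
  stopifnot(guide_majority_fraction > 0, guide_majority_fraction < 1,
            coexpression_ratio_max > 1)
  structure(list(guide_majority_fraction = guide_majority_fraction,
                 coexpression_ratio_max = coexpression_ratio_max),
            class = "arm_params")
}

#' Median-of-ratios size factors
#'
#' The library scale factor is the median, over hairpins with a positive
#' geometric mean across libraries, of the ratio of that hairpin's count
#' to its geometric mean.  Rows containing a zero are excluded from the
#' median.  This is the estimator behind `estimateSizeFactors` in
#' standard count-normalization workflows.
#'
#' Size factors are defined only up to a common scale (normalization
#' divides every library by its factor, so only ratios matter); the
#' returned factors follow the geometric-mean-1 convention, which makes
#' re-estimating factors from an already-normalized matrix return
#' exactly 1 for every library.
#'
#' @param counts Numeric matrix, hairpins x libraries.
#' @return Named numeric vector of positive per-library factors with
#'   geometric mean 1.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L || nrow(counts) < 1L)
    stop("counts must be a non-empty matrix", call. = FALSE)
  log_geo <- rowMeans(log(counts))
  ok <- is.finite(log_geo)
  if (!any(ok))
    stop("no hairpin has all-positive counts across libraries; add a ",
         "pseudo-count before calling size_factors", call. = FALSE)
  log_sf <- apply(counts, 2L, function(col) {
    median(log(col[ok]) - log_geo[ok])
  })
  sf <- exp(log_sf - mean(log_sf))
  names(sf) <- colnames(counts)
  sf
}

#' Normalize counts by size factors
#'
#' @param counts Numeric matrix, hairpins x libraries.
#' @param factors Output of [size_factors()] (recomputed when omitted).
#' @return Matrix of normalized counts (`counts[, j] / factors[j]`).
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  sweep(counts, 2L, factors, "/")
}

# arm totals (mature + isomiR classes; moR/loR/OTHER reported separately)
# per hairpin x arm x library from a class table
arm_counts <- function(classes, libs) {
  sel <- classes$label %in% ARM_CLASSES & classes$arm %in% c("5p", "3p")
  cl <- classes[sel, , drop = FALSE]
  hp <- sort(unique(classes$hairpin_id))
  out <- list()
  for (a in c("5p", "3p")) {
    m <- matrix(0, length(hp), length(libs), dimnames = list(hp, libs))
    sub <- cl[cl$arm == a, , drop = FALSE]
    for (lib in libs) {
      t <- tapply(sub[[lib]], sub$hairpin_id, sum)
      m[names(t), lib] <- t
    }
    out[[a]] <- m
  }
  out
}

#' Per-hairpin arm summary (guide arm, dominance, co-expression)
#'
#' Arm totals count mature plus all isomiR labels on that arm; offset and
#' loop reads are excluded.  The guide arm must hold strictly more than
#' `guide_majority_fraction` of the 5p+3p total (an exact tie leaves the
#' guide undefined); arms are co-expressed when the dominant/minor ratio
#' is strictly below `coexpression_ratio_max` (a zero minor arm is never
#' co-expressed).
#'
#' @param classes Class count table (`$classes` from
#'   [classify_assignments()]).
#' @param params [arm_params()].
#' @return `data.frame` with one row per hairpin x library: `count_5p`,
#'   `count_3p`, `guide_arm`, `guide_fraction` (percent), `coexpressed`.
#' @export
arm_summary <- function(classes, params = arm_params()) {
  libs <- setdiff(names(classes), c("hairpin_id", "arm", "label", "seq"))
  ac <- arm_counts(classes, libs)
  hp <- rownames(ac$`5p`)
  rows <- list()
  for (lib in libs) {
    c5 <- ac$`5p`[, lib]; c3 <- ac$`3p`[, lib]
    tot <- c5 + c3
    frac5 <- ifelse(tot > 0, c5 / tot, NA_real_)
    guide <- rep("undefined", length(hp))
    guide[!is.na(frac5) & frac5 > params$guide_majority_fraction] <- "5p"
    guide[!is.na(frac5) & (1 - frac5) > params$guide_majority_fraction] <- "3p"
    gf <- ifelse(guide == "5p", frac5 * 100,
                 ifelse(guide == "3p", (1 - frac5) * 100, NA_real_))
    mn <- pmin(c5, c3); mx <- pmax(c5, c3)
    coex <- mn > 0 & (mx / mn) < params$coexpression_ratio_max
    rows[[lib]] <- data.frame(
      hairpin_id = hp, library = lib, count_5p = unname(c5),
      count_3p = unname(c3), guide_arm = guide,
      guide_fraction = unname(gf), coexpressed = unname(coex),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect arm switching across libraries
#'
#' A hairpin switches arms when its guide (dominant) arm differs between
#' any two libraries in which a guide is defined.
#'
#' @param summaries Output of [arm_summary()].
#' @return `data.frame` with one row per hairpin: per-library dominant
#'   arm columns plus `switching` flag.
#' @export
detect_arm_switching <- function(summaries) {
  libs <- unique(summaries$library)
  hp <- unique(summaries$hairpin_id)
  out <- data.frame(hairpin_id = hp, stringsAsFactors = FALSE)
  for (lib in libs) {
    s <- summaries[summaries$library == lib, ]
    out[[lib]] <- s$guide_arm[match(hp, s$hairpin_id)]
  }
  def <- as.matrix(out[libs])
  out$switching <- apply(def, 1L, function(g) {
    g <- g[g %in% c("5p", "3p")]
    length(unique(g)) > 1L
  })
  out
}

#' Per-hairpin isomiR class fractions and cross-hairpin means
#'
#' For every hairpin passing the strictly-greater read threshold in a
#' library, computes each class's percentage of the 5p+3p arm total
#' (mature + six isomiR classes + OTHER sum to 100).  Cross-hairpin
#' means are unweighted: each hairpin contributes equally.
#'
#' @param classes Class count table.
#' @param eligible Hairpin x library logical matrix from
#'   [classify_assignments()] (all eligible when omitted).
#' @return List with `per_hairpin` (long `data.frame` of fractions) and
#'   `means` (library x class matrix of unweighted mean percentages).
#' @export
isomir_ratios <- function(classes, eligible = NULL) {
  libs <- setdiff(names(classes), c("hairpin_id", "arm", "label", "seq"))
  lab_set <- c(ARM_CLASSES, "OTHER")
  sel <- classes$label %in% lab_set & classes$arm %in% c("5p", "3p")
  cl <- classes[sel, , drop = FALSE]
  rows <- list()
  for (lib in libs) {
    hp_tot <- tapply(cl[[lib]], cl$hairpin_id, sum)
    hps <- names(hp_tot)[hp_tot > 0]
    if (!is.null(eligible)) {
      ok <- rownames(eligible)[eligible[, lib]]
      hps <- intersect(hps, ok)
    }
    for (h in hps) {
      sub <- cl[cl$hairpin_id == h, , drop = FALSE]
      tot <- sum(sub[[lib]])
      fr <- vapply(lab_set, function(lb) {
        100 * sum(sub[[lib]][sub$label == lb]) / tot
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        hairpin_id = h, library = lib, label = lab_set,
        fraction = unname(fr), stringsAsFactors = FALSE)
    }
  }
  per_hairpin <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hairpin_id = character(0), library = character(0),
               label = character(0), fraction = numeric(0))
  means <- matrix(NA_real_, length(libs), length(lab_set),
                  dimnames = list(libs, lab_set))
  for (lib in libs) {
    sub <- per_hairpin[per_hairpin$library == lib, ]
    if (nrow(sub))
      means[lib, ] <- vapply(lab_set, function(lb)
        mean(sub$fraction[sub$label == lb]), 0)
  }
  list(per_hairpin = per_hairpin, means = means)
}

#' Pearson-distance / average-linkage clustering
#'
#' Distance is `1 - r` (Pearson), in `[0, 2]`; agglomeration is
#' unweighted average linkage (UPGMA) via [stats::hclust()].  Rows with
#' zero variance have no defined correlation; their distances are set to
#' the maximum (2) and the rows are flagged.
#'
#' @param profiles Numeric matrix, entities x libraries (>= 2 rows).
#' @return List with `dist` (full distance matrix), `hclust` (the
#'   dendrogram), and `constant_rows` (flagged entity names).
#' @export
pearson_upgma <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L)
    stop("need at least two entities to cluster", call. = FALSE)
  v <- apply(profiles, 1L, stats::var)
  const <- v == 0 | is.na(v)
  r <- suppressWarnings(cor(t(profiles), method = "pearson"))
  d <- 1 - r
  d[is.na(d)] <- 2
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  list(dist = d, hclust = hc,
       constant_rows = rownames(profiles)[const])
}
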