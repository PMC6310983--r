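#' Spearman correlation with t-approximation p-value
#'
#' Shared backend for all correlation results in the package: rank
#' correlation with average ranks for ties, two-sided p-value via the
#' t approximation (\code{stats::cor.test(..., exact = FALSE)}).
#'
#' @param x,y Numeric vectors of equal length.
#' @return A \code{correlation_result}: list with \code{rho},
#'   \code{p_value} and \code{n}.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (p = %.3g, n = %d)\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Correlation between combination divergence and frequency
#'
#' Pools combination counts across species profiles and correlates each of
#' the 256 unambiguous combinations' Hamming distance to the canonical
#' GT-AG with its (pooled) count. The canonical combination itself
#' (distance 0) is included. A negative coefficient means that
#' combinations more diverged from GT-AG are rarer.
#'
#' @param profiles A \code{species_profile} or list of them.
#' @param pool Sum counts across profiles (default TRUE). With
#'   \code{pool = FALSE} each profile is first normalised to frequencies
#'   and the mean frequency per combination is used.
#' @return A \code{correlation_result} (n = 256).
#' @export
divergence_frequency_correlation <- function(profiles, pool = TRUE) {
  profiles <- .as_profile_list(profiles)
  combos <- all_splice_combos()
  mat <- vapply(profiles, function(p) p$counts[combos],
                numeric(length(combos)))
  mat <- matrix(mat, nrow = length(combos))
  if (pool) {
    y <- rowSums(mat)
  } else {
    tot <- colSums(mat)
    if (any(tot == 0)) stop("profile with all-zero counts")
    y <- rowMeans(sweep(mat, 2L, tot, "/"))
  }
  if (all(y == 0)) stop("all pooled counts are zero")
  x <- combo_hamming(combos, "GTAG")
  spearman_correlation(x, y)
}

.as_profile_list <- function(profiles) {
  if (inherits(profiles, "species_profile")) profiles <- list(profiles)
  if (length(profiles) < 1L) stop("need at least one profile")
  stopifnot(all(vapply(profiles, inherits, logical(1), "species_profile")))
  profiles
}

#' Pairwise similarity of species splice-site profiles
#'
#' Spearman correlation over the 256 aligned combination counts for each
#' pair of profiles. The matrix is symmetric with unit diagonal; profiles
#' with zero variance across combinations yield NA entries.
#'
#' @param profiles List of \code{species_profile} objects (>= 2).
#' @return Square numeric matrix with species labels as dimnames.
#' @export
profile_similarity_matrix <- function(profiles) {
  profiles <- .as_profile_list(profiles)
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  combos <- all_splice_combos()
  mat <- vapply(profiles, function(p) p$counts[combos],
                numeric(length(combos)))
  labels <- vapply(profiles, function(p) p$species, character(1))
  labels <- make.unique(labels)
  degenerate <- apply(mat, 2L, function(v) stats::var(v) == 0)
  rho <- suppressWarnings(stats::cor(mat, method = "spearman"))
  rho[degenerate, ] <- NA_real_
  rho[, degenerate] <- NA_real_
  d <- diag(rho)
  d[!degenerate] <- 1
  diag(rho) <- d
  dimnames(rho) <- list(labels, labels)
  rho
}

#' Correlate two per-species count vectors
#'
#' Used e.g. for the relation between the number of non-canonical
#' splice-site combinations and the total number of splice sites per
#' species, or between splice-site counts and genome size.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A \code{correlation_result}.
#' @export
correlate_counts <- function(x, y) spearman_correlation(x, y)

#' Compare intron lengths of a focal gene set against random background
#'
#' Each replicate draws \code{length(focal)} background intron lengths
#' without replacement, runs a two-sided rank-sum (Mann-Whitney/Wilcoxon)
#' test against the focal lengths and records the mean difference
#' (focal - sample). Repetition averages out the random selection.
#'
#' @param focal Numeric vector of intron lengths (non-empty).
#' @param background Numeric vector with at least \code{length(focal)}
#'   values.
#' @param reps Number of replicates (default 100).
#' @param seed Integer seed for the replicate sampling stream.
#' @return A \code{resampling_result}: list with vectors \code{p_values}
#'   and \code{mean_diffs}, scalars \code{median_p},
#'   \code{mean_mean_diff}, \code{reps}, \code{seed}.
#' @export
compare_intron_lengths <- function(focal, background, reps = 100,
                                   seed = 1) {
  if (length(focal) == 0L) stop("focal set is empty")
  if (length(background) < length(focal)) {
    stop("background smaller than focal set")
  }
  p <- numeric(reps)
  md <- numeric(reps)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (r in seq_len(reps)) {
    samp <- sample(background, length(focal), replace = FALSE)
    p[r] <- suppressWarnings(
      stats::wilcox.test(focal, samp, alternative = "two.sided")$p.value)
    md[r] <- mean(focal) - mean(samp)
  }
  structure(list(p_values = p, mean_diffs = md,
                 median_p = stats::median(p),
                 mean_mean_diff = mean(md),
                 reps = reps, seed = seed),
            class = "resampling_result")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(
    "resampling_result: %d reps, median p = %.4g, mean diff = %.2f\n",
    x$reps, x$median_p, x$mean_mean_diff))
  invisible(x)
}

#' Enrichment of minor combinations in long introns
#'
#' Minor non-canonical combinations without ambiguous bases are counted in
#' introns longer than \code{threshold} and compared against their
#' frequency in shorter introns. The enrichment ratio uses Laplace
#' pseudocounts of 1 to stabilise rare combinations. After ranking by this
#' ratio, the base composition of the 4-letter combination is reported per
#' rank so base preferences along the ranking can be inspected.
#'
#' @param introns Intron data.frame from \code{\link{extract_introns}}.
#' @param threshold Length cutoff in nt (default 5000).
#' @param min_length Lower length cutoff applied first (default 20).
#' @return List with \code{table} -- data.frame (rank, combo, count_long,
#'   count_short, proportion_long, proportion_short, ratio, n_A, n_C, n_G,
#'   n_T) sorted by descending ratio with lexicographic tie-break -- and
#'   \code{no_long_introns}, a warning flag.
#' @export
long_intron_enrichment <- function(introns, threshold = 5000,
                                   min_length = 20) {
  introns <- introns[!is.na(introns$combo) &
                       introns$length >= min_length &
                       introns$class == "minor" &
                       !is_ambiguous_combo(introns$combo), , drop = FALSE]
  is_long <- introns$length > threshold
  minors <- setdiff(all_splice_combos(),
                    c("GTAG", .REFERENCE_COMBOS))
  cl <- table(factor(introns$combo[is_long], levels = minors))
  cs <- table(factor(introns$combo[!is_long], levels = minors))
  n_long <- sum(cl); n_short <- sum(cs)
  if (n_long == 0L) {
    warning("no minor-combination introns longer than ", threshold, " nt")
  }
  pl <- (as.integer(cl) + 1) / (n_long + length(minors))
  ps <- (as.integer(cs) + 1) / (n_short + length(minors))
  tab <- data.frame(
    combo = minors,
    count_long = as.integer(cl), count_short = as.integer(cs),
    proportion_long = if (n_long > 0L) as.integer(cl) / n_long else 0,
    proportion_short = if (n_short > 0L) as.integer(cs) / n_short else 0,
    ratio = pl / ps,
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$ratio, tab$combo), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  for (b in c("A", "C", "G", "T")) {
    tab[[paste0("n_", b)]] <-
      lengths(regmatches(tab$combo, gregexpr(b, tab$combo, fixed = TRUE)))
  }
  rownames(tab) <- NULL
  list(table = tab[, c("rank", "combo", "count_long", "count_short",
                       "proportion_long", "proportion_short", "ratio",
                       "n_A", "n_C", "n_G", "n_T")],
       no_long_introns = n_long == 0L)
}

#' Proportion of genes with a non-canonical splice site by intron count
#'
#' For each intron count, the fraction of genes carrying at least one
#' non-canonical splice-site combination; across multiple species the
#' median and quartiles of the per-species proportions are reported.
#'
#' @param gene_summaries data.frame with columns \code{intron_count}
#'   (>= 1), \code{has_noncanonical} (logical) and optionally
#'   \code{species}.
#' @return data.frame with columns intron_count, n_genes, median, q25,
#'   q75, n_species.
#' @export
noncanonical_by_intron_count <- function(gene_summaries) {
  stopifnot(all(c("intron_count", "has_noncanonical") %in%
                  names(gene_summaries)))
  if (any(gene_summaries$intron_count < 1)) {
    stop("intron_count must be >= 1")
  }
  if (is.null(gene_summaries$species)) gene_summaries$species <- "sample"
  per <- stats::aggregate(
    has_noncanonical ~ intron_count + species,
    data = gene_summaries, FUN = mean)
  n_genes <- stats::aggregate(
    has_noncanonical ~ intron_count, data = gene_summaries, FUN = length)
  out <- do.call(rbind, lapply(split(per, per$intron_count), function(d) {
    q <- stats::quantile(d$has_noncanonical, c(0.25, 0.5, 0.75),
                         names = FALSE)
    data.frame(intron_count = d$intron_count[1L],
               median = q[2L], q25 = q[1L], q75 = q[3L],
               n_species = nrow(d))
  }))
  out <- merge(out,
               stats::setNames(n_genes, c("intron_count", "n_genes")),
               by = "intron_count")
  out <- out[order(out$intron_count),
             c("intron_count", "n_genes", "median", "q25", "q75",
               "n_species")]
  rownames(out) <- NULL
  out
}

#' Compare non-canonical proportions between a gene set and the genome
#'
#' Per species, the proportion of genes with non-canonical splice sites in
#' a focal set (e.g. single-copy genes) is compared against the genome-wide
#' proportion with a two-sided Mann-Whitney U test across species.
#'
#' @param per_species data.frame with columns \code{proportion_in_set} and
#'   \code{proportion_overall}, one row per species (>= 3 rows).
#' @return List with \code{p_value}, \code{statistic},
#'   \code{mean_in_set}, \code{mean_overall}, \code{n_species}.
#' @export
compare_gene_sets <- function(per_species) {
  stopifnot(all(c("proportion_in_set", "proportion_overall") %in%
                  names(per_species)))
  if (nrow(per_species) < 3L) stop("need at least 3 species pairs")
  wt <- suppressWarnings(
    stats::wilcox.test(per_species$proportion_in_set,
                       per_species$proportion_overall,
                       alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       mean_in_set = mean(per_species$proportion_in_set),
       mean_overall = mean(per_species$proportion_overall),
       n_species = nrow(per_species))
}
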