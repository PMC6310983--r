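#' Substitution spectrum containers
#'
#' A substitution spectrum holds counts over the 12 ordered single-base
#' substitutions X>Y (X != Y in A,C,G,T); rates are counts normalised to
#' sum to 1.
#'
#' @param counts Named numeric vector; names must be a subset of the 12
#'   categories in \code{"A>C"} notation. Missing categories count 0.
#' @param skipped Optional named counts of skipped records (e.g.
#'   heterozygous, indel, multiallelic).
#' @return An object of class \code{substitution_spectrum} with elements
#'   \code{counts} (full 12-vector), \code{rates} and \code{skipped}.
#' @export
substitution_spectrum <- function(counts = numeric(0), skipped = integer(0)) {
  cats <- substitution_categories()
  full <- stats::setNames(numeric(12L), cats)
  if (length(counts) > 0L) {
    if (is.null(names(counts)) || !all(names(counts) %in% cats)) {
      stop("counts must be named with categories like 'A>G'")
    }
    full[names(counts)] <- counts
  }
  if (any(full < 0)) stop("negative substitution counts")
  tot <- sum(full)
  structure(list(counts = full,
                 rates = if (tot > 0) full / tot else full,
                 total = tot,
                 skipped = skipped),
            class = "substitution_spectrum")
}

#' @rdname substitution_spectrum
#' @export
substitution_categories <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(to = b, from = b, stringsAsFactors = FALSE)
  g <- g[g$from != g$to, ]
  sort(paste0(g$from, ">", g$to))
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat("substitution_spectrum:", x$total, "substitutions\n")
  print(round(x$rates, 4))
  if (length(x$skipped)) {
    cat("skipped:", paste(names(x$skipped), x$skipped, sep = "=",
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Genome-wide substitution spectrum from a VCF
#'
#' Counts homozygous-alternative biallelic SNPs per ordered substitution
#' REF>ALT. Indels, multi-allelic records, heterozygous and missing
#' genotypes are skipped and tallied. With multiple samples a record
#' counts once if its first sample is homozygous alternative.
#'
#' @param path Path to a VCF (v4.x) file.
#' @return A \code{substitution_spectrum}.
#' @export
substitution_spectrum_from_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  gt <- if (ncol(v@gt) >= 2L) {
    vcfR::extract.gt(v, element = "GT")[, 1L]
  } else rep(NA_character_, nrow(fix))

  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  snp <- !multi & !indel & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  hom_alt <- snp & !is.na(gt_clean) & gt_clean %in% c("1/1", "1")
  het <- snp & !is.na(gt_clean) & !(gt_clean %in% c("1/1", "1", "0/0", "0"))

  cat_of <- paste0(ref, ">", alt)
  counts <- table(factor(cat_of[hom_alt],
                         levels = substitution_categories()))
  substitution_spectrum(
    stats::setNames(as.numeric(counts), names(counts)),
    skipped = c(multiallelic = sum(multi), indel = sum(indel),
                heterozygous = sum(het),
                hom_ref_or_missing = sum(snp & !hom_alt & !het)))
}

#' Substitution spectrum implied by minor splice-site combinations
#'
#' Each minor combination is assigned to its closest reference among
#' GT-AG, GC-AG and AT-AC (see \code{\link{closest_reference}}) and the
#' implied substitutions ref_base>obs_base are accumulated.
#'
#' @param minor_combos Character vector of unambiguous minor combinations.
#' @return A \code{substitution_spectrum}.
#' @export
splice_site_spectrum <- function(minor_combos) {
  counts <- stats::setNames(numeric(12L), substitution_categories())
  for (combo in minor_combos) {
    cr <- closest_reference(combo)  # errors on canonical/major input
    key <- paste0(cr$substitutions$ref_base, ">", cr$substitutions$obs_base)
    for (k in key) counts[k] <- counts[k] + 1
  }
  substitution_spectrum(counts)
}

#' Chi-square comparison of an observed spectrum against expected rates
#'
#' Pearson chi-square with expected counts = observed total x expected
#' rates, over the categories where either is non-zero. Categories with
#' expected rate 0 but observed counts > 0 are pooled into an "other"
#' category with a warning. A reported p-value of 0 means underflow; the
#' smallest representable tail is used instead.
#'
#' @param observed A \code{substitution_spectrum} (counts used).
#' @param expected A \code{substitution_spectrum} (rates used).
#' @return List (class \code{chisq_result}) with statistic, df, p_value,
#'   and data.frame \code{table} (category, observed, expected).
#' @export
compare_spectra <- function(observed, expected) {
  o <- observed$counts
  r <- expected$rates
  if (sum(o) < 1) stop("observed spectrum is empty")
  if (sum(r) <= 0) stop("expected spectrum has no rates")

  keep <- r > 0 | o > 0
  o <- o[keep]; r <- r[keep]
  if (any(r == 0 & o > 0)) {
    warning("categories with observed counts but zero expected rate ",
            "pooled into 'other'")
    pool <- r == 0 & o > 0
    o <- c(o[!pool], other = sum(o[pool]))
    # the pooled category gets the leftover expected mass (zero here, so
    # give it a minimal floor to keep the statistic finite)
    r <- c(r[!pool], other = .Machine$double.xmin)
  }
  r <- r / sum(r)
  ct <- suppressWarnings(stats::chisq.test(x = o, p = r))
  p <- max(ct$p.value, .Machine$double.xmin)
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = p,
                 table = data.frame(category = names(o),
                                    observed = unname(o),
                                    expected = unname(sum(o) * r),
                                    stringsAsFactors = FALSE)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Overlap splice-site dinucleotide positions with variant positions
#'
#' A splice-site combination overlaps the variant set when any of its four
#' border bases (two donor, two acceptor) coincides with a variant
#' position. For overlapping sites the majority allele across genotypes is
#' classified as reference or alternative; ties count as
#' alternative-majority (conservative against the reference allele).
#'
#' @param introns Intron data.frame (seq_name, start, end; 1-based closed).
#' @param vcf_path Path to a VCF file.
#' @return List (class \code{overlap_report}) with n_sites, n_overlapping,
#'   n_reference_majority, n_alternative_majority.
#' @export
overlap_variants <- function(introns, vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  var_key <- paste(fix[, "CHROM"], as.integer(fix[, "POS"]))

  gt <- if (ncol(v@gt) >= 2L) vcfR::extract.gt(v, element = "GT") else NULL
  ref_major <- vapply(seq_len(nrow(fix)), function(i) {
    if (is.null(gt)) return(FALSE)
    g <- gsub("|", "/", gt[i, ], fixed = TRUE)
    alleles <- unlist(strsplit(g[!is.na(g)], "/", fixed = TRUE))
    n_ref <- sum(alleles == "0"); n_alt <- sum(alleles != "0")
    n_ref > n_alt  # tie -> alternative majority
  }, logical(1))
  names(ref_major) <- var_key

  n_overlap <- 0L; n_refmaj <- 0L
  for (i in seq_len(nrow(introns))) {
    pos <- c(introns$start[i], introns$start[i] + 1L,
             introns$end[i] - 1L, introns$end[i])
    keys <- paste(introns$seq_name[i], pos)
    hit <- keys[keys %in% var_key]
    if (length(hit) == 0L) next
    n_overlap <- n_overlap + 1L
    # a site's majority call: reference-majority iff every hit variant is
    # reference-major
    if (all(ref_major[hit])) n_refmaj <- n_refmaj + 1L
  }
  structure(list(n_sites = nrow(introns),
                 n_overlapping = n_overlap,
                 n_reference_majority = n_refmaj,
                 n_alternative_majority = n_overlap - n_refmaj),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report:", x$n_overlapping, "of", x$n_sites,
      "sites overlap variants (", x$n_reference_majority,
      "reference-majority /", x$n_alternative_majority,
      "alternative-majority )\n")
  invisible(x)
}
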