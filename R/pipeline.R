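#' Analysis configuration
#'
#' Houses the survey's constants: introns of at least 20 bp enter the
#' statistics, a splice site is supported when coverage drops by at least
#' 20\% from exon to intron, long introns are those beyond 5 kb, the
#' random background selection in length comparisons is repeated 100
#' times, and shift-equivalence is searched within +/- 3 nt.
#'
#' @param min_intron_length Minimum intron length in nt (default 20).
#' @param min_drop Minimum relative coverage drop in (0,1) (default 0.2).
#' @param long_intron_threshold Long-intron cutoff in nt (default 5000).
#' @param resample_reps Replicates for length comparisons (default 100).
#' @param max_shift Maximum shift for equivalence search (default 3).
#' @param seed Integer seed for all stochastic steps (default 1).
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(min_intron_length = 20, min_drop = 0.2,
                            long_intron_threshold = 5000,
                            resample_reps = 100, max_shift = 3, seed = 1) {
  stopifnot(min_intron_length >= 1, min_drop > 0, min_drop < 1,
            long_intron_threshold > 0, resample_reps >= 1, max_shift >= 1)
  structure(list(min_intron_length = min_intron_length,
                 min_drop = min_drop,
                 long_intron_threshold = long_intron_threshold,
                 resample_reps = resample_reps,
                 max_shift = max_shift, seed = as.integer(seed)),
            class = "analysis_config")
}

.provenance <- function(config) {
  sprintf("# ncsplice %s; seed=%d; min_intron=%g; min_drop=%g",
          as.character(utils::packageVersion("ncsplice")),
          config$seed, config$min_intron_length, config$min_drop)
}

.out <- function(outdir, name) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  file.path(outdir, name)
}

#' Classify splice sites of an annotated genome
#'
#' Reads genome and annotation, filters genes with annotation errors,
#' selects representative transcripts, extracts CDS-flanked introns,
#' classifies the border combinations and builds the species profile.
#' Writes \code{introns.tsv}, \code{profile.tsv},
#' \code{filter_report.tsv}/\code{.json} and \code{introns.bed} to
#' \code{outdir}.
#'
#' @param fasta,gff3 Input paths.
#' @param outdir Output directory.
#' @param config An \code{\link{analysis_config}}.
#' @param species Label for the profile.
#' @return Invisibly, a list with introns, profile, report, annotation,
#'   assembly.
#' @export
run_classify <- function(fasta, gff3, outdir,
                         config = analysis_config(),
                         species = "sample") {
  assembly <- read_genome(fasta)
  annotation <- read_annotation(gff3, assembly)
  flt <- filter_genes(annotation, assembly)
  if (nrow(flt$annotation$genes) == 0L) {
    stop("no genes retained after filtering")
  }
  introns <- extract_introns(flt$annotation, assembly)
  profile <- build_profile(introns, min_length = config$min_intron_length,
                           species = species)
  if (profile$total_introns == 0L) {
    warning("no introns of length >= ", config$min_intron_length,
            "; profile is empty")
  }
  write_intron_table(introns, .out(outdir, "introns.tsv"))
  if (nrow(introns) > 0L) {
    write_intron_bed(introns, .out(outdir, "introns.bed"))
  }
  write_profile(profile, .out(outdir, "profile.tsv"))
  write_filter_report(flt$report, .out(outdir, "filter_report.tsv"),
                      .out(outdir, "filter_report.json"))
  invisible(list(introns = introns, profile = profile,
                 report = flt$report, annotation = flt$annotation,
                 assembly = assembly))
}

#' Validate splice sites against RNA-Seq coverage
#'
#' Applies the coverage-drop rule to every intron and summarises usage and
#' validation ratios per class. Writes \code{support_calls.tsv},
#' \code{usage_summary.tsv} and \code{validation_ratios.tsv} (plus a JSON
#' summary) to \code{outdir}.
#'
#' @param introns Intron data.frame or path to an \code{introns.tsv}.
#' @param coverage Path to a BedGraph coverage file, or a
#'   \code{coverage_track}.
#' @param outdir Output directory.
#' @param config An \code{\link{analysis_config}}.
#' @return Invisibly, list with calls, usage, ratios.
#' @export
run_validate <- function(introns, coverage, outdir,
                         config = analysis_config()) {
  if (is.character(introns)) introns <- read_intron_table(introns)
  if (is.character(coverage)) coverage <- read_coverage(coverage)
  introns <- introns[introns$length >= config$min_intron_length, ,
                     drop = FALSE]
  calls <- validate_introns(introns, coverage, min_drop = config$min_drop)
  usage <- summarize_usage(calls)
  ratios <- validation_ratio(calls)
  utils::write.table(calls, .out(outdir, "support_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(usage, .out(outdir, "usage_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ratios, .out(outdir, "validation_ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(usage = usage, ratios = ratios),
                       .out(outdir, "validation_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(calls = calls, usage = usage, ratios = ratios))
}

#' Profile-level statistics
#'
#' Computes the divergence-frequency correlation over pooled profiles,
#' the pairwise profile similarity matrix (when >= 2 profiles), and the
#' per-species correlation between non-canonical counts and total splice
#' sites. When an intron table is supplied, also runs the long-intron
#' enrichment. Writes TSV/JSON reports to \code{outdir}.
#'
#' @param profiles List of \code{species_profile} objects or paths to
#'   profile TSVs.
#' @param outdir Output directory.
#' @param config An \code{\link{analysis_config}}.
#' @param introns Optional intron data.frame (or path) for the
#'   length-based analyses.
#' @return Invisibly, list with divergence, similarity, count_correlation,
#'   enrichment.
#' @export
run_stats <- function(profiles, outdir, config = analysis_config(),
                      introns = NULL) {
  if (is.character(profiles)) profiles <- as.list(profiles)
  profiles <- lapply(profiles, function(p) {
    if (is.character(p)) read_profile(p) else p
  })
  divergence <- divergence_frequency_correlation(profiles)
  sim <- NULL
  if (length(profiles) >= 2L) {
    sim <- profile_similarity_matrix(profiles)
    utils::write.table(cbind(species = rownames(sim), as.data.frame(sim)),
                       .out(outdir, "similarity_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    warning("fewer than 2 profiles; similarity matrix skipped")
  }
  counts <- data.frame(
    species = vapply(profiles, function(p) p$species, character(1)),
    total = vapply(profiles, function(p) sum(p$counts), numeric(1)),
    noncanonical = vapply(profiles, function(p) {
      sum(p$counts[names(p$counts) != "GTAG"])
    }, numeric(1)))
  count_corr <- NULL
  if (nrow(counts) >= 3L) {
    count_corr <- correlate_counts(counts$noncanonical, counts$total)
  }
  enrichment <- NULL
  if (!is.null(introns)) {
    if (is.character(introns)) introns <- read_intron_table(introns)
    enrichment <- long_intron_enrichment(
      introns, threshold = config$long_intron_threshold,
      min_length = config$min_intron_length)
    utils::write.table(enrichment$table,
                       .out(outdir, "long_intron_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(counts, .out(outdir, "species_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(divergence_frequency = divergence[c("rho", "p_value", "n")],
         count_correlation = if (!is.null(count_corr)) {
           count_corr[c("rho", "p_value", "n")]
         } else NULL),
    .out(outdir, "stats_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(list(divergence = divergence, similarity = sim,
                 count_correlation = count_corr,
                 enrichment = enrichment))
}

#' Substitution-spectrum comparison
#'
#' Computes the genome-wide substitution spectrum from homozygous SNPs in
#' a VCF, the spectrum implied by the minor non-canonical combinations of
#' an intron table, their chi-square comparison, and the overlap of
#' splice-site border positions with variant positions. Writes
#' \code{genome_spectrum.tsv}, \code{splice_spectrum.tsv} and
#' \code{substitution_summary.json} to \code{outdir}.
#'
#' @param vcf Path to the VCF file.
#' @param introns Intron data.frame or path to an \code{introns.tsv}.
#' @param outdir Output directory.
#' @param config An \code{\link{analysis_config}}.
#' @return Invisibly, list with genome_spectrum, splice_spectrum, chisq,
#'   overlap.
#' @export
run_substitution <- function(vcf, introns, outdir,
                             config = analysis_config()) {
  if (!file.exists(vcf)) stop("VCF not found: ", vcf)
  if (is.character(introns)) introns <- read_intron_table(introns)
  introns <- introns[introns$length >= config$min_intron_length, ,
                     drop = FALSE]
  genome_spec <- substitution_spectrum_from_vcf(vcf)
  minors <- introns$combo[!is.na(introns$class) &
                            introns$class == "minor" &
                            !is_ambiguous_combo(introns$combo)]
  splice_spec <- splice_site_spectrum(minors)
  chisq <- NULL
  if (genome_spec$total == 0) {
    warning("no homozygous SNPs in VCF; spectrum comparison skipped")
  } else if (splice_spec$total > 0) {
    chisq <- compare_spectra(splice_spec, genome_spec)
  }
  nc <- introns[!is.na(introns$class) & introns$class != "canonical", ,
                drop = FALSE]
  overlap <- overlap_variants(nc, vcf)
  .write_spectrum_tsv(genome_spec, .out(outdir, "genome_spectrum.tsv"))
  .write_spectrum_tsv(splice_spec, .out(outdir, "splice_spectrum.tsv"))
  jsonlite::write_json(
    list(chisq = if (!is.null(chisq)) {
      chisq[c("statistic", "df", "p_value")]
    } else NULL,
    overlap = unclass(overlap)),
    .out(outdir, "substitution_summary.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  invisible(list(genome_spectrum = genome_spec,
                 splice_spectrum = splice_spec, chisq = chisq,
                 overlap = overlap))
}

.write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(
    data.frame(substitution = names(spectrum$counts),
               count = unname(spectrum$counts),
               rate = unname(spectrum$rates)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a complete synthetic input set
#'
#' Runs the generator end to end: genome + annotation + manifest,
#' coverage track and VCF, all under one seed, into \code{outdir}.
#'
#' @param gen_config A \code{\link{generator_config}}.
#' @param outdir Output directory.
#' @param exon_depth,noise Coverage options (see
#'   \code{\link{simulate_coverage}}).
#' @param spectrum A \code{substitution_spectrum} for the VCF (default: a
#'   transition-biased spectrum).
#' @param n_variants Number of planted SNPs.
#' @return Invisibly, the generator output plus coverage/vcf paths.
#' @export
run_simulate <- function(gen_config, outdir, exon_depth = 100,
                         noise = FALSE,
                         spectrum = default_spectrum(),
                         n_variants = 1000) {
  gen <- generate_genome(gen_config, dir = outdir)
  cov_path <- file.path(outdir, "coverage.bedgraph")
  simulate_coverage(gen$manifest, exon_depth = exon_depth, noise = noise,
                    seed = gen_config$seed, path = cov_path)
  vcf_path <- file.path(outdir, "variants.vcf")
  simulate_vcf(gen$assembly, gen$manifest, spectrum,
               n_variants = n_variants, seed = gen_config$seed,
               path = vcf_path)
  gen$paths$coverage <- cov_path
  gen$paths$vcf <- vcf_path
  invisible(gen)
}

#' A transition-biased default substitution spectrum
#'
#' Transitions (A<->G, C<->T) three times as likely as each transversion,
#' the pattern typical of plant nuclear genomes.
#'
#' @return A \code{substitution_spectrum}.
#' @export
default_spectrum <- function() {
  cats <- substitution_categories()
  transitions <- c("A>G", "G>A", "C>T", "T>C")
  w <- ifelse(cats %in% transitions, 3, 1)
  substitution_spectrum(stats::setNames(w, cats))
}
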