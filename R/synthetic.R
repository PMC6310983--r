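#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the study conditions of a typical annotated plant
#' genome survey: a class composition of 98.7\% GT-AG, 1.2\% GC-AG,
#' 0.06\% AT-AC and 0.09\% minor combinations (weights are normalised to
#' sum to 1), around 4-5 CDS-flanked introns per gene, a log-normal intron
#' length body with mode near 200 nt plus a small heavy tail beyond 5 kb,
#' and an even strand mix.
#'
#' @param n_genes Number of genes.
#' @param introns_per_gene Single count or range c(min, max), sampled
#'   uniformly per gene.
#' @param exon_length Range c(min, max) of CDS exon lengths in nt
#'   (min >= 12).
#' @param intron_meanlog,intron_sdlog Log-normal body of the intron length
#'   distribution.
#' @param long_fraction Fraction of introns drawn from the long tail.
#' @param long_range Range c(min, max) of long-tail intron lengths in nt.
#' @param min_intron Minimum intron length (default 20 nt).
#' @param composition Named weights for classes canonical, major_GC_AG,
#'   major_AT_AC, minor.
#' @param minor_mode \code{"uniform"} over the 253 minor combinations, or
#'   \code{"distance"}: probability proportional to 3^-d where d is the
#'   Hamming distance to GT-AG, mimicking the observed divergence
#'   gradient.
#' @param minus_fraction Fraction of genes on the minus strand.
#' @param ambiguity_rate Per-intron probability that one border base is
#'   replaced by N (exercises masking).
#' @param spliced_fraction Planted spliced fraction s per intron: a scalar
#'   or a range c(lo, hi) sampled uniformly.
#' @param spacer Intergenic spacer length in nt.
#' @param n_seqs Number of chromosome sequences to tile genes onto.
#' @param inject_internal_stop,inject_out_of_bounds Number of genes to
#'   corrupt (annotation-error injection for testing the gene filter).
#' @param seed Mandatory integer seed.
#' @return A list of class \code{generator_config}.
#' @export
generator_config <- function(n_genes = 100,
                             introns_per_gene = c(1, 8),
                             exon_length = c(30, 300),
                             intron_meanlog = log(180),
                             intron_sdlog = 0.55,
                             long_fraction = 0.01,
                             long_range = c(5001, 8000),
                             min_intron = 20,
                             composition = c(canonical = 98.7,
                                             major_GC_AG = 1.2,
                                             major_AT_AC = 0.06,
                                             minor = 0.09),
                             minor_mode = c("uniform", "distance"),
                             minus_fraction = 0.5,
                             ambiguity_rate = 0,
                             spliced_fraction = 0.9,
                             spacer = 150,
                             n_seqs = 1,
                             inject_internal_stop = 0,
                             inject_out_of_bounds = 0,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  minor_mode <- match.arg(minor_mode)
  if (length(introns_per_gene) == 1L) {
    introns_per_gene <- rep(introns_per_gene, 2L)
  }
  if (!all(names(composition) ==
           c("canonical", "major_GC_AG", "major_AT_AC", "minor"))) {
    stop("composition must be named canonical, major_GC_AG, major_AT_AC, ",
         "minor")
  }
  if (any(composition < 0) || sum(composition) <= 0) {
    stop("composition weights must be non-negative and sum to > 0")
  }
  composition <- composition / sum(composition)
  if (exon_length[1L] < 12) stop("exon_length minimum must be >= 12")
  if (min_intron < 4) stop("min_intron must be >= 4")
  structure(list(n_genes = n_genes, introns_per_gene = introns_per_gene,
                 exon_length = exon_length,
                 intron_meanlog = intron_meanlog,
                 intron_sdlog = intron_sdlog,
                 long_fraction = long_fraction, long_range = long_range,
                 min_intron = min_intron, composition = composition,
                 minor_mode = minor_mode,
                 minus_fraction = minus_fraction,
                 ambiguity_rate = ambiguity_rate,
                 spliced_fraction = spliced_fraction,
                 spacer = spacer, n_seqs = n_seqs,
                 inject_internal_stop = inject_internal_stop,
                 inject_out_of_bounds = inject_out_of_bounds,
                 seed = as.integer(seed)),
            class = "generator_config")
}

.BASES <- c("A", "C", "G", "T")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.minor_combos <- function() {
  setdiff(all_splice_combos(), c("GTAG", "GCAG", "ATAC"))
}

.rand_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

.sample_intron_lengths <- function(n, config) {
  len <- round(stats::rlnorm(n, config$intron_meanlog, config$intron_sdlog))
  len <- pmin(pmax(len, config$min_intron), 5000L)
  long <- stats::runif(n) < config$long_fraction
  len[long] <- sample(config$long_range[1L]:config$long_range[2L],
                      sum(long), replace = TRUE)
  as.integer(len)
}

.sample_combos <- function(n, config) {
  cls <- sample(names(config$composition), n, replace = TRUE,
                prob = config$composition)
  combo <- character(n)
  combo[cls == "canonical"] <- "GTAG"
  combo[cls == "major_GC_AG"] <- "GCAG"
  combo[cls == "major_AT_AC"] <- "ATAC"
  n_minor <- sum(cls == "minor")
  if (n_minor > 0L) {
    minors <- .minor_combos()
    w <- if (config$minor_mode == "distance") {
      3 ^ (-combo_hamming(minors, "GTAG"))
    } else rep(1, length(minors))
    combo[cls == "minor"] <- sample(minors, n_minor, replace = TRUE,
                                    prob = w)
  }
  if (config$ambiguity_rate > 0) {
    hit <- which(stats::runif(n) < config$ambiguity_rate)
    for (i in hit) {
      p <- sample.int(4L, 1L)
      substr(combo[i], p, p) <- "N"
    }
  }
  combo
}

#' Generate a synthetic genome, annotation and truth manifest
#'
#' Tiles protein-coding genes with CDS-flanked introns onto chromosome
#' sequences separated by random spacer DNA. Each intron's first and last
#' dinucleotides are overwritten with its assigned border combination;
#' each CDS starts with ATG, ends with a stop codon and contains no
#' internal stop, so the generated annotation passes
#' \code{\link{filter_genes}} with zero losses (unless error injection is
#' requested). The same seed and configuration produce byte-identical
#' files.
#'
#' @param config A \code{\link{generator_config}}.
#' @param dir Output directory (created if needed); writes
#'   \code{genome.fasta}, \code{annotation.gff3} and
#'   \code{manifest.json}. With \code{dir = NULL} nothing is written.
#' @return List with \code{assembly} (DNAStringSet), \code{annotation}
#'   (a \code{gene_annotation}), \code{manifest} (see below) and, when
#'   written, \code{paths}. The manifest holds the configuration, a
#'   \code{genes} table, an \code{introns} table (gene, transcript,
#'   interval, strand, length, planted combo and class, spliced fraction),
#'   \code{seq_lengths} and \code{corrupted} gene IDs.
#' @export
generate_genome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n <- config$n_genes
  seq_of_gene <- rep(sprintf("chr%d", seq_len(config$n_seqs)),
                     length.out = n)
  seq_of_gene <- sort(seq_of_gene)  # contiguous blocks per chromosome
  strand_of_gene <- ifelse(stats::runif(n) < config$minus_fraction,
                           "-", "+")
  stop_idx <- if (config$inject_internal_stop > 0) {
    sample.int(n, min(config$inject_internal_stop, n))
  } else integer(0)

  nonstop <- apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste,
                   collapse = "")
  nonstop <- setdiff(nonstop, .STOP_CODONS)

  seq_names_all <- sprintf("chr%d", seq_len(config$n_seqs))
  spacer_v <- character(n)
  gene_seq_v <- character(n)  # sense-strand; minus genes flipped in batch
  offset <- stats::setNames(integer(config$n_seqs), seq_names_all)
  gene_start <- gene_end <- integer(n)
  gene_n_int <- integer(n)
  cds_l <- vector("list", n)
  introns_l <- vector("list", n)

  for (g in seq_len(n)) {
    gid <- sprintf("gene%05d", g)
    tid <- sprintf("mRNA%05d", g)
    sn <- seq_of_gene[g]
    strand <- strand_of_gene[g]
    int_range <- config$introns_per_gene[1L]:config$introns_per_gene[2L]
    n_int <- int_range[sample.int(length(int_range), 1L)]
    n_ex <- n_int + 1L
    ex_len <- sample(config$exon_length[1L]:config$exon_length[2L], n_ex,
                     replace = TRUE)
    total <- sum(ex_len)
    ex_len[n_ex] <- ex_len[n_ex] - total %% 3L
    total <- sum(ex_len)
    n_cod <- total %/% 3L
    internal <- sample(nonstop, n_cod - 2L, replace = TRUE)
    if (g %in% stop_idx && length(internal) > 0L) {
      internal[ceiling(length(internal) / 2)] <- "TAA"
    }
    cds_seq <- paste0("ATG", paste(internal, collapse = ""),
                      sample(.STOP_CODONS, 1L))

    ex_end <- cumsum(ex_len)
    ex_start <- c(1L, ex_end[-n_ex] + 1L)
    exon_seqs <- substring(cds_seq, ex_start, ex_end)

    int_len <- .sample_intron_lengths(n_int, config)
    combos <- .sample_combos(n_int, config)
    intron_seqs <- vapply(seq_len(n_int), function(i) {
      s <- .rand_dna(int_len[i])
      substr(s, 1L, 2L) <- substr(combos[i], 1L, 2L)
      substr(s, int_len[i] - 1L, int_len[i]) <- substr(combos[i], 3L, 4L)
      s
    }, character(1))

    # sense-strand gene sequence and local coordinates
    parts <- character(n_ex + n_int)
    parts[seq(1L, by = 2L, length.out = n_ex)] <- exon_seqs
    if (n_int > 0L) {
      parts[seq(2L, by = 2L, length.out = n_int)] <- intron_seqs
    }
    gene_seq <- paste(parts, collapse = "")
    glen <- nchar(gene_seq)
    part_len <- nchar(parts)
    part_end <- cumsum(part_len)
    part_start <- c(1L, part_end[-length(part_end)] + 1L)
    ex_i <- seq(1L, by = 2L, length.out = n_ex)
    int_i <- if (n_int > 0L) seq(2L, by = 2L, length.out = n_int) else
      integer(0)

    if (strand == "-") {
      flip <- function(s, e) list(start = glen - e + 1L, end = glen - s + 1L)
      ex_coord <- flip(part_start[ex_i], part_end[ex_i])
      int_coord <- flip(part_start[int_i], part_end[int_i])
    } else {
      ex_coord <- list(start = part_start[ex_i], end = part_end[ex_i])
      int_coord <- list(start = part_start[int_i], end = part_end[int_i])
    }

    base <- offset[[sn]] + config$spacer
    spacer_v[g] <- .rand_dna(config$spacer)
    gene_seq_v[g] <- gene_seq
    offset[[sn]] <- base + glen

    gene_start[g] <- base + min(ex_coord$start)
    gene_end[g] <- base + max(ex_coord$end)
    gene_n_int[g] <- n_int
    cds_l[[g]] <- list(tid = tid, start = base + ex_coord$start,
                       end = base + ex_coord$end)
    if (n_int > 0L) {
      sfrac <- if (length(config$spliced_fraction) == 2L) {
        stats::runif(n_int, config$spliced_fraction[1L],
                     config$spliced_fraction[2L])
      } else rep(config$spliced_fraction, n_int)
      # biological (5'->3') intron order: genomic order on +, reversed on -
      bio_index <- if (strand == "-") rev(seq_len(n_int)) else
        seq_len(n_int)
      introns_l[[g]] <- list(
        gid = gid, tid = tid, index = bio_index,
        start = base + int_coord$start, end = base + int_coord$end,
        length = int_len, combo = combos, sfrac = sfrac)
    }
  }

  minus <- strand_of_gene == "-"
  if (any(minus)) gene_seq_v[minus] <- revcomp(gene_seq_v[minus])

  # terminal spacer so no gene touches a sequence end
  seqs <- Biostrings::DNAStringSet(vapply(seq_names_all, function(sn) {
    sel <- seq_of_gene == sn
    paste(c(rbind(spacer_v[sel], gene_seq_v[sel]), .rand_dna(config$spacer)),
          collapse = "")
  }, character(1)))
  names(seqs) <- seq_names_all

  gene_ids <- sprintf("gene%05d", seq_len(n))
  tx_ids <- sprintf("mRNA%05d", seq_len(n))
  genes <- data.frame(gene_id = gene_ids, transcript_id = tx_ids,
                      seq_name = seq_of_gene, strand = strand_of_gene,
                      start = gene_start, end = gene_end,
                      n_introns = gene_n_int, stringsAsFactors = FALSE)
  cds <- data.frame(
    transcript_id = rep(tx_ids, lengths(lapply(cds_l, `[[`, "start"))),
    start = unlist(lapply(cds_l, `[[`, "start")),
    end = unlist(lapply(cds_l, `[[`, "end")),
    stringsAsFactors = FALSE)
  introns_l <- introns_l[!vapply(introns_l, is.null, logical(1))]
  introns <- if (length(introns_l) > 0L) {
    data.frame(
      gene_id = unlist(lapply(introns_l, function(x)
        rep(x$gid, length(x$start)))),
      transcript_id = unlist(lapply(introns_l, function(x)
        rep(x$tid, length(x$start)))),
      index = unlist(lapply(introns_l, `[[`, "index")),
      seq_name = rep(seq_of_gene[gene_n_int > 0L],
                     gene_n_int[gene_n_int > 0L]),
      start = unlist(lapply(introns_l, `[[`, "start")),
      end = unlist(lapply(introns_l, `[[`, "end")),
      strand = rep(strand_of_gene[gene_n_int > 0L],
                   gene_n_int[gene_n_int > 0L]),
      length = unlist(lapply(introns_l, `[[`, "length")),
      combo = unlist(lapply(introns_l, `[[`, "combo")),
      spliced_fraction = unlist(lapply(introns_l, `[[`, "sfrac")),
      stringsAsFactors = FALSE)
  } else .empty_truth_introns()
  introns$class <- as.character(classify_combo(introns$combo))

  corrupted <- genes$gene_id[stop_idx]
  if (config$inject_out_of_bounds > 0) {
    oob_pool <- setdiff(seq_len(n), stop_idx)
    oob_idx <- sample(oob_pool, min(config$inject_out_of_bounds,
                                    length(oob_pool)))
    for (g in oob_idx) {
      tid <- genes$transcript_id[g]
      j <- which(cds$transcript_id == tid)
      j <- j[length(j)]
      cds$end[j] <- cds$end[j] +
        Biostrings::width(seqs[genes$seq_name[g]])
    }
    corrupted <- c(corrupted, genes$gene_id[oob_idx])
  }

  annotation <- structure(list(
    genes = genes[, c("gene_id", "seq_name", "strand")],
    transcripts = data.frame(transcript_id = genes$transcript_id,
                             gene_id = genes$gene_id,
                             stringsAsFactors = FALSE),
    cds = cds,
    source = "ncsplice::generate_genome",
    dropped_features = 0L), class = "gene_annotation")

  manifest <- structure(list(
    config = unclass(config),
    genes = genes,
    introns = introns,
    seq_lengths = stats::setNames(Biostrings::width(seqs), names(seqs)),
    corrupted = corrupted), class = "truth_manifest")

  out <- list(assembly = seqs, annotation = annotation,
              manifest = manifest)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "genome.fasta"),
                  gff3 = file.path(dir, "annotation.gff3"),
                  manifest = file.path(dir, "manifest.json"))
    Biostrings::writeXStringSet(seqs, paths$fasta)
    write_annotation(annotation, paths$gff3)
    write_manifest(manifest, paths$manifest)
    out$paths <- paths
  }
  out
}

.empty_truth_introns <- function() {
  data.frame(gene_id = character(0), transcript_id = character(0),
             index = integer(0), seq_name = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             length = integer(0), combo = character(0),
             class = character(0), spliced_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write / read a truth manifest as JSON
#'
#' @param manifest A \code{truth_manifest}.
#' @param path JSON file path.
#' @return \code{path} (write) or a \code{truth_manifest} (read).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$seq_lengths <- unlist(m$seq_lengths)
  m$corrupted <- as.character(unlist(m$corrupted))
  structure(m, class = "truth_manifest")
}

#' Simulate per-base RNA-Seq coverage from a truth manifest
#'
#' Exonic bases of every gene get depth \code{exon_depth}; intronic bases
#' get \code{exon_depth * (1 - s)} with each intron's planted spliced
#' fraction s; intergenic bases get 0. With \code{noise = TRUE} depths are
#' Poisson counts with those means, otherwise they are deterministic
#' (rounded).
#'
#' @param manifest A \code{truth_manifest}.
#' @param exon_depth Mean exonic depth (> 0).
#' @param noise Logical: Poisson counting noise (default FALSE).
#' @param seed Seed for the noise stream.
#' @param path Optional BedGraph output path.
#' @return A \code{coverage_track} (and the file, when \code{path} is
#'   given).
#' @export
simulate_coverage <- function(manifest, exon_depth = 100, noise = FALSE,
                              seed = 1, path = NULL) {
  if (exon_depth <= 0) stop("exon_depth must be > 0")
  s <- manifest$introns$spliced_fraction
  if (length(s) > 0 && (any(s < 0) || any(s > 1))) {
    stop("spliced fractions must be in [0, 1]")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  track <- lapply(manifest$seq_lengths, function(L) numeric(L))
  cds <- manifest$genes
  # exon depth over the whole gene span first, then overwrite introns
  for (i in seq_len(nrow(cds))) {
    sn <- cds$seq_name[i]
    track[[sn]][cds$start[i]:cds$end[i]] <- exon_depth
  }
  intr <- manifest$introns
  for (i in seq_len(nrow(intr))) {
    sn <- intr$seq_name[i]
    track[[sn]][intr$start[i]:intr$end[i]] <-
      exon_depth * (1 - intr$spliced_fraction[i])
  }
  if (isTRUE(noise) || (is.numeric(noise) && noise > 0)) {
    track <- lapply(track, function(v) {
      pos <- v > 0
      v[pos] <- stats::rpois(sum(pos), v[pos])
      v
    })
  } else {
    track <- lapply(track, round)
  }
  track <- structure(track, class = "coverage_track")
  if (!is.null(path)) write_coverage(track, path)
  track
}

#' Simulate a VCF of homozygous SNPs from a substitution spectrum
#'
#' Places homozygous-alternative biallelic SNPs at random positions whose
#' reference base matches the drawn substitution category, avoiding the
#' four border bases of every intron in the manifest. The planted variants
#' are returned so spectra and overlaps can be checked against ground
#' truth.
#'
#' @param assembly The generated \link[Biostrings]{DNAStringSet}.
#' @param manifest The matching \code{truth_manifest}.
#' @param spectrum A \code{substitution_spectrum} (rates used; must not be
#'   all zero).
#' @param n_variants Number of SNPs to plant (>= 1).
#' @param seed Integer seed.
#' @param path Optional VCF output path.
#' @return data.frame of planted variants (seq_name, pos, ref, alt).
#' @export
simulate_vcf <- function(assembly, manifest, spectrum, n_variants = 1000,
                         seed = 1, path = NULL) {
  if (n_variants < 1) stop("n_variants must be >= 1")
  if (spectrum$total <= 0 && sum(spectrum$rates) <= 0) {
    stop("spectrum is all zero")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # genome positions per reference base, splice-site borders excluded
  excluded <- new.env(parent = emptyenv())
  intr <- manifest$introns
  excl_key <- character(0)
  if (nrow(intr) > 0L) {
    excl_key <- c(paste(intr$seq_name, intr$start),
                  paste(intr$seq_name, intr$start + 1L),
                  paste(intr$seq_name, intr$end - 1L),
                  paste(intr$seq_name, intr$end))
  }
  pos_by_base <- lapply(stats::setNames(.BASES, .BASES), function(b) NULL)
  for (sn in names(assembly)) {
    chars <- strsplit(as.character(assembly[[sn]]), "", fixed = TRUE)[[1L]]
    for (b in .BASES) {
      p <- which(chars == b)
      p <- p[!(paste(sn, p) %in% excl_key)]
      if (length(p) > 0L) {
        pos_by_base[[b]] <- rbind(pos_by_base[[b]],
                                  data.frame(seq_name = sn, pos = p,
                                             stringsAsFactors = FALSE))
      }
    }
  }

  cats <- sample(substitution_categories(), n_variants, replace = TRUE,
                 prob = spectrum$rates)
  ref <- substr(cats, 1L, 1L)
  alt <- substr(cats, 3L, 3L)
  rows <- vector("list", 4L)
  for (k in seq_along(.BASES)) {
    b <- .BASES[k]
    idx <- which(ref == b)
    if (length(idx) == 0L) next
    pool <- pos_by_base[[b]]
    if (is.null(pool) || nrow(pool) < length(idx)) {
      stop("not enough ", b, " positions to place ", length(idx),
           " variants")
    }
    pick <- pool[sample.int(nrow(pool), length(idx)), , drop = FALSE]
    rows[[k]] <- data.frame(seq_name = pick$seq_name, pos = pick$pos,
                            ref = b, alt = alt[idx],
                            stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, rows)
  variants <- variants[order(variants$seq_name, variants$pos), ,
                       drop = FALSE]
  rownames(variants) <- NULL

  if (!is.null(path)) {
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=ncsplice::simulate_vcf",
      sprintf("##contig=<ID=%s,length=%d>", names(assembly),
              Biostrings::width(assembly)),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sample1", sep = "\t"))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t1/1",
                    variants$seq_name, variants$pos, variants$ref,
                    variants$alt)
    writeLines(c(header, body), path)
  }
  variants
}

#' Simulate per-species splice-site profiles at the count level
#'
#' Draws combination counts for many species directly from the class
#' composition, without building genomes: per species, a total splice-site
#' count is drawn log-uniformly from \code{total_range} (the span observed
#' across sequenced plant genomes), the class weights are jittered by a
#' log-normal factor (\code{jitter_sdlog}) to emulate between-species
#' variation in non-canonical content, and that many combinations are
#' sampled. This is the fast stand-in for a multi-genome survey when only
#' profile-level statistics are needed.
#'
#' @param n_species Number of species profiles (default 121).
#' @param total_range Range of per-species total splice-site counts,
#'   sampled log-uniformly (default c(1500, 372000)).
#' @param config A \code{\link{generator_config}} supplying the class
#'   composition and minor-combination mode; its seed is used.
#' @param jitter_sdlog Log-normal sd of the per-species multiplicative
#'   jitter applied to the non-canonical class weights (default 0.5; 0
#'   disables).
#' @return List of \code{species_profile} objects named sp001, sp002, ...
#' @export
simulate_species_profiles <- function(n_species = 121,
                                      total_range = c(1500, 372000),
                                      config = generator_config(seed = 1),
                                      jitter_sdlog = 0.5) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  totals <- round(exp(stats::runif(n_species, log(total_range[1L]),
                                   log(total_range[2L]))))
  lapply(seq_len(n_species), function(i) {
    cfg <- config
    if (jitter_sdlog > 0) {
      w <- cfg$composition
      w[-1L] <- w[-1L] * stats::rlnorm(3L, 0, jitter_sdlog)
      cfg$composition <- w / sum(w)
    }
    combos <- .sample_combos(totals[i], cfg)
    counts <- table(factor(combos[!grepl("[^ACGT]", combos)],
                           levels = all_splice_combos()))
    structure(list(species = sprintf("sp%03d", i),
                   counts = stats::setNames(as.integer(counts),
                                            names(counts)),
                   ambiguous_masked = sum(grepl("[^ACGT]", combos)),
                   total_introns = totals[i],
                   min_length = config$min_intron),
              class = "species_profile")
  })
}
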