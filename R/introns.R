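#' Extract CDS-flanked introns of representative transcripts
#'
#' One intron is emitted per gap between consecutive CDS segments of each
#' selected transcript. The border combination (donor + acceptor
#' dinucleotide) is read strand-awarely so that the donor is always at the
#' biological 5' end of the intron; on the minus strand the combination is
#' computed on the reverse complement. Zero-length gaps produce no intron.
#' UTR introns never enter: only CDS segments are considered.
#'
#' @param annotation A filtered \code{gene_annotation}.
#' @param assembly The matching \link[Biostrings]{DNAStringSet}.
#' @param transcripts data.frame with columns gene_id, transcript_id, as
#'   returned by \code{\link{select_representative_transcript}} (the
#'   default).
#' @return data.frame with one row per intron: seq_name, start, end
#'   (1-based closed genomic interval), strand, length, combo, class,
#'   gene_id, transcript_id, index (ordinal within transcript, in
#'   biological 5'\eqn{\to}3' order).
#' @export
extract_introns <- function(annotation, assembly,
                            transcripts =
                              select_representative_transcript(annotation)) {
  cds <- annotation$cds
  cds <- cds[cds$transcript_id %in% transcripts$transcript_id, , drop = FALSE]
  meta <- merge(transcripts[, c("gene_id", "transcript_id")],
                annotation$genes, by = "gene_id", sort = FALSE)
  cds <- merge(cds, meta, by = "transcript_id", sort = FALSE)
  cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]

  same_tx <- cds$transcript_id[-1L] == cds$transcript_id[-nrow(cds)]
  i <- which(same_tx)
  if (nrow(cds) < 2L || length(i) == 0L) {
    return(.empty_intron_table())
  }
  istart <- cds$end[i] + 1L
  iend <- cds$start[i + 1L] - 1L
  keep <- iend >= istart
  i <- i[keep]; istart <- istart[keep]; iend <- iend[keep]
  if (length(i) == 0L) return(.empty_intron_table())

  out <- data.frame(
    seq_name = cds$seq_name[i],
    start = istart, end = iend,
    strand = cds$strand[i],
    length = iend - istart + 1L,
    combo = NA_character_,
    gene_id = cds$gene_id[i],
    transcript_id = cds$transcript_id[i],
    stringsAsFactors = FALSE)

  # gaps shorter than 4 nt have no well-formed border combination; they are
  # retained (inspectable) with NA combo and are excluded by the length
  # cutoff downstream anyway
  long_enough <- out$length >= 4L
  out$combo[long_enough] <- intron_combo(out[long_enough, , drop = FALSE],
                                         assembly)
  out$class <- factor(NA_character_, levels = .SPLICE_CLASSES)
  out$class[long_enough] <- classify_combo(out$combo[long_enough])

  # ordinal index in biological order: genomic order on +, reversed on -
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  idx <- stats::ave(out$start, out$transcript_id,
                    FUN = function(s) seq_along(s))
  n_tx <- stats::ave(out$start, out$transcript_id, FUN = length)
  out$index <- as.integer(ifelse(out$strand == "-", n_tx - idx + 1L, idx))
  rownames(out) <- NULL
  out
}

.empty_intron_table <- function() {
  data.frame(seq_name = character(0), start = integer(0), end = integer(0),
             strand = character(0), length = integer(0),
             combo = character(0),
             gene_id = character(0), transcript_id = character(0),
             class = factor(character(0), levels = .SPLICE_CLASSES),
             index = integer(0), stringsAsFactors = FALSE)
}

#' Border combination of genomic intervals
#'
#' Reads the terminal dinucleotides of each interval and returns the
#' 4-letter donor+acceptor combination in biological orientation.
#'
#' @param introns data.frame with seq_name, start, end, strand (1-based
#'   closed intervals of length >= 4).
#' @param assembly A \link[Biostrings]{DNAStringSet}.
#' @return Character vector of combinations.
#' @export
intron_combo <- function(introns, assembly) {
  n <- nrow(introns)
  if (n == 0L) return(character(0))
  if (any(introns$end - introns$start + 1L < 4L)) {
    stop("interval shorter than 4 nt has no border combination")
  }
  combo <- character(n)
  for (sn in unique(introns$seq_name)) {
    j <- which(introns$seq_name == sn)
    chars <- as.character(assembly[[sn]])
    if (any(introns$start[j] < 1L) || any(introns$end[j] > nchar(chars))) {
      stop("intron interval outside sequence bounds on ", sn)
    }
    left <- substring(chars, introns$start[j], introns$start[j] + 1L)
    right <- substring(chars, introns$end[j] - 1L, introns$end[j])
    plus <- paste0(left, right)
    minus <- paste0(revcomp(right), revcomp(left))
    combo[j] <- ifelse(introns$strand[j] == "-", minus, plus)
  }
  combo
}

#' Build a species splice-site profile
#'
#' Counts all unambiguous border combinations among introns of at least
#' \code{min_length} nt (shorter introns are excluded entirely, following
#' the convention that only introns and intron-like sequences of 20 bp or
#' more are analysed). Combinations containing ambiguity characters are
#' masked: they count toward the total and the \code{ambiguous_masked}
#' tally but not toward the 256 combination counts.
#'
#' @param introns Intron data.frame from \code{\link{extract_introns}}.
#' @param min_length Minimum intron length in nt (default 20).
#' @param species Label for the profile.
#' @return An object of class \code{species_profile}: list with
#'   \code{species}, \code{counts} (named integer vector over all 256
#'   combinations), \code{ambiguous_masked}, \code{total_introns}, and
#'   \code{min_length}.
#' @export
build_profile <- function(introns, min_length = 20, species = "sample") {
  if (min_length < 1) stop("min_length must be >= 1")
  introns <- introns[introns$length >= min_length, , drop = FALSE]
  combo <- introns$combo
  combo[is.na(combo)] <- "NNNN"  # malformed borders are masked, not counted
  amb <- is_ambiguous_combo(combo)
  counts <- table(factor(introns$combo[!amb], levels = all_splice_combos()))
  structure(list(species = species,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 ambiguous_masked = sum(amb),
                 total_introns = nrow(introns),
                 min_length = min_length),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cls <- classify_combo(names(x$counts))
  by_class <- tapply(x$counts, cls, sum)
  cat("species_profile '", x$species, "': ", x$total_introns,
      " introns (>= ", x$min_length, " nt), ", x$ambiguous_masked,
      " masked ambiguous\n", sep = "")
  cat(sprintf("  %s: %d\n", names(by_class)[1:4], by_class[1:4]), sep = "")
  invisible(x)
}

#' Class composition of a profile
#'
#' @param profile A \code{species_profile}.
#' @param masked Whether masked ambiguous combinations enter the
#'   denominator (default FALSE: fractions over unambiguous counts only).
#' @return Named numeric vector of fractions for canonical, major_GC_AG,
#'   major_AT_AC and minor.
#' @export
profile_composition <- function(profile, masked = FALSE) {
  cls <- classify_combo(names(profile$counts))
  by_class <- tapply(profile$counts, cls, sum)[1:4]
  denom <- sum(profile$counts) + if (masked) profile$ambiguous_masked else 0L
  by_class / denom
}

#' Write / read a species profile as TSV
#'
#' The file has 256 combination rows (columns combo, count) preceded by
#' comment header lines recording species, masked-ambiguous count, total
#' introns and the length cutoff.
#'
#' @param profile A \code{species_profile}.
#' @param path File path.
#' @return \code{path} (write) or a \code{species_profile} (read).
#' @export
write_profile <- function(profile, path) {
  hdr <- c(paste0("# species=", profile$species),
           paste0("# ambiguous_masked=", profile$ambiguous_masked),
           paste0("# total_introns=", profile$total_introns),
           paste0("# min_length=", profile$min_length),
           "combo\tcount")
  writeLines(c(hdr, paste(names(profile$counts), profile$counts, sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key, default = NA) {
    hit <- sub(paste0("^# ", key, "="), "", grep(paste0("^# ", key, "="),
                                                 hdr, value = TRUE))
    if (length(hit) == 0L) default else hit[1L]
  }
  tab <- utils::read.delim(text = lines[!grepl("^# ", lines)],
                           stringsAsFactors = FALSE)
  counts <- stats::setNames(rep(0L, 256L), all_splice_combos())
  counts[tab$combo] <- as.integer(tab$count)
  structure(list(species = get("species", "sample"),
                 counts = counts,
                 ambiguous_masked = as.integer(get("ambiguous_masked", 0)),
                 total_introns = as.integer(get("total_introns",
                                                sum(counts))),
                 min_length = as.numeric(get("min_length", 20))),
            class = "species_profile")
}

#' Write an intron table as TSV, or its intervals as BED6
#'
#' @param introns Intron data.frame from \code{\link{extract_introns}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_intron_table <- function(introns, path) {
  utils::write.table(introns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_intron_table
#' @export
read_intron_table <- function(path) {
  introns <- utils::read.delim(path, stringsAsFactors = FALSE)
  introns$class <- factor(introns$class, levels = .SPLICE_CLASSES)
  introns
}

#' @rdname write_intron_table
#' @export
write_intron_bed <- function(introns, path) {
  gr <- GenomicRanges::GRanges(
    introns$seq_name,
    IRanges::IRanges(introns$start, introns$end),
    strand = introns$strand)
  gr$name <- paste(introns$transcript_id, introns$index, introns$combo,
                   sep = "|")
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Detect shift-equivalent alternative intron placements
#'
#' An annotated intron placement is shift-equivalent to the placement moved
#' by s nt (both boundaries together) when the mature mRNA -- the
#' concatenation of the flanking exonic sequence -- is identical under both
#' splicings. This happens exactly when the s-length exon sequence given up
#' at one end equals the s-length intron sequence exposed at the other end,
#' and it is how alignment ambiguity converts e.g. a GC-AG intron into an
#' annotated CA-GG combination. Placements whose shifted interval would
#' leave the sequence (or whose compared flank does) are skipped silently.
#'
#' @param intron A single-row intron data.frame (or list) with seq_name,
#'   start, end, strand.
#' @param assembly A \link[Biostrings]{DNAStringSet}.
#' @param max_shift Maximum absolute shift in nt (default 3).
#' @return data.frame with one row per equivalent placement: shift (signed,
#'   genomic nt), start, end, combo, class. Zero rows when no shift
#'   preserves the mRNA.
#' @export
detect_shift_equivalence <- function(intron, assembly, max_shift = 3) {
  if (max_shift < 1) stop("max_shift must be >= 1")
  sn <- intron$seq_name[1L]
  a <- intron$start[1L]; b <- intron$end[1L]
  strand <- intron$strand[1L]
  chars <- as.character(assembly[[sn]])
  L <- nchar(chars)

  rows <- list()
  for (s in setdiff(seq(-max_shift, max_shift), 0L)) {
    na <- a + s; nb <- b + s
    # need the new intron and one exonic base each side within bounds
    if (na < 2L || nb > L - 1L) next
    if (s > 0L) {
      gained_exon <- substring(chars, a, a + s - 1L)
      exposed_intron <- substring(chars, b + 1L, b + s)
    } else {
      k <- -s
      gained_exon <- substring(chars, b - k + 1L, b)
      exposed_intron <- substring(chars, a - k, a - 1L)
    }
    if (gained_exon != exposed_intron) next
    combo <- intron_combo(data.frame(seq_name = sn, start = na, end = nb,
                                     strand = strand,
                                     stringsAsFactors = FALSE), assembly)
    rows[[length(rows) + 1L]] <- data.frame(
      shift = s, start = na, end = nb, combo = combo,
      class = classify_combo(combo), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(shift = integer(0), start = integer(0),
                      end = integer(0), combo = character(0),
                      class = factor(character(0), levels = .SPLICE_CLASSES),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Mature mRNA under a given intron placement
#'
#' Concatenation of the sequence flanking the intron within a window,
#' oriented 5'\eqn{\to}3' on the coding strand; used to verify
#' shift-equivalent placements byte-for-byte.
#'
#' @param intron Single-row intron (seq_name, start, end, strand).
#' @param assembly A \link[Biostrings]{DNAStringSet}.
#' @param flank_start,flank_end Genomic window (default: whole sequence).
#' @return Character scalar, the spliced sequence of the window.
#' @export
spliced_flanks <- function(intron, assembly, flank_start = 1L,
                           flank_end = NULL) {
  chars <- as.character(assembly[[intron$seq_name[1L]]])
  if (is.null(flank_end)) flank_end <- nchar(chars)
  left <- substring(chars, flank_start, intron$start[1L] - 1L)
  right <- substring(chars, intron$end[1L] + 1L, flank_end)
  mrna <- paste0(left, right)
  if (intron$strand[1L] == "-") mrna <- revcomp(mrna)
  mrna
}
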