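#' Read a per-base coverage track from a BedGraph file
#'
#' BedGraph rows (seq, start, end, depth; 0-based half-open) are expanded
#' to one depth value per base; positions not covered by any row get depth
#' 0. Overlapping rows with conflicting depths are an error; rows
#' restating the same depth are tolerated.
#'
#' @param path Path to a BedGraph file.
#' @param assembly Optional \link[Biostrings]{DNAStringSet}; when given,
#'   per-sequence vectors are padded to the full sequence length and rows
#'   beyond it are an error.
#' @return An object of class \code{coverage_track}: named list of numeric
#'   depth vectors (1-based indexing).
#' @export
read_coverage <- function(path, assembly = NULL) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) stop("negative depth in coverage file: ", path)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(hits) > 0L) {
    qs <- S4Vectors::queryHits(hits); ss <- S4Vectors::subjectHits(hits)
    if (any(gr$score[qs] != gr$score[ss])) {
      stop("overlapping rows with conflicting depths in ", path)
    }
  }
  seq_names <- unique(as.character(GenomicRanges::seqnames(gr)))
  track <- lapply(stats::setNames(seq_names, seq_names), function(sn) {
    sel <- gr[GenomicRanges::seqnames(gr) == sn]
    len <- if (!is.null(assembly)) {
      if (!sn %in% names(assembly)) {
        stop("coverage for unknown sequence: ", sn)
      }
      Biostrings::width(assembly[names(assembly) == sn])
    } else {
      max(GenomicRanges::end(sel))
    }
    if (max(GenomicRanges::end(sel)) > len) {
      stop("coverage row beyond end of sequence ", sn)
    }
    depth <- numeric(len)
    for (i in seq_along(sel)) {
      depth[GenomicRanges::start(sel)[i]:GenomicRanges::end(sel)[i]] <-
        sel$score[i]
    }
    depth
  })
  structure(track, class = "coverage_track")
}

#' Write a coverage track as BedGraph
#'
#' Run-length compressed; zero-depth runs are emitted too, so the file
#' round-trips exactly.
#'
#' @param track A \code{coverage_track} (named list of depth vectors).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_coverage <- function(track, path) {
  rows <- lapply(names(track), function(sn) {
    r <- rle(track[[sn]])
    end <- cumsum(r$lengths)
    start0 <- c(0L, end[-length(end)])
    data.frame(seq = sn, start = start0, end = end, depth = r$values,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Depths at the four positions flanking an intron
#'
#' E5/I5 are the last exonic and first intronic base at the biological 5'
#' (donor) end; I3/E3 the last intronic and first exonic base at the 3'
#' (acceptor) end. On the minus strand the donor positions map to the
#' genomic right end of the interval.
#'
#' @param intron Single-row intron (seq_name, start, end, strand).
#' @param track A \code{coverage_track}.
#' @return Named numeric vector with elements E5, I5, I3, E3.
#' @export
boundary_depths <- function(intron, track) {
  sn <- intron$seq_name[1L]
  depth <- track[[sn]]
  if (is.null(depth)) stop("no coverage for sequence ", sn)
  a <- intron$start[1L]; b <- intron$end[1L]
  if (a < 2L) stop("intron has no upstream exonic flank on ", sn)
  if (b > length(depth) - 1L) {
    stop("intron has no downstream exonic flank on ", sn)
  }
  if (intron$strand[1L] == "-") {
    c(E5 = depth[b + 1L], I5 = depth[b], I3 = depth[a], E3 = depth[a - 1L])
  } else {
    c(E5 = depth[a - 1L], I5 = depth[a], I3 = depth[b], E3 = depth[b + 1L])
  }
}

#' Apply the coverage-drop support rule to boundary depths
#'
#' A splice site is supported by RNA-Seq when the read depth drops by at
#' least \code{min_drop} (default 20\%) stepping from the terminal exonic
#' base to the adjacent intronic base. Usage is \code{1 - I/E} clipped to
#' [0, 1], so that supported is exactly usage >= \code{min_drop}; with zero
#' exonic depth the site is unsupported with reason \code{no_expression}
#' and undefined usage.
#'
#' @param depths Named vector from \code{\link{boundary_depths}}.
#' @param min_drop Minimum relative drop in (0, 1); default 0.2.
#' @return A list (class \code{support_call}) with donor_supported,
#'   acceptor_supported, combination_supported, donor_usage,
#'   acceptor_usage, donor_reason, acceptor_reason.
#' @export
evaluate_support <- function(depths, min_drop = 0.2) {
  if (min_drop <= 0 || min_drop >= 1) stop("min_drop must be in (0, 1)")
  site <- function(E, I) {
    if (E <= 0) {
      list(supported = FALSE, usage = NA_real_, reason = "no_expression")
    } else {
      usage <- min(max(1 - I / E, 0), 1)
      # epsilon keeps the exact-boundary case (I = (1-min_drop)*E) supported
      # in floating point, so supported <=> usage >= min_drop holds
      list(supported = I <= (1 - min_drop) * E + 1e-9 * E, usage = usage,
           reason = NA_character_)
    }
  }
  don <- site(depths[["E5"]], depths[["I5"]])
  acc <- site(depths[["E3"]], depths[["I3"]])
  structure(list(donor_supported = don$supported,
                 acceptor_supported = acc$supported,
                 combination_supported = don$supported && acc$supported,
                 donor_usage = don$usage, acceptor_usage = acc$usage,
                 donor_reason = don$reason, acceptor_reason = acc$reason),
            class = "support_call")
}

#' Evaluate coverage support for a whole intron table
#'
#' @param introns Intron data.frame from \code{\link{extract_introns}}.
#' @param track A \code{coverage_track}.
#' @param min_drop Minimum relative drop (default 0.2).
#' @return data.frame: the intron table plus E5, I5, I3, E3,
#'   donor_supported, acceptor_supported, combination_supported,
#'   donor_usage, acceptor_usage, donor_reason, acceptor_reason, and
#'   \code{no_coverage} (TRUE where the track lacks the sequence).
#' @export
validate_introns <- function(introns, track, min_drop = 0.2) {
  n <- nrow(introns)
  cols <- data.frame(E5 = NA_real_, I5 = NA_real_, I3 = NA_real_,
                     E3 = NA_real_,
                     donor_supported = NA, acceptor_supported = NA,
                     combination_supported = NA,
                     donor_usage = NA_real_, acceptor_usage = NA_real_,
                     donor_reason = NA_character_,
                     acceptor_reason = NA_character_,
                     no_coverage = FALSE,
                     stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
  for (i in seq_len(n)) {
    if (!introns$seq_name[i] %in% names(track)) {
      cols$no_coverage[i] <- TRUE
      next
    }
    bd <- boundary_depths(introns[i, ], track)
    sc <- evaluate_support(bd, min_drop)
    cols[i, c("E5", "I5", "I3", "E3")] <- as.list(bd)
    cols$donor_supported[i] <- sc$donor_supported
    cols$acceptor_supported[i] <- sc$acceptor_supported
    cols$combination_supported[i] <- sc$combination_supported
    cols$donor_usage[i] <- sc$donor_usage
    cols$acceptor_usage[i] <- sc$acceptor_usage
    cols$donor_reason[i] <- sc$donor_reason
    cols$acceptor_reason[i] <- sc$acceptor_reason
  }
  out <- cbind(introns, cols)
  rownames(out) <- NULL
  out
}

#' Summarise splice-site usage per class
#'
#' Per splice-site class: number of introns with defined usage, median
#' donor (5') and acceptor (3') usage, the Spearman correlation between
#' paired donor and acceptor usage, and the supported fraction.
#'
#' @param calls data.frame from \code{\link{validate_introns}} (needs
#'   class, donor_usage, acceptor_usage, combination_supported).
#' @return data.frame with one row per class: class, n, median_donor_usage,
#'   median_acceptor_usage, usage_rho (NA when constant or n < 3),
#'   supported_fraction.
#' @export
summarize_usage <- function(calls) {
  classes <- .SPLICE_CLASSES[1:4]
  rows <- lapply(classes, function(cl) {
    d <- calls[!is.na(calls$class) & calls$class == cl, , drop = FALSE]
    ok <- !is.na(d$donor_usage) & !is.na(d$acceptor_usage)
    d <- d[ok, , drop = FALSE]
    rho <- NA_real_
    if (nrow(d) >= 3L && stats::var(d$donor_usage) > 0 &&
        stats::var(d$acceptor_usage) > 0) {
      rho <- spearman_correlation(d$donor_usage, d$acceptor_usage)$rho
    }
    data.frame(class = cl, n = nrow(d),
               median_donor_usage =
                 if (nrow(d)) stats::median(d$donor_usage) else NA_real_,
               median_acceptor_usage =
                 if (nrow(d)) stats::median(d$acceptor_usage) else NA_real_,
               usage_rho = rho,
               supported_fraction =
                 if (nrow(d)) mean(d$combination_supported) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validation ratios: fraction of splice sites supported by coverage
#'
#' Reported overall and per class, both excluding introns without
#' expression (no exonic coverage at either boundary) and including them
#' as unsupported.
#'
#' @param calls data.frame from \code{\link{validate_introns}}.
#' @return data.frame with columns class ("all" plus the four classes),
#'   n_total, n_expressed, n_supported, ratio_excluding (supported /
#'   expressed; NA when nothing expressed), ratio_including (supported /
#'   total).
#' @export
validation_ratio <- function(calls) {
  calls <- calls[!calls$no_coverage, , drop = FALSE]
  groups <- c("all", .SPLICE_CLASSES[1:4])
  rows <- lapply(groups, function(cl) {
    d <- if (cl == "all") calls else {
      calls[!is.na(calls$class) & calls$class == cl, , drop = FALSE]
    }
    expressed <- !is.na(d$donor_usage) & !is.na(d$acceptor_usage)
    supported <- d$combination_supported %in% TRUE
    data.frame(class = cl, n_total = nrow(d),
               n_expressed = sum(expressed),
               n_supported = sum(supported),
               ratio_excluding = if (sum(expressed) > 0) {
                 sum(supported & expressed) / sum(expressed)
               } else NA_real_,
               ratio_including = if (nrow(d) > 0) {
                 sum(supported) / nrow(d)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
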