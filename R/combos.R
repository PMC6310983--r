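#' Splice-site combination utilities
#'
#' A splice-site combination is the 4-letter concatenation of the donor
#' dinucleotide (first two intronic bases, 5' end) and the acceptor
#' dinucleotide (last two intronic bases, 3' end), written in DNA letters on
#' the coding strand (GT, not GU). The canonical combination is GT-AG; GC-AG
#' and AT-AC are the major non-canonical combinations; the remaining 253
#' unambiguous combinations are minor non-canonical. Any combination
#' containing a non-A/C/G/T IUPAC character is "ambiguous" and is masked
#' from diversity statistics.
#'
#' @name splice-combos
NULL

.SPLICE_CLASSES <- c("canonical", "major_GC_AG", "major_AT_AC", "minor",
                     "ambiguous")

#' All 256 unambiguous splice-site combinations
#'
#' @return Character vector of the 256 four-letter combinations over
#'   \{A,C,G,T\}, in lexicographic order.
#' @export
all_splice_combos <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p4 = b, p3 = b, p2 = b, p1 = b,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3, g$p4))
}

.check_combo <- function(combo) {
  if (!is.character(combo)) stop("combo must be a character vector")
  bad <- nchar(combo) != 4L
  if (any(bad)) {
    stop("splice-site combination must be exactly 4 characters, got: ",
         paste(unique(combo[bad]), collapse = ", "))
  }
  invisible(combo)
}

#' Is a combination ambiguous?
#'
#' @param combo Character vector of 4-letter combinations.
#' @return Logical vector: TRUE where any character is outside A/C/G/T.
#' @export
is_ambiguous_combo <- function(combo) {
  .check_combo(combo)
  grepl("[^ACGT]", combo)
}

#' Classify splice-site combinations
#'
#' GT-AG is canonical; GC-AG and AT-AC are the two major non-canonical
#' combinations; all other unambiguous combinations are minor non-canonical;
#' combinations containing a non-A/C/G/T character are ambiguous.
#'
#' @param combo Character vector of 4-letter combinations (donor dinucleotide
#'   followed by acceptor dinucleotide, biological orientation).
#' @return Factor with levels canonical, major_GC_AG, major_AT_AC, minor,
#'   ambiguous.
#' @examples
#' classify_combo(c("GTAG", "GCAG", "ATAC", "CAGG", "GNAG"))
#' @export
classify_combo <- function(combo) {
  .check_combo(combo)
  out <- rep("minor", length(combo))
  out[combo == "GTAG"] <- "canonical"
  out[combo == "GCAG"] <- "major_GC_AG"
  out[combo == "ATAC"] <- "major_AT_AC"
  out[is_ambiguous_combo(combo)] <- "ambiguous"
  factor(out, levels = .SPLICE_CLASSES)
}

#' Hamming distance between splice-site combinations
#'
#' Position-wise mismatch count between two unambiguous 4-letter
#' combinations; used as the divergence of a combination from a reference
#' such as the canonical GT-AG.
#'
#' @param combo,reference Character vectors of unambiguous combinations
#'   (recycled to common length).
#' @return Integer vector of distances in 0..4.
#' @examples
#' combo_hamming("CAGG", "GTAG")  # 3
#' @export
combo_hamming <- function(combo, reference = "GTAG") {
  .check_combo(combo)
  .check_combo(reference)
  if (any(is_ambiguous_combo(combo)) || any(is_ambiguous_combo(reference))) {
    stop("combo_hamming requires unambiguous combinations")
  }
  n <- max(length(combo), length(reference))
  combo <- rep_len(combo, n)
  reference <- rep_len(reference, n)
  a <- matrix(unlist(strsplit(combo, "", fixed = TRUE)), nrow = 4L)
  b <- matrix(unlist(strsplit(reference, "", fixed = TRUE)), nrow = 4L)
  as.integer(colSums(a != b))
}

.REFERENCE_COMBOS <- c("GTAG", "GCAG", "ATAC")

#' Closest reference combination for a minor combination
#'
#' Assigns a minor non-canonical combination to the nearest of the canonical
#' and major combinations (GT-AG, GC-AG, AT-AC) by Hamming distance and
#' lists the single-base substitutions implied by that origin. Ties are
#' broken in the preference order GT-AG > GC-AG > AT-AC (the globally most
#' frequent origin wins).
#'
#' @param combo A single unambiguous minor combination.
#' @return A list with elements \code{reference} (the chosen origin),
#'   \code{distance}, and \code{substitutions}, a data.frame with columns
#'   \code{position} (1..4), \code{ref_base}, \code{obs_base}.
#' @examples
#' closest_reference("GCAC")  # GC-AG origin, G->C at position 4
#' @export
closest_reference <- function(combo) {
  .check_combo(combo)
  if (length(combo) != 1L) stop("closest_reference takes a single combination")
  if (is_ambiguous_combo(combo)) stop("ambiguous combination: ", combo)
  cls <- as.character(classify_combo(combo))
  if (cls != "minor") {
    stop("closest_reference is defined for minor combinations only, got ",
         combo, " (", cls, ")")
  }
  d <- combo_hamming(rep(combo, 3L), .REFERENCE_COMBOS)
  ref <- .REFERENCE_COMBOS[which.min(d)]  # which.min: first minimum wins
  oc <- strsplit(combo, "", fixed = TRUE)[[1L]]
  rc <- strsplit(ref, "", fixed = TRUE)[[1L]]
  pos <- which(oc != rc)
  list(reference = ref,
       distance = min(d),
       substitutions = data.frame(position = pos,
                                  ref_base = rc[pos],
                                  obs_base = oc[pos],
                                  stringsAsFactors = FALSE))
}

#' Reverse complement of character DNA
#'
#' Thin vectorised wrapper around Biostrings' IUPAC-aware reverse complement.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
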