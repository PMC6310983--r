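#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased (IUPAC ambiguity codes are retained) and named
#' by the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped, multi-record).
#' @return A \link[Biostrings]{DNAStringSet} with unique names.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup) > 0L) {
    stop("duplicate sequence name(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) stop("empty sequence in FASTA")
  seqs
}

#' Read a gene annotation from GFF3
#'
#' Parses gene, mRNA/transcript and CDS features linked by ID/Parent
#' attributes. Coordinates are kept 1-based closed (the GFF3 and
#' R/Bioconductor convention). Features on sequences absent from the
#' assembly are dropped and counted. Only CDS structure is retained;
#' UTR/exon features are ignored.
#'
#' @param path Path to a GFF3 file.
#' @param assembly Optional \link[Biostrings]{DNAStringSet} from
#'   \code{\link{read_genome}}; when given, features on unknown sequences
#'   are dropped (count recorded in the result).
#' @return An object of class \code{gene_annotation}: a list with data
#'   frames \code{genes} (gene_id, seq_name, strand), \code{transcripts}
#'   (transcript_id, gene_id), \code{cds} (transcript_id, start, end), the
#'   source path, and \code{dropped_features}, the number of features
#'   discarded for lying on sequences absent from the assembly.
#' @export
read_annotation <- function(path, assembly = NULL) {
  if (!file.exists(path)) stop("annotation GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  keep <- type %in% c("gene", "mRNA", "transcript", "CDS")
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)

  dropped <- 0L
  if (!is.null(assembly)) {
    on_known <- as.character(GenomicRanges::seqnames(gr)) %in% names(assembly)
    dropped <- sum(!on_known)
    # drop whole genes (and their children) that live on unknown sequences
    bad_genes <- unique(mc$ID[type == "gene" & !on_known])
    gr <- gr[on_known]
    mc <- S4Vectors::mcols(gr)
    type <- as.character(mc$type)
    if (length(bad_genes) > 0L) {
      parent1 <- .first_parent(mc$Parent)
      tx_bad <- mc$ID[type %in% c("mRNA", "transcript") & parent1 %in% bad_genes]
      keep2 <- !(parent1 %in% c(bad_genes, tx_bad))
      dropped <- dropped + sum(!keep2)
      gr <- gr[keep2]
      mc <- S4Vectors::mcols(gr)
      type <- as.character(mc$type)
    }
  }

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  is_cds <- type == "CDS"

  genes <- data.frame(
    gene_id = as.character(mc$ID[is_gene]),
    seq_name = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    stringsAsFactors = FALSE)
  if (anyNA(genes$gene_id)) stop("gene feature without ID attribute in ", path)
  dupg <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dupg) > 0L) {
    stop("duplicate gene ID(s) in annotation: ", paste(dupg, collapse = ", "))
  }

  tx_parent <- .first_parent(mc$Parent[is_tx])
  transcripts <- data.frame(
    transcript_id = as.character(mc$ID[is_tx]),
    gene_id = tx_parent,
    stringsAsFactors = FALSE)
  orphan_tx <- transcripts$transcript_id[
    is.na(transcripts$gene_id) | !(transcripts$gene_id %in% genes$gene_id)]
  if (length(orphan_tx) > 0L) {
    stop("transcript(s) with missing/unknown Parent gene near line ",
         .gff_line_of(path, orphan_tx[1L]), ": ",
         paste(orphan_tx, collapse = ", "))
  }

  cds_parent <- .first_parent(mc$Parent[is_cds])
  cds <- data.frame(
    transcript_id = cds_parent,
    start = GenomicRanges::start(gr)[is_cds],
    end = GenomicRanges::end(gr)[is_cds],
    stringsAsFactors = FALSE)
  bad_cds <- which(is.na(cds$transcript_id) |
                     !(cds$transcript_id %in% transcripts$transcript_id))
  if (length(bad_cds) > 0L) {
    i <- bad_cds[1L]
    stop("CDS with missing/unknown Parent at line ",
         .gff_line_of(path, what = NULL, cds_row = cds[i, ],
                      seq = as.character(GenomicRanges::seqnames(gr))[is_cds][i]))
  }
  cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]
  rownames(cds) <- NULL

  structure(list(genes = genes, transcripts = transcripts, cds = cds,
                 source = path, dropped_features = dropped),
            class = "gene_annotation")
}

# Parent columns from rtracklayer are CharacterList; take the first parent.
.first_parent <- function(parent) {
  if (length(parent) == 0L) return(character(0))
  vapply(as.list(parent), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, character(1))
}

# Best-effort line number lookup for error messages.
.gff_line_of <- function(path, what = NULL, cds_row = NULL, seq = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!is.null(what)) {
    hit <- grep(paste0("ID=", what, "(;|$)"), lines)[1L]
  } else {
    pat <- paste0("^", seq, "\t.*\tCDS\t", cds_row$start, "\t", cds_row$end,
                  "\t")
    hit <- grep(pat, lines)[1L]
  }
  if (is.na(hit)) "?" else hit
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      nrow(x$cds), "CDS segments",
      sprintf("(%d features dropped; source: %s)\n",
              x$dropped_features, x$source))
  invisible(x)
}

#' Write a gene annotation back to GFF3
#'
#' Inverse of \code{\link{read_annotation}} up to attribute ordering; used
#' for provenance and round-trip checks. CDS phase is recomputed from the
#' transcript structure.
#'
#' @param annotation A \code{gene_annotation}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  g <- annotation$genes
  tx <- merge(annotation$transcripts, g, by = "gene_id", sort = FALSE)
  cds <- merge(annotation$cds, tx, by = "transcript_id", sort = FALSE)
  cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]

  # feature extents: transcripts and genes span their CDS
  tx_start <- tapply(cds$start, cds$transcript_id, min)
  tx_end <- tapply(cds$end, cds$transcript_id, max)
  tx2 <- tx
  tx2$start <- as.integer(tx_start[tx2$transcript_id])
  tx2$end <- as.integer(tx_end[tx2$transcript_id])
  g_start <- tapply(tx2$start, tx2$gene_id, min)
  g_end <- tapply(tx2$end, tx2$gene_id, max)
  g2 <- g
  g2$start <- as.integer(g_start[g2$gene_id])
  g2$end <- as.integer(g_end[g2$gene_id])

  phase <- .cds_phase(cds)
  lines <- c("##gff-version 3",
    sprintf("%s\tncsplice\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g2$seq_name, g2$start, g2$end, g2$strand, g2$gene_id),
    sprintf("%s\tncsplice\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            tx2$seq_name, tx2$start, tx2$end, tx2$strand,
            tx2$transcript_id, tx2$gene_id),
    sprintf("%s\tncsplice\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
            cds$seq_name, cds$start, cds$end, cds$strand, phase,
            cds$transcript_id))
  writeLines(lines, path)
  invisible(path)
}

# GFF3 phase per CDS segment, honouring strand (translation order).
.cds_phase <- function(cds) {
  phase <- integer(nrow(cds))
  for (i in split(seq_len(nrow(cds)), cds$transcript_id)) {
    ord <- if (cds$strand[i[1L]] == "-") rev(i) else i
    w <- cds$end[ord] - cds$start[ord] + 1L
    before <- c(0L, cumsum(w))[seq_along(w)]
    phase[ord] <- (3L - before %% 3L) %% 3L
  }
  phase
}

#' Filter genes with annotation errors or inconsistencies
#'
#' A transcript is valid when it has at least one CDS segment, all segments
#' lie within the bounds of their sequence, segments do not overlap, the
#' total CDS length is a multiple of 3, and the strand-aware conceptual
#' translation contains no internal stop codon. Genes retaining at least
#' one valid transcript are kept (with only their valid transcripts);
#' all other genes are removed and accounted for in the report.
#'
#' @param annotation A \code{gene_annotation}.
#' @param assembly The matching \link[Biostrings]{DNAStringSet}.
#' @return A list with elements \code{annotation} (filtered) and
#'   \code{report}, a \code{filter_report}: counts of removals per reason
#'   (\code{no_cds}, \code{out_of_bounds}, \code{overlapping_cds},
#'   \code{not_multiple_of_3}, \code{internal_stop}) and a data.frame
#'   \code{removed} (gene_id, reason).
#' @export
filter_genes <- function(annotation, assembly) {
  g <- annotation$genes
  tx <- annotation$transcripts
  cds <- annotation$cds

  tx_status <- .transcript_status(annotation, assembly)
  tx$status <- tx_status[tx$transcript_id]
  # genes with no annotated transcript at all count as no_cds
  gene_tx <- split(tx$status, factor(tx$gene_id, levels = g$gene_id))
  reasons <- c("no_cds", "out_of_bounds", "overlapping_cds",
               "not_multiple_of_3", "internal_stop")
  gene_reason <- vapply(gene_tx, function(st) {
    if (length(st) == 0L) return("no_cds")
    if (any(st == "ok")) return("ok")
    # report the least severe failure among the gene's transcripts
    reasons[min(match(st, reasons))]
  }, character(1))

  keep_genes <- names(gene_reason)[gene_reason == "ok"]
  removed <- data.frame(gene_id = names(gene_reason)[gene_reason != "ok"],
                        reason = unname(gene_reason[gene_reason != "ok"]),
                        stringsAsFactors = FALSE)
  counts <- vapply(reasons, function(r) sum(removed$reason == r), integer(1))

  tx_keep <- tx[tx$gene_id %in% keep_genes & tx$status == "ok",
                c("transcript_id", "gene_id")]
  rownames(tx_keep) <- NULL
  ann <- structure(list(
    genes = g[g$gene_id %in% keep_genes, , drop = FALSE],
    transcripts = tx_keep,
    cds = cds[cds$transcript_id %in% tx_keep$transcript_id, , drop = FALSE],
    source = annotation$source,
    dropped_features = annotation$dropped_features),
    class = "gene_annotation")
  rownames(ann$genes) <- rownames(ann$cds) <- NULL

  report <- structure(list(counts = counts, removed = removed,
                           n_input = nrow(g), n_retained = length(keep_genes)),
                      class = "filter_report")
  list(annotation = ann, report = report)
}

# Per-transcript validity: "ok" or the first failing reason. Vectorised
# over all transcripts; translation is batched through one DNAStringSet.
.transcript_status <- function(annotation, assembly) {
  tx <- annotation$transcripts
  cds <- annotation$cds
  g <- annotation$genes
  tx_meta <- merge(tx, g, by = "gene_id", sort = FALSE)
  seq_len_of <- stats::setNames(Biostrings::width(assembly), names(assembly))

  status <- stats::setNames(rep("ok", nrow(tx_meta)), tx_meta$transcript_id)
  strand_of <- stats::setNames(tx_meta$strand, tx_meta$transcript_id)
  seq_of <- stats::setNames(tx_meta$seq_name, tx_meta$transcript_id)

  status[!(tx_meta$transcript_id %in% cds$transcript_id)] <- "no_cds"

  cds <- cds[cds$transcript_id %in% tx_meta$transcript_id, , drop = FALSE]
  cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]
  cds$seq_name <- seq_of[cds$transcript_id]
  slen <- seq_len_of[cds$seq_name]
  oob <- is.na(slen) | cds$start < 1L | cds$end > slen |
    cds$end < cds$start
  status[unique(cds$transcript_id[oob])] <- "out_of_bounds"

  same <- cds$transcript_id[-1L] == cds$transcript_id[-nrow(cds)]
  ovl <- same & cds$start[-1L] <= cds$end[-nrow(cds)]
  bad_ovl <- unique(cds$transcript_id[-1L][ovl])
  status[bad_ovl[status[bad_ovl] == "ok"]] <- "overlapping_cds"

  total <- rowsum(cds$end - cds$start + 1L, cds$transcript_id)
  bad_len <- rownames(total)[total[, 1L] < 3L | total[, 1L] %% 3L != 0L]
  status[bad_len[status[bad_len] == "ok"]] <- "not_multiple_of_3"

  check <- names(status)[status == "ok"]
  if (length(check) > 0L) {
    d <- cds[cds$transcript_id %in% check, , drop = FALSE]
    piece <- character(nrow(d))
    for (sn in unique(d$seq_name)) {
      j <- which(d$seq_name == sn)
      chars <- as.character(assembly[[sn]])
      piece[j] <- substring(chars, d$start[j], d$end[j])
    }
    spliced <- vapply(split(piece, d$transcript_id), paste, character(1),
                      collapse = "")
    minus <- strand_of[names(spliced)] == "-"
    if (any(minus)) spliced[minus] <- revcomp(spliced[minus])
    aa <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAStringSet(spliced),
      if.fuzzy.codon = "X", no.init.codon = TRUE)))
    internal <- substr(aa, 1L, nchar(aa) - 1L)
    bad <- grepl("*", internal, fixed = TRUE)
    status[names(spliced)[bad]] <- "internal_stop"
  }
  status
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_retained, "of", x$n_input, "genes retained\n")
  for (r in names(x$counts)) {
    if (x$counts[[r]] > 0L) cat("  removed (", r, "): ", x$counts[[r]],
                                "\n", sep = "")
  }
  invisible(x)
}

#' Write a filter report as TSV plus JSON summary
#'
#' @param report A \code{filter_report} from \code{\link{filter_genes}}.
#' @param tsv_path,json_path Output paths (either may be NULL to skip).
#' @return Invisibly, the report.
#' @export
write_filter_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(report$removed, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(n_input = report$n_input,
                              n_retained = report$n_retained,
                              removed_by_reason = as.list(report$counts)),
                         json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}

#' Select the representative transcript of each gene
#'
#' The representative transcript encodes the longest polypeptide; after the
#' divisible-by-3 filter this is equivalently the transcript with the
#' largest total CDS length. Ties are broken by the lexicographically
#' smallest transcript ID, so the choice is deterministic and independent
#' of input order.
#'
#' @param annotation A filtered \code{gene_annotation}.
#' @param gene_id Optional single gene ID; default all genes.
#' @return data.frame with columns gene_id, transcript_id, cds_length.
#' @export
select_representative_transcript <- function(annotation, gene_id = NULL) {
  tx <- annotation$transcripts
  if (!is.null(gene_id)) {
    tx <- tx[tx$gene_id %in% gene_id, , drop = FALSE]
    if (nrow(tx) == 0L) stop("gene has no valid transcripts: ", gene_id)
  }
  cds <- annotation$cds
  len <- tapply(cds$end - cds$start + 1L, cds$transcript_id, sum)
  tx$cds_length <- as.integer(len[tx$transcript_id])
  if (anyNA(tx$cds_length)) {
    stop("transcript without CDS encountered; run filter_genes first")
  }
  ord <- order(tx$gene_id, -tx$cds_length, tx$transcript_id)
  tx <- tx[ord, , drop = FALSE]
  rep_tx <- tx[!duplicated(tx$gene_id), c("gene_id", "transcript_id",
                                          "cds_length")]
  rownames(rep_tx) <- NULL
  rep_tx
}
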