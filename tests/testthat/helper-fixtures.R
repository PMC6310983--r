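# In-code fixtures shared across test files. Everything is built at test
# time; no binary data on disk.

# write a FASTA file from a named character vector, return path
write_fasta_fixture <- function(seqs, dir = tempdir()) {
  path <- tempfile("genome", tmpdir = dir, fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), path)
  path
}

# write GFF3 lines (with standard header), return path
write_gff_fixture <- function(lines, dir = tempdir()) {
  path <- tempfile("ann", tmpdir = dir, fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_row <- function(seq, type, start, end, strand, attrs) {
  paste(seq, "test", type, start, end, ".", strand, ".", attrs, sep = "\t")
}

# a clean two-exon plus-strand gene: ATG GTAAGT...CTCTAG GCC TAA
# CDS1 = 1..3 (ATG), intron = 4..23 (20 nt, GT..AG), CDS2 = 24..29
two_exon_genome <- function() {
  seq <- paste0("ATG", "GTAAGTTTTTCTCTCTCTAG", "GCCTAA",
                "ACGTACGTAC")  # trailing spacer
  fa <- write_fasta_fixture(list(chr1 = seq))
  gff <- write_gff_fixture(c(
    gff_row("chr1", "gene", 1, 29, "+", "ID=g1"),
    gff_row("chr1", "mRNA", 1, 29, "+", "ID=t1;Parent=g1"),
    gff_row("chr1", "CDS", 1, 3, "+", "Parent=t1"),
    gff_row("chr1", "CDS", 24, 29, "+", "Parent=t1")))
  list(fasta = fa, gff3 = gff, seq = seq)
}

# the same gene mirrored onto the minus strand of the reverse complement
two_exon_genome_minus <- function() {
  fx <- two_exon_genome()
  L <- nchar(fx$seq)
  rseq <- ncsplice::revcomp(fx$seq)
  fa <- write_fasta_fixture(list(chr1 = rseq))
  mirror <- function(s, e) c(L - e + 1, L - s + 1)
  c1 <- mirror(1, 3); c2 <- mirror(24, 29)
  gff <- write_gff_fixture(c(
    gff_row("chr1", "gene", mirror(1, 29)[1], mirror(1, 29)[2], "-",
            "ID=g1"),
    gff_row("chr1", "mRNA", mirror(1, 29)[1], mirror(1, 29)[2], "-",
            "ID=t1;Parent=g1"),
    gff_row("chr1", "CDS", c2[1], c2[2], "-", "Parent=t1"),
    gff_row("chr1", "CDS", c1[1], c1[2], "-", "Parent=t1")))
  list(fasta = fa, gff3 = gff, seq = rseq)
}

# profile built directly from a named count vector
profile_from_counts <- function(counts, species = "toy") {
  full <- stats::setNames(rep(0L, 256L), ncsplice::all_splice_combos())
  full[names(counts)] <- as.integer(counts)
  structure(list(species = species, counts = full, ambiguous_masked = 0L,
                 total_introns = sum(full), min_length = 20),
            class = "species_profile")
}

# independent Spearman oracle: average ranks, then Pearson on the ranks
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# write a small VCF fixture; records = data.frame(chrom,pos,ref,alt,gt)
write_vcf_fixture <- function(records, dir = tempdir()) {
  path <- tempfile("var", tmpdir = dir, fileext = ".vcf")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", "s1", sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  records$chrom, records$pos, records$ref, records$alt,
                  records$gt)
  writeLines(c(header, body), path)
  path
}

# write a BedGraph fixture from data.frame(seq,start,end,depth), 0-based
write_bedgraph_fixture <- function(rows, dir = tempdir()) {
  path <- tempfile("cov", tmpdir = dir, fileext = ".bedgraph")
  writeLines(sprintf("%s\t%d\t%d\t%g", rows$seq, rows$start, rows$end,
                     rows$depth), path)
  path
}
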