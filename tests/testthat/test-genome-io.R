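test_that("read_genome normalises case, concatenates lines, names by first token", {
  fa <- write_fasta_fixture(list(chr1 = "acgT"))
  asm <- read_genome(fa)
  expect_equal(as.character(asm), c(chr1 = "ACGT"))

  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">a some description", "AC", "GT", ">b", "NN"), fa2)
  asm2 <- read_genome(fa2)
  expect_equal(names(asm2), c("a", "b"))
  expect_equal(as.character(asm2[["a"]]), "ACGT")
  expect_equal(as.character(asm2[["b"]]), "NN")
})

test_that("read_genome rejects empty files and duplicate names", {
  empty <- tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_genome(empty), "no sequences")

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">a desc", "ACGT", ">a", "TT"), dup)
  expect_error(read_genome(dup), "duplicate.*a")
})

test_that("read_annotation builds the gene/transcript/CDS structure", {
  fa <- write_fasta_fixture(list(chr1 = strrep("ACGT", 30)))
  gff <- write_gff_fixture(c(
    gff_row("chr1", "gene", 1, 100, "+", "ID=g1"),
    gff_row("chr1", "mRNA", 1, 100, "+", "ID=t1;Parent=g1"),
    gff_row("chr1", "CDS", 1, 30, "+", "Parent=t1"),
    gff_row("chr1", "CDS", 61, 99, "+", "Parent=t1"),
    gff_row("chr1", "mRNA", 1, 100, "+", "ID=t2;Parent=g1"),
    gff_row("chr1", "CDS", 1, 30, "+", "Parent=t2"),
    gff_row("chr1", "CDS", 71, 100, "+", "Parent=t2")))
  ann <- read_annotation(gff, read_genome(fa))
  expect_equal(nrow(ann$genes), 1L)
  expect_equal(nrow(ann$transcripts), 2L)
  expect_equal(nrow(ann$cds), 4L)
  # GFF3 1-based inclusive coordinates are kept as-is internally
  expect_equal(ann$cds$start[ann$cds$transcript_id == "t1"], c(1L, 61L))
  expect_equal(ann$cds$end[ann$cds$transcript_id == "t1"], c(30L, 99L))
})

test_that("read_annotation errors on CDS with unknown Parent, citing the line", {
  fa <- write_fasta_fixture(list(chr1 = strrep("ACGT", 30)))
  gff <- write_gff_fixture(c(
    gff_row("chr1", "gene", 1, 100, "+", "ID=g1"),
    gff_row("chr1", "mRNA", 1, 100, "+", "ID=t1;Parent=g1"),
    gff_row("chr1", "CDS", 1, 30, "+", "Parent=t_undefined")))
  expect_error(read_annotation(gff, read_genome(fa)),
               "CDS with missing/unknown Parent at line 4")
})

test_that("features on sequences absent from the assembly are dropped and counted", {
  fa <- write_fasta_fixture(list(chr1 = strrep("ACGT", 30)))
  gff <- write_gff_fixture(c(
    gff_row("chr1", "gene", 1, 100, "+", "ID=g1"),
    gff_row("chr1", "mRNA", 1, 100, "+", "ID=t1;Parent=g1"),
    gff_row("chr1", "CDS", 1, 30, "+", "Parent=t1"),
    gff_row("chrZ", "gene", 1, 50, "+", "ID=g2"),
    gff_row("chrZ", "mRNA", 1, 50, "+", "ID=t9;Parent=g2"),
    gff_row("chrZ", "CDS", 1, 30, "+", "Parent=t9")))
  ann <- read_annotation(gff, read_genome(fa))
  expect_equal(ann$genes$gene_id, "g1")
  expect_equal(ann$dropped_features, 3L)
})

test_that("filter_genes removes out-of-bounds, internal-stop and overlap cases with reasons", {
  # g1 clean; g2 CDS beyond sequence end; g3 internal TAA in frame;
  # g4 overlapping CDS segments
  clean <- two_exon_genome()
  seq2 <- paste0(clean$seq, "ATGTAACCCTGA", strrep("A", 20))
  # g3: ATG TAA CCC TGA at 40..51 -> internal stop after codon 1
  fa <- write_fasta_fixture(list(chr1 = seq2))
  gff <- write_gff_fixture(c(
    gff_row("chr1", "gene", 1, 29, "+", "ID=g1"),
    gff_row("chr1", "mRNA", 1, 29, "+", "ID=t1;Parent=g1"),
    gff_row("chr1", "CDS", 1, 3, "+", "Parent=t1"),
    gff_row("chr1", "CDS", 24, 29, "+", "Parent=t1"),
    gff_row("chr1", "gene", 1, 2000, "+", "ID=g2"),
    gff_row("chr1", "mRNA", 1, 2000, "+", "ID=t2;Parent=g2"),
    gff_row("chr1", "CDS", 1998, 2000, "+", "Parent=t2"),
    gff_row("chr1", "gene", 40, 51, "+", "ID=g3"),
    gff_row("chr1", "mRNA", 40, 51, "+", "ID=t3;Parent=g3"),
    gff_row("chr1", "CDS", 40, 51, "+", "Parent=t3"),
    gff_row("chr1", "gene", 1, 29, "+", "ID=g4"),
    gff_row("chr1", "mRNA", 1, 29, "+", "ID=t4;Parent=g4"),
    gff_row("chr1", "CDS", 1, 6, "+", "Parent=t4"),
    gff_row("chr1", "CDS", 4, 9, "+", "Parent=t4")))
  asm <- read_genome(fa)
  ann <- read_annotation(gff, asm)
  flt <- filter_genes(ann, asm)
  expect_setequal(flt$annotation$genes$gene_id, "g1")
  rm <- flt$report$removed
  expect_equal(rm$reason[rm$gene_id == "g2"], "out_of_bounds")
  expect_equal(rm$reason[rm$gene_id == "g3"], "internal_stop")
  expect_equal(rm$reason[rm$gene_id == "g4"], "overlapping_cds")
  # removed + retained accounts for every input gene
  expect_equal(nrow(rm) + flt$report$n_retained, flt$report$n_input)
})

test_that("filter_genes is idempotent", {
  fx <- two_exon_genome()
  asm <- read_genome(fx$fasta)
  ann <- read_annotation(fx$gff3, asm)
  once <- filter_genes(ann, asm)
  twice <- filter_genes(once$annotation, asm)
  expect_equal(twice$annotation, once$annotation)
  expect_equal(nrow(twice$report$removed), 0L)
})

test_that("representative transcript maximises CDS length with lexicographic ties", {
  ann <- structure(list(
    genes = data.frame(gene_id = "g1", seq_name = "chr1", strand = "+",
                       stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = c("t2", "t1", "t3"),
                             gene_id = "g1", stringsAsFactors = FALSE),
    cds = data.frame(transcript_id = c("t2", "t1", "t3"),
                     start = c(1L, 1L, 1L),
                     end = c(300L, 300L, 150L), stringsAsFactors = FALSE),
    source = "in-memory", dropped_features = 0L),
    class = "gene_annotation")
  rep1 <- select_representative_transcript(ann)
  expect_equal(rep1$transcript_id, "t1")  # tie 300 vs 300 -> smaller ID
  expect_equal(rep1$cds_length, 300L)

  # invariance to transcript input order
  ann2 <- ann
  ord <- c(3L, 1L, 2L)
  ann2$transcripts <- ann2$transcripts[ord, ]
  ann2$cds <- ann2$cds[ord, ]
  expect_equal(select_representative_transcript(ann2), rep1)
})

test_that("annotation round-trips through GFF3 with identical intervals", {
  gen <- generate_genome(generator_config(n_genes = 15, seed = 5))
  path <- tempfile(fileext = ".gff3")
  write_annotation(gen$annotation, path)
  back <- read_annotation(path, gen$assembly)
  ord <- function(d) {
    d <- d[order(d$transcript_id, d$start), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(back$cds), ord(gen$annotation$cds))
  expect_setequal(back$genes$gene_id, gen$annotation$genes$gene_id)
})
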