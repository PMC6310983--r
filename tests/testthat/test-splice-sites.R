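test_that("extract_introns reads border dinucleotides on both strands", {
  fx <- two_exon_genome()
  asm <- read_genome(fx$fasta)
  ann <- read_annotation(fx$gff3, asm)
  intr <- extract_introns(filter_genes(ann, asm)$annotation, asm)
  expect_equal(nrow(intr), 1L)
  expect_equal(intr$start, 4L)
  expect_equal(intr$end, 23L)
  expect_equal(intr$length, 20L)
  expect_equal(intr$combo, "GTAG")
  expect_equal(as.character(intr$class), "canonical")

  # mirrored minus-strand version gives the identical combination
  fm <- two_exon_genome_minus()
  asm2 <- read_genome(fm$fasta)
  ann2 <- read_annotation(fm$gff3, asm2)
  intr2 <- extract_introns(filter_genes(ann2, asm2)$annotation, asm2)
  expect_equal(intr2$combo, "GTAG")
  expect_equal(intr2$length, 20L)
})

test_that("single-CDS transcripts yield no introns", {
  fa <- write_fasta_fixture(list(chr1 = paste0("ATGAAATGA", strrep("C", 10))))
  gff <- write_gff_fixture(c(
    gff_row("chr1", "gene", 1, 9, "+", "ID=g1"),
    gff_row("chr1", "mRNA", 1, 9, "+", "ID=t1;Parent=g1"),
    gff_row("chr1", "CDS", 1, 9, "+", "Parent=t1")))
  asm <- read_genome(fa)
  intr <- extract_introns(filter_genes(read_annotation(gff, asm),
                                       asm)$annotation, asm)
  expect_equal(nrow(intr), 0L)
})

test_that("classification partitions the 256 combinations as 1 + 2 + 253", {
  cls <- classify_combo(all_splice_combos())
  expect_equal(as.vector(table(cls)[c("canonical", "major_GC_AG",
                                      "major_AT_AC", "minor")]),
               c(1L, 1L, 1L, 253L))
  expect_equal(as.character(classify_combo("GTAG")), "canonical")
  expect_equal(as.character(classify_combo("CAGG")), "minor")
  expect_equal(as.character(classify_combo("GNAG")), "ambiguous")
  expect_error(classify_combo("GTA"), "4 characters")
})

test_that("Hamming distances match brute-force enumeration", {
  expect_equal(combo_hamming("GTAG", "GTAG"), 0L)
  expect_equal(combo_hamming("CAGG", "GTAG"), 3L)
  expect_error(combo_hamming("GNAG", "GTAG"), "unambiguous")

  # brute-force oracle over all 256 combinations
  oracle <- vapply(all_splice_combos(), function(cm) {
    sum(strsplit(cm, "")[[1]] != strsplit("GTAG", "")[[1]])
  }, integer(1))
  expect_equal(combo_hamming(all_splice_combos(), "GTAG"),
               unname(oracle))
  hist <- table(oracle)
  expect_equal(as.vector(hist), c(1L, 12L, 54L, 108L, 81L))
  # binomial closed form: choose(4,d) * 3^d
  expect_equal(as.vector(hist[-1]), choose(4, 1:4) * 3^(1:4))
})

test_that("closest_reference minimises distance with GTAG>GCAG>ATAC tie-break", {
  r <- closest_reference("GCAC")
  expect_equal(r$reference, "GCAG")
  expect_equal(r$substitutions,
               data.frame(position = 4L, ref_base = "G", obs_base = "C",
                          stringsAsFactors = FALSE))

  r2 <- closest_reference("CAGG")  # distances 3/3/4 -> GTAG by preference
  expect_equal(r2$reference, "GTAG")
  expect_equal(r2$substitutions$ref_base, c("G", "T", "A"))
  expect_equal(r2$substitutions$obs_base, c("C", "A", "G"))

  r3 <- closest_reference("GTAC")  # distance 1 to both GTAG and ATAC
  expect_equal(r3$reference, "GTAG")
  expect_equal(r3$substitutions$position, 4L)

  expect_error(closest_reference("GTAG"), "minor")
  expect_error(closest_reference("GCAG"), "minor")
})

test_that("closest_reference distance never exceeds distance to GTAG", {
  minors <- setdiff(all_splice_combos(), c("GTAG", "GCAG", "ATAC"))
  for (cm in minors) {
    expect_lte(closest_reference(cm)$distance, combo_hamming(cm, "GTAG"))
  }
})

test_that("build_profile applies the length cutoff and masks ambiguity", {
  intr <- data.frame(
    combo = c("GTAG", "GTAG", "GTAG", "GCAG", "GNAG"),
    length = rep(25L, 5L), stringsAsFactors = FALSE)
  p <- build_profile(intr, min_length = 20)
  expect_equal(unname(p$counts["GTAG"]), 3L)
  expect_equal(unname(p$counts["GCAG"]), 1L)
  expect_equal(p$ambiguous_masked, 1L)
  expect_equal(p$total_introns, 5L)
  expect_equal(sum(p$counts) + p$ambiguous_masked, p$total_introns)

  # a 19 nt intron is excluded entirely
  short <- data.frame(combo = "GTAG", length = 19L,
                      stringsAsFactors = FALSE)
  p2 <- build_profile(short)
  expect_equal(p2$total_introns, 0L)
  expect_equal(sum(p2$counts), 0L)

  p3 <- build_profile(intr[0, , drop = FALSE])
  expect_equal(p3$total_introns, 0L)
})

test_that("profiles survive a TSV round trip", {
  gen <- generate_genome(generator_config(n_genes = 30, seed = 3))
  intr <- extract_introns(gen$annotation, gen$assembly)
  p <- build_profile(intr, species = "roundtrip")
  path <- tempfile(fileext = ".tsv")
  write_profile(p, path)
  back <- read_profile(path)
  expect_equal(back$counts, p$counts)
  expect_equal(back$species, p$species)
  expect_equal(back$ambiguous_masked, p$ambiguous_masked)
  expect_equal(back$total_introns, p$total_introns)
})

test_that("profiles are invariant under genome reverse-complement mirroring", {
  gen <- generate_genome(generator_config(n_genes = 25, seed = 13))
  asm <- gen$assembly
  ann <- gen$annotation
  p1 <- build_profile(extract_introns(ann, asm))

  L <- Biostrings::width(asm)[1]
  asm_rc <- Biostrings::reverseComplement(asm)
  mirror <- function(d) {
    s <- d$start; e <- d$end
    d$start <- L - e + 1L
    d$end <- L - s + 1L
    d
  }
  ann_rc <- ann
  ann_rc$cds <- mirror(ann_rc$cds)
  ann_rc$genes$strand <- ifelse(ann_rc$genes$strand == "+", "-", "+")
  p2 <- build_profile(extract_introns(ann_rc, asm_rc))
  expect_equal(p2$counts, p1$counts)
})

test_that("shift-equivalent placements reproduce the annotated mature mRNA", {
  asm <- Biostrings::DNAStringSet(c(chr1 = "ATGGCAAATTAGGTTT"))
  intron <- data.frame(seq_name = "chr1", start = 5L, end = 13L,
                       strand = "+", stringsAsFactors = FALSE)
  expect_equal(intron_combo(intron, asm), "CAGG")
  alt <- detect_shift_equivalence(intron, asm, max_shift = 3)
  # the GC-AG diagnosis: exactly one equivalent placement is canonical/major
  major <- alt[alt$class %in% c("canonical", "major_GC_AG", "major_AT_AC"), ]
  expect_equal(nrow(major), 1L)
  expect_equal(major$shift, -1L)
  expect_equal(major$combo, "GCAG")
  # every reported placement reproduces the mature mRNA byte-for-byte
  ref_mrna <- spliced_flanks(intron, asm)
  expect_equal(ref_mrna, "ATGGTTT")
  for (i in seq_len(nrow(alt))) {
    expect_equal(spliced_flanks(alt[i, c("start", "end")] |>
                                  cbind(seq_name = "chr1", strand = "+"),
                                asm),
                 ref_mrna)
  }
})

test_that("shift equivalence returns nothing without repeated context", {
  # break the downstream G so no shift preserves the mRNA
  asm <- Biostrings::DNAStringSet(c(chr1 = "ATGGCAAATTAGTTTT"))
  intron <- data.frame(seq_name = "chr1", start = 5L, end = 13L,
                       strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(detect_shift_equivalence(intron, asm)), 0L)

  # canonical intron with non-repeating flanks
  asm2 <- Biostrings::DNAStringSet(c(chr1 = "ATCGTAAACCTAGCAT"))
  intron2 <- data.frame(seq_name = "chr1", start = 4L, end = 13L,
                        strand = "+", stringsAsFactors = FALSE)
  expect_equal(intron_combo(intron2, asm2), "GTAG")
  expect_equal(nrow(detect_shift_equivalence(intron2, asm2)), 0L)
})
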