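test_that("gene_model enforces CDS invariants", {
  expect_error(gene_model("g", "chr1", "+", rbind(c(1L, 9L)),
                          rbind(c(1L, 9L)), "ATGAAATGA"), NA)
  expect_error(gene_model("g", "chr1", "+", rbind(c(1L, 8L)),
                          rbind(c(1L, 8L)), "ATGAAATG"), "divisible by 3|length")
  expect_error(gene_model("g", "chr1", "+", rbind(c(1L, 9L)),
                          rbind(c(1L, 9L)), "TTGAAATGA"), "ATG")
  expect_error(gene_model("g", "chr1", "+", rbind(c(1L, 9L)),
                          rbind(c(1L, 9L)), "ATGAAAAAA"), "stop")
  expect_error(gene_model("g", "chr1", "+", rbind(c(10L, 15L), c(5L, 9L)),
                          rbind(c(5L, 9L), c(10L, 15L)), "ATGAAATGAAAA"),
               "sorted")
})

test_that("impact classification follows the simplified consequence table", {
  genes <- make_test_genes()
  gA <- genes$geneA
  # 1-bp insertion inside the CDS: frameshift, HIGH
  ins <- classify_impact("chr1", 150L, cds_base(gA, 40),
                         paste0(cds_base(gA, 40), "T"), genes)
  expect_equal(ins$category, "HIGH")
  expect_equal(ins$reason, "frameshift")
  # 3-bp insertion: in-frame, MODERATE
  ins3 <- classify_impact("chr1", 150L, cds_base(gA, 40),
                          paste0(cds_base(gA, 40), "TTT"), genes)
  expect_equal(ins3$category, "MODERATE")
  expect_equal(ins3$reason, "inframe_indel")
  # far from any gene: MODIFIER
  expect_equal(classify_impact("chr1", 50000L, "A", "T", genes)$category,
               "MODIFIER")
  # chromosome mismatch is no overlap, not an error
  expect_equal(classify_impact("chrX", 150L, "A", "T", genes)$category,
               "MODIFIER")
  # exon but outside CDS (UTR): LOW noncoding
  utr <- classify_impact("chr1", 105L, "A", "T", genes)
  expect_equal(utr$category, "LOW")
  expect_equal(utr$reason, "noncoding")
  # intronic (inside geneB's span, between its exons): MODIFIER
  intr <- classify_impact("chr1", 1100L, "A", "T", genes)
  expect_equal(intr$category, "MODIFIER")
  expect_equal(intr$reason, "intronic")
})

test_that("SNV classification agrees with a codon-table oracle on both strands", {
  genes <- make_test_genes()
  set.seed(77)
  for (gene in genes) {
    cds <- gene$cds_sequence
    n_aa <- nchar(cds) / 3 - 1
    for (rep in 1:40) {
      cpos <- sample(4:(nchar(cds) - 3L), 1)  # skip start and stop codons
      ref_t <- substr(cds, cpos, cpos)
      alt_t <- sample(setdiff(c("A", "C", "G", "T"), ref_t), 1)
      # oracle: translate the substituted CDS by hand
      edited <- cds
      substr(edited, cpos, cpos) <- alt_t
      aa0 <- oracle_translate(cds)
      aa1 <- oracle_translate(edited)
      codon_i <- (cpos - 1) %/% 3 + 1
      expected <- if (substr(aa1, codon_i, codon_i) == substr(aa0, codon_i, codon_i))
        c("LOW", "synonymous")
      else if (substr(aa1, codon_i, codon_i) == "*") c("HIGH", "stop_gain")
      else c("MODERATE", "missense")
      # map to genomic coordinates (strand-aware)
      gpos <- mendelsieve:::cds_to_genomic(gene, cpos)
      ref_g <- if (gene$strand == "+") ref_t else comp1(ref_t)
      alt_g <- if (gene$strand == "+") alt_t else comp1(alt_t)
      got <- classify_impact(gene$chrom, gpos, ref_g, alt_g, genes)
      expect_equal(c(got$category, got$reason), expected,
                   info = sprintf("%s cds %d %s>%s", gene$gene_id, cpos,
                                  ref_t, alt_t))
    }
  }
})

test_that("start-disrupting edits are start_lost", {
  genes <- make_test_genes()
  gA <- genes$geneA
  # genomic position of CDS base 1 is the CDS interval start for + strand
  got <- classify_impact("chr1", 111L, cds_base(gA, 1), "C", genes)
  expect_equal(got$reason, "start_lost")
  expect_equal(got$category, "HIGH")
})

test_that("toy CDS frameshift reproduces the manual translation oracle", {
  # ATG AAA GGT AAA TGA = M K G K *; inserting T between c.4 and c.5 gives
  # ATG ATA AGG TAA = M I R *, so p.(Lys2IlefsTer3), 3 of 4 residues retained
  cons <- frameshift_consequence("ATGAAAGGTAAATGA", c(4, 5), "T")
  expect_equal(cons$protein_notation, "p.(Lys2IlefsTer3)")
  expect_equal(cons$cdna_notation, "c.4_5insT")
  expect_equal(cons$truncated_length, 3L)
  expect_equal(cons$full_length, 4L)
  expect_equal(cons$retained_fraction, 0.75)
})

test_that("in-frame edits never produce fs notation", {
  cds <- "ATGAAAGGTAAATGA"
  # 3-bp insertion at a codon boundary
  cons <- frameshift_consequence(cds, c(6, 7), "CAT")
  expect_false(grepl("fs", cons$protein_notation))
  # 3-bp deletion
  cons <- frameshift_consequence(cds, c(7, 9))
  expect_false(grepl("fs", cons$protein_notation))
  set.seed(31)
  for (i in 1:50) {
    cds <- random_test_cds(sample(10:60, 1))
    p <- sample(4:(nchar(cds) - 4L), 1)
    ins <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    cons <- frameshift_consequence(cds, c(p, p + 1), ins)
    expect_false(grepl("fs", cons$protein_notation),
                 info = paste(cds, p, ins))
  }
})

test_that("a shifted frame with no downstream stop yields Ter?", {
  # after the insertion the only stop falls out of frame
  cds <- "ATGAAAAAAAAATGA"  # M K K K *
  cons <- frameshift_consequence(cds, c(4, 5), "C")
  expect_match(cons$protein_notation, "fsTer\\?", fixed = FALSE)
  expect_true(is.na(cons$truncated_length))
  expect_true(is.na(cons$retained_fraction))
})

test_that("insertions are 3'-normalized before naming", {
  # inserting A anywhere in the AAA run of ATG AAA GGT ... names the most-3' site
  cds <- "ATGAAAGGTAAATGA"
  a <- frameshift_consequence(cds, c(3, 4), "A")
  b <- frameshift_consequence(cds, c(6, 7), "A")
  expect_equal(a$cdna_notation, "c.6_7insA")
  expect_equal(a$cdna_notation, b$cdna_notation)
  expect_equal(a$protein_notation, b$protein_notation)
})

test_that("coordinate errors are reported", {
  expect_error(frameshift_consequence("ATGAAATGA", c(40, 41), "T"), "outside CDS")
})

test_that("frameshift predictor matches the brute-force oracle on random CDS/insertions", {
  set.seed(1234)
  n_cases <- 300
  for (i in seq_len(n_cases)) {
    cds <- random_test_cds(sample(10:120, 1))
    p <- sample(4:(nchar(cds) - 4L), 1)
    len <- sample(c(1L, 1L, 2L, 4L), 1)  # non-multiples of 3
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    cons <- frameshift_consequence(cds, c(p, p + 1), ins)
    expect_equal(cons$truncated_length, oracle_truncated_length(cds, p, ins),
                 info = sprintf("case %d: %s ins %s at %d", i, cds, ins, p))
    # consistency: the notation's arithmetic reproduces truncated_length
    if (grepl("fsTer[0-9]", cons$protein_notation)) {
      tf <- truncation_fraction(cons$protein_notation, cons$full_length)
      expect_identical(tf$truncated_length, cons$truncated_length)
    }
  }
})

test_that("determinism: identical inputs give identical consequences", {
  cds <- random_test_cds(30)
  a <- frameshift_consequence(cds, c(10, 11), "AG")
  b <- frameshift_consequence(cds, c(10, 11), "AG")
  expect_identical(a, b)
})

test_that("truncation arithmetic follows the fsTer counting convention", {
  # stop at residue pos + N - 1; retained residues (pos-1) + (N-1)
  tf <- truncation_fraction("Glu47GlyfsTer3", 490)
  expect_equal(tf$truncated_length, 48L)
  expect_equal(tf$percent_retained, 100 * 48 / 490)
  expect_equal(tf$percent_retained_rounded, 10L)

  tf <- truncation_fraction("Lys2IlefsTer3", 4)
  expect_equal(tf$truncated_length, 3L)
  expect_equal(tf$percent_retained, 75)

  tf <- truncation_fraction("Met1ValfsTer2", 2)
  expect_equal(tf$truncated_length, 1L)
  expect_equal(tf$percent_retained, 50)

  # wrapped notation accepted; in-frame notation rejected
  expect_equal(truncation_fraction("p.(Glu47GlyfsTer3)", 490)$truncated_length, 48L)
  expect_error(truncation_fraction("p.(Lys2_Gly3insHis)", 100), "in-frame")
})

test_that("gene model TSV + FASTA round trip preserves the models", {
  genes <- make_test_genes()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_gene_models(genes, tsv, fa)
  back <- read_gene_models(tsv, fa)
  expect_equal(names(back), names(genes))
  for (id in names(genes)) {
    expect_equal(back[[id]]$cds_sequence, genes[[id]]$cds_sequence)
    expect_equal(back[[id]]$cds_intervals, genes[[id]]$cds_intervals)
    expect_equal(back[[id]]$exons, genes[[id]]$exons)
    expect_equal(back[[id]]$strand, genes[[id]]$strand)
  }
})
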