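# Shared fixture builders and independent oracles for the test suite.

ped6 <- function(sire_genotyped = FALSE) {
  pedigree_spec("dam", c("hairless1", "hairless2"),
                c("coated1", "coated2", "coated3"),
                sire_id = "sire", sire_genotyped = sire_genotyped)
}

# Build a variant_set from a compact spec: one row per variant, genotypes as
# a named list of state vectors in pedigree sample order.
make_vs <- function(sites, geno_rows, depth = 30L) {
  samples <- names(geno_rows[[1]])
  geno <- do.call(rbind, lapply(geno_rows, function(g) unlist(g)[samples]))
  colnames(geno) <- samples
  d <- matrix(as.integer(depth), nrow(geno), ncol(geno),
              dimnames = list(NULL, samples))
  variant_set(sites, geno, d)
}

# A single-variant set with the given states for the standard 6-sample family.
one_variant <- function(dam = "het", affected = c("hom_alt", "hom_alt"),
                        unaffected = c("het", "hom_ref", "het"),
                        depth = 30L, chrom = "chr1", pos = 100L) {
  dam <- unname(dam); affected <- unname(affected); unaffected <- unname(unaffected)
  st <- c(dam = dam,
          hairless1 = affected[1], hairless2 = affected[2],
          coated1 = unaffected[1], coated2 = unaffected[2],
          coated3 = unaffected[3])
  make_vs(data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                     stringsAsFactors = FALSE),
          list(as.list(st)), depth = depth)
}

# Independent translation oracle: a hand-written codon table lookup, not
# sharing any code path with the package's Biostrings-based translation.
CODON_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0) return("")
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(CODON_TABLE[codons], collapse = "")
}

# Length of the edited protein up to (excluding) the first stop; NA if the
# edited frame never reaches a stop.
oracle_truncated_length <- function(cds, insert_after, inserted) {
  edited <- paste0(substr(cds, 1, insert_after), inserted,
                   substr(cds, insert_after + 1, nchar(cds)))
  aa <- oracle_translate(edited)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at < 0) NA_integer_ else as.integer(stop_at - 1L)
}

# A random valid CDS (ATG + sense codons + stop) via the oracle table.
random_test_cds <- function(n_codons) {
  sense <- names(CODON_TABLE)[CODON_TABLE != "*"]
  stops <- names(CODON_TABLE)[CODON_TABLE == "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""),
         sample(stops, 1L))
}

# Tiny two-gene annotation set on chr1 used across impact tests:
#   geneA (+): exon 101-240 with CDS 111-230 (120 bp, 39 aa + stop)
#   geneB (-): CDS split over two intervals on the minus strand
make_test_genes <- function() {
  set.seed(421)
  cdsA <- random_test_cds(40)  # 120 bp
  geneA <- gene_model("geneA", "chr1", "+",
                      exons = rbind(c(101L, 240L)),
                      cds_intervals = rbind(c(111L, 230L)),
                      cds_sequence = cdsA)
  cdsB <- random_test_cds(50)  # 150 bp: 90 + 60 split
  geneB <- gene_model("geneB", "chr1", "-",
                      exons = rbind(c(1000L, 1069L), c(1200L, 1299L)),
                      cds_intervals = rbind(c(1000L, 1059L), c(1210L, 1299L)),
                      cds_sequence = cdsB)
  list(geneA = geneA, geneB = geneB)
}

# Genomic base of a gene's CDS at a given CDS coordinate, from the model's
# own sequence (transcript orientation), used to build consistent SNVs.
cds_base <- function(gene, cpos) substr(gene$cds_sequence, cpos, cpos)

comp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]
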