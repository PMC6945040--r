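#' Configuration for the synthetic pedigree generator
#'
#' Defines the study conditions the generator emulates: a small annotated
#' genome, a background of biallelic SNVs with population allele
#' frequencies and near-complete catalog membership, Mendelian
#' transmission in a sire x dam -> offspring nuclear family with the sire
#' ungenotyped, one planted recessive 1-bp coding insertion, per-sample
#' Poisson depth noise and genotype missingness.
#'
#' @param seed Integer seed; the same configuration always yields
#'   byte-identical outputs.
#' @param n_genes Number of gene models (default 30).
#' @param n_chromosomes Number of synthetic chromosomes (1-3, default 3).
#' @param chrom_length Length of each chromosome in bp (default 400000,
#'   giving a realistically small coding fraction of about 2%).
#' @param n_background_variants Background biallelic SNV count (default 10000).
#' @param catalog_membership_prob Probability a background variant is
#'   present in the catalog (default 0.99: population catalogs of the scale
#'   the cascade subtracts cover all but a fraction of a percent of the
#'   variants called in any one family).
#' @param n_catalog_extra Catalog sites absent from the family VCF
#'   (default 2000).
#' @param allele_freq_shape Beta shape parameters for founder alternate
#'   allele frequency (default c(0.5, 2), a rare-skewed site frequency
#'   spectrum).
#' @param mean_depth Mean per-sample read depth, Poisson per sample-site
#'   (default 30 reads).
#' @param missing_rate Per-genotype dropout probability (default 0.05).
#' @param n_affected,n_unaffected Offspring counts (defaults 2 and 3,
#'   the hairless/coated litter structure).
#' @param sire_genotyped Is the sire present in the genotype matrix?
#'   Default `FALSE` (only the dam and offspring sequenced).
#' @param n_decoy_inframe Number of planted in-frame 3-bp coding insertion
#'   decoys that segregate like the causal variant but are only MODERATE
#'   impact (default 1), exercising the triage stage.
#' @param hard_mode If `TRUE`, the planted variants are not exempted from
#'   depth and missingness noise.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 30L, n_chromosomes = 3L,
                       chrom_length = 400000L, n_background_variants = 10000L,
                       catalog_membership_prob = 0.99, n_catalog_extra = 2000L,
                       allele_freq_shape = c(0.5, 2), mean_depth = 30,
                       missing_rate = 0.05, n_affected = 2L, n_unaffected = 3L,
                       sire_genotyped = FALSE, n_decoy_inframe = 1L,
                       hard_mode = FALSE) {
  stopifnot(n_genes >= 1, n_chromosomes >= 1, n_chromosomes <= 3,
            n_background_variants >= 1,
            catalog_membership_prob >= 0, catalog_membership_prob <= 1,
            missing_rate >= 0, missing_rate <= 1,
            mean_depth >= 0, n_affected >= 1, n_unaffected >= 0)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 n_background_variants = as.integer(n_background_variants),
                 catalog_membership_prob = catalog_membership_prob,
                 n_catalog_extra = as.integer(n_catalog_extra),
                 allele_freq_shape = allele_freq_shape,
                 mean_depth = mean_depth, missing_rate = missing_rate,
                 n_affected = as.integer(n_affected),
                 n_unaffected = as.integer(n_unaffected),
                 sire_genotyped = isTRUE(sire_genotyped),
                 n_decoy_inframe = as.integer(n_decoy_inframe),
                 hard_mode = isTRUE(hard_mode)),
            class = "sim_config")
}

# Run fn under a deterministic seed without disturbing the caller's RNG.
with_sim_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

#' Generate a synthetic annotated genome
#'
#' Builds `n_chromosomes` random chromosome sequences and places
#' `n_genes` non-overlapping gene models on them, on mixed strands, each
#' with a valid CDS (ATG start, no internal stop, stop-terminated, length
#' divisible by 3) split over 1-3 exons with short UTR flanks, and ample
#' intergenic space so intronic/intergenic variants exist.
#'
#' @param config A [sim_config()]. Draws use the configuration seed; the
#'   same configuration reproduces the genome exactly.
#' @return A list with `genes` (named list of [gene_model()]) and `genome`
#'   (named list of chromosome sequences as single strings).
#' @export
generate_genome_and_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, function() {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    genome <- lapply(chroms, function(ch)
      sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE))
    names(genome) <- chroms

    genes <- list()
    gene_chrom <- rep(chroms, length.out = config$n_genes)
    per_chrom <- table(factor(gene_chrom, levels = chroms))
    for (ch in chroms) {
      k <- per_chrom[[ch]]
      if (k == 0) next
      window <- config$chrom_length %/% k
      for (j in seq_len(k)) {
        gid <- sprintf("gene%03d", length(genes) + 1L)
        n_codons <- sample(100:400, 1L)
        cds <- random_cds(n_codons)
        cds_len <- nchar(cds)
        n_ex <- sample(1:3, 1L)
        # split the CDS length into n_ex genomic pieces (transcript order)
        cuts <- sort(sample(seq_len(cds_len - 1L), n_ex - 1L))
        piece_len <- diff(c(0L, cuts, cds_len))
        introns <- if (n_ex > 1) sample(100:1000, n_ex - 1L, replace = TRUE)
                   else integer()
        utr <- sample(30:100, 2L)
        strand <- sample(c("+", "-"), 1L)
        gene_len <- sum(piece_len) + sum(introns) + sum(utr)
        margin <- window - gene_len - 200L
        if (margin < 1L) stop("chromosome window too small for gene ", gid)
        start <- (j - 1L) * window + sample(margin, 1L) + 100L
        # genomic order of CDS pieces: transcript order on +, reversed on -
        g_piece <- if (strand == "+") piece_len else rev(piece_len)
        cds_iv <- matrix(0L, n_ex, 2L)
        at <- start + utr[1]
        for (e in seq_len(n_ex)) {
          cds_iv[e, ] <- c(at, at + g_piece[e] - 1L)
          at <- at + g_piece[e] + if (e < n_ex) introns[e] else 0L
        }
        exons <- cds_iv
        exons[1, 1] <- exons[1, 1] - utr[1]
        exons[n_ex, 2] <- exons[n_ex, 2] + utr[2]
        # lay the CDS across the genome (reverse-complement on minus strand)
        g_seq <- if (strand == "+") cds else revcomp(cds)
        g_chars <- strsplit(g_seq, "")[[1]]
        taken <- 0L
        for (e in seq_len(n_ex)) {
          idx <- cds_iv[e, 1]:cds_iv[e, 2]
          genome[[ch]][idx] <- g_chars[taken + seq_along(idx)]
          taken <- taken + length(idx)
        }
        genes[[gid]] <- gene_model(gid, ch, strand, exons, cds_iv, cds)
      }
    }
    list(genes = genes,
         genome = lapply(genome, paste, collapse = ""))
  })
}

# Choose a CDS insertion point whose genomic anchor and anchor+1 fall in
# the same CDS interval (so the VCF left-anchored representation is exact),
# away from the start codon and the stop codon.
pick_insertion_point <- function(gene) {
  len <- nchar(gene$cds_sequence)
  for (i in 1:200) {
    p <- sample(seq(4L, len - 4L), 1L)
    if (gene$strand == "+") {
      anchor <- cds_to_genomic(gene, p)
      if (cds_to_genomic(gene, p + 1L) == anchor + 1L) return(list(p = p, anchor = anchor))
    } else {
      anchor <- cds_to_genomic(gene, p + 1L)
      if (cds_to_genomic(gene, p) == anchor + 1L) return(list(p = p, anchor = anchor))
    }
  }
  stop("could not place an insertion inside a single CDS interval of ",
       gene$gene_id)
}

#' Simulate a nuclear-family genotype matrix with a planted causal variant
#'
#' Background biallelic SNVs get founder genotypes drawn from a Beta site
#' frequency spectrum under Hardy-Weinberg, offspring genotypes by random
#' Mendelian transmission, Poisson per-sample depths, and random genotype
#' dropout. Exactly one 1-bp coding insertion is planted with the
#' recessive segregation pattern: both founders heterozygous, all affected
#' offspring homozygous alternate, unaffected offspring drawn from
#' het-by-het transmission conditioned on not being homozygous alternate.
#' The planted site is fully called with depth at least 20 unless
#' `hard_mode` is set. Optional in-frame 3-bp insertion decoys segregate
#' the same way. The sire's calls are omitted from the genotype matrix
#' when `sire_genotyped` is `FALSE`.
#'
#' @param config A [sim_config()].
#' @param annotated Output of [generate_genome_and_genes()] for the same
#'   configuration.
#' @return A list with `variants` (a [variant_set()]), `pedigree`
#'   (a [pedigree_spec()]), `truth` (planted-variant truth record including
#'   the expected protein notation computed by the consequence predictor),
#'   and `catalog` (a data.frame of catalog sites: every background variant
#'   with probability `catalog_membership_prob`, plus extra sites absent
#'   from the family, never the planted variants).
#' @export
simulate_family <- function(config, annotated) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotated$genes
  genome <- annotated$genome
  if (length(genes) == 0) stop("no genes: nowhere to plant the causal variant")
  with_sim_seed(config$seed + 1L, function() {
    chroms <- names(genome)
    chrom_len <- vapply(genome, nchar, integer(1))
    total <- sum(chrom_len)
    n <- config$n_background_variants

    # --- background biallelic SNVs ---
    gidx <- sort(sample.int(total, n))
    cum <- cumsum(chrom_len)
    ci <- findInterval(gidx - 1L, c(0L, cum[-length(cum)]))
    pos <- gidx - c(0L, cum)[ci]
    chrom <- chroms[ci]
    ref <- vapply(seq_len(n), function(i) substr(genome[[ci[i]]], pos[i], pos[i]),
                  character(1))
    bases <- c("A", "C", "G", "T")
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1),
                  USE.NAMES = FALSE)

    f <- stats::rbeta(n, config$allele_freq_shape[1], config$allele_freq_shape[2])
    sire_gt <- stats::rbinom(n, 2L, f)
    dam_gt <- stats::rbinom(n, 2L, f)
    n_off <- config$n_affected + config$n_unaffected
    off_gt <- matrix(0L, n, n_off)
    for (o in seq_len(n_off))
      off_gt[, o] <- stats::rbinom(n, 1L, sire_gt / 2) +
                     stats::rbinom(n, 1L, dam_gt / 2)

    # --- planted causal insertion (+ optional in-frame decoys) ---
    n_plant <- 1L + config$n_decoy_inframe
    plant_genes <- sample(names(genes), n_plant)
    plants <- vector("list", n_plant)
    for (k in seq_len(n_plant)) {
      g <- genes[[plant_genes[k]]]
      pt <- pick_insertion_point(g)
      ins_len <- if (k == 1L) 1L else 3L
      ins_t <- paste(sample(bases, ins_len, replace = TRUE), collapse = "")
      anchor_ref <- substr(genome[[g$chrom]], pt$anchor, pt$anchor)
      ins_g <- if (g$strand == "+") ins_t else revcomp(ins_t)
      unaff <- sample(0:1, config$n_unaffected, replace = TRUE,
                      prob = c(1 / 3, 2 / 3))
      plants[[k]] <- list(
        gene_id = g$gene_id, chrom = g$chrom, pos = pt$anchor,
        ref = anchor_ref, alt = paste0(anchor_ref, ins_g),
        cds_point = pt$p, inserted = ins_t,
        sire_gt = 1L, dam_gt = 1L,
        aff_gt = rep(2L, config$n_affected), unaff_gt = unaff,
        role = if (k == 1L) "causal" else "decoy_inframe")
    }

    # --- assemble the variant table, sorted ---
    p_chrom <- vapply(plants, `[[`, "", "chrom")
    p_pos <- vapply(plants, function(p) p$pos, integer(1))
    # a cataloged background SNV sharing a planted site would defeat the
    # site-level subtraction; drop background variants at planted positions
    clash <- paste(chrom, pos) %in% paste(p_chrom, p_pos)
    if (any(clash)) {
      keep <- !clash
      chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
      f <- f[keep]; sire_gt <- sire_gt[keep]; dam_gt <- dam_gt[keep]
      off_gt <- off_gt[keep, , drop = FALSE]; gidx <- gidx[keep]
      n <- sum(keep)
    }
    sites <- data.frame(
      chrom = c(chrom, p_chrom),
      pos = c(pos, p_pos),
      ref = c(ref, vapply(plants, `[[`, "", "ref")),
      alt = c(alt, vapply(plants, `[[`, "", "alt")),
      stringsAsFactors = FALSE)
    gt <- rbind(
      cbind(sire_gt, dam_gt, off_gt),
      do.call(rbind, lapply(plants, function(p)
        c(p$sire_gt, p$dam_gt, p$aff_gt, p$unaff_gt))))
    plant_flag <- c(rep(FALSE, n), rep(TRUE, n_plant))
    ord <- order(match(sites$chrom, chroms), sites$pos)
    sites <- sites[ord, ]; gt <- gt[ord, , drop = FALSE]
    plant_flag <- plant_flag[ord]
    rownames(sites) <- NULL

    # --- sample ids and pedigree ---
    aff_ids <- paste0("hairless", seq_len(config$n_affected))
    unaff_ids <- paste0("coated", seq_len(config$n_unaffected))
    colnames(gt) <- c("sire", "dam", aff_ids, unaff_ids)
    ped <- pedigree_spec("dam", aff_ids, unaff_ids, sire_id = "sire",
                         sire_genotyped = config$sire_genotyped)
    samples <- pedigree_samples(ped)

    # --- depth and missingness noise ---
    m <- nrow(sites)
    depth <- matrix(stats::rpois(m * length(samples), config$mean_depth),
                    m, length(samples), dimnames = list(NULL, samples))
    miss <- matrix(stats::rbinom(m * length(samples), 1L,
                                 config$missing_rate) == 1L,
                   m, length(samples))
    if (!config$hard_mode) {
      depth[plant_flag, ] <- pmax(depth[plant_flag, , drop = FALSE], 20L)
      miss[plant_flag, ] <- FALSE
    }
    geno <- matrix(c("hom_ref", "het", "hom_alt")[gt[, samples] + 1L],
                   m, length(samples), dimnames = list(NULL, samples))
    geno[miss] <- "missing"
    variants <- variant_set(sites, geno, depth)

    # --- catalog: most background variants, never the planted ones ---
    in_cat <- stats::rbinom(n, 1L, config$catalog_membership_prob) == 1L
    plant_gidx <- c(0L, cum)[match(p_chrom, chroms)] + p_pos
    extra <- sample.int(total, config$n_catalog_extra)
    extra <- setdiff(extra, c(gidx, plant_gidx))
    eci <- findInterval(extra - 1L, c(0L, cum[-length(cum)]))
    catalog <- data.frame(
      chrom = c(chrom[in_cat], chroms[eci]),
      pos = c(pos[in_cat], extra - c(0L, cum)[eci]),
      stringsAsFactors = FALSE)
    catalog <- catalog[order(match(catalog$chrom, chroms), catalog$pos), ]
    rownames(catalog) <- NULL

    causal <- plants[[1]]
    cons <- frameshift_consequence(genes[[causal$gene_id]],
                                   c(causal$cds_point, causal$cds_point + 1L),
                                   causal$inserted)
    truth <- list(
      causal = list(chrom = causal$chrom, pos = causal$pos,
                    ref = causal$ref, alt = causal$alt,
                    gene_id = causal$gene_id,
                    cds_insertion_point = causal$cds_point,
                    inserted = causal$inserted,
                    genotypes = c(sire = "het", dam = "het",
                                  stats::setNames(rep("hom_alt", config$n_affected), aff_ids),
                                  stats::setNames(c("hom_ref", "het")[causal$unaff_gt + 1L],
                                                  unaff_ids)),
                    expected_category = "HIGH",
                    expected_reason = "frameshift",
                    expected_protein_notation = cons$protein_notation,
                    expected_cdna_notation = cons$cdna_notation),
      decoys = lapply(plants[-1], function(p)
        list(chrom = p$chrom, pos = p$pos, ref = p$ref, alt = p$alt,
             gene_id = p$gene_id, role = p$role)),
      background_in_catalog = sum(in_cat),
      n_background = n)

    list(variants = variants, pedigree = ped, truth = truth, catalog = catalog)
  })
}

#' Simulate a complete analysis-ready bundle in memory
#'
#' Convenience wrapper running [generate_genome_and_genes()] and
#' [simulate_family()] for one configuration.
#'
#' @param config A [sim_config()].
#' @return The [simulate_family()] result with `genes` and `genome` added.
#' @export
simulate_bundle <- function(config = sim_config()) {
  annotated <- generate_genome_and_genes(config)
  fam <- simulate_family(config, annotated)
  fam$genes <- annotated$genes
  fam$genome <- annotated$genome
  fam
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes every input the pipeline consumes, in the dialects its readers
#' expect: the pedigree VCF, the catalog TSV, the gene table and CDS FASTA,
#' the reference FASTA, the pedigree TSV and a truth JSON, plus a manifest
#' of paths and MD5 checksums. Regeneration with the same configuration
#' reproduces the checksums exactly.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return data.frame manifest with columns `file` and `md5`, invisibly
#'   also written to `manifest.tsv`.
#' @export
write_fixture_bundle <- function(config, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  b <- simulate_bundle(config)
  paths <- c(vcf = file.path(out_dir, "pedigree.vcf"),
             catalog = file.path(out_dir, "catalog.tsv"),
             genes = file.path(out_dir, "genes.tsv"),
             cds = file.path(out_dir, "cds.fasta"),
             genome = file.path(out_dir, "genome.fasta"),
             pedigree = file.path(out_dir, "pedigree.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_pedigree_vcf(b$variants, b$pedigree, paths["vcf"])
  utils::write.table(b$catalog, paths["catalog"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_models(b$genes, paths["genes"], paths["cds"])
  ref <- Biostrings::DNAStringSet(unlist(b$genome))
  Biostrings::writeXStringSet(ref, paths["genome"], width = 70L)
  write_pedigree_tsv(b$pedigree, paths["pedigree"])
  jsonlite::write_json(b$truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- data.frame(file = basename(unname(paths)),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
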