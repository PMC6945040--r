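GENO_STATES <- c("hom_ref", "het", "hom_alt", "missing")

#' Pedigree specification for a nuclear family
#'
#' Describes the sample ids and roles of a sire x dam nuclear family under an
#' autosomal recessive model: one dam, an optional sire (which may be
#' ungenotyped, as when only the dam and offspring were sequenced), affected
#' offspring expected to be homozygous for the causal allele, and unaffected
#' offspring expected to be carriers or homozygous reference.
#'
#' @param dam_id Sample id of the dam (must be genotyped).
#' @param affected_ids Character vector of affected offspring sample ids
#'   (at least one).
#' @param unaffected_ids Character vector of unaffected offspring sample ids
#'   (may be empty).
#' @param sire_id Optional sample id of the sire, or `NA` if unknown.
#' @param sire_genotyped Logical; is the sire present in the genotype data?
#'   Ignored (forced `FALSE`) when `sire_id` is `NA`.
#' @return An object of class `pedigree_spec`.
#' @examples
#' ped <- pedigree_spec("dam", c("hairless1", "hairless2"),
#'                      c("coated1", "coated2", "coated3"))
#' pedigree_samples(ped)
#' @export
pedigree_spec <- function(dam_id, affected_ids, unaffected_ids = character(),
                          sire_id = NA_character_, sire_genotyped = FALSE) {
  stopifnot(is.character(dam_id), length(dam_id) == 1L, nzchar(dam_id))
  affected_ids <- as.character(affected_ids)
  unaffected_ids <- as.character(unaffected_ids)
  if (length(affected_ids) < 1L)
    stop("pedigree must contain at least one affected offspring")
  ids <- c(dam_id, if (!is.na(sire_id)) sire_id, affected_ids, unaffected_ids)
  if (anyDuplicated(ids))
    stop("pedigree sample ids must be unique: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.na(sire_id)) sire_genotyped <- FALSE
  structure(
    list(dam_id = dam_id, sire_id = sire_id,
         affected_ids = affected_ids, unaffected_ids = unaffected_ids,
         sire_genotyped = isTRUE(sire_genotyped)),
    class = "pedigree_spec"
  )
}

#' @export
print.pedigree_spec <- function(x, ...) {
  cat("pedigree_spec: dam =", x$dam_id,
      "| sire =", if (is.na(x$sire_id)) "<unknown>" else
        paste0(x$sire_id, if (x$sire_genotyped) " (genotyped)" else " (ungenotyped)"),
      "\n  affected:  ", paste(x$affected_ids, collapse = ", "),
      "\n  unaffected:", paste(x$unaffected_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Genotyped sample ids of a pedigree
#'
#' @param pedigree A [pedigree_spec()].
#' @return Character vector of sample ids expected in genotype data, in a
#'   stable order (dam, sire if genotyped, affected, unaffected).
#' @export
pedigree_samples <- function(pedigree) {
  stopifnot(inherits(pedigree, "pedigree_spec"))
  c(pedigree$dam_id,
    if (pedigree$sire_genotyped) pedigree$sire_id,
    pedigree$affected_ids, pedigree$unaffected_ids)
}

#' Read a pedigree description from a 4-column TSV
#'
#' Columns: `sample_id`, `role` (dam/sire/offspring), `status`
#' (affected/unaffected/unknown), `genotyped` (yes/no).
#'
#' @param path Path to the TSV file.
#' @return A [pedigree_spec()].
#' @export
read_pedigree_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "role", "status", "genotyped")
  if (!all(need %in% names(df)))
    stop("pedigree TSV must have columns: ", paste(need, collapse = ", "))
  dam <- df$sample_id[df$role == "dam"]
  sire <- df$sample_id[df$role == "sire"]
  if (length(dam) != 1L) stop("pedigree TSV must name exactly one dam")
  off <- df[df$role == "offspring", ]
  pedigree_spec(
    dam_id = dam,
    affected_ids = off$sample_id[off$status == "affected"],
    unaffected_ids = off$sample_id[off$status == "unaffected"],
    sire_id = if (length(sire) == 1L) sire else NA_character_,
    sire_genotyped = length(sire) == 1L &&
      tolower(df$genotyped[df$role == "sire"]) %in% c("yes", "true", "1")
  )
}

#' Write a pedigree description to a 4-column TSV
#'
#' @param pedigree A [pedigree_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree_tsv <- function(pedigree, path) {
  rows <- data.frame(
    sample_id = c(pedigree$dam_id,
                  if (!is.na(pedigree$sire_id)) pedigree$sire_id,
                  pedigree$affected_ids, pedigree$unaffected_ids),
    role = c("dam", if (!is.na(pedigree$sire_id)) "sire",
             rep("offspring", length(pedigree$affected_ids) +
                   length(pedigree$unaffected_ids))),
    status = c("unaffected", if (!is.na(pedigree$sire_id)) "unaffected",
               rep("affected", length(pedigree$affected_ids)),
               rep("unaffected", length(pedigree$unaffected_ids))),
    genotyped = "yes",
    stringsAsFactors = FALSE
  )
  if (!is.na(pedigree$sire_id) && !pedigree$sire_genotyped)
    rows$genotyped[rows$role == "sire"] <- "no"
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- variant set -----------------------------------------------------------

#' Construct a multi-sample variant set
#'
#' The container every filter operates on: one row per (site, alt allele)
#' with per-sample diploid genotype states and read depths. Multiallelic
#' records are represented split, one row per alternate allele.
#'
#' @param sites data.frame with columns `chrom` (character), `pos` (1-based
#'   integer), `ref`, `alt` (non-empty uppercase A/C/G/T/N strings) and
#'   optionally `site_depth` (integer, `NA` when absent).
#' @param geno Character matrix (variants x samples) with values
#'   `"hom_ref"`, `"het"`, `"hom_alt"` or `"missing"`; column names are
#'   sample ids.
#' @param depth Integer matrix of per-sample read depths, same shape as
#'   `geno`; `NA` where depth was not recorded.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(sites, geno, depth = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  n <- nrow(sites)
  geno <- as.matrix(geno)
  if (is.null(depth)) depth <- matrix(NA_integer_, n, ncol(geno),
                                      dimnames = dimnames(geno))
  depth <- as.matrix(depth)
  if (nrow(geno) != n || nrow(depth) != n || !identical(dim(geno), dim(depth)))
    stop("geno/depth dimensions do not match sites")
  if (is.null(colnames(geno))) stop("geno must have sample ids as colnames")
  bad <- !(geno %in% GENO_STATES)
  if (any(bad)) stop("invalid genotype state(s): ",
                     paste(unique(geno[bad]), collapse = ", "))
  if (n > 0) {
    sites$pos <- as.integer(sites$pos)
    if (any(sites$pos < 1L)) stop("pos must be >= 1")
    if (any(!grepl("^[ACGTN]+$", sites$ref)) || any(!grepl("^[ACGTN]+$", sites$alt)))
      stop("ref/alt must be non-empty uppercase A/C/G/T/N strings")
    key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
    if (anyDuplicated(key))
      stop("duplicate (chrom, pos, ref, alt) records are an input error: ",
           key[duplicated(key)][1])
  }
  if (!"site_depth" %in% names(sites)) sites$site_depth <- rep(NA_integer_, n)
  rownames(sites) <- NULL
  structure(list(sites = sites[c("chrom", "pos", "ref", "alt", "site_depth")],
                 geno = geno, depth = depth),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$sites), "variants x", ncol(x$geno), "samples (",
      paste(colnames(x$geno), collapse = ", "), ")\n")
  if (nrow(x$sites) > 0) print(utils::head(x$sites, 5))
  invisible(x)
}

#' Number of variants in a variant set
#' @param x A `variant_set`.
#' @return Integer count of variant rows.
#' @export
n_variants <- function(x) {
  stopifnot(inherits(x, "variant_set"))
  nrow(x$sites)
}

#' Subset a variant set by row
#' @param x A `variant_set`.
#' @param i Row index (logical or integer).
#' @param ... Unused.
#' @export
`[.variant_set` <- function(x, i, ...) {
  variant_set(x$sites[i, , drop = FALSE],
              x$geno[i, , drop = FALSE],
              x$depth[i, , drop = FALSE])
}

variant_keys <- function(x, allele_aware = FALSE) {
  if (allele_aware)
    paste(x$sites$chrom, x$sites$pos, x$sites$ref, x$sites$alt, sep = ":")
  else
    paste(x$sites$chrom, x$sites$pos, sep = ":")
}

# Chromosome blocks must be contiguous and positions non-decreasing within
# each block; this is the sortedness every reader asserts and every writer
# requires.
assert_sorted_sites <- function(sites, what = "variant collection") {
  if (nrow(sites) < 2) return(invisible(TRUE))
  r <- rle(sites$chrom)
  if (anyDuplicated(r$values))
    stop(what, " is not sorted: chromosome ",
         r$values[duplicated(r$values)][1], " appears in non-contiguous blocks")
  dp <- diff(sites$pos)
  bad <- which(dp < 0 & sites$chrom[-1] == sites$chrom[-nrow(sites)])
  if (length(bad))
    stop(what, " is not sorted: position decreases at record ", bad[1] + 1L)
  invisible(TRUE)
}

# ---- VCF I/O ---------------------------------------------------------------

# Map one diploid GT string to a state for alternate allele `alt_index`.
# Any other alt allele counts as non-carrier for that allele.
gt_to_state <- function(gt, alt_index) {
  out <- character(length(gt))
  gt <- sub(":.*", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  for (i in seq_along(gt)) {
    if (is.na(gt[i]) || gt[i] == "." || gt[i] == "./.") { out[i] <- "missing"; next }
    p <- parts[[i]]
    if (length(p) != 2L)
      stop("non-diploid GT '", gt[i], "' at record ", i,
           "; the recessive model assumes diploid autosomes")
    if (any(p == ".")) { out[i] <- "missing"; next }
    a <- suppressWarnings(as.integer(p))
    if (anyNA(a)) stop("malformed GT '", gt[i], "' at record ", i)
    k <- sum(a == alt_index[i])
    out[i] <- c("hom_ref", "het", "hom_alt")[k + 1L]
  }
  out
}

#' Read a multi-sample pedigree VCF
#'
#' Reads a VCF 4.x file (plain or bgzip) into a [variant_set()]. Diploid GT
#' fields are mapped to genotype states (`./.` to missing, `0/0` hom_ref,
#' `0/1`/`1/0` het, `1/1` hom_alt); phased separators are accepted and
#' treated as unphased; non-diploid genotypes are a parse error.
#' Multiallelic records are split into one row per alternate allele, with
#' states computed per allele (any other alternate allele counts as
#' non-carrier). Per-sample `DP` is captured when present; the INFO `DP`
#' field, when present, is stored as `site_depth`.
#'
#' @param path Path to the VCF file.
#' @param pedigree A [pedigree_spec()]; every genotyped pedigree sample must
#'   appear in the VCF header.
#' @return A `variant_set` with one column per genotyped pedigree sample,
#'   in file order (asserted sorted by chromosome block and position).
#' @export
read_pedigree_vcf <- function(path, pedigree) {
  stopifnot(inherits(pedigree, "pedigree_spec"))
  samples <- pedigree_samples(pedigree)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(vcf@fix) || nrow(vcf@fix) == 0) {
    geno <- matrix(character(), 0, length(samples),
                   dimnames = list(NULL, samples))
    return(variant_set(data.frame(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  stringsAsFactors = FALSE), geno))
  }
  have <- colnames(vcf@gt)[-1]
  absent <- setdiff(samples, have)
  if (length(absent))
    stop("pedigree sample(s) missing from VCF header: ",
         paste(absent, collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  info_dp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "DP")))
  fix <- as.data.frame(vcf@fix[, , drop = FALSE], stringsAsFactors = FALSE)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_i <- rep(seq_len(nrow(fix)), n_alt)
  alt_i <- sequence(n_alt)
  sites <- data.frame(chrom = fix$CHROM[row_i],
                      pos = as.integer(fix$POS[row_i]),
                      ref = toupper(fix$REF[row_i]),
                      alt = toupper(unlist(alts)),
                      site_depth = if (is.null(info_dp)) NA_integer_ else info_dp[row_i],
                      stringsAsFactors = FALSE)
  geno <- matrix(NA_character_, nrow(sites), length(samples),
                 dimnames = list(NULL, samples))
  depth <- matrix(NA_integer_, nrow(sites), length(samples),
                  dimnames = list(NULL, samples))
  for (s in samples) {
    geno[, s] <- gt_to_state(gt[row_i, s], alt_i)
    if (!is.null(dp)) depth[, s] <- as.integer(round(dp[row_i, s]))
  }
  assert_sorted_sites(sites, paste0("VCF '", path, "'"))
  variant_set(sites, geno, depth)
}

#' Write a variant set as a VCF 4.2 file
#'
#' Emits a plain-text VCF with per-sample `GT:DP` and, where recorded, an
#' INFO `DP` field; `read_pedigree_vcf()` on the result reproduces the
#' input exactly. Input must already be sorted; unsorted input is an error,
#' never silently re-sorted.
#'
#' @param variants A [variant_set()] sorted by (chrom, pos).
#' @param pedigree The matching [pedigree_spec()] (columns are written in
#'   pedigree sample order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree_vcf <- function(variants, pedigree, path) {
  stopifnot(inherits(variants, "variant_set"), inherits(pedigree, "pedigree_spec"))
  samples <- pedigree_samples(pedigree)
  if (!all(samples %in% colnames(variants$geno)))
    stop("variant set lacks pedigree sample(s): ",
         paste(setdiff(samples, colnames(variants$geno)), collapse = ", "))
  assert_sorted_sites(variants$sites, "variant set")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined site depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  n <- n_variants(variants)
  if (n == 0) { writeLines(hdr, path); return(invisible(path)) }
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  cols <- vapply(samples, function(s) {
    d <- variants$depth[, s]
    paste0(gt_code[variants$geno[, s]],
           ":", ifelse(is.na(d), ".", as.character(d)))
  }, character(n))
  if (n == 1) cols <- matrix(cols, nrow = 1, dimnames = list(NULL, samples))
  info <- ifelse(is.na(variants$sites$site_depth), ".",
                 paste0("DP=", variants$sites$site_depth))
  body <- paste(variants$sites$chrom, variants$sites$pos, ".",
                variants$sites$ref, variants$sites$alt, ".", "PASS",
                info, "GT:DP",
                apply(cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Tally genotype states by pedigree role
#'
#' For one variant, counts genotype states separately for the dam, the sire
#' (when genotyped), the affected offspring and the unaffected offspring.
#'
#' @param variants A [variant_set()].
#' @param pedigree A [pedigree_spec()].
#' @param which Row index of the variant to tally (default 1).
#' @return Named list of per-role integer count vectors over the four states;
#'   each vector sums to the role's size.
#' @export
genotype_counts <- function(variants, pedigree, which = 1L) {
  stopifnot(inherits(variants, "variant_set"), inherits(pedigree, "pedigree_spec"))
  g <- variants$geno[which, , drop = TRUE]
  tally <- function(ids) {
    v <- factor(g[ids], levels = GENO_STATES)
    stats::setNames(as.integer(table(v)), GENO_STATES)
  }
  out <- list(dam = tally(pedigree$dam_id))
  if (pedigree$sire_genotyped) out$sire <- tally(pedigree$sire_id)
  out$affected <- tally(pedigree$affected_ids)
  out$unaffected <- tally(pedigree$unaffected_ids)
  out
}
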