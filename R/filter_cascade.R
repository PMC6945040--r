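# Ordered stage identifiers of the full-family cascade; affected_only drops
# the two stages that need dam/sibling genotypes.
CASCADE_STAGES <- c("catalog_subtraction", "quality", "affected_hom_alt",
                    "carrier_parent_het", "unaffected_not_hom_alt",
                    "impact_triage")

#' Build a background-variant catalog index
#'
#' A catalog is the population-scale set of known variant sites that
#' family-private ("novel") variants are defined against. Membership is
#' tested at site level by (chrom, pos), mirroring `vcftools --diff-site`
#' semantics; an allele-aware mode matching (chrom, pos, ref, alt) is
#' available behind a flag.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions (same length).
#' @param ref,alt Optional allele vectors; required for `allele_aware`
#'   membership tests.
#' @return An object of class `catalog_index`.
#' @export
catalog_index <- function(chrom, pos, ref = NULL, alt = NULL) {
  if (length(chrom) == 1L && length(pos) > 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  keys <- unique(paste(chrom, as.integer(pos), sep = ":"))
  allele_keys <- NULL
  if (!is.null(ref) && !is.null(alt))
    allele_keys <- unique(paste(chrom, as.integer(pos), ref, alt, sep = ":"))
  structure(list(site_keys = keys, allele_keys = allele_keys),
            class = "catalog_index")
}

#' @export
print.catalog_index <- function(x, ...) {
  cat("catalog_index:", length(x$site_keys), "sites",
      if (!is.null(x$allele_keys)) "(allele-aware capable)", "\n")
  invisible(x)
}

#' Read a catalog from a VCF or a 2-column TSV
#'
#' @param path A VCF 4.x file (plain or gzipped) or a TSV whose first two
#'   columns are chrom and pos (header optional; gzip accepted).
#' @return A [catalog_index()].
#' @export
read_catalog <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    if (nrow(fix) == 0) return(catalog_index(character(), integer()))
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    n_alt <- lengths(alts)
    i <- rep(seq_len(nrow(fix)), n_alt)
    return(catalog_index(fix$CHROM[i], as.integer(fix$POS[i]),
                         fix$REF[i], unlist(alts)))
  }
  first <- readLines(path, n = 1L)
  has_header <- grepl("^(chrom|#)", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("catalog TSV needs at least 2 columns (chrom, pos)")
  ref <- if (ncol(df) >= 4) as.character(df[[3]]) else NULL
  alt <- if (ncol(df) >= 4) as.character(df[[4]]) else NULL
  catalog_index(as.character(df[[1]]), as.integer(df[[2]]), ref, alt)
}

#' Remove cataloged sites, keeping family-private variants
#'
#' @param variants A [variant_set()].
#' @param catalog A [catalog_index()].
#' @param allele_aware If `TRUE`, match (chrom, pos, ref, alt) instead of
#'   (chrom, pos); requires a catalog built with alleles. Default `FALSE`,
#'   the site-level semantics of `vcftools --diff-site`.
#' @return The variants whose key is absent from the catalog, order preserved.
#' @export
subtract_catalog <- function(variants, catalog, allele_aware = FALSE) {
  stopifnot(inherits(variants, "variant_set"), inherits(catalog, "catalog_index"))
  if (allele_aware) {
    if (is.null(catalog$allele_keys))
      stop("catalog was built without alleles; allele-aware subtraction unavailable")
    keep <- !(variant_keys(variants, allele_aware = TRUE) %in% catalog$allele_keys)
  } else {
    keep <- !(variant_keys(variants) %in% catalog$site_keys)
  }
  variants[keep]
}

#' Quality policy for depth and missingness filtering
#'
#' @param min_depth Minimum site depth in reads; sites with depth statistic
#'   strictly below this are removed. Default 20.
#' @param max_missing_pedigree Maximum number of missing genotypes tolerated
#'   across all genotyped pedigree samples. Default 2.
#' @param max_missing_affected Maximum missing genotypes tolerated among
#'   affected samples. Default 0: any missing affected genotype disqualifies.
#' @param depth_statistic How the site depth statistic is computed:
#'   `"mean_sample_dp"` (default) is the mean per-sample DP across genotyped
#'   pedigree samples, falling back to the INFO DP when no per-sample depth
#'   was recorded; `"info_dp"` uses the INFO DP only.
#' @return An object of class `quality_policy`.
#' @export
quality_policy <- function(min_depth = 20L, max_missing_pedigree = 2L,
                           max_missing_affected = 0L,
                           depth_statistic = c("mean_sample_dp", "info_dp")) {
  stopifnot(min_depth >= 0, max_missing_pedigree >= 0, max_missing_affected >= 0)
  structure(list(min_depth = as.numeric(min_depth),
                 max_missing_pedigree = as.integer(max_missing_pedigree),
                 max_missing_affected = as.integer(max_missing_affected),
                 depth_statistic = match.arg(depth_statistic)),
            class = "quality_policy")
}

site_depth_statistic <- function(variants, pedigree, policy) {
  samples <- pedigree_samples(pedigree)
  info_dp <- as.numeric(variants$sites$site_depth)
  if (policy$depth_statistic == "info_dp") return(info_dp)
  d <- variants$depth[, samples, drop = FALSE]
  stat <- rowMeans(d, na.rm = TRUE)
  no_sample_dp <- !is.finite(stat)
  stat[no_sample_dp] <- info_dp[no_sample_dp]
  stat
}

#' Remove poor-quality variants by depth and missingness
#'
#' A variant survives iff (a) its site depth statistic is at least
#' `min_depth` (removal is strict less-than), (b) at most
#' `max_missing_affected` affected genotypes are missing, and (c) at most
#' `max_missing_pedigree` genotypes are missing across the genotyped
#' pedigree. A variant with no recorded depth at all fails the depth
#' criterion whenever `min_depth > 0`: read support is not invented.
#'
#' @param variants A [variant_set()].
#' @param pedigree A [pedigree_spec()].
#' @param policy A [quality_policy()].
#' @return The surviving variants, order preserved.
#' @export
apply_quality_filter <- function(variants, pedigree, policy = quality_policy()) {
  stopifnot(inherits(variants, "variant_set"), inherits(policy, "quality_policy"))
  if (n_variants(variants) == 0) return(variants)
  samples <- pedigree_samples(pedigree)
  stat <- site_depth_statistic(variants, pedigree, policy)
  depth_ok <- if (policy$min_depth > 0) !is.na(stat) & stat >= policy$min_depth
              else rep(TRUE, n_variants(variants))
  miss_all <- rowSums(variants$geno[, samples, drop = FALSE] == "missing")
  miss_aff <- rowSums(variants$geno[, pedigree$affected_ids, drop = FALSE] == "missing")
  keep <- depth_ok &
    miss_aff <= policy$max_missing_affected &
    miss_all <= policy$max_missing_pedigree
  variants[keep]
}

#' Keep variants homozygous alternate in every affected sample
#'
#' Under the recessive model affected offspring carry two copies of the
#' causal allele.
#'
#' @inheritParams apply_quality_filter
#' @return The surviving variants, order preserved.
#' @export
filter_affected_hom_alt <- function(variants, pedigree) {
  stopifnot(inherits(variants, "variant_set"), inherits(pedigree, "pedigree_spec"))
  if (n_variants(variants) == 0) return(variants)
  g <- variants$geno[, pedigree$affected_ids, drop = FALSE]
  variants[rowSums(g == "hom_alt") == length(pedigree$affected_ids)]
}

#' Keep variants heterozygous in genotyped carrier parents
#'
#' Phenotypically unaffected parents of affected offspring are obligate
#' carriers, so the dam must be heterozygous; a missing dam genotype is not
#' heterozygous and fails. Ungenotyped parents impose no constraint; a
#' genotyped sire, when present, must also be heterozygous.
#'
#' @inheritParams apply_quality_filter
#' @return The surviving variants, order preserved.
#' @export
filter_carrier_parent <- function(variants, pedigree) {
  stopifnot(inherits(variants, "variant_set"), inherits(pedigree, "pedigree_spec"))
  if (!pedigree$dam_id %in% colnames(variants$geno))
    stop("dam '", pedigree$dam_id, "' is not genotyped in this variant set")
  if (n_variants(variants) == 0) return(variants)
  keep <- variants$geno[, pedigree$dam_id] == "het"
  if (pedigree$sire_genotyped)
    keep <- keep & variants$geno[, pedigree$sire_id] == "het"
  variants[keep]
}

#' Exclude variants homozygous alternate in any unaffected sample
#'
#' Unaffected siblings may be carriers (het) or homozygous reference, but a
#' homozygous-alternate unaffected sibling contradicts the recessive model.
#'
#' @inheritParams apply_quality_filter
#' @return The surviving variants, order preserved.
#' @export
filter_unaffected_not_hom_alt <- function(variants, pedigree) {
  stopifnot(inherits(variants, "variant_set"), inherits(pedigree, "pedigree_spec"))
  if (n_variants(variants) == 0) return(variants)
  if (length(pedigree$unaffected_ids) == 0) return(variants)
  g <- variants$geno[, pedigree$unaffected_ids, drop = FALSE]
  variants[rowSums(g == "hom_alt") == 0]
}

#' Funnel report of surviving counts per stage
#'
#' @param input_count Number of variants entering the cascade.
#' @param stages Character vector of stage names, in application order.
#' @param counts Integer vector of surviving counts after each stage.
#' @return An object of class `funnel_report` (a data.frame of stage/count
#'   rows with the input count as attribute). Counts must be non-increasing.
#' @export
funnel_report <- function(input_count, stages, counts) {
  stopifnot(length(stages) == length(counts))
  all_counts <- c(input_count, counts)
  if (any(diff(all_counts) > 0))
    stop("funnel counts must be non-increasing: ",
         paste(all_counts, collapse = " -> "))
  structure(data.frame(stage = stages, count = as.integer(counts),
                       stringsAsFactors = FALSE),
            input_count = as.integer(input_count),
            class = c("funnel_report", "data.frame"))
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("funnel: input =", attr(x, "input_count"), "\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-24s %d\n", x$stage[i], x$count[i]))
  invisible(x)
}

#' Run the full prioritization cascade
#'
#' Applies, in order: catalog subtraction, quality filtering, the
#' segregation filters (affected homozygous-alternate; carrier parent
#' heterozygous; no unaffected homozygous-alternate), and coding-impact
#' triage. In `affected_only` mode — emulating a study design where only
#' the affected individuals were sequenced — the carrier-parent and
#' unaffected-sibling stages are skipped.
#'
#' @param variants A [variant_set()].
#' @param catalog A [catalog_index()], or `NULL` to skip subtraction.
#' @param pedigree A [pedigree_spec()].
#' @param policy A [quality_policy()].
#' @param genes List of [gene_model()] objects for impact triage, or `NULL`
#'   to skip the triage stage.
#' @param mode `"full_family"` (default) or `"affected_only"`.
#' @param retain Impact categories retained by the triage stage.
#' @param allele_aware Passed to [subtract_catalog()].
#' @return A list with `survivors` (a `variant_set`), `funnel`
#'   (a [funnel_report()]), and `impacts` (impact annotation data.frame for
#'   the survivors, `NULL` when triage was skipped).
#' @export
run_cascade <- function(variants, catalog, pedigree, policy = quality_policy(),
                        genes = NULL, mode = c("full_family", "affected_only"),
                        retain = c("MODERATE", "HIGH"), allele_aware = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(variants, "variant_set"))
  input_count <- n_variants(variants)
  stages <- character()
  counts <- integer()
  cur <- variants

  if (!is.null(catalog)) cur <- subtract_catalog(cur, catalog, allele_aware)
  stages <- c(stages, "catalog_subtraction"); counts <- c(counts, n_variants(cur))

  cur <- apply_quality_filter(cur, pedigree, policy)
  stages <- c(stages, "quality"); counts <- c(counts, n_variants(cur))

  cur <- filter_affected_hom_alt(cur, pedigree)
  stages <- c(stages, "affected_hom_alt"); counts <- c(counts, n_variants(cur))

  if (mode == "full_family") {
    cur <- filter_carrier_parent(cur, pedigree)
    stages <- c(stages, "carrier_parent_het"); counts <- c(counts, n_variants(cur))
    cur <- filter_unaffected_not_hom_alt(cur, pedigree)
    stages <- c(stages, "unaffected_not_hom_alt"); counts <- c(counts, n_variants(cur))
  }

  impacts <- NULL
  if (!is.null(genes)) {
    impacts <- annotate_variants(cur, genes)
    keep <- impacts$category %in% retain
    cur <- cur[keep]
    impacts <- impacts[keep, , drop = FALSE]
    rownames(impacts) <- NULL
  }
  stages <- c(stages, "impact_triage"); counts <- c(counts, n_variants(cur))

  list(survivors = cur,
       funnel = funnel_report(input_count, stages, counts),
       impacts = impacts)
}
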