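std_geno <- function(dam = "het", aff = c("hom_alt", "hom_alt"),
                     unaff = c("het", "hom_ref", "het")) {
  as.list(c(dam = dam, hairless1 = aff[1], hairless2 = aff[2],
            coated1 = unaff[1], coated2 = unaff[2], coated3 = unaff[3]))
}

test_that("catalog subtraction is a site-level set difference", {
  ped <- ped6()
  sites <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2", "chr3"),
                      pos = c(100L, 200L, 50L, 60L, 10L),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  vs <- make_vs(sites, rep(list(std_geno()), 5))
  cat_idx <- catalog_index(c("chr1", "chr2", "chr4"), c(100L, 60L, 7L))
  out <- subtract_catalog(vs, cat_idx)
  expect_equal(out$sites$chrom, c("chr1", "chr2", "chr3"))
  expect_equal(out$sites$pos, c(200L, 50L, 10L))

  expect_equal(n_variants(subtract_catalog(vs, catalog_index(character(), integer()))), 5L)
  expect_equal(n_variants(subtract_catalog(vs, catalog_index(sites$chrom, sites$pos))), 0L)
})

test_that("allele-aware subtraction distinguishes alleles at one site", {
  ped <- ped6()
  sites <- data.frame(chrom = "chr1", pos = c(100L, 100L), ref = "A",
                      alt = c("T", "G"), stringsAsFactors = FALSE)
  vs <- make_vs(sites, rep(list(std_geno()), 2))
  cat_idx <- catalog_index("chr1", 100L, ref = "A", alt = "T")
  expect_equal(n_variants(subtract_catalog(vs, cat_idx)), 0L)  # site-level
  out <- subtract_catalog(vs, cat_idx, allele_aware = TRUE)
  expect_equal(out$sites$alt, "G")
  expect_error(subtract_catalog(vs, catalog_index("chr1", 100L),
                                allele_aware = TRUE), "without alleles")
})

test_that("quality filter applies depth and missingness rules at their boundaries", {
  ped <- ped6()
  pol <- quality_policy()
  expect_equal(n_variants(apply_quality_filter(one_variant(depth = 19L), ped, pol)), 0L)
  expect_equal(n_variants(apply_quality_filter(one_variant(depth = 20L), ped, pol)), 1L)

  # one missing affected genotype disqualifies
  v <- one_variant(affected = c("missing", "hom_alt"))
  expect_equal(n_variants(apply_quality_filter(v, ped, pol)), 0L)
  # three missing of six disqualifies; two missing unaffected (affected called) passes
  v <- one_variant(dam = "missing", unaffected = c("missing", "missing", "het"))
  expect_equal(n_variants(apply_quality_filter(v, ped, pol)), 0L)
  v <- one_variant(unaffected = c("missing", "missing", "het"))
  expect_equal(n_variants(apply_quality_filter(v, ped, pol)), 1L)

  # absent depth fails when a depth minimum is in force, passes when disabled
  v <- one_variant()
  v$depth[] <- NA_integer_
  expect_equal(n_variants(apply_quality_filter(v, ped, pol)), 0L)
  expect_equal(n_variants(apply_quality_filter(v, ped, quality_policy(min_depth = 0))), 1L)
  # ...but INFO site depth rescues it under the default statistic
  v$sites$site_depth <- 25L
  expect_equal(n_variants(apply_quality_filter(v, ped, pol)), 1L)
})

test_that("affected-hom-alt filter: exactly one of the 4^2 affected pairs passes", {
  ped <- ped6()
  states <- c("hom_ref", "het", "hom_alt", "missing")
  grid <- expand.grid(a1 = states, a2 = states, stringsAsFactors = FALSE)
  passed <- vapply(seq_len(nrow(grid)), function(i) {
    v <- one_variant(affected = c(grid$a1[i], grid$a2[i]))
    n_variants(filter_affected_hom_alt(v, ped)) == 1L
  }, logical(1))
  expect_equal(sum(passed), 1L)
  expect_true(passed[grid$a1 == "hom_alt" & grid$a2 == "hom_alt"])
})

test_that("carrier-parent filter requires a called heterozygous dam", {
  ped <- ped6()
  expect_equal(n_variants(filter_carrier_parent(one_variant(dam = "het"), ped)), 1L)
  expect_equal(n_variants(filter_carrier_parent(one_variant(dam = "hom_ref"), ped)), 0L)
  # a missing dam genotype is not heterozygous
  expect_equal(n_variants(filter_carrier_parent(one_variant(dam = "missing"), ped)), 0L)
  # a genotyped sire is an obligate carrier too
  ped2 <- ped6(sire_genotyped = TRUE)
  st <- std_geno(); st$sire <- "hom_ref"
  v <- make_vs(data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "T"),
               list(st))
  expect_equal(n_variants(filter_carrier_parent(v, ped2)), 0L)
  st$sire <- "het"
  v <- make_vs(data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "T"),
               list(st))
  expect_equal(n_variants(filter_carrier_parent(v, ped2)), 1L)
  # dam absent from the genotype matrix is a configuration error
  bad <- pedigree_spec("granddam", "hairless1", "coated1")
  expect_error(filter_carrier_parent(one_variant(), bad), "granddam")
})

test_that("unaffected filter: 8 of the 27 called triples pass", {
  ped <- ped6()
  states <- c("hom_ref", "het", "hom_alt")
  grid <- expand.grid(u1 = states, u2 = states, u3 = states,
                      stringsAsFactors = FALSE)
  passed <- vapply(seq_len(nrow(grid)), function(i) {
    v <- one_variant(unaffected = unlist(grid[i, ]))
    n_variants(filter_unaffected_not_hom_alt(v, ped)) == 1L
  }, logical(1))
  expect_equal(sum(passed), 8L)
  expect_true(all(!grepl("hom_alt", apply(grid[passed, ], 1, paste, collapse = " "))))
})

test_that("segregation filters commute and match a brute-force predicate", {
  ped <- ped6()
  set.seed(202)
  states <- c("hom_ref", "het", "hom_alt", "missing")
  n <- 200
  sites <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  samples <- pedigree_samples(ped)
  geno <- matrix(sample(states, n * 6, replace = TRUE), n, 6,
                 dimnames = list(NULL, samples))
  vs <- variant_set(sites, geno,
                    matrix(30L, n, 6, dimnames = list(NULL, samples)))

  key <- function(x) paste(x$sites$chrom, x$sites$pos)
  orders <- list(
    function(v) filter_unaffected_not_hom_alt(
      filter_carrier_parent(filter_affected_hom_alt(v, ped), ped), ped),
    function(v) filter_affected_hom_alt(
      filter_unaffected_not_hom_alt(filter_carrier_parent(v, ped), ped), ped),
    function(v) filter_carrier_parent(
      filter_affected_hom_alt(filter_unaffected_not_hom_alt(v, ped), ped), ped))
  results <- lapply(orders, function(f) key(f(vs)))
  expect_identical(results[[1]], results[[2]])
  expect_identical(results[[1]], results[[3]])

  # brute-force per-variant predicate
  brute <- vapply(seq_len(n), function(i) {
    g <- geno[i, ]
    g["dam"] == "het" &&
      all(g[c("hairless1", "hairless2")] == "hom_alt") &&
      !any(g[c("coated1", "coated2", "coated3")] == "hom_alt")
  }, logical(1))
  expect_identical(results[[1]], key(vs[brute]))
})

test_that("uniform random called genotypes pass all three filters at rate 8/729", {
  ped <- ped6()
  # exact enumeration over the 3^6 called-genotype configurations
  states <- c("hom_ref", "het", "hom_alt")
  grid <- expand.grid(rep(list(states), 6), stringsAsFactors = FALSE)
  names(grid) <- pedigree_samples(ped)
  hits <- sum(grid$dam == "het" &
                grid$hairless1 == "hom_alt" & grid$hairless2 == "hom_alt" &
                grid$coated1 != "hom_alt" & grid$coated2 != "hom_alt" &
                grid$coated3 != "hom_alt")
  expect_equal(hits / nrow(grid), 8 / 729)

  # simulation through the filters themselves at n = 50,000 within 3 SE
  set.seed(505)
  n <- 50000
  samples <- pedigree_samples(ped)
  geno <- matrix(sample(states, n * 6, replace = TRUE), n, 6,
                 dimnames = list(NULL, samples))
  vs <- variant_set(data.frame(chrom = "chr1", pos = seq_len(n), ref = "A",
                               alt = "T", stringsAsFactors = FALSE),
                    geno, matrix(30L, n, 6, dimnames = list(NULL, samples)))
  surv <- filter_unaffected_not_hom_alt(
    filter_carrier_parent(filter_affected_hom_alt(vs, ped), ped), ped)
  p <- 8 / 729
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(n_variants(surv) / n - p), 3 * se)
})

test_that("funnel report enforces non-increasing counts", {
  fr <- funnel_report(100L, c("catalog_subtraction", "quality"), c(40L, 30L))
  expect_s3_class(fr, "funnel_report")
  expect_equal(attr(fr, "input_count"), 100L)
  expect_error(funnel_report(100L, c("a", "b"), c(40L, 50L)), "non-increasing")
  expect_error(funnel_report(10L, "a", 20L), "non-increasing")
})

test_that("run_cascade applies stages in order and reports every count", {
  b <- simulate_bundle(sim_config(seed = 3, n_background_variants = 500,
                                  n_genes = 6, chrom_length = 100000L))
  cat_idx <- do.call(catalog_index, b$catalog)
  res <- run_cascade(b$variants, cat_idx, b$pedigree, quality_policy(),
                     b$genes, mode = "full_family")
  expect_equal(res$funnel$stage,
               c("catalog_subtraction", "quality", "affected_hom_alt",
                 "carrier_parent_het", "unaffected_not_hom_alt",
                 "impact_triage"))
  counts <- c(attr(res$funnel, "input_count"), res$funnel$count)
  expect_true(all(diff(counts) <= 0))
  expect_equal(n_variants(res$survivors), res$funnel$count[6])

  # planted causal variant survives the full cascade
  keys <- paste(res$survivors$sites$chrom, res$survivors$sites$pos,
                res$survivors$sites$alt)
  expect_true(paste(b$truth$causal$chrom, b$truth$causal$pos,
                    b$truth$causal$alt) %in% keys)

  # empty input: all counts zero
  empty <- b$variants[integer()]
  res0 <- run_cascade(empty, cat_idx, b$pedigree, quality_policy(), b$genes)
  expect_true(all(res0$funnel$count == 0L))
  expect_error(run_cascade(b$variants, cat_idx, b$pedigree, quality_policy(),
                           b$genes, mode = "both_parents"))
})
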