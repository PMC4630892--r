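fake_scan <- function(effect, p, breed, snp_id = NULL) {
  n <- length(effect)
  out <- tibble::tibble(
    snp_id = snp_id %||% sprintf("snp%05d", seq_len(n)),
    effect = effect, std_error = 1, statistic = effect,
    p_value = p, n = 100L, breed = breed, trait = "t",
    excluded = FALSE)
  class(out) <- c("gwas_table", class(out))
  out
}

test_that("the quota is a tenth of the panel, as in the 71,726-SNP study", {
  n <- 71726
  withr::with_seed(1, {
    eff_a <- rnorm(n); eff_b <- rnorm(n)
    pa <- runif(n); pb <- runif(n)
  })
  sel <- select_snps(fake_scan(eff_a, pa, "BB"), fake_scan(eff_b, pb, "TC"),
                     fraction = 0.10, direction = "same")
  expect_identical(attr(sel, "n_quota"), 7173)
  expect_length(sel, 7173)
})

test_that("the sign filter is exact on a two-SNP panel", {
  a <- fake_scan(c(1, 1), c(0.01, 0.01), "BB", c("s1", "s2"))
  b <- fake_scan(c(1, -1), c(0.01, 0.01), "TC", c("s1", "s2"))
  expect_warning(same <- select_snps(a, b, 1, "same"), "qualifying")
  expect_identical(as.character(same), "s1")
  expect_warning(diff <- select_snps(a, b, 1, "different"), "qualifying")
  expect_identical(as.character(diff), "s2")
  # zero effects have no sign and qualify for neither direction
  z <- fake_scan(c(0, 1), c(0.01, 0.01), "TC", c("s1", "s2"))
  expect_warning(s <- select_snps(a, z, 1, "same"), "qualifying")
  expect_identical(as.character(s), "s2")
})

test_that("selection is deterministic and order-invariant", {
  withr::with_seed(2, {
    a <- fake_scan(rnorm(500), runif(500), "BB")
    b <- fake_scan(rnorm(500), runif(500), "TC")
  })
  s1 <- select_snps(a, b, 0.1, "same")
  shuffle <- withr::with_seed(3, sample(500))
  s2 <- select_snps(a[shuffle, ], b[rev(shuffle), ], 0.1, "same")
  expect_identical(as.character(s1), as.character(s2))
})

test_that("raising the fraction never drops a previously selected SNP", {
  withr::with_seed(4, {
    a <- fake_scan(rnorm(400), runif(400), "BB")
    b <- fake_scan(rnorm(400), runif(400), "TC")
  })
  s10 <- select_snps(a, b, 0.10, "different")
  s25 <- select_snps(a, b, 0.25, "different")
  expect_true(all(s10 %in% s25))
})

test_that("merging unions per-trait sets and removes the overlap", {
  lists <- merge_snp_lists(same = list(t1 = c("a", "b"), t2 = c("b", "c")),
                           different = list(t1 = c("c", "d")))
  expect_setequal(lists$list_of_same, c("a", "b"))
  expect_setequal(lists$list_of_different, "d")
  expect_identical(lists$n_overlap_removed, 1L)
  # trait-count fractions partition each list
  sums <- tapply(lists$trait_counts$fraction, lists$trait_counts$direction, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  cnt <- lists$trait_counts
  expect_identical(cnt$n_snps[cnt$direction == "same" & cnt$n_traits == 2], 1L)

  # disjoint unions pass through unchanged
  l2 <- merge_snp_lists(same = list(c("a", "b")), different = list(c("x")))
  expect_setequal(l2$list_of_same, c("a", "b"))
  expect_setequal(l2$list_of_different, "x")
})

test_that("list sizes respect the union bound over traits", {
  withr::with_seed(5, {
    panel <- 1000
    same_sets <- lapply(1:5, function(i) {
      a <- fake_scan(rnorm(panel), runif(panel), "BB")
      b <- fake_scan(rnorm(panel), runif(panel), "TC")
      select_snps(a, b, 0.10, "same")
    })
    diff_sets <- lapply(1:5, function(i) {
      a <- fake_scan(rnorm(panel), runif(panel), "BB")
      b <- fake_scan(rnorm(panel), runif(panel), "TC")
      select_snps(a, b, 0.10, "different")
    })
  })
  lists <- merge_snp_lists(same_sets, diff_sets)
  bound <- 5 * ceiling(0.10 * panel)
  expect_lte(length(lists$list_of_same), bound)
  expect_lte(length(lists$list_of_different), bound)
})

test_that("degenerate full-panel lists reproduce the whole-panel GRM", {
  pop <- simulate_population(tiny_config(seed = 61))
  map <- genotype_map(pop$genotypes)
  all_ids <- map$snp_id[!map$monomorphic]
  lists <- structure(list(list_of_same = all_ids, list_of_different = all_ids,
                          n_overlap_removed = 0L),
                     class = "snp_lists")
  grms <- suppressMessages(build_variant_grms(pop$genotypes, lists))
  G_W <- suppressMessages(build_grm(pop$genotypes))
  expect_equal(unclass(grms$G_S), unclass(G_W), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(grms$G_D), unclass(G_W), tolerance = 1e-12,
               ignore_attr = TRUE)

  empty <- structure(list(list_of_same = character(0),
                          list_of_different = all_ids,
                          n_overlap_removed = 0L), class = "snp_lists")
  expect_error(build_variant_grms(pop$genotypes, empty), "list-of-same")
})

test_that("planted shared-sign QTL are enriched in the same-direction list", {
  # 200 equal-magnitude common QTL with perfectly consistent signs among
  # 5000 SNPs, marked heritability 0.9; shallow families (few sibs) so an
  # unstructured null stays calibrated and the QTL are the only signal
  n_rep <- 10
  cap <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_sires = 400, n_dams = 800, n_offspring_cows = 1600,
                      n_offspring_bulls = 2, n_snps = 5000, n_qtl = 200,
                      fixed_effect_spec = no_fe_spec, seed = 700 + r)
    ped <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(ped, cfg)
    p_all <- allele_frequencies(geno)
    qtl <- withr::with_seed(800 + r,
                            sample(p_all$snp_id[p_all$p > 0.2 &
                                                  p_all$p < 0.8], 200))
    signs <- withr::with_seed(900 + r, sample(c(-1, 1), 200, replace = TRUE))
    cows <- ped[ped$role == "calibration", ]
    scans <- withr::with_seed(950 + r, lapply(cfg$breeds, function(b) {
      ids <- cows$animal[cows$breed == b]
      g <- unclass(geno)[ids, qtl, drop = FALSE]
      bv <- as.numeric(g %*% signs)
      bv <- bv / sd(bv) * sqrt(0.9)
      dat <- tibble::tibble(animal = ids,
                            pheno = bv + rnorm(length(ids), 0, sqrt(0.1)))
      K <- diag(length(ids))
      dimnames(K) <- list(ids, ids)
      gwas_scan(dat, geno, K, response = "pheno", fixed = ~1,
                null_components = null_free(1))
    }))
    sel <- select_snps(scans[[1]], scans[[2]], 0.10, "same")
    cap[r] <- mean(qtl %in% sel)
  }
  expect_gte(mean(cap), 0.8)
})
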