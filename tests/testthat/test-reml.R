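test_that("univariate estimates match the grid restricted-likelihood oracle", {
  for (seed in c(101, 202)) {
    cfg <- sim_config(n_sires = 10, n_dams = 100, n_offspring_cows = 200,
                      n_offspring_bulls = 2, n_snps = 60, n_qtl = 10,
                      h2_marked = 0, h2_polygenic = 0.5,
                      fixed_effect_spec = no_fe_spec, seed = seed)
    pop <- simulate_population(cfg)
    cows <- pop$phenotypes[pop$phenotypes$sex == "F" &
                             pop$phenotypes$breed == "BB", ]
    A <- build_nrm(pop$pedigree, ids = cows$animal)
    fit <- reml_fit(cows, response = "pheno", fixed = ~1,
                    random = list(pedigree = mm_term(A, "diagonal")))
    expect_true(fit$converged)
    expect_nondecreasing_trace(fit)
    h2_fit <- with(list(v = tidy(fit)$estimate), v[1] / (v[1] + v[2]))
    oracle <- grid_reml_univariate(cows$pheno,
                                   matrix(1, nrow(cows), 1),
                                   unclass(A)[cows$animal, cows$animal])
    expect_lt(abs(h2_fit - oracle$h2), 0.011)
  }
})

test_that("pure-noise phenotypes drive the genetic variance to the floor", {
  cfg <- sim_config(n_sires = 20, n_dams = 400, n_offspring_cows = 800,
                    n_offspring_bulls = 2, n_snps = 60, n_qtl = 10,
                    h2_marked = 0, h2_polygenic = 0,
                    fixed_effect_spec = no_fe_spec, seed = 7)
  pop <- simulate_population(cfg)
  cows <- pop$phenotypes[pop$phenotypes$sex == "F" &
                           pop$phenotypes$breed == "BB", ]
  A <- build_nrm(pop$pedigree, ids = cows$animal)
  fit <- reml_fit(cows, response = "pheno", fixed = ~1,
                  random = list(pedigree = mm_term(A, "diagonal")))
  cmp <- tidy(fit)
  h2 <- cmp$estimate[1] / sum(cmp$estimate)
  expect_lt(h2, 0.05)
  expect_nondecreasing_trace(fit)
})

test_that("the free cross-covariance fit nests the constrained one", {
  cfg <- sim_config(n_sires = 8, n_dams = 60, n_offspring_cows = 120,
                    n_offspring_bulls = 2, n_snps = 400, n_qtl = 80,
                    rho_qtl = 0.8, seed = 15)
  pop <- simulate_population(cfg)
  cows <- pop$phenotypes[pop$phenotypes$sex == "F", ]
  G <- suppressMessages(build_grm(pop$genotypes))
  free <- reml_fit(cows, response = "pheno", fixed = ~1,
                   random = list(genomic = mm_term(G, "unstructured")),
                   trait = "breed")
  fixed0 <- reml_fit(cows, response = "pheno", fixed = ~1,
                     random = list(genomic = mm_term(G, "diagonal")),
                     trait = "breed")
  expect_gte(free$loglik, fixed0$loglik - 1e-6)
  expect_nondecreasing_trace(free)
  expect_nondecreasing_trace(fixed0)
  # gradient is (near) stationary at convergence for the free directions
  scale <- max(abs(free$theta))
  expect_lt(max(abs(free$gradient)) * scale / free$n, 0.05)
})

test_that("non-identifiable duplicate random terms are refused", {
  pop <- simulate_population(tiny_config(seed = 18))
  cows <- pop$phenotypes[pop$phenotypes$sex == "F", ]
  A <- build_nrm(pop$pedigree)
  expect_error(
    reml_fit(cows, response = "pheno", fixed = ~1,
             random = list(a = mm_term(A, "diagonal"),
                           b = mm_term(A, "diagonal")),
             trait = "breed"),
    class = "gencor_structure_error")
})

test_that("genomic correlation and missing heritability follow their definitions", {
  pop <- simulate_population(tiny_config(seed = 19, n_offspring_cows = 60))
  cows <- pop$phenotypes[pop$phenotypes$sex == "F", ]
  A <- build_nrm(pop$pedigree)
  G <- suppressMessages(build_grm(pop$genotypes))
  fit <- reml_fit(cows, response = "pheno", fixed = ~1,
                  random = list(pedigree = mm_term(A, "diagonal"),
                                genomic = mm_term(G, "unstructured")),
                  trait = "breed")

  # overwrite the estimates with worked-example values and check arithmetic
  cmp <- fit$components
  set_est <- function(cmp, term, t1, t2, v) {
    i <- cmp$term == term & cmp$trait_1 == t1 & cmp$trait_2 == t2
    cmp$estimate[i] <- v
    cmp
  }
  cmp <- set_est(cmp, "genomic", "BB", "BB", 0.8)
  cmp <- set_est(cmp, "genomic", "TC", "TC", 0.5)
  cmp <- set_est(cmp, "genomic", "BB", "TC", 0.5)
  cmp$at_floor <- FALSE
  fit$components <- cmp
  expect_equal(genomic_correlation(fit), 0.5 / sqrt(0.8 * 0.5),
               tolerance = 1e-12)

  cmp <- set_est(cmp, "genomic", "BB", "TC", 0)
  fit$components <- cmp
  expect_equal(genomic_correlation(fit), 0)

  # C_miss worked rows: printed two-breed study values reproduce at 2 d.p.
  cmp <- set_est(cmp, "pedigree", "TC", "TC", 0.18)
  cmp <- set_est(cmp, "genomic", "TC", "TC", 0.58)
  fit$components <- cmp
  expect_equal(round(missing_heritability(fit, "TC"), 2), 0.24)
  cmp <- set_est(cmp, "pedigree", "BB", "BB", 0.36)
  cmp <- set_est(cmp, "genomic", "BB", "BB", 0.39)
  fit$components <- cmp
  expect_equal(round(missing_heritability(fit, "BB"), 2), 0.48)
  # sigma_u = 0: everything missing
  cmp <- set_est(cmp, "genomic", "BB", "BB", 0)
  fit$components <- cmp
  expect_equal(missing_heritability(fit, "BB"), 1)

  # undefined cases flag NA instead of inventing a number
  cmp$at_floor[cmp$term == "genomic" & cmp$trait_1 == "BB" &
                 cmp$trait_2 == "BB"] <- TRUE
  fit$components <- cmp
  expect_warning(rg <- genomic_correlation(fit), "floor")
  expect_true(is.na(rg))
})

test_that("parameter summaries stay inside their domains", {
  pop <- simulate_population(tiny_config(seed = 23, n_offspring_cows = 80,
                                         n_snps = 300, n_qtl = 60))
  cows <- pop$phenotypes[pop$phenotypes$sex == "F", ]
  A <- build_nrm(pop$pedigree)
  G <- suppressMessages(build_grm(pop$genotypes))
  fit <- reml_fit(cows, response = "pheno", fixed = ~ comp,
                  random = list(pedigree = mm_term(A, "diagonal"),
                                genomic = mm_term(G, "unstructured")),
                  trait = "breed")
  ps <- parameter_summary(fit)
  expect_true(all(ps$h2_p >= 0 & ps$h2_p <= 1))
  expect_true(all(ps$h2_g >= 0 & ps$h2_g <= 1))
  expect_true(all(ps$h2_p + ps$h2_g <= 1 + 1e-12))
  expect_true(all(ps$c_miss >= 0 & ps$c_miss <= 1))
  expect_true(all(abs(ps$r_g) <= 1))
  gl <- glance(fit)
  expect_identical(gl$n_records, nrow(cows))
  expect_true(gl$converged)
})

test_that("missing responses are dropped from the likelihood but predicted", {
  pop <- simulate_population(tiny_config(seed = 29, n_offspring_cows = 60))
  cows <- pop$phenotypes[pop$phenotypes$sex == "F" &
                           pop$phenotypes$breed == "BB", ]
  A <- build_nrm(pop$pedigree, ids = unique(c(cows$animal)))
  masked <- cows
  masked$pheno[1:10] <- NA
  fit <- reml_fit(masked, response = "pheno", fixed = ~1,
                  random = list(pedigree = mm_term(A, "diagonal")))
  expect_identical(fit$n, nrow(cows) - 10L)
  sol <- solve_mme(fit)
  expect_true(all(cows$animal[1:10] %in% sol$random$animal))
})
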