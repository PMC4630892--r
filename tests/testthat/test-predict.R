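small_study <- function(seed = 51, ...) {
  cfg <- tiny_config(seed = seed, n_sires = 6, n_dams = 40,
                     n_offspring_cows = 80, n_offspring_bulls = 60,
                     n_snps = 400, n_qtl = 80, h2_marked = 0.5,
                     h2_polygenic = 0.1, ...)
  pop <- simulate_population(cfg)
  list(pop = pop,
       A = build_nrm(pop$pedigree),
       G = suppressMessages(build_grm(pop$genotypes)))
}

test_that("schemes classify and validate their selectors", {
  sc <- validation_scheme(c(breed = "BB", sex = "F"),
                          c(breed = "TC", sex = "F"))
  expect_identical(sc$kind, "cross-breed within-sex")
  expect_identical(validation_scheme(c(breed = "BB", sex = "F"),
                                     c(breed = "BB", sex = "M"))$kind,
                   "within-breed cross-sex")
  expect_identical(validation_scheme(c(breed = "BB", sex = "F"),
                                     c(breed = "TC", sex = "M"))$kind,
                   "cross-breed cross-sex")
  expect_error(validation_scheme(c(breed = "BB", sex = "F"),
                                 c(breed = "BB", sex = "F")),
               class = "gencor_config_error")
  expect_length(study_schemes(), 6)
})

test_that("adjusted phenotypes subtract the within-breed BLUEs", {
  st <- small_study(52)
  pheno <- st$pop$phenotypes
  fits <- within_breed_fits(pheno, st$A, fixed = ~ cg + comp)
  adj <- adjusted_phenotypes(pheno, fits, response = "pheno")
  expect_setequal(adj$animal, pheno$animal)

  # shifting one contemporary group is absorbed by its BLUE (compared at the
  # same variance components so only the fixed-effect solutions move)
  shifted <- pheno
  grp <- shifted$cg == shifted$cg[1]
  shifted$pheno[grp] <- shifted$pheno[grp] + 10
  fits2 <- stats::setNames(lapply(names(fits), function(b) {
    sub <- shifted[shifted$breed == b, , drop = FALSE]
    reml_fit(sub, response = "pheno", fixed = ~ cg + comp,
             random = list(pedigree = mm_term(st$A, "unstructured")),
             trait = "sex", start = fits[[b]]$theta, max_iter = 0)
  }), names(fits))
  adj2 <- adjusted_phenotypes(shifted, fits2, response = "pheno")
  m <- dplyr::inner_join(adj, adj2, by = c("animal", "breed", "sex"))
  expect_lt(max(abs(m$adjusted.x - m$adjusted.y)), 1e-6)

  # records with unseen factor levels are dropped, not mis-adjusted
  alien <- pheno[1:2, ]
  alien$cg <- "no_such_group"
  expect_message(adj3 <- adjusted_phenotypes(alien, fits, response = "pheno"),
                 "unseen")
  expect_identical(nrow(adj3), 0L)
})

test_that("with only an intercept, adjustment is per-sex mean-centring", {
  st <- small_study(53)
  pheno <- st$pop$phenotypes
  fits <- within_breed_fits(pheno, st$A, fixed = ~1)
  adj <- adjusted_phenotypes(pheno, fits, response = "pheno")
  j <- dplyr::inner_join(adj, pheno, by = c("animal", "breed", "sex"))
  # adjusted = observed minus the (BLUE) intercept of that breed x sex cell
  for (b in unique(j$breed)) for (s in unique(j$sex)) {
    cell <- j[j$breed == b & j$sex == s, ]
    expect_equal(stats::sd(cell$pheno - cell$adjusted), 0, tolerance = 1e-8)
  }
})

test_that("adjusted phenotypes correlate with total genetic value at sqrt(h2)", {
  cfg <- sim_config(n_sires = 20, n_dams = 300, n_offspring_cows = 600,
                    n_offspring_bulls = 400, n_snps = 500, n_qtl = 100,
                    h2_marked = 0.4, h2_polygenic = 0.2, seed = 54)
  pop <- simulate_population(cfg)
  A <- build_nrm(pop$pedigree)
  fits <- within_breed_fits(pop$phenotypes, A, fixed = ~ cg + aod + comp + age)
  adj <- adjusted_phenotypes(pop$phenotypes, fits, response = "pheno")
  d <- dplyr::inner_join(adj, pop$truth$true_breeding_values,
                         by = c("animal", "breed", "sex"))
  expect_gte(nrow(d), 800)
  expect_lt(abs(stats::cor(d$adjusted, d$gv_total) - sqrt(0.6)), 0.05)
})

test_that("gblup masks everything outside the calibration cell", {
  st <- small_study(55)
  pheno <- st$pop$phenotypes
  sc <- validation_scheme(c(breed = "BB", sex = "F"),
                          c(breed = "TC", sex = "F"))
  gebv1 <- gblup_predict(pheno, st$G, sc, fixed = ~1)
  # perturbing masked phenotypes (all non-calibration records) changes nothing
  leaked <- pheno
  mask <- !(leaked$breed == "BB" & leaked$sex == "F")
  leaked$pheno[mask] <- leaked$pheno[mask] + 5 * stats::rnorm(sum(mask))
  gebv2 <- gblup_predict(leaked, st$G, sc, fixed = ~1)
  expect_equal(gebv1$gebv, gebv2$gebv, tolerance = 1e-10)
  expect_identical(attr(gebv1, "n_calibration"),
                   sum(pheno$breed == "BB" & pheno$sex == "F"))
})

test_that("genomically uninformative validation animals shrink to the mean", {
  st <- small_study(56)
  pheno <- st$pop$phenotypes
  ids <- rownames(st$G)
  # sever the cross-breed genomic links entirely
  blocked <- unclass(st$G)
  bb <- pheno$animal[pheno$breed == "BB"]
  tc <- setdiff(ids, bb)
  blocked[bb, tc] <- 0; blocked[tc, bb] <- 0
  Gb <- gencor:::new_relationship_matrix(blocked, "genomic", 0.95)
  sc <- validation_scheme(c(breed = "BB", sex = "F"),
                          c(breed = "TC", sex = "F"))
  gebv <- gblup_predict(pheno, Gb, sc, fixed = ~1)
  val <- gebv$gebv[gebv$animal %in% tc]
  expect_lt(stats::sd(val), 1e-8)
})

test_that("accuracy and bias follow their defining identities", {
  sc <- validation_scheme(c(breed = "BB", sex = "F"),
                          c(breed = "TC", sex = "F"))
  adjusted <- tibble::tibble(animal = sprintf("v%02d", 1:20), breed = "TC",
                             sex = "F", adjusted = rnorm(20))
  as_gebv <- function(x) {
    out <- tibble::tibble(animal = adjusted$animal, gebv = x)
    attr(out, "scheme") <- sc
    attr(out, "n_calibration") <- 10L
    out
  }
  perfect <- accuracy_and_bias(as_gebv(adjusted$adjusted), adjusted)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$bias, 1)
  doubled <- accuracy_and_bias(as_gebv(2 * adjusted$adjusted), adjusted)
  expect_equal(doubled$accuracy, 1)
  expect_equal(doubled$bias, 0.5)
  flipped <- accuracy_and_bias(as_gebv(-adjusted$adjusted), adjusted)
  expect_equal(flipped$accuracy, -1)
  expect_equal(flipped$bias, -1)
  expect_warning(
    nullcase <- accuracy_and_bias(as_gebv(rep(0, 20)), adjusted),
    "zero-variance")
  expect_true(is.na(nullcase$accuracy))
  expect_error(accuracy_and_bias(as_gebv(rnorm(20)), adjusted[1:2, ]),
               class = "gencor_config_error")
})

test_that("the validation grid is a complete factorial with exact averages", {
  st <- small_study(57)
  pheno <- st$pop$phenotypes
  fits <- within_breed_fits(pheno, st$A, fixed = ~1)
  adj <- adjusted_phenotypes(pheno, fits, response = "pheno")
  grms <- list(G_W = st$G, G_half = st$G)
  report <- run_validation_grid(pheno, grms, adjusted = adj, fixed = ~1)
  expect_identical(nrow(report), 1L * 6L * 2L)
  avg <- report_averages(report)
  # single trait: averages equal the cells exactly
  j <- dplyr::inner_join(avg, report, by = c("scheme", "kind", "grm"))
  expect_equal(j$mean_accuracy, j$accuracy, tolerance = 1e-12)
  expect_equal(j$mean_bias, j$bias, tolerance = 1e-12)
})
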