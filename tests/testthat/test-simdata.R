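test_that("pedigree counts, roles and breed separation follow the design", {
  cfg <- sim_config(n_sires = 5, n_dams = 50, n_offspring_cows = 75,
                    n_offspring_bulls = 70, n_snps = 50, n_qtl = 10, seed = 2)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 2 * (55 + 145))
  counts <- dplyr::count(ped, breed, role)
  expect_setequal(counts$n[counts$role == "founder"], 55)
  expect_setequal(counts$n[counts$role == "calibration"], 75)
  expect_setequal(counts$n[counts$role == "validation"], 70)

  # every offspring has both parents recorded, within its own breed
  off <- ped[ped$role != "founder", ]
  expect_false(anyNA(off$sire))
  expect_false(anyNA(off$dam))
  breed_of <- setNames(ped$breed, ped$animal)
  expect_identical(unname(breed_of[off$sire]), off$breed)
  expect_identical(unname(breed_of[off$dam]), off$breed)

  # validation bulls are sons of calibration cows
  bulls <- ped[ped$role == "validation", ]
  role_of <- setNames(ped$role, ped$animal)
  expect_true(all(role_of[bulls$dam] == "calibration"))
  # and never sired by their dam's own sire
  cow_sire <- setNames(ped$sire, ped$animal)
  expect_true(all(bulls$sire != cow_sire[bulls$dam]))
})

test_that("sons per dam respect the litter limit and match the mating table", {
  cfg <- tiny_config(seed = 5, n_offspring_bulls = 35, litter_limit = 3)
  ped <- simulate_pedigree(cfg)
  matings <- attr(ped, "matings")
  sons <- dplyr::count(ped[ped$role == "validation", ], dam)
  expect_true(all(sons$n >= 1 & sons$n <= cfg$litter_limit))
  expect_gte(mean(sons$n), 1)
  # generator's own assignment table agrees with the emitted pedigree
  expect_equal(sort(paste(matings$offspring, matings$dam, matings$sire)),
               sort(paste(ped$animal[ped$role == "validation"],
                          ped$dam[ped$role == "validation"],
                          ped$sire[ped$role == "validation"])))
})

test_that("infeasible mating designs are rejected as configuration errors", {
  expect_error(sim_config(n_dams = 10, n_offspring_cows = 200,
                          litter_limit = 4, seed = 1),
               class = "gencor_config_error")
  expect_error(tiny_config(fst_divergence = 1), class = "gencor_config_error")
  expect_error(tiny_config(h2_marked = 0.7, h2_polygenic = 0.4),
               class = "gencor_config_error")
  expect_error(tiny_config(n_qtl = 500, n_snps = 100),
               class = "gencor_config_error")
  expect_error(sim_config(), "seed")
})

test_that("identical seed and config give bit-identical output", {
  cfg <- tiny_config(seed = 99)
  pop1 <- simulate_population(cfg)
  pop2 <- simulate_population(cfg)
  expect_identical(pop1$pedigree, pop2$pedigree)
  expect_identical(unclass(pop1$genotypes), unclass(pop2$genotypes))
  expect_identical(pop1$phenotypes, pop2$phenotypes)
  expect_identical(pop1$truth$qtl_effects, pop2$truth$qtl_effects)
  # and a different seed gives different draws
  pop3 <- simulate_population(tiny_config(seed = 100))
  expect_false(identical(pop1$phenotypes$pheno, pop3$phenotypes$pheno))
})

test_that("zero divergence gives near-identical breed allele frequencies", {
  cfg <- sim_config(n_sires = 2000, n_dams = 2000, n_offspring_cows = 4,
                    n_offspring_bulls = 2, n_snps = 250, n_qtl = 10,
                    fst_divergence = 0, seed = 31)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  founders <- ped[ped$role == "founder", ]
  p_bb <- colMeans(geno[founders$animal[founders$breed == "BB"], ]) / 2
  p_tc <- colMeans(geno[founders$animal[founders$breed == "TC"], ]) / 2
  expect_lt(mean(abs(p_bb - p_tc)), 0.02)
})

test_that("gene drop never produces non-Mendelian genotype codes", {
  pop <- simulate_population(tiny_config(seed = 12))
  ped <- pop$pedigree
  g <- unclass(pop$genotypes)
  off <- ped[ped$role != "founder", ]
  for (i in seq_len(nrow(off))) {
    child <- g[off$animal[i], ]
    s <- g[off$sire[i], ]; d <- g[off$dam[i], ]
    # impossible: child allele count outside what the parents can transmit
    min_child <- (s == 2) + (d == 2)
    max_child <- (s > 0) + (d > 0)
    expect_true(all(child >= min_child & child <= max_child))
  }
})

test_that("full-sib genomic relationships average near the pedigree 0.5", {
  cfg <- sim_config(n_sires = 2, n_dams = 100, n_offspring_cows = 800,
                    n_offspring_bulls = 2, n_snps = 1500, n_qtl = 50,
                    litter_limit = 8, seed = 77)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  bb <- ped[ped$breed == "BB" & ped$role == "calibration", ]
  fam <- split(bb$animal, paste(bb$sire, bb$dam))
  pairs <- do.call(rbind, lapply(fam[lengths(fam) >= 2], function(ids) {
    t(utils::combn(ids, 2))
  }))
  expect_gte(nrow(pairs), 1000)
  founders_bb <- ped$animal[ped$breed == "BB" & ped$role == "founder"]
  g_bb <- suppressMessages(build_grm(
    geno, animals = bb$animal, blend = 1,
    freqs = allele_frequencies(geno, animals = founders_bb)))
  rels <- g_bb[cbind(pairs[, 1], pairs[, 2])]
  expect_lt(abs(mean(rels) - 0.5), 0.05)
})

test_that("phenotypes carry the configured variance partition", {
  cfg <- sim_config(n_sires = 20, n_dams = 300, n_offspring_cows = 600,
                    n_offspring_bulls = 500, n_snps = 600, n_qtl = 120,
                    h2_marked = 0.5, h2_polygenic = 0,
                    fixed_effect_spec = no_fe_spec, seed = 21)
  pop <- simulate_population(cfg)
  d <- dplyr::inner_join(pop$phenotypes, pop$truth$true_breeding_values,
                         by = c("animal", "breed", "sex"))
  expect_gte(nrow(d), 1000)
  co <- coef(lm(pheno ~ gv_marked, data = d))
  r2 <- summary(lm(pheno ~ gv_marked, data = d))$r.squared
  expect_lt(abs(co[2] - 1), 0.05)
  expect_lt(abs(r2 - 0.5), 0.05)
})

test_that("cross-breed QTL effect correlation hits its target", {
  # degenerate case: rho = 1 is exact whatever the frequencies
  pop1 <- simulate_population(tiny_config(seed = 8, rho_qtl = 1))
  expect_equal(pop1$truth$realized_rho, 1, tolerance = 1e-12)
  # independent case: sampling error bound at 500 QTL
  pop0 <- simulate_population(
    tiny_config(seed = 9, rho_qtl = 0, n_snps = 1200, n_qtl = 500))
  expect_lt(abs(pop0$truth$realized_rho), 0.1)
  # moderate target within Monte-Carlo error at 100+ QTL
  pop8 <- simulate_population(
    tiny_config(seed = 10, rho_qtl = 0.8, n_snps = 600, n_qtl = 200))
  expect_lt(abs(pop8$truth$realized_rho - 0.8), 0.15)
})

test_that("breeds are pedigree-disconnected but genomically connected", {
  pop <- simulate_population(tiny_config(seed = 14))
  A <- build_nrm(pop$pedigree)
  G <- suppressMessages(build_grm(pop$genotypes))
  bb <- pop$pedigree$animal[pop$pedigree$breed == "BB"]
  tc <- pop$pedigree$animal[pop$pedigree$breed == "TC"]
  expect_equal(max(abs(A[bb, tc])), 0)
  expect_gt(stats::sd(G[bb, tc]), 0)
})
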