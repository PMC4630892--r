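#' Simulate a two-breed pedigree
#'
#' Builds two pedigree-disconnected populations, one per breed. Within each
#' breed, calibration cows are daughters of founder sire x founder dam
#' matings, and validation bulls are sons of calibration cows mated to founder
#' sires other than their own sire. There are no cross-breed parentage links,
#' so the pedigree relationship between animals of different breeds is
#' exactly zero.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `animal`, `sire`, `dam` (`NA` for unknown
#'   founder parents), `breed`, `sex` (`"F"`/`"M"`), `role`
#'   (`"founder"`, `"calibration"`, `"validation"`) and `generation`.
#'   The attribute `"matings"` records the generator's own dam/sire
#'   assignment table for the validation bulls.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_preserved(config$seed, {
    breed_peds <- lapply(config$breeds, function(b) sim_pedigree_one_breed(config, b))
  })
  ped <- dplyr::bind_rows(lapply(breed_peds, `[[`, "ped"))
  attr(ped, "matings") <- dplyr::bind_rows(lapply(breed_peds, `[[`, "matings"))
  ped
}

sim_pedigree_one_breed <- function(config, breed) {
  sires <- id_labels(paste0(breed, "_S"), config$n_sires)
  dams <- id_labels(paste0(breed, "_D"), config$n_dams)
  cows <- id_labels(paste0(breed, "_C"), config$n_offspring_cows)
  bulls <- id_labels(paste0(breed, "_B"), config$n_offspring_bulls)

  # cows: dams cycled under the litter limit, then shuffled; sires cycled so
  # every sire is used
  cow_dam <- sample(rep_len(dams, config$n_offspring_cows))
  cow_sire <- sample(rep_len(sires, config$n_offspring_cows))

  # bulls: dam is a calibration cow (litter-limited); sire is a founder sire
  # that is not the cow's own sire (no sire-daughter matings)
  bull_dam <- sample(rep_len(cows, config$n_offspring_bulls))
  dam_sire <- cow_sire[match(bull_dam, cows)]
  bull_sire <- vapply(dam_sire, function(s) {
    sample(setdiff(sires, s), 1L)
  }, character(1), USE.NAMES = FALSE)

  ped <- tibble::tibble(
    animal = c(sires, dams, cows, bulls),
    sire = c(rep(NA_character_, length(sires) + length(dams)), cow_sire, bull_sire),
    dam = c(rep(NA_character_, length(sires) + length(dams)), cow_dam, bull_dam),
    breed = breed,
    sex = c(rep("M", length(sires)), rep("F", length(dams)),
            rep("F", length(cows)), rep("M", length(bulls))),
    role = c(rep("founder", length(sires) + length(dams)),
             rep("calibration", length(cows)),
             rep("validation", length(bulls))),
    generation = c(rep(0L, length(sires) + length(dams)),
                   rep(1L, length(cows)), rep(2L, length(bulls)))
  )
  matings <- tibble::tibble(breed = breed, offspring = bulls,
                            dam = bull_dam, sire = bull_sire)
  list(ped = ped, matings = matings)
}

#' Simulate genotypes by gene drop along a pedigree
#'
#' Founder allele frequencies are drawn per breed around a shared ancestral
#' frequency using the Balding-Nichols beta model, with divergence controlled
#' by `fst_divergence`; founder genotypes are Hardy-Weinberg draws at those
#' frequencies, and every non-founder inherits one allele from each parent by
#' Mendelian gene drop at unlinked loci. Codes count copies of the second
#' allele, so they are always in `{0, 1, 2}` and never incompatible with the
#' parents' transmissible alleles.
#'
#' @param pedigree Pedigree tibble from [simulate_pedigree()].
#' @param config The same [sim_config()].
#' @return An integer matrix (animals x SNPs, dimnames set) of class
#'   `genotype_matrix` with attribute `"map"`: a tibble with `snp_id`, `chr`,
#'   `pos`, `allele_1`, `allele_2` and `monomorphic` (TRUE when the SNP is
#'   monomorphic across both breeds combined).
#' @export
simulate_genotypes <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$fst_divergence >= 1) stop_config("`fst_divergence` must be < 1.")
  m <- config$n_snps
  fst <- config$fst_divergence

  geno <- with_seed_preserved(config$seed + 1L, {
    p0 <- stats::runif(m, 0.05, 0.95)
    freqs <- lapply(config$breeds, function(b) {
      if (fst == 0) {
        p0
      } else {
        stats::rbeta(m, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
      }
    })
    names(freqs) <- config$breeds

    ord <- order(pedigree$generation)
    geno <- matrix(NA_integer_, nrow = nrow(pedigree), ncol = m,
                   dimnames = list(pedigree$animal, NULL))
    row_of <- stats::setNames(seq_len(nrow(pedigree)), pedigree$animal)
    for (i in ord) {
      sire <- pedigree$sire[i]
      dam <- pedigree$dam[i]
      if (is.na(sire) && is.na(dam)) {
        p <- freqs[[pedigree$breed[i]]]
        geno[i, ] <- stats::rbinom(m, 2L, p)
      } else {
        from_sire <- stats::rbinom(m, 1L, geno[row_of[[sire]], ] / 2)
        from_dam <- stats::rbinom(m, 1L, geno[row_of[[dam]], ] / 2)
        geno[i, ] <- from_sire + from_dam
      }
    }
    geno
  })

  snp_ids <- id_labels("snp", m)
  colnames(geno) <- snp_ids
  n_chr <- min(29L, m)
  chr <- ((seq_len(m) - 1L) %% n_chr) + 1L
  pos <- ((seq_len(m) - 1L) %/% n_chr + 1L) * 100000L
  overall_p <- colMeans(geno) / 2
  map <- tibble::tibble(snp_id = snp_ids, chr = chr, pos = pos,
                        allele_1 = "A", allele_2 = "B",
                        monomorphic = overall_p == 0 | overall_p == 1)
  new_genotype_matrix(geno, map)
}

new_genotype_matrix <- function(geno, map) {
  stopifnot(is.matrix(geno), nrow(map) == ncol(geno))
  structure(geno, map = map, class = c("genotype_matrix", class(geno)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x), " animals x ", ncol(x), " SNPs (",
      sum(genotype_map(x)$monomorphic), " monomorphic)\n", sep = "")
  invisible(x)
}

#' Marker map of a genotype matrix
#' @param genotypes A `genotype_matrix`.
#' @return The map tibble stored alongside the genotype codes.
#' @export
genotype_map <- function(genotypes) {
  map <- attr(genotypes, "map")
  if (is.null(map)) stop_structure("`genotypes` carries no marker map.")
  map
}

# subset that keeps the map in step
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  map <- attr(x, "map")
  out <- NextMethod(drop = drop)
  if (!is.matrix(out)) return(out)
  if (!missing(j)) {
    idx <- seq_len(ncol(x))
    names(idx) <- colnames(x)
    map <- map[if (is.character(j)) idx[j] else idx[j], , drop = FALSE]
  }
  new_genotype_matrix(out, map)
}

#' Simulate QTL effects and phenotypes
#'
#' Draws allele-substitution effects for the QTL from a multivariate normal
#' across the two breeds and two sexes (cross-breed correlation `rho_qtl`,
#' between-sex correlation `rg_sexes`), computes marker-based breeding values
#' as genotype times effect, adds a pedigree-sampled polygenic deviate
#' carrying the missing-heritability fraction, fixed effects (contemporary
#' group, age of dam, breed-composition and age covariates), and an
#' independent residual scaled so the phenotypic variance partition matches
#' the configuration.
#'
#' @param pedigree,genotypes,config Output of the two previous stages plus the
#'   shared configuration.
#' @return A list with `phenotypes` (tibble: `animal`, `breed`, `sex`, `role`,
#'   `cg`, `aod`, `comp`, `age`, `pheno`; founders carry no phenotype and are
#'   excluded) and `truth` (a `sim_truth` list with `qtl_ids`, `qtl_effects`,
#'   `true_breeding_values`, `realized_rho` and `variance_partition`).
#' @export
simulate_phenotypes <- function(pedigree, genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  map <- genotype_map(genotypes)
  fe <- config$fixed_effect_spec
  ped_pheno <- pedigree[pedigree$role != "founder", ]
  n_ph <- nrow(ped_pheno)

  res <- with_seed_preserved(config$seed + 2L, {
    poly_ok <- which(!map$monomorphic)
    if (length(poly_ok) < config$n_qtl) {
      stop_config("fewer polymorphic SNPs (", length(poly_ok),
                  ") than requested QTL (", config$n_qtl, ").")
    }
    qtl_idx <- sort(sample(poly_ok, config$n_qtl))
    qtl_ids <- map$snp_id[qtl_idx]

    # effects for (breed x sex) with Kronecker correlation structure
    r_b <- matrix(c(1, config$rho_qtl, config$rho_qtl, 1), 2)
    r_s <- matrix(c(1, config$rg_sexes, config$rg_sexes, 1), 2)
    sigma <- kronecker(r_b, r_s)
    ev <- eigen(sigma, symmetric = TRUE)
    rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
    raw <- matrix(stats::rnorm(config$n_qtl * 4L), ncol = 4L) %*% rt
    # columns: (breed1, F), (breed1, M), (breed2, F), (breed2, M)
    colnames(raw) <- paste(rep(config$breeds, each = 2), c("F", "M"), sep = ".")

    Z <- genotypes[ped_pheno$animal, qtl_idx, drop = FALSE]
    storage.mode(Z) <- "double"

    # per-breed scaling so the own-sex marked variance is h2_marked
    scale_b <- numeric(2)
    names(scale_b) <- config$breeds
    g_own <- numeric(n_ph)
    g_both <- matrix(0, n_ph, 2, dimnames = list(ped_pheno$animal, c("F", "M")))
    for (b in config$breeds) {
      rows <- ped_pheno$breed == b
      gb <- Z[rows, , drop = FALSE] %*% raw[, paste(b, c("F", "M"), sep = ".")]
      # centre within breed: breed-mean genetic differences are confounded
      # with the per-breed fixed effects and would distort the within-breed
      # variance partition
      gb <- sweep(gb, 2, colMeans(gb), "-")
      own <- ifelse(ped_pheno$sex[rows] == "F", gb[, 1], gb[, 2])
      s <- stats::sd(own)
      if (!is.finite(s) || s == 0) {
        stop_config("degenerate marked component: zero variance in breed ", b, ".")
      }
      k <- if (config$h2_marked > 0) sqrt(config$h2_marked) / s else 0
      scale_b[b] <- k
      g_both[rows, ] <- gb * k
      g_own[rows] <- own * k
    }

    # pedigree-sampled polygenic deviates: shared + sex-specific components
    # give a between-sex correlation of rg_sexes
    drop_poly <- function() gene_drop_normal(pedigree)
    c_sh <- drop_poly(); d_f <- drop_poly(); d_m <- drop_poly()
    rg <- config$rg_sexes
    a_f <- sqrt(abs(rg)) * c_sh + sqrt(1 - abs(rg)) * d_f
    a_m <- sign(rg) * sqrt(abs(rg)) * c_sh + sqrt(1 - abs(rg)) * d_m
    if (rg == 0) { a_f <- d_f; a_m <- d_m }
    idx_ph <- match(ped_pheno$animal, pedigree$animal)
    a_both <- cbind(F = a_f[idx_ph], M = a_m[idx_ph]) * sqrt(config$h2_polygenic)
    a_own <- ifelse(ped_pheno$sex == "F", a_both[, "F"], a_both[, "M"])

    # fixed effects
    cg_levels <- paste0(rep(config$breeds, each = fe$n_cg), "_cg",
                        formatC(seq_len(fe$n_cg), width = 2, flag = "0"))
    cg_eff <- stats::setNames(stats::rnorm(length(cg_levels), 0, fe$sd_cg), cg_levels)
    cg <- paste0(ped_pheno$breed, "_cg",
                 formatC(sample(fe$n_cg, n_ph, replace = TRUE), width = 2, flag = "0"))
    aod_eff <- stats::rnorm(fe$n_aod, 0, fe$sd_aod)
    aod <- sample(fe$n_aod, n_ph, replace = TRUE)
    comp <- stats::runif(n_ph)
    age <- stats::runif(n_ph, -1, 1)

    sigma_e <- sqrt(1 - config$h2_marked - config$h2_polygenic)
    e <- stats::rnorm(n_ph, 0, sigma_e)

    pheno <- 10 + cg_eff[cg] + aod_eff[aod] + fe$slope_comp * comp +
      fe$slope_age * age + g_own + a_own + e

    phenotypes <- tibble::tibble(
      animal = ped_pheno$animal, breed = ped_pheno$breed,
      sex = ped_pheno$sex, role = ped_pheno$role,
      cg = cg, aod = factor(aod), comp = comp, age = age,
      pheno = as.numeric(pheno)
    )

    eff <- tibble::tibble(
      snp_id = rep(qtl_ids, 4L),
      breed = rep(rep(config$breeds, each = 2), each = config$n_qtl),
      sex = rep(rep(c("F", "M"), 2), each = config$n_qtl),
      effect = as.numeric(raw) *
        rep(scale_b[rep(config$breeds, each = 2)], each = config$n_qtl)
    )
    realized_rho <- stats::cor(
      raw[, paste(config$breeds[1], "F", sep = ".")],
      raw[, paste(config$breeds[2], "F", sep = ".")]
    )
    tbv <- tibble::tibble(
      animal = ped_pheno$animal, breed = ped_pheno$breed, sex = ped_pheno$sex,
      gv_marked_F = g_both[, "F"], gv_marked_M = g_both[, "M"],
      gv_marked = g_own,
      gv_polygenic_F = a_both[, "F"], gv_polygenic_M = a_both[, "M"],
      gv_polygenic = a_own,
      gv_total = g_own + a_own
    )
    vp <- phenotypes |>
      dplyr::mutate(gm = g_own, gp = a_own) |>
      dplyr::group_by(.data$breed) |>
      dplyr::summarise(var_marked = stats::var(.data$gm),
                       var_polygenic = stats::var(.data$gp),
                       var_residual = sigma_e^2, .groups = "drop") |>
      dplyr::mutate(h2_marked_target = config$h2_marked,
                    h2_polygenic_target = config$h2_polygenic)

    truth <- structure(
      list(qtl_ids = qtl_ids, qtl_effects = eff,
           true_breeding_values = tbv,
           realized_rho = realized_rho,
           variance_partition = vp),
      class = "sim_truth"
    )
    list(phenotypes = phenotypes, truth = truth)
  })
  res
}

# standard-normal additive deviates along a pedigree: founders N(0,1),
# offspring = mid-parent + Mendelian-sampling N(0, 1/2)
gene_drop_normal <- function(pedigree) {
  n <- nrow(pedigree)
  out <- numeric(n)
  row_of <- stats::setNames(seq_len(n), pedigree$animal)
  for (i in order(pedigree$generation)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (is.na(s) && is.na(d)) {
      out[i] <- stats::rnorm(1)
    } else {
      out[i] <- 0.5 * (out[row_of[[s]]] + out[row_of[[d]]]) +
        stats::rnorm(1, 0, sqrt(0.5))
    }
  }
  out
}

#' Simulate a complete two-breed study population
#'
#' Convenience wrapper running [simulate_pedigree()], [simulate_genotypes()]
#' and [simulate_phenotypes()] under one configuration.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_population` with elements `pedigree`,
#'   `genotypes`, `phenotypes`, `truth` and `config`.
#' @export
#' @examples
#' pop <- simulate_population(sim_config(
#'   n_sires = 4, n_dams = 20, n_offspring_cows = 40, n_offspring_bulls = 30,
#'   n_snps = 100, n_qtl = 20, seed = 7))
#' dplyr::count(pop$phenotypes, breed, sex)
simulate_population <- function(config) {
  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(ped, config)
  ph <- simulate_phenotypes(ped, geno, config)
  structure(list(pedigree = ped, genotypes = geno,
                 phenotypes = ph$phenotypes, truth = ph$truth,
                 config = config),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population> breeds:", paste(x$config$breeds, collapse = ", "), "\n")
  cat(" ", nrow(x$pedigree), "animals,", ncol(x$genotypes), "SNPs,",
      length(x$truth$qtl_ids), "QTL, realized cross-breed effect correlation",
      round(x$truth$realized_rho, 3), "\n")
  invisible(x)
}
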