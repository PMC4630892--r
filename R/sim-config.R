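#' Configuration for the two-breed simulator
#'
#' Defines the mating design, marker panel and quantitative-trait architecture
#' of a simulated pair of pedigree-disconnected populations. The design mirrors
#' a beef-cattle reference/validation layout: within each breed a set of
#' unrelated founder sires and dams produces a generation of calibration cows,
#' and validation bulls are then bred as sons of those calibration cows, so
#' that the validation animals are progeny of the reference animals.
#'
#' The trait architecture has three layers: a *marked* component generated by
#' QTL that are part of the genotyped SNP panel (captured by a genomic
#' relationship matrix), a *polygenic* component sampled along the pedigree
#' only (the "missing" fraction, invisible to the markers), and an
#' independent residual. QTL allele-substitution effects are drawn from a
#' multivariate normal across the two breeds and the two sexes, so that the
#' cross-breed effect correlation (`rho_qtl`) and the between-sex genetic
#' correlation (`rg_sexes`) are both controllable.
#'
#' @param n_sires,n_dams Founder sires and dams per breed.
#' @param n_offspring_cows Calibration cows per breed (daughters of the
#'   founder matings).
#' @param n_offspring_bulls Validation bulls per breed (sons of calibration
#'   cows, sired by founder sires other than the cow's own sire).
#' @param n_snps,n_qtl Size of the SNP panel and number of causal SNPs
#'   (`n_qtl <= n_snps`).
#' @param fst_divergence Wright's F_ST-style divergence of breed allele
#'   frequencies around a shared ancestral frequency, in `[0, 1)`. Zero means
#'   identical expected frequencies in both breeds.
#' @param rho_qtl Target correlation of QTL allele-substitution effects
#'   between the two breeds, in `[-1, 1]`.
#' @param h2_marked Proportion of phenotypic variance due to the simulated QTL.
#' @param h2_polygenic Proportion due to the pedigree-only polygenic term
#'   (the missing-heritability fraction). `h2_marked + h2_polygenic < 1`.
#' @param rg_sexes Genetic correlation of the trait between the sexes.
#' @param litter_limit Maximum offspring per dam within a generation.
#' @param fixed_effect_spec List with elements `n_cg` (contemporary-group
#'   levels per breed), `sd_cg` (SD of their effects), `n_aod` and `sd_aod`
#'   (age-of-dam classes), `slope_comp` (slope on the breed-composition
#'   covariate) and `slope_age` (slope on the age covariate).
#' @param breeds Two breed labels.
#' @param seed Integer seed; mandatory. Identical seed and configuration give
#'   bit-identical simulation output.
#'
#' @return An object of class `sim_config` (a validated list). The derived
#'   element `n_founders_per_breed` equals `n_sires + n_dams`.
#' @seealso [simulate_population()]
#' @export
#' @examples
#' cfg <- sim_config(n_sires = 5, n_dams = 50, n_offspring_cows = 75,
#'                   n_offspring_bulls = 70, n_snps = 200, n_qtl = 20,
#'                   seed = 1)
#' cfg$n_founders_per_breed
sim_config <- function(n_sires = 40, n_dams = 400,
                       n_offspring_cows = 800, n_offspring_bulls = 800,
                       n_snps = 5000, n_qtl = 500,
                       fst_divergence = 0.1, rho_qtl = 0.8,
                       h2_marked = 0.4, h2_polygenic = 0.2,
                       rg_sexes = 0.9, litter_limit = 4,
                       fixed_effect_spec = list(n_cg = 10, sd_cg = 0.5,
                                                n_aod = 4, sd_aod = 0.2,
                                                slope_comp = 0.3,
                                                slope_age = 0.1),
                       breeds = c("BB", "TC"), seed) {
  if (missing(seed)) stop_config("`seed` is mandatory in a sim_config.")
  seed <- check_count(seed, "seed", min = 0L)
  if (seed >= 2^31 - 10) stop_config("`seed` must be below 2^31 - 10.")

  n_sires <- check_count(n_sires, "n_sires")
  n_dams <- check_count(n_dams, "n_dams")
  n_offspring_cows <- check_count(n_offspring_cows, "n_offspring_cows")
  n_offspring_bulls <- check_count(n_offspring_bulls, "n_offspring_bulls")
  n_snps <- check_count(n_snps, "n_snps")
  n_qtl <- check_count(n_qtl, "n_qtl")
  litter_limit <- check_count(litter_limit, "litter_limit")
  if (n_qtl > n_snps) stop_config("`n_qtl` must not exceed `n_snps`.")
  if (n_sires < 2) {
    stop_config("`n_sires` must be >= 2 so bulls can avoid sire-daughter matings.")
  }

  fst_divergence <- check_proportion(fst_divergence, "fst_divergence",
                                     0, 1, hi_open = TRUE)
  rho_qtl <- check_proportion(rho_qtl, "rho_qtl", -1, 1)
  rg_sexes <- check_proportion(rg_sexes, "rg_sexes", -1, 1)
  h2_marked <- check_proportion(h2_marked, "h2_marked", 0, 1)
  h2_polygenic <- check_proportion(h2_polygenic, "h2_polygenic", 0, 1)
  if (h2_marked + h2_polygenic >= 1) {
    stop_config("`h2_marked + h2_polygenic` must be < 1 ",
                "(residual variance would be non-positive).")
  }

  if (!is.character(breeds) || length(breeds) != 2L || anyDuplicated(breeds)) {
    stop_config("`breeds` must be two distinct labels.")
  }

  fe_defaults <- list(n_cg = 10, sd_cg = 0.5, n_aod = 4, sd_aod = 0.2,
                      slope_comp = 0.3, slope_age = 0.1)
  fixed_effect_spec <- utils::modifyList(fe_defaults, fixed_effect_spec %||% list())
  fixed_effect_spec$n_cg <- check_count(fixed_effect_spec$n_cg, "n_cg")
  fixed_effect_spec$n_aod <- check_count(fixed_effect_spec$n_aod, "n_aod")

  # mating feasibility: offspring must be assignable under the litter limit
  if (n_offspring_cows > n_dams * litter_limit) {
    stop_config("infeasible mating design: ", n_offspring_cows,
                " cows requested from ", n_dams, " dams with litter limit ",
                litter_limit, ".")
  }
  if (n_offspring_bulls > n_offspring_cows * litter_limit) {
    stop_config("infeasible mating design: ", n_offspring_bulls,
                " bulls requested from ", n_offspring_cows,
                " calibration cows with litter limit ", litter_limit, ".")
  }

  structure(
    list(n_sires = n_sires, n_dams = n_dams,
         n_founders_per_breed = n_sires + n_dams,
         n_offspring_cows = n_offspring_cows,
         n_offspring_bulls = n_offspring_bulls,
         n_snps = n_snps, n_qtl = n_qtl,
         fst_divergence = fst_divergence, rho_qtl = rho_qtl,
         h2_marked = h2_marked, h2_polygenic = h2_polygenic,
         rg_sexes = rg_sexes, litter_limit = litter_limit,
         fixed_effect_spec = fixed_effect_spec,
         breeds = breeds, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  breeds:", paste(x$breeds, collapse = ", "), "\n")
  cat("  per breed:", x$n_sires, "sires +", x$n_dams, "dams ->",
      x$n_offspring_cows, "calibration cows,",
      x$n_offspring_bulls, "validation bulls\n")
  cat("  panel:", x$n_snps, "SNPs,", x$n_qtl, "QTL, Fst divergence",
      x$fst_divergence, "\n")
  cat("  architecture: h2_marked", x$h2_marked, ", h2_polygenic",
      x$h2_polygenic, ", rho_qtl", x$rho_qtl, ", rg_sexes", x$rg_sexes, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
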