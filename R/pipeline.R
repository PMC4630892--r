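#' Run the full two-breed genomic-correlation study
#'
#' Replays the complete analysis flow on a simulated population (or one
#' supplied directly): build the pedigree relationship matrix and the
#' whole-panel genomic matrix `G_W`; fit the bi-variate pedigree + genomic
#' model on the calibration cows (same phenotype treated as a different
#' trait in each breed) to estimate the genomic correlation and the
#' missing-heritability fractions; scan each breed's cows for SNP effects
#' with a polygenic background; select the sign-consistent and
#' sign-discordant SNP lists and materialise `G_S` and `G_D`; refit the
#' bi-variate model under each variant; and validate GBLUP predictions
#' (accuracy and bias) across the cow/bull calibration-validation schemes.
#'
#' @param config A [sim_config()]; ignored when `population` is given.
#' @param population Optional pre-simulated [simulate_population()] result.
#' @param fraction Per-trait selection fraction for the SNP lists.
#' @param blend Identity-blend weight for all genomic matrices.
#' @param schemes Validation schemes (default: all six cow/bull schemes).
#' @param keep_population Keep the simulated population in the result.
#' @param verbose Progress messages.
#' @return A list of class `gencor_study`:
#' \describe{
#'   \item{`genetic_parameters`}{tibble of `h2_p`, `h2_g`, `c_miss` per breed
#'     and `r_g`, one block per GRM variant (`G_W`, `G_S`, `G_D`);}
#'   \item{`validation`}{`validation_report` over trait x scheme x GRM;}
#'   \item{`validation_averages`}{its per-scheme means;}
#'   \item{`snp_lists`}{the de-overlapped lists;}
#'   \item{`fits`}{the three bi-variate fits;}
#'   \item{`gwas`}{per-breed scan tables;}
#'   \item{`truth`}{the simulation ground truth (when simulated).}
#' }
#' @export
run_pipeline <- function(config = NULL, population = NULL, fraction = 0.10,
                         blend = 0.95, schemes = NULL,
                         keep_population = FALSE, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.null(population)) {
    stopifnot(inherits(config, "sim_config"))
    say("simulating population ...")
    population <- simulate_population(config)
  }
  ped <- population$pedigree
  geno <- population$genotypes
  pheno <- population$phenotypes
  breeds <- sort(unique(pheno$breed))
  fixed <- ~ cg + aod + comp + age

  say("building relationship matrices ...")
  A <- build_nrm(ped)
  freqs <- allele_frequencies(geno) # across-breed frequencies
  G_W <- suppressMessages(
    build_grm(geno, freqs = freqs, blend = blend, label = "whole panel"))

  cows <- pheno[pheno$sex == "F", , drop = FALSE]
  bivar <- function(G) {
    reml_fit(cows, response = "pheno", fixed = fixed,
             random = list(pedigree = mm_term(A, "diagonal"),
                           genomic = mm_term(G, "unstructured")),
             animal = "animal", trait = "breed")
  }
  say("bi-variate REML with G_W ...")
  fit_w <- bivar(G_W)

  say("GWAS per breed ...")
  gwas <- lapply(breeds, function(b) {
    gwas_scan(cows[cows$breed == b, , drop = FALSE], geno, A,
              response = "pheno", fixed = fixed, animal = "animal",
              breed = b, trait = "pheno")
  })
  names(gwas) <- breeds

  say("selecting SNP lists ...")
  same <- list(pheno = select_snps(gwas[[1]], gwas[[2]], fraction, "same"))
  diff <- list(pheno = select_snps(gwas[[1]], gwas[[2]], fraction, "different"))
  lists <- merge_snp_lists(same, diff)
  variant <- build_variant_grms(geno, lists, blend = blend, freqs = freqs)

  say("bi-variate REML with G_S / G_D ...")
  fit_s <- bivar(variant$G_S)
  fit_d <- bivar(variant$G_D)
  fits <- list(G_W = fit_w, G_S = fit_s, G_D = fit_d)

  genetic_parameters <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::bind_cols(tibble::tibble(grm = nm), parameter_summary(f))
  })

  say("within-breed two-sex fits and adjusted phenotypes ...")
  wb <- within_breed_fits(pheno, A, response = "pheno", fixed = fixed)
  adj <- adjusted_phenotypes(pheno, wb)

  say("validation grid ...")
  grms <- list(G_W = G_W, G_S = variant$G_S, G_D = variant$G_D)
  report <- run_validation_grid(pheno, grms, schemes = schemes, adjusted = adj,
                                responses = "pheno", fixed = fixed)

  structure(
    list(genetic_parameters = genetic_parameters,
         validation = report,
         validation_averages = report_averages(report),
         snp_lists = lists,
         fits = fits, gwas = gwas,
         within_breed_fits = wb,
         adjusted = adj,
         truth = population$truth,
         config = population$config,
         population = if (keep_population) population else NULL),
    class = "gencor_study")
}

#' @export
print.gencor_study <- function(x, ...) {
  cat("<gencor_study>\n\nGenetic parameters by GRM variant:\n")
  print(x$genetic_parameters)
  cat("\nValidation averages:\n")
  print(x$validation_averages)
  invisible(x)
}
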