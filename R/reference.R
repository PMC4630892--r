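#' Published reference estimates for the two-breed cattle study
#'
#' REML genetic-parameter estimates and GBLUP validation results, as printed
#' (two decimal places), from a study of 1829 Brahman (BB) and 1973 Tropical
#' Composite (TC) cattle with five tropical-adaptation traits and a
#' 71,726-SNP panel. They serve as worked-example inputs for arithmetic
#' consistency checks: the missing-heritability fraction must satisfy
#' `c_miss = h2_p / (h2_p + h2_g)` within rounding, and the validation
#' "Average" rows must equal the mean of the per-trait cells within rounding.
#'
#' @param type `"parameters"` (per breed `h2_p`, `h2_g`, `c_miss` and the
#'   genomic correlation `r_g`, per GRM variant), `"validation"` (per-trait
#'   accuracy and bias per calibration : validation direction and GRM
#'   variant) or `"validation_averages"` (the printed Average rows).
#' @return A tibble.
#' @export
#' @examples
#' ref <- reference_estimates("parameters")
#' with(subset(ref, grm == "G_W"), summary(h2_p / (h2_p + h2_g) - c_miss))
reference_estimates <- function(type = c("parameters", "validation",
                                         "validation_averages")) {
  type <- match.arg(type)
  path <- system.file("extdata", paste0("reference_", type, ".csv"),
                      package = "gencor", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
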