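# shared small simulation setups

tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_sires = 4, n_dams = 20, n_offspring_cows = 40,
         n_offspring_bulls = 30, n_snps = 120, n_qtl = 25, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# fixed-effect-free architecture so the phenotypic variance partition is
# exactly the genetic one plus residual
no_fe_spec <- list(sd_cg = 0, sd_aod = 0, slope_comp = 0, slope_age = 0)

# null-model components with the polygenic variance forced to zero
null_free <- function(var_e = 1) {
  tibble::tibble(term = c("polygenic", "residual"),
                 trait_1 = "trait1", trait_2 = "trait1",
                 estimate = c(0, var_e))
}

# three-animal fixture: founder sire S, unrelated dam unknown, offspring pair
trio_pedigree <- function() {
  tibble::tibble(animal = c("S", "D", "O"),
                 sire = c(NA, NA, "S"),
                 dam = c(NA, NA, "D"))
}
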