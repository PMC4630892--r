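# gencor

Harnessing two unrelated populations for genomic selection: across-breed
genomic relationship matrices, bi-variate pedigree + genomic REML, mixed-model
GWAS, sign-based SNP selection, and GBLUP validation.

## The problem

Merging two breeds into one genomic-selection reference population only pays
off when the marker-captured genetic effects for the trait are correlated
across the breeds. Two pedigree-disconnected populations (say Brahman, BB,
and Tropical Composite, TC) have a numerator relationship matrix **A** whose
between-breed block is exactly zero — but their marker-based relationship
matrix **G** still links them through shared alleles. Fitting the same
phenotype as a different trait in each breed, with one additive component
structured by **A** and one by **G**,

    y_b = X_b β_b + Z_b a_b + M_b u_b + e_b ,   b ∈ {BB, TC}

where var(u) carries a free cross-breed block σ_u(BB,TC)·**G**, gives

* the **genomic correlation** r_G = σ_u(BB,TC) / √(σ²_u(BB) σ²_u(TC)),
* the **missing heritability** C_miss = 1 − σ²_u / (σ²_u + σ²_a),

and the per-breed partition h²_P (pedigree) and h²_G (genomic). Selecting
the 10 % of SNPs whose GWAS effects have the *same* sign in both breeds
(consistent LD phase) yields a matrix **G**_S that drives r̂_G towards +1 and
improves across-breed prediction; the opposite-sign list yields **G**_D and
mirrors everything with a negative sign. `gencor` implements this entire
cycle, plus a two-breed gene-drop simulator with known truth, so the whole
study replays on synthetic data.

## Worked example

```r
library(gencor)

cfg <- sim_config(n_sires = 10, n_dams = 80, n_offspring_cows = 160,
                  n_offspring_bulls = 120, n_snps = 1500, n_qtl = 200,
                  h2_marked = 0.5, h2_polygenic = 0.2, rho_qtl = 0.8,
                  seed = 2024)
study <- run_pipeline(cfg)
study
```

```
<gencor_study>

Genetic parameters by GRM variant:
# A tibble: 6 × 6
  grm   trait       h2_p  h2_g     c_miss    r_g
1 G_W   BB    0.00000149 0.760 0.00000196  0.999
2 G_W   TC    0.528      0.287 0.648       0.999
3 G_S   BB    0.190      0.632 0.231       0.999
4 G_S   TC    0.251      0.580 0.302       0.999
5 G_D   BB    0.00000224 0.513 0.00000436 -0.999
6 G_D   TC    0.654      0.346 0.654      -0.999

Validation averages (excerpt):
   scheme             kind                    grm   mean_accuracy mean_bias
 7 BB cows : TC cows  cross-breed within-sex  G_D         -0.578    -0.993
 8 BB cows : TC cows  cross-breed within-sex  G_S          0.732     1.03
 9 BB cows : TC cows  cross-breed within-sex  G_W          0.232     1.07
 1 BB cows : BB bulls within-breed cross-sex  G_D          0.385     0.539
 2 BB cows : BB bulls within-breed cross-sex  G_S          0.541     0.735
 3 BB cows : BB bulls within-breed cross-sex  G_W          0.552     0.895
```

Reading the output: under the whole-panel matrix `G_W` a sizeable share of
genetic variance stays with the pedigree term (missing heritability; here
0.65 in TC), and the genomic correlation is weakly identified at this small
scale (a boundary estimate, 0.999). Restricting the matrix to the
sign-consistent list (`G_S`) shifts variance from the pedigree to the
genomic term (C_miss drops) and lifts across-breed cow-to-cow prediction
accuracy from 0.23 to 0.73, while the sign-discordant list (`G_D`) makes it
strongly negative (−0.58). Within-breed accuracies are barely affected — the
published pattern, reproduced end to end on simulated data. At small n the
r_G estimates sit on the [−1, 1] boundary; the replicated suites in
`tests/testthat/test-acceptance.R` run the same pipeline at larger n where
the whole-panel estimate is interior.

The pieces are available individually — `build_nrm()`, `build_grm()`,
`reml_fit()` / `tidy()` / `glance()` / `parameter_summary()`, `gwas_scan()`,
`select_snps()`, `merge_snp_lists()`, `build_variant_grms()`,
`gblup_predict()`, `accuracy_and_bias()`, `run_validation_grid()` — and each
result type has an `autoplot()` method. PLINK `.ped/.map` and
`.bed/.bim/.fam` readers/writers are included. See the methods vignette
(`vignettes/genomic-correlation-methods.Rmd`) for the models, numerical
choices and simulator assumptions.

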