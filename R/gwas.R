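#' Single-SNP mixed-model association scan
#'
#' Within one population, tests each SNP as an additive fixed covariate
#' (genotype coded 0/1/2) in a uni-variate animal model that carries the
#' usual fixed effects plus a pedigree-based polygenic random effect. The
#' default, fast mode estimates the polygenic and residual variances once
#' under the null model (no SNP) and then tests every SNP by generalised
#' least squares on the decorrelated data -- the standard two-stage
#' approximation which reduces the scan from one REML fit per SNP to a single
#' spectral decomposition plus vectorised regressions. `method = "exact"`
#' re-estimates the variance components for every SNP (slow; intended for
#' spot checks of the approximation).
#'
#' Effects are reported as allele-substitution estimates (trait units per
#' copy of the second allele), with Wald statistics and two-sided p-values on
#' a t reference distribution. SNPs that are monomorphic within the scanned
#' subset have no defined effect: they are flagged `excluded` with `NA`
#' statistics and should not enter any ranking.
#'
#' @param data Records of one population (e.g. the calibration cows of one
#'   breed), one row per animal.
#' @param genotypes Genotype matrix covering the scanned animals.
#' @param nrm Pedigree relationship matrix covering the scanned animals.
#' @param response,fixed,animal As in [reml_fit()].
#' @param snps Optional SNP subset to scan (default: all columns).
#' @param method `"two-stage"` (default) or `"exact"`.
#' @param null_components Optional tibble (layout of `tidy()` on a fit, terms
#'   `polygenic` and `residual`) fixing the null variance components instead
#'   of estimating them -- e.g. to share one null fit across permutations, or
#'   to force the polygenic variance to zero, in which case the scan reduces
#'   to ordinary least squares on the adjusted phenotype.
#' @param breed,trait Labels stamped on the output rows.
#' @return A `gwas_table` tibble: `snp_id`, `effect`, `std_error`,
#'   `statistic`, `p_value`, `n`, `breed`, `trait`, `excluded`. The null-model
#'   variance components are stored in the `"null_components"` attribute.
#' @export
gwas_scan <- function(data, genotypes, nrm, response = "pheno", fixed = ~1,
                      animal = "animal", snps = NULL,
                      method = c("two-stage", "exact"),
                      null_components = NULL,
                      breed = NA_character_, trait = "trait") {
  method <- match.arg(method)
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  start <- NULL
  if (!is.null(null_components)) {
    start <- stats::setNames(null_components$estimate,
                             paste(null_components$term,
                                   null_components$trait_1,
                                   null_components$trait_2, sep = ":"))
  }
  null_fit <- reml_fit(data, response = response, fixed = fixed,
                       random = list(polygenic = mm_term(nrm, "diagonal")),
                       animal = animal, start = start,
                       max_iter = if (is.null(null_components)) 200 else 0,
                       variance_floor = if (is.null(null_components)) 1e-6 else 0)
  if (!null_fit$converged) {
    stop_numeric("gwas_scan: null model did not converge; ",
                 "logL trace length ", length(null_fit$loglik_trace), ".")
  }

  snp_ids <- snps %||% colnames(genotypes)
  G <- unclass(genotypes)[data[[animal]], snp_ids, drop = FALSE]
  storage.mode(G) <- "double"
  G[is.na(G)] <- NA_real_

  if (method == "two-stage") {
    res <- gwas_two_stage(null_fit, G)
  } else {
    res <- gwas_exact(data, G, nrm, response, fixed, animal)
  }

  out <- tibble::tibble(
    snp_id = snp_ids, effect = res$beta, std_error = res$se,
    statistic = res$stat, p_value = res$p,
    n = nrow(G), breed = breed, trait = trait,
    excluded = res$excluded
  )
  attr(out, "null_components") <- tidy(null_fit)
  class(out) <- c("gwas_table", class(out))
  out
}

gwas_two_stage <- function(null_fit, G) {
  mod <- null_fit$model
  V <- null_fit$state$V
  dV <- diag(V)
  if (max(abs(V - diag(dV, nrow(V)))) < 1e-12 * max(dV)) {
    # diagonal covariance (e.g. zero polygenic variance): no eigen needed
    w <- 1 / sqrt(dV)
    ystar <- mod$y * w
    Xstar <- mod$X * w
    G <- G * w
    decorrelate <- function(M) M
  } else {
    ev <- eigen(V, symmetric = TRUE)
    W <- t(ev$vectors) / sqrt(pmax(ev$values, 1e-12))
    ystar <- as.numeric(W %*% mod$y)
    Xstar <- W %*% mod$X
    decorrelate <- function(M) W %*% M
  }
  qx <- qr(Xstar)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  yres <- ystar - Q %*% crossprod(Q, ystar)

  # mean-impute missing genotypes within the scan so centring stays exact
  na_mask <- is.na(G)
  if (any(na_mask)) {
    mu <- colMeans(G, na.rm = TRUE)
    G[na_mask] <- mu[col(G)[na_mask]]
  }
  mono <- apply(G, 2, function(g) length(unique(g)) < 2)

  Gstar <- decorrelate(G)
  Gres <- Gstar - Q %*% crossprod(Q, Gstar)
  den <- colSums(Gres^2)
  num <- as.numeric(crossprod(Gres, yres))
  beta <- ifelse(den > 1e-10, num / den, NA_real_)
  df <- length(ystar) - qx$rank - 1L
  ss_y <- sum(yres^2)
  s2 <- pmax((ss_y - beta^2 * den) / df, 1e-300)
  se <- sqrt(s2 / den)
  stat <- beta / se
  p <- 2 * stats::pt(-abs(stat), df)
  excluded <- mono | !(den > 1e-10) | !is.finite(stat)
  beta[excluded] <- NA_real_; se[excluded] <- NA_real_
  stat[excluded] <- NA_real_; p[excluded] <- NA_real_
  list(beta = unname(beta), se = unname(se), stat = unname(stat),
       p = unname(p), excluded = unname(excluded))
}

gwas_exact <- function(data, G, nrm, response, fixed, animal) {
  m <- ncol(G)
  beta <- se <- stat <- p <- rep(NA_real_, m)
  excluded <- rep(FALSE, m)
  for (j in seq_len(m)) {
    g <- G[, j]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (length(unique(g)) < 2) {
      excluded[j] <- TRUE
      next
    }
    dat_j <- data
    dat_j[[".snp"]] <- g
    fixed_j <- stats::update(fixed, ~ . + .snp)
    fit_j <- reml_fit(dat_j, response = response, fixed = fixed_j,
                      random = list(polygenic = mm_term(nrm, "diagonal")),
                      animal = animal)
    sol <- solve_mme(fit_j)
    row <- sol$fixed[sol$fixed$term == ".snp", ]
    beta[j] <- row$estimate
    se[j] <- row$std_error
    stat[j] <- row$estimate / row$std_error
    p[j] <- 2 * stats::pnorm(-abs(stat[j]))
  }
  list(beta = beta, se = se, stat = stat, p = p, excluded = excluded)
}

#' Manhattan-style plot of a scan
#' @param object A `gwas_table`.
#' @param ... Unused.
#' @return A ggplot of -log10 p-values by marker index.
#' @method autoplot gwas_table
#' @export
autoplot.gwas_table <- function(object, ...) {
  df <- object[!object$excluded, ]
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$index, -log10(.data$p_value))) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::labs(x = "marker index", y = expression(-log[10](p)))
}
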