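#' Define a calibration/validation scheme
#'
#' A scheme names which breed-by-sex cell keeps its phenotypes (calibration)
#' and which cell is scored (validation). The three canonical schemes of a
#' two-breed cow/bull design are: cows of one breed predicting cows of the
#' other breed (cross-breed within-sex), cows predicting bulls of the same
#' breed (within-breed cross-sex) and cows predicting bulls of the other
#' breed (cross-breed cross-sex).
#'
#' @param calibration,validation Named character vectors with elements
#'   `breed` and `sex`.
#' @param label Scheme label.
#' @return A `validation_scheme` object.
#' @export
validation_scheme <- function(calibration, validation, label = NULL) {
  req <- c("breed", "sex")
  if (!all(req %in% names(calibration)) || !all(req %in% names(validation))) {
    stop_config("calibration/validation selectors need `breed` and `sex`.")
  }
  if (identical(calibration[req], validation[req])) {
    stop_config("calibration and validation cells must not overlap.")
  }
  kind <- if (calibration[["breed"]] != validation[["breed"]] &&
              calibration[["sex"]] == validation[["sex"]]) {
    "cross-breed within-sex"
  } else if (calibration[["breed"]] == validation[["breed"]]) {
    "within-breed cross-sex"
  } else {
    "cross-breed cross-sex"
  }
  structure(list(calibration = calibration[req], validation = validation[req],
                 kind = kind,
                 label = label %||% paste0(calibration[["breed"]], " ",
                                           sex_word(calibration[["sex"]]),
                                           " : ", validation[["breed"]], " ",
                                           sex_word(validation[["sex"]]))),
            class = "validation_scheme")
}

sex_word <- function(s) c(F = "cows", M = "bulls")[[s]]

#' @export
print.validation_scheme <- function(x, ...) {
  cat("<validation_scheme>", x$label, "-", x$kind, "\n")
  invisible(x)
}

#' The six schemes of a two-breed cow/bull validation design
#'
#' @param breeds The two breed labels.
#' @return List of six [validation_scheme()]s: both directions of cows
#'   predicting cows of the other breed, cows predicting bulls of the same
#'   breed, and cows predicting bulls of the other breed.
#' @export
study_schemes <- function(breeds = c("BB", "TC")) {
  b1 <- breeds[1]; b2 <- breeds[2]
  list(
    validation_scheme(c(breed = b1, sex = "F"), c(breed = b2, sex = "F")),
    validation_scheme(c(breed = b2, sex = "F"), c(breed = b1, sex = "F")),
    validation_scheme(c(breed = b1, sex = "F"), c(breed = b1, sex = "M")),
    validation_scheme(c(breed = b2, sex = "F"), c(breed = b2, sex = "M")),
    validation_scheme(c(breed = b1, sex = "F"), c(breed = b2, sex = "M")),
    validation_scheme(c(breed = b2, sex = "F"), c(breed = b1, sex = "M"))
  )
}

#' Within-breed two-sex pedigree fits
#'
#' Fits, per breed, a bi-variate animal model treating the phenotype in cows
#' and in bulls as two traits with a pedigree relationship matrix, yielding
#' the between-sex genetic correlation and the within-breed fixed-effect
#' solutions (BLUE) later used to adjust validation phenotypes.
#'
#' @param data Phenotype records for both breeds and sexes.
#' @param nrm Pedigree relationship matrix covering all recorded animals.
#' @param response,fixed,animal As in [reml_fit()].
#' @param breed_col,sex_col Column names.
#' @return Named list (one per breed) of bi-variate [reml_fit()]s with sex as
#'   the trait.
#' @export
within_breed_fits <- function(data, nrm, response = "pheno", fixed = ~1,
                              animal = "animal", breed_col = "breed",
                              sex_col = "sex") {
  breeds <- sort(unique(data[[breed_col]]))
  fits <- lapply(breeds, function(b) {
    sub <- data[data[[breed_col]] == b, , drop = FALSE]
    reml_fit(sub, response = response, fixed = fixed,
             random = list(pedigree = mm_term(nrm, "unstructured")),
             animal = animal, trait = sex_col)
  })
  stats::setNames(fits, breeds)
}

#' Phenotypes adjusted for within-breed fixed effects
#'
#' Subtracts the fixed-effect solutions of the within-breed per-sex fits from
#' the observed phenotypes. Records carrying a factor level that was unseen
#' in the corresponding within-breed fit cannot be adjusted and are dropped
#' with a message.
#'
#' @param data Phenotype records to adjust.
#' @param fits Named list of per-breed fits from [within_breed_fits()].
#' @param response,breed_col Column names.
#' @return Tibble `animal`, `breed`, `sex`, `adjusted`.
#' @export
adjusted_phenotypes <- function(data, fits, response = "pheno",
                                breed_col = "breed") {
  out <- lapply(names(fits), function(b) {
    sub <- data[data[[breed_col]] == b & !is.na(data[[response]]), , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    fe <- fitted_fixed_effects(fits[[b]], newdata = sub)
    keep <- !is.na(fe)
    tibble::tibble(animal = sub$animal[keep], breed = b,
                   sex = sub[[fits[[b]]$model$trait_col %||% "sex"]][keep],
                   adjusted = sub[[response]][keep] - fe[keep])
  })
  dplyr::bind_rows(out)
}

#' GBLUP prediction under a masking scheme
#'
#' Merges both breeds and sexes into one dataset, masks every phenotype
#' outside the calibration cell, re-estimates the genomic and residual
#' variances by uni-variate REML on the unmasked records (a single
#' marker-based random term, no pedigree term), and returns genomic estimated
#' breeding values (GEBV) for all animals covered by the relationship matrix.
#' Masked phenotypes never enter the likelihood or the predictions, so
#' perturbing them cannot change any GEBV.
#'
#' @param data Merged phenotype records (all breeds and sexes).
#' @param grm Genomic relationship matrix covering all animals to score.
#' @param scheme A [validation_scheme()]; only records matching its
#'   calibration cell keep their phenotypes.
#' @param response,fixed,animal As in [reml_fit()].
#' @param breed_col,sex_col Column names for the selector.
#' @param components Optional fixed variance components (tibble as from
#'   `tidy()` on a previous fit) to reuse instead of re-estimating.
#' @return Tibble `animal`, `gebv`, with the scheme, fitted components and
#'   calibration size in attributes.
#' @export
gblup_predict <- function(data, grm, scheme, response = "pheno", fixed = ~1,
                          animal = "animal", breed_col = "breed",
                          sex_col = "sex", components = NULL) {
  stopifnot(inherits(scheme, "validation_scheme"))
  cal <- data[[breed_col]] == scheme$calibration[["breed"]] &
    data[[sex_col]] == scheme$calibration[["sex"]] &
    !is.na(data[[response]])
  if (!any(cal)) {
    stop_config("calibration cell `", scheme$label, "` has no records.")
  }
  obs <- droplevels(data[cal, , drop = FALSE])

  start <- NULL
  if (!is.null(components)) {
    start <- stats::setNames(components$estimate,
                             paste(components$term, components$trait_1,
                                   components$trait_2, sep = ":"))
  }
  fit <- reml_fit(obs, response = response, fixed = fixed,
                  random = list(genomic = mm_term(grm, "diagonal")),
                  animal = animal, start = start,
                  max_iter = if (is.null(components)) 200 else 0)
  sol <- solve_mme(fit)
  gebv <- sol$random[sol$random$term == "genomic", c("animal", "blup")]
  out <- tibble::tibble(animal = gebv$animal, gebv = gebv$blup)
  attr(out, "scheme") <- scheme
  attr(out, "components") <- tidy(fit)
  attr(out, "n_calibration") <- nrow(obs)
  out
}

#' Accuracy and dispersion bias of genomic predictions
#'
#' Accuracy is the product-moment correlation between GEBV and the adjusted
#' phenotype over the validation animals; bias is the slope of the ordinary
#' regression of the adjusted phenotype on the GEBV (slope 1 means
#' dispersion-unbiased predictions; this is the regression in that direction,
#' not the inverse one).
#'
#' @param gebv Output of [gblup_predict()].
#' @param adjusted Output of [adjusted_phenotypes()].
#' @param scheme The [validation_scheme()] whose validation cell is scored;
#'   defaults to the scheme stored on `gebv`.
#' @return One-row tibble: `scheme`, `kind`, `n_calibration`, `n_validation`,
#'   `accuracy`, `bias`. Zero-variance GEBV yield `NA` accuracy/bias with a
#'   warning.
#' @export
accuracy_and_bias <- function(gebv, adjusted, scheme = attr(gebv, "scheme")) {
  stopifnot(inherits(scheme, "validation_scheme"))
  val <- adjusted[adjusted$breed == scheme$validation[["breed"]] &
                    adjusted$sex == scheme$validation[["sex"]], , drop = FALSE]
  joined <- dplyr::inner_join(val, gebv, by = "animal")
  if (nrow(joined) < 3) {
    stop_config("fewer than 3 validation animals with both GEBV and ",
                "adjusted phenotype for `", scheme$label, "`.")
  }
  if (stats::sd(joined$gebv) < 1e-12) {
    warning("zero-variance GEBV: accuracy and bias undefined for `",
            scheme$label, "`.")
    acc <- NA_real_; slope <- NA_real_
  } else {
    acc <- stats::cor(joined$gebv, joined$adjusted)
    slope <- stats::cov(joined$adjusted, joined$gebv) / stats::var(joined$gebv)
  }
  lab <- scheme[["label"]]; knd <- scheme[["kind"]]
  tibble::tibble(scheme = lab, kind = knd,
                 n_calibration = attr(gebv, "n_calibration") %||% NA_integer_,
                 n_validation = nrow(joined),
                 accuracy = acc, bias = slope)
}

#' Full trait x scheme x GRM validation grid
#'
#' Runs [gblup_predict()] and [accuracy_and_bias()] for every combination of
#' trait, scheme and relationship-matrix variant, the full factorial of a
#' multi-matrix validation study.
#'
#' @param data Merged phenotype records.
#' @param grms Named list of genomic relationship matrices (e.g. `G_W`,
#'   `G_S`, `G_D`).
#' @param schemes List of [validation_scheme()]s (default [study_schemes()]
#'   over the breeds present).
#' @param adjusted Adjusted phenotypes from [adjusted_phenotypes()]; when a
#'   list named by trait, matched per response.
#' @param responses Response column(s); one per trait.
#' @param fixed,animal,breed_col,sex_col As in [gblup_predict()].
#' @return A `validation_report` tibble: `trait`, `scheme`, `kind`, `grm`,
#'   `n_calibration`, `n_validation`, `accuracy`, `bias`. Schemes whose
#'   calibration cell is empty for a trait are skipped with a message.
#' @seealso [report_averages()]
#' @export
run_validation_grid <- function(data, grms, schemes = NULL, adjusted,
                                responses = "pheno", fixed = ~1,
                                animal = "animal", breed_col = "breed",
                                sex_col = "sex") {
  if (is.null(schemes)) {
    schemes <- study_schemes(sort(unique(data[[breed_col]])))
  }
  rows <- list()
  for (resp in responses) {
    adj <- if (is.data.frame(adjusted)) adjusted else adjusted[[resp]]
    for (sc in schemes) {
      for (gname in names(grms)) {
        row <- tryCatch({
          gebv <- gblup_predict(data, grms[[gname]], sc, response = resp,
                                fixed = fixed, animal = animal,
                                breed_col = breed_col, sex_col = sex_col)
          accuracy_and_bias(gebv, adj, sc)
        }, gencor_config_error = function(e) {
          message("skipping ", sc$label, " x ", gname, ": ",
                  conditionMessage(e))
          NULL
        })
        if (!is.null(row)) {
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            tibble::tibble(trait = resp, grm = gname), row)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("validation_report", class(out))
  out
}

#' Per-scheme averages of a validation report
#'
#' The arithmetic mean of the per-trait accuracies and biases for each
#' scheme x GRM cell -- the "Average" rows of a validation table.
#'
#' @param report A `validation_report`.
#' @return Tibble `scheme`, `kind`, `grm`, `mean_accuracy`, `mean_bias`,
#'   `n_traits`.
#' @export
report_averages <- function(report) {
  report |>
    dplyr::group_by(.data$scheme, .data$kind, .data$grm) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     mean_bias = mean(.data$bias),
                     n_traits = dplyr::n(), .groups = "drop")
}

#' Plot a validation report
#' @param object A `validation_report`.
#' @param metric `"accuracy"` or `"bias"`.
#' @param ... Unused.
#' @return A ggplot comparing GRM variants across schemes.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, metric = c("accuracy", "bias"),
                                       ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$scheme, .data[[metric]],
                               fill = .data$grm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = if (metric == "bias") 1 else 0,
                        linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = metric, fill = NULL)
}
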