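#' Solutions of the mixed-model equations
#'
#' Returns the best linear unbiased estimates (BLUE) of the fixed effects and
#' best linear unbiased predictions (BLUP) of each random term at the
#' (co)variance components of a fit, equivalent to solving Henderson's
#' mixed-model equations. Predictions are produced for every animal covered
#' by a term's relationship matrix, so animals without records (or with
#' masked responses) are predicted through their relationships with recorded
#' animals.
#'
#' Fixed-effect solutions are reported under the identifiability constraint
#' used in fitting (first level of each factor set to zero).
#'
#' @param fit A [reml_fit()].
#' @param components Optional replacement component tibble (same layout as
#'   `tidy(fit)`) at which to solve; default: the fitted estimates.
#' @param ids Optional animal ids to predict (default: all animals in each
#'   term's relationship matrix).
#' @return List with `fixed` (tibble: `trait`, `term`, `estimate`,
#'   `std_error`) and `random` (tibble: `term`, `animal`, `trait`, `blup`).
#' @export
solve_mme <- function(fit, components = NULL, ids = NULL) {
  mod <- fit$model
  state <- fit$state
  if (!is.null(components)) {
    theta <- fit$theta
    key <- paste(components$term, components$trait_1, components$trait_2,
                 sep = ":")
    theta[key] <- components$estimate
    Vlist <- build_structure_matrices(
      mod, tibble::tibble(term = sub(":.*", "", names(theta)),
                          trait_1 = fit$components$trait_1,
                          trait_2 = fit$components$trait_2))
    state <- reml_state(theta, Vlist, mod)
  } else {
    theta <- fit$theta
  }

  # fixed effects
  beta <- as.numeric(state$beta)
  se <- sqrt(pmax(diag(state$C), 0))
  cn <- colnames(mod$X)
  fixed <- tibble::tibble(
    trait = sub(":.*$", "", cn),
    term = sub("^[^:]*:", "", cn),
    estimate = beta, std_error = se
  )

  # random-effect predictions: u_hat = Cov(u, y) V^-1 (y - X beta) = Cov(u,y) P y
  Py <- as.numeric(state$Py)
  cmp <- if (is.null(components)) fit$components else components
  traits <- fit$traits
  rand <- list()
  for (k in seq_along(mod$terms)) {
    nm <- names(mod$terms)[k]
    K <- unclass(mod$terms[[k]]$K)
    targets <- ids %||% rownames(K)
    B <- matrix(0, length(traits), length(traits),
                dimnames = list(traits, traits))
    for (r in which(cmp$term == nm)) {
      B[cmp$trait_1[r], cmp$trait_2[r]] <- cmp$estimate[r]
      B[cmp$trait_2[r], cmp$trait_1[r]] <- cmp$estimate[r]
    }
    for (t in seq_along(traits)) {
      u_t <- numeric(length(targets))
      for (t2 in seq_along(traits)) {
        if (B[t, t2] == 0) next
        recs <- which(mod$rec_trait == t2)
        u_t <- u_t + B[t, t2] *
          as.numeric(K[targets, mod$rec_animal[recs], drop = FALSE] %*% Py[recs])
      }
      rand[[length(rand) + 1]] <- tibble::tibble(
        term = nm, animal = targets, trait = traits[t], blup = u_t)
    }
  }
  list(fixed = fixed, random = dplyr::bind_rows(rand))
}

# fitted fixed-effect values for records, or for new data via the stored
# formula and factor levels; records whose factor levels were unseen in the
# fit are returned as NA
fitted_fixed_effects <- function(fit, newdata = NULL) {
  mod <- fit$model
  if (is.null(newdata)) {
    return(as.numeric(mod$X %*% fit$state$beta))
  }
  traits <- fit$traits
  trait_f <- if (is.null(mod$trait_col)) {
    factor(rep(traits[1], nrow(newdata)), levels = traits)
  } else {
    factor(as.character(newdata[[mod$trait_col]]), levels = traits)
  }
  out <- rep(NA_real_, nrow(newdata))
  beta <- stats::setNames(as.numeric(fit$state$beta), colnames(mod$X))
  for (t in seq_along(traits)) {
    rows <- which(trait_f == traits[t])
    if (length(rows) == 0) next
    sub <- newdata[rows, , drop = FALSE]
    xlev <- mod$xlevels[[traits[t]]]
    seen <- rep(TRUE, nrow(sub))
    for (v in names(xlev)) {
      seen <- seen & as.character(sub[[v]]) %in% xlev[[v]]
    }
    if (!all(seen)) {
      message("dropping ", sum(!seen), " record(s) with factor levels unseen ",
              "in the `", traits[t], "` fit.")
    }
    if (!any(seen)) next
    sub2 <- sub[seen, , drop = FALSE]
    for (v in names(xlev)) sub2[[v]] <- factor(as.character(sub2[[v]]), levels = xlev[[v]])
    Xt <- stats::model.matrix(mod$fixed, stats::model.frame(mod$fixed, sub2))
    colnames(Xt) <- paste(traits[t], colnames(Xt), sep = ":")
    use <- intersect(colnames(Xt), names(beta))
    out[rows[seen]] <- as.numeric(Xt[, use, drop = FALSE] %*% beta[use])
  }
  out
}
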