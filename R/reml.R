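#' Declare a random term for the mixed model
#'
#' A random term contributes `B %x% K` to the covariance of the records,
#' where `K` is a fixed animal-by-animal relationship matrix and `B` is an
#' estimable trait-covariance block. Structures:
#' \describe{
#'   \item{`"diagonal"`}{one variance per trait, cross-trait covariance fixed
#'     at zero (e.g. a pedigree term across two breeds with no common
#'     ancestors, where the covariance is structurally zero and not
#'     estimated);}
#'   \item{`"unstructured"`}{full block: per-trait variances plus a free
#'     covariance, kept positive semidefinite during estimation (e.g. a
#'     genomic term whose cross-breed covariance yields the genomic
#'     correlation). Limited to two traits.}
#' }
#'
#' @param K A `relationship_matrix` (or symmetric matrix with animal id
#'   dimnames) covering every animal in the model.
#' @param structure Trait-covariance structure.
#' @return An object of class `mm_term`.
#' @export
mm_term <- function(K, structure = c("unstructured", "diagonal")) {
  structure <- match.arg(structure)
  if (is.null(rownames(K))) stop_structure("`K` must have animal id dimnames.")
  structure(list(K = K, structure = structure), class = "mm_term")
}

#' Fit a multi-trait animal model by restricted maximum likelihood
#'
#' Average-information REML with step-halving and an expectation-maximisation
#' fallback, for models of the form
#' `y = X beta + sum_k Z_k u_k + e`, where each random term has covariance
#' `B_k %x% K_k` ([mm_term()]) and the residual is diagonal with one variance
#' per trait. Fixed effects are fitted separately per trait (block-diagonal
#' design), matching the usual multi-breed animal model where each breed has
#' its own contemporary-group and covariate solutions. The restricted
#' log-likelihood is guaranteed non-decreasing over iterations: proposed
#' average-information steps that would decrease it are halved and, failing
#' that, replaced by an EM-style update.
#'
#' Records with a missing response are dropped from the likelihood but their
#' animals still receive predictions through the relationship matrices (see
#' [solve_mme()]).
#'
#' @param data Data frame, one row per record.
#' @param response Name of the response column.
#' @param fixed One-sided formula of fixed effects (applied within each
#'   trait; an intercept is always included). The first level of each factor
#'   is constrained to zero (treatment contrasts), which is the
#'   identifiability constraint under which fixed-effect solutions are
#'   reported.
#' @param random Named list of [mm_term()]s.
#' @param animal Name of the animal id column.
#' @param trait Optional name of the column assigning each record to a trait
#'   (e.g. breed, or sex); `NULL` fits a univariate model.
#' @param max_iter,tol_loglik,tol_param Convergence control: iteration cap,
#'   relative restricted-log-likelihood change, and parameter change relative
#'   to the phenotypic variance.
#' @param variance_floor Lower bound for variances, as a fraction of the
#'   per-trait phenotypic variance.
#' @param start Optional named numeric vector of starting values (names as in
#'   `tidy()` output: `term:trait1:trait2`).
#' @param verbose Print the restricted log-likelihood per iteration.
#' @return An object of class `reml_fit`; see [tidy.reml_fit()],
#'   [glance.reml_fit()], [genomic_correlation()], [missing_heritability()],
#'   [parameter_summary()] and [solve_mme()].
#' @export
reml_fit <- function(data, response, fixed = ~1, random, animal = "animal",
                     trait = NULL, max_iter = 200, tol_loglik = 1e-8,
                     tol_param = 1e-6, variance_floor = 1e-6,
                     start = NULL, verbose = FALSE) {
  mod <- build_model(data, response, fixed, random, animal, trait)
  n <- length(mod$y)
  p <- ncol(mod$X)

  params <- init_params(mod, start, variance_floor)
  theta <- params$theta
  floor_vec <- params$floor
  info <- params$info # tibble: term, trait_1, trait_2, is_var, n_rec

  Vlist <- build_structure_matrices(mod, info)
  loglik_trace <- numeric(0)
  state <- reml_state(theta, Vlist, mod)
  if (!is.finite(state$loglik)) stop_numeric("restricted likelihood not finite at start.")
  converged <- FALSE
  iter <- 0
  n_tiny <- 0L
  AI <- NULL

  repeat {
    if (max_iter == 0) { # evaluate-only mode (components supplied)
      converged <- TRUE
      loglik_trace <- state$loglik
      break
    }
    iter <- iter + 1
    loglik_trace <- c(loglik_trace, state$loglik)
    if (verbose) {
      cat(sprintf("iter %3d  logL_R = %.6f\n", iter, state$loglik))
    }
    gs <- reml_gradient_ai(theta, Vlist, mod, state)
    AI <- gs$AI

    # active-set average-information step: parameters pinned at the variance
    # floor with an outward-pointing gradient are dropped from the update so
    # they cannot stall the free directions
    at_floor <- info$is_var & theta <= floor_vec * (1 + 1e-8)
    free <- !(at_floor & gs$grad < 0)
    step <- numeric(length(theta))
    if (any(free)) {
      Af <- AI[free, free, drop = FALSE]
      step[free] <- tryCatch(
        solve(Af + diag(1e-8 * max(diag(Af)) + 1e-12, sum(free)),
              gs$grad[free]),
        error = function(e) rep(0, sum(free)))
    }
    accepted <- FALSE
    new_state <- NULL; new_theta <- NULL
    h <- 1
    for (half in 1:12) {
      cand <- constrain_theta(theta + h * step, info, floor_vec)
      cand_state <- try_state(cand, Vlist, mod)
      if (!is.null(cand_state) && cand_state$loglik >= state$loglik - 1e-10) {
        accepted <- TRUE; new_theta <- cand; new_state <- cand_state
        break
      }
      h <- h / 2
    }
    if (!accepted) {
      # EM-style fallback on the variance parameters
      cand <- theta
      for (j in which(info$is_var)) {
        cand[j] <- theta[j] +
          theta[j]^2 * (gs$ypvpy[j] - gs$trpv[j]) / max(info$n_rec[j], 1)
      }
      cand <- constrain_theta(cand, info, floor_vec)
      cand_state <- try_state(cand, Vlist, mod)
      if (!is.null(cand_state) && cand_state$loglik >= state$loglik - 1e-10) {
        new_theta <- cand; new_state <- cand_state; accepted <- TRUE
      }
    }
    if (!accepted) {
      # no uphill move found: treat as converged at a local optimum
      converged <- TRUE
      break
    }

    d_loglik <- new_state$loglik - state$loglik
    d_param <- max(abs(new_theta - theta))
    theta <- new_theta; state <- new_state
    tiny_ll <- d_loglik < tol_loglik * (1 + abs(state$loglik))
    n_tiny <- if (tiny_ll) n_tiny + 1L else 0L
    if (tiny_ll &&
        (d_param < tol_param * max(params$var_pheno) || n_tiny >= 3L)) {
      # either fully settled, or the likelihood has been flat for several
      # iterations while constrained parameters shuffle along a boundary
      converged <- TRUE
      loglik_trace <- c(loglik_trace, state$loglik)
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning("reml_fit: not converged within ", max_iter, " iterations.")
  }

  gs <- reml_gradient_ai(theta, Vlist, mod, state)
  se <- rep(NA_real_, length(theta))
  vcov_theta <- tryCatch(solve(gs$AI), error = function(e) NULL)
  if (!is.null(vcov_theta)) se <- sqrt(pmax(diag(vcov_theta), 0))

  components <- tibble::tibble(
    term = info$term, trait_1 = info$trait_1, trait_2 = info$trait_2,
    estimate = theta, std_error = se,
    at_floor = info$is_var & theta <= floor_vec * (1 + 1e-6)
  )

  structure(
    list(components = components, loglik = state$loglik,
         loglik_trace = loglik_trace, iterations = iter,
         converged = converged, gradient = gs$grad,
         ai_matrix = gs$AI, vcov_theta = vcov_theta,
         traits = mod$traits, terms = mod$terms,
         model = mod, theta = theta, state = state,
         n = n, n_fixed = p),
    class = "reml_fit"
  )
}

# ---- model assembly --------------------------------------------------------

build_model <- function(data, response, fixed, random, animal, trait) {
  if (!response %in% names(data)) stop_config("response column `", response, "` not found.")
  if (!animal %in% names(data)) stop_config("animal column `", animal, "` not found.")
  if (!is.list(random) || length(random) == 0 ||
      !all(vapply(random, inherits, logical(1), "mm_term"))) {
    stop_config("`random` must be a non-empty named list of mm_term objects.")
  }
  if (is.null(names(random)) || any(names(random) == "")) {
    names(random) <- paste0("term", seq_along(random))
  }
  # identical structure + identical K => non-identifiable
  if (length(random) > 1) {
    for (i in seq_along(random)) for (j in seq_along(random)) {
      if (i < j && random[[i]]$structure == random[[j]]$structure &&
          isTRUE(all.equal(unclass(random[[i]]$K), unclass(random[[j]]$K),
                           check.attributes = FALSE))) {
        stop_structure("random terms `", names(random)[i], "` and `",
                       names(random)[j],
                       "` have identical covariance structure and identical ",
                       "relationship matrix: not identifiable.")
      }
    }
  }

  keep <- !is.na(data[[response]])
  dat <- data[keep, , drop = FALSE]
  if (nrow(dat) == 0) stop_config("no records with observed response.")

  if (is.null(trait)) {
    trait_f <- factor(rep("trait1", nrow(dat)))
  } else {
    if (!trait %in% names(dat)) stop_config("trait column `", trait, "` not found.")
    trait_f <- factor(dat[[trait]])
  }
  traits <- levels(trait_f)
  if (any(table(trait_f) == 0)) stop_config("every trait needs at least one record.")

  for (k in seq_along(random)) {
    if (random[[k]]$structure == "unstructured" && length(traits) > 2) {
      stop_config("unstructured trait blocks are limited to two traits.")
    }
    missing_animals <- setdiff(dat[[animal]], rownames(random[[k]]$K))
    if (length(missing_animals) > 0) {
      stop_structure("relationship matrix of term `", names(random)[k],
                     "` does not cover: ",
                     paste(utils::head(missing_animals, 5), collapse = ", "))
    }
  }

  # block-diagonal fixed design: separate solutions per trait
  Xs <- vector("list", length(traits))
  xlevels <- vector("list", length(traits))
  for (t in seq_along(traits)) {
    sub <- droplevels(dat[trait_f == traits[t], , drop = FALSE])
    mf <- stats::model.frame(fixed, data = sub, na.action = stats::na.pass)
    Xt <- stats::model.matrix(fixed, mf)
    if (anyNA(Xt)) stop_config("missing values in fixed-effect columns.")
    # drop rank-deficient columns (confounded levels absorbed)
    qrX <- qr(Xt)
    if (qrX$rank < ncol(Xt)) {
      Xt <- Xt[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    }
    colnames(Xt) <- paste(traits[t], colnames(Xt), sep = ":")
    Xs[[t]] <- Xt
    xlevels[t] <- list(stats::.getXlevels(stats::terms(fixed, data = sub), mf))
  }
  names(xlevels) <- traits
  X <- matrix(0, nrow(dat), sum(vapply(Xs, ncol, integer(1))))
  colnames(X) <- unlist(lapply(Xs, colnames))
  col0 <- 0
  trait_idx <- as.integer(trait_f)
  for (t in seq_along(traits)) {
    rows <- which(trait_idx == t)
    X[rows, col0 + seq_len(ncol(Xs[[t]]))] <- Xs[[t]]
    col0 <- col0 + ncol(Xs[[t]])
  }

  list(y = as.numeric(dat[[response]]), X = X,
       rec_animal = as.character(dat[[animal]]),
       rec_trait = trait_idx, traits = traits,
       terms = random, fixed = fixed, xlevels = xlevels,
       trait_col = trait, animal_col = animal, response_col = response)
}

init_params <- function(mod, start, variance_floor) {
  traits <- mod$traits
  nt <- length(traits)
  var_pheno <- vapply(seq_len(nt), function(t) {
    stats::var(mod$y[mod$rec_trait == t])
  }, numeric(1))
  var_pheno[!is.finite(var_pheno) | var_pheno <= 0] <- 1

  rows <- list()
  nterm <- length(mod$terms)
  for (k in seq_along(mod$terms)) {
    tm <- mod$terms[[k]]
    nm <- names(mod$terms)[k]
    for (t in seq_len(nt)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        term = nm, trait_1 = traits[t], trait_2 = traits[t], is_var = TRUE,
        value = 0.5 * var_pheno[t] / nterm,
        floor = variance_floor * var_pheno[t],
        n_rec = sum(mod$rec_trait == t))
    }
    if (tm$structure == "unstructured" && nt == 2) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        term = nm, trait_1 = traits[1], trait_2 = traits[2], is_var = FALSE,
        value = 0, floor = -Inf, n_rec = length(mod$y))
    }
  }
  for (t in seq_len(nt)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      term = "residual", trait_1 = traits[t], trait_2 = traits[t],
      is_var = TRUE, value = 0.5 * var_pheno[t],
      floor = variance_floor * var_pheno[t],
      n_rec = sum(mod$rec_trait == t))
  }
  info <- dplyr::bind_rows(rows)
  theta <- info$value
  names(theta) <- paste(info$term, info$trait_1, info$trait_2, sep = ":")
  if (!is.null(start)) {
    hit <- intersect(names(start), names(theta))
    theta[hit] <- start[hit]
  }
  list(theta = theta, floor = info$floor, info = info, var_pheno = var_pheno)
}

# one dense symmetric structure matrix per parameter: V(theta) = sum theta_j V_j
build_structure_matrices <- function(mod, info) {
  n <- length(mod$y)
  idx_by_trait <- lapply(seq_along(mod$traits),
                         function(t) which(mod$rec_trait == t))
  Krec_cache <- list()
  out <- vector("list", nrow(info))
  for (j in seq_len(nrow(info))) {
    term <- info$term[j]
    t1 <- match(info$trait_1[j], mod$traits)
    t2 <- match(info$trait_2[j], mod$traits)
    M <- matrix(0, n, n)
    if (term == "residual") {
      d <- idx_by_trait[[t1]]
      M[cbind(d, d)] <- 1
    } else {
      if (is.null(Krec_cache[[term]])) {
        K <- mod$terms[[term]]$K
        Krec_cache[[term]] <- unclass(K)[mod$rec_animal, mod$rec_animal]
      }
      Krec <- Krec_cache[[term]]
      i1 <- idx_by_trait[[t1]]; i2 <- idx_by_trait[[t2]]
      if (t1 == t2) {
        M[i1, i1] <- Krec[i1, i1]
      } else {
        M[i1, i2] <- Krec[i1, i2]
        M[i2, i1] <- Krec[i2, i1]
      }
    }
    out[[j]] <- M
  }
  out
}

constrain_theta <- function(theta, info, floor_vec) {
  theta[info$is_var] <- pmax(theta[info$is_var], floor_vec[info$is_var])
  # keep each unstructured 2x2 block positive semidefinite
  cov_rows <- which(!info$is_var)
  for (j in cov_rows) {
    v1 <- theta[info$term == info$term[j] & info$is_var &
                  info$trait_1 == info$trait_1[j]]
    v2 <- theta[info$term == info$term[j] & info$is_var &
                  info$trait_1 == info$trait_2[j]]
    bound <- 0.999 * sqrt(v1 * v2)
    if (abs(theta[j]) > bound) theta[j] <- sign(theta[j]) * bound
  }
  theta
}

# core linear algebra at a parameter value
reml_state <- function(theta, Vlist, mod) {
  n <- length(mod$y)
  V <- matrix(0, n, n)
  for (j in seq_along(theta)) {
    if (theta[j] != 0) V <- V + theta[j] * Vlist[[j]]
  }
  ch <- chol(V)
  Vinv <- chol2inv(ch)
  ViX <- Vinv %*% mod$X
  XtViX <- crossprod(mod$X, ViX)
  chX <- chol(XtViX)
  C <- chol2inv(chX) # (X' V^-1 X)^-1
  Viy <- Vinv %*% mod$y
  beta <- C %*% crossprod(ViX, mod$y)
  Py <- Viy - ViX %*% (C %*% crossprod(ViX, mod$y))
  loglik <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                      sum(mod$y * Py))
  list(V = V, Vinv = Vinv, ViX = ViX, C = C, beta = beta, Py = Py,
       loglik = as.numeric(loglik))
}

try_state <- function(theta, Vlist, mod) {
  out <- tryCatch(reml_state(theta, Vlist, mod), error = function(e) NULL)
  if (!is.null(out) && !is.finite(out$loglik)) out <- NULL
  out
}

reml_gradient_ai <- function(theta, Vlist, mod, state) {
  np <- length(theta)
  Py <- state$Py
  trpv <- numeric(np)
  ypvpy <- numeric(np)
  W <- matrix(0, length(Py), np) # V_j P y
  for (j in seq_len(np)) {
    Vj <- Vlist[[j]]
    # tr(P V_j) = tr(V^-1 V_j) - tr(C (V^-1 X)' V_j (V^-1 X))
    tr1 <- sum(state$Vinv * Vj)
    B <- Vj %*% state$ViX
    tr2 <- sum(state$C * crossprod(state$ViX, B))
    trpv[j] <- tr1 - tr2
    W[, j] <- Vj %*% Py
    ypvpy[j] <- sum(Py * W[, j])
  }
  grad <- -0.5 * (trpv - ypvpy)
  # P W
  PW <- state$Vinv %*% W - state$ViX %*% (state$C %*% crossprod(state$ViX, W))
  AI <- 0.5 * crossprod(W, PW)
  list(grad = grad, AI = AI, trpv = trpv, ypvpy = ypvpy)
}

# ---- accessors -------------------------------------------------------------

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> ", length(x$traits), " trait(s), ", x$n, " records, ",
      x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged",
      "; logL_R = ", format(x$loglik, digits = 8), "\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Tidy a REML fit
#'
#' @param x A [reml_fit()] object.
#' @param ... Unused.
#' @return Tibble of (co)variance components: `term`, `trait_1`, `trait_2`,
#'   `estimate`, `std_error` (from the inverse average-information matrix at
#'   convergence; approximate) and `at_floor`.
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, ...) x$components

#' Glance at a REML fit
#'
#' @param x A [reml_fit()] object.
#' @param ... Unused.
#' @return One-row tibble with the restricted log-likelihood, iteration
#'   count, convergence flag and sizes.
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, iterations = x$iterations,
                 converged = x$converged, n_records = x$n,
                 n_fixed = x$n_fixed, n_components = nrow(x$components))
}

component_value <- function(fit, term, t1, t2 = t1) {
  cmp <- fit$components
  hit <- cmp$term == term &
    ((cmp$trait_1 == t1 & cmp$trait_2 == t2) |
       (cmp$trait_1 == t2 & cmp$trait_2 == t1))
  if (!any(hit)) return(NULL)
  cmp[hit, , drop = FALSE][1, ]
}

#' Genomic correlation from a bi-variate fit
#'
#' The correlation between the marker-captured genetic effects of the same
#' phenotype in the two populations:
#' `r_G = sigma_u12 / sqrt(sigma_u1^2 * sigma_u2^2)`, taken from the
#' unstructured trait block of the genomic random term. Guaranteed to lie in
#' `[-1, 1]` by the positive-semidefiniteness constraint on the block.
#'
#' @param fit A bi-variate [reml_fit()].
#' @param term Name of the genomic random term.
#' @return The correlation, or `NA` (with a warning) when either genomic
#'   variance sits at the variance floor, in which case the correlation is
#'   undefined.
#' @export
genomic_correlation <- function(fit, term = "genomic") {
  tr <- fit$traits
  if (length(tr) != 2) stop_config("genomic_correlation needs a bi-variate fit.")
  v1 <- component_value(fit, term, tr[1])
  v2 <- component_value(fit, term, tr[2])
  cv <- component_value(fit, term, tr[1], tr[2])
  if (is.null(v1) || is.null(v2) || is.null(cv)) {
    stop_config("term `", term, "` has no unstructured trait block.")
  }
  if (v1$at_floor || v2$at_floor) {
    warning("genomic correlation undefined: a genomic variance is at the floor.")
    return(NA_real_)
  }
  as.numeric(cv$estimate / sqrt(v1$estimate * v2$estimate))
}

#' Fraction of missing heritability
#'
#' The fraction of additive genetic variance not captured by the SNPs used to
#' build the genomic matrix: `C_miss = 1 - sigma_u^2 / (sigma_u^2 +
#' sigma_a^2)`, where `sigma_a^2` is the pedigree-based and `sigma_u^2` the
#' marker-based genetic variance for the given trait (breed). Equivalently
#' `h2_P / (h2_P + h2_G)` on the proportion scale.
#'
#' @param fit A [reml_fit()] with a pedigree and a genomic term.
#' @param trait Trait (breed) label; defaults to the first trait.
#' @param pedigree_term,genomic_term Term names.
#' @return A proportion in `[0, 1]`, or `NA` when both variances are at the
#'   floor (undefined).
#' @export
missing_heritability <- function(fit, trait = fit$traits[1],
                                 pedigree_term = "pedigree",
                                 genomic_term = "genomic") {
  va <- component_value(fit, pedigree_term, trait)
  vu <- component_value(fit, genomic_term, trait)
  if (is.null(va) || is.null(vu)) stop_config("terms not found in fit.")
  if (va$at_floor && vu$at_floor) {
    warning("missing heritability undefined: both genetic variances at floor.")
    return(NA_real_)
  }
  as.numeric(1 - vu$estimate / (vu$estimate + va$estimate))
}

#' Per-breed heritability partition and genomic correlation
#'
#' Summarises a bi-variate pedigree + genomic fit the way multi-breed REML
#' tables are usually reported: per trait (breed) the proportion of
#' phenotypic variance explained by the pedigree term
#' (`h2_p = sigma_a^2 / (sigma_a^2 + sigma_u^2 + sigma_e^2)`), by the genomic
#' term (`h2_g`), the missing-heritability fraction `c_miss` and, repeated on
#' each row, the across-breed genomic correlation `r_g`.
#'
#' @inheritParams missing_heritability
#' @return Tibble with one row per trait: `trait`, `h2_p`, `h2_g`, `c_miss`,
#'   `r_g` (`NA` for univariate fits).
#' @export
parameter_summary <- function(fit, pedigree_term = "pedigree",
                              genomic_term = "genomic") {
  rg <- if (length(fit$traits) == 2 &&
            !is.null(component_value(fit, genomic_term,
                                     fit$traits[1], fit$traits[2]))) {
    suppressWarnings(genomic_correlation(fit, genomic_term))
  } else {
    NA_real_
  }
  purrr::map_dfr(fit$traits, function(tr) {
    va <- component_value(fit, pedigree_term, tr)$estimate
    vu <- component_value(fit, genomic_term, tr)$estimate
    ve <- component_value(fit, "residual", tr)$estimate
    tot <- va + vu + ve
    tibble::tibble(trait = tr, h2_p = va / tot, h2_g = vu / tot,
                   c_miss = missing_heritability(fit, tr, pedigree_term,
                                                 genomic_term),
                   r_g = rg)
  })
}

#' Restricted log-likelihood trace plot
#' @param object A [reml_fit()].
#' @param ... Unused.
#' @return A ggplot of the restricted log-likelihood across iterations.
#' @method autoplot reml_fit
#' @export
autoplot.reml_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik_trace),
                       loglik = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "restricted log-likelihood")
}
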