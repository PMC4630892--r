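# Independent oracles used to cross-check the implementation. These are
# deliberately naive and share no code with the package internals.

# Exhaustive pairwise additive-relationship recursion (Wright/tabular
# definition applied pair by pair with memoisation). Pedigree rows must list
# parents before offspring; unknown parents are NA.
naive_nrm <- function(ped) {
  n <- nrow(ped)
  pos <- setNames(seq_len(n), ped$animal)
  sire <- ped$sire
  dam <- ped$dam
  memo <- new.env(hash = TRUE)
  rel <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    key <- paste(min(i, j), max(i, j))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      s <- parent_idx(i, sire); d <- parent_idx(i, dam)
      1 + 0.5 * rel(s, d)
    } else {
      # recurse on the younger (later-positioned) animal
      if (i < j) { a <- i; b <- j } else { a <- j; b <- i }
      s <- parent_idx(b, sire); d <- parent_idx(b, dam)
      0.5 * (rel(a, s) + rel(a, d))
    }
    memo[[key]] <- val
    val
  }
  parent_idx <- function(i, par) {
    p <- par[i]
    if (is.na(p)) 0 else pos[[p]]
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- rel(i, j)
  }
  A
}

# random valid pedigree: parents always precede offspring
random_pedigree <- function(n, p_known = 0.7) {
  animal <- sprintf("a%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    if (runif(1) < p_known) {
      pick <- sample(i - 1L, 2L)
      sire[i] <- animal[pick[1]]
      dam[i] <- animal[pick[2]]
    }
  }
  tibble::tibble(animal = animal, sire = sire, dam = dam)
}

# Exact univariate restricted log-likelihood profile on a heritability grid.
# Model: y = X b + u + e, var(u) = s2 * h2 * K, var(e) = s2 * (1 - h2);
# the total variance s2 is profiled out analytically. Works in the
# eigenbasis of K so each grid point costs O(n^2).
grid_reml_univariate <- function(y, X, K, grid = seq(0.0, 0.99, by = 0.01)) {
  n <- length(y)
  p <- qr(X)$rank
  ev <- eigen(K, symmetric = TRUE)
  U <- ev$vectors
  d <- ev$values
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  ll <- vapply(grid, function(h2) {
    v0 <- h2 * d + (1 - h2)
    if (any(v0 <= 0)) return(-Inf)
    XtV <- Xt / v0
    XtVX <- crossprod(Xt, XtV)
    bh <- solve(XtVX, crossprod(XtV, yt))
    r <- yt - Xt %*% bh
    ypy <- sum(r^2 / v0)
    s2 <- ypy / (n - p)
    -0.5 * (sum(log(v0)) + determinant(XtVX)$modulus[1] +
              (n - p) * log(s2) + (n - p))
  }, numeric(1))
  list(h2 = grid[which.max(ll)], loglik = ll, grid = grid)
}

expect_nondecreasing_trace <- function(fit, tol = 1e-7) {
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -tol * (1 + abs(tr[-length(tr)]))))
}
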