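#' Relationship matrices
#'
#' `relationship_matrix` objects are symmetric animal-by-animal matrices with
#' a `kind` tag (`"pedigree"` or `"genomic"`), the identity-blend factor used
#' (genomic kind) and a provenance record (SNP list or pedigree depth).
#'
#' @param mat Symmetric numeric matrix with animal ids as dimnames.
#' @param kind `"pedigree"` or `"genomic"`.
#' @param blend Identity blend weight used (genomic kind), else `NA`.
#' @param provenance Free-form list describing how the matrix was built.
#' @return The matrix with class `relationship_matrix` and metadata attributes.
#' @keywords internal
new_relationship_matrix <- function(mat, kind, blend = NA_real_,
                                    provenance = list()) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat),
            !is.null(rownames(mat)), kind %in% c("pedigree", "genomic"))
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat)))) {
    stop_numeric("relationship matrix is not symmetric to tolerance.")
  }
  structure((mat + t(mat)) / 2, kind = kind, blend = blend,
            provenance = provenance,
            class = c("relationship_matrix", class(mat)))
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("<relationship_matrix> kind:", attr(x, "kind"), "-", nrow(x), "animals")
  if (!is.na(attr(x, "blend"))) cat(", blend", attr(x, "blend"))
  prov <- attr(x, "provenance")
  if (!is.null(prov$label)) cat(", ", prov$label, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
`[.relationship_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out) && nrow(out) == ncol(out) &&
      identical(rownames(out), colnames(out))) {
    return(structure(out, kind = attr(x, "kind"), blend = attr(x, "blend"),
                     provenance = attr(x, "provenance"),
                     class = class(x)))
  }
  out
}

#' Pedigree-based numerator relationship matrix
#'
#' Computes additive relationships by the tabular method:
#' `a_ij = (a_j,sire(i) + a_j,dam(i)) / 2` with diagonal
#' `1 + a_sire,dam / 2`, processing animals in topological order. Ancestors
#' further than `max_ancestor_generations` generations above the target
#' animals are treated as unknown founders, i.e. the recursion uses a
#' truncated pedigree. Animals in disconnected pedigree components (for
#' example, two breeds without common ancestors) have relationship exactly
#' zero.
#'
#' @param pedigree Data frame with columns `animal`, `sire`, `dam`; unknown
#'   parents are `NA`, `""` or `"0"`. Extra columns are ignored.
#' @param max_ancestor_generations Ancestor truncation depth (>= 1).
#' @param ids Animals to return the matrix for (default: every animal in the
#'   pedigree). Ancestors are used in the recursion up to the truncation
#'   depth even when not part of `ids`.
#' @return A `relationship_matrix` of kind `"pedigree"` over `ids`.
#' @export
#' @examples
#' ped <- tibble::tibble(animal = c("S", "D", "O"),
#'                       sire = c(NA, NA, "S"), dam = c(NA, NA, "D"))
#' build_nrm(ped)["S", "O"] # 0.5
build_nrm <- function(pedigree, max_ancestor_generations = 3, ids = NULL) {
  max_ancestor_generations <- check_count(max_ancestor_generations,
                                          "max_ancestor_generations")
  ped <- normalise_pedigree(pedigree)
  ids <- ids %||% ped$animal
  missing_ids <- setdiff(ids, ped$animal)
  if (length(missing_ids) > 0) {
    stop_structure("animals not in the pedigree: ",
                   paste(utils::head(missing_ids, 5), collapse = ", "))
  }

  ped <- truncate_pedigree(ped, ids, max_ancestor_generations)
  ord <- pedigree_topological_order(ped)

  n <- nrow(ped)
  sire_idx <- match(ped$sire, ped$animal)
  dam_idx <- match(ped$dam, ped$animal)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in ord) {
    s <- sire_idx[i]; d <- dam_idx[i]
    before <- ord[seq_len(match(i, ord) - 1L)]
    rel <- numeric(length(before))
    if (!is.na(s)) rel <- rel + A[before, s] / 2
    if (!is.na(d)) rel <- rel + A[before, d] / 2
    A[before, i] <- rel
    A[i, before] <- rel
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  new_relationship_matrix(A[ids, ids, drop = FALSE], kind = "pedigree",
                          provenance = list(label = "pedigree NRM",
                                            depth = max_ancestor_generations))
}

normalise_pedigree <- function(pedigree) {
  req <- c("animal", "sire", "dam")
  if (!all(req %in% names(pedigree))) {
    stop_structure("pedigree needs columns `animal`, `sire`, `dam`.")
  }
  ped <- tibble::as_tibble(pedigree[req])
  ped$sire <- clean_parent(ped$sire)
  ped$dam <- clean_parent(ped$dam)
  if (anyDuplicated(ped$animal)) {
    stop_structure("duplicated animal ids in pedigree.")
  }
  for (col in c("sire", "dam")) {
    bad <- setdiff(stats::na.omit(ped[[col]]), ped$animal)
    if (length(bad) > 0) {
      stop_structure("unknown id referenced as ", col, ": ",
                     paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  ped
}

clean_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("", "0", "NA")] <- NA_character_
  x
}

# Kahn topological sort (parents before offspring); errors on cycles
pedigree_topological_order <- function(ped) {
  n <- nrow(ped)
  sire_idx <- match(ped$sire, ped$animal)
  dam_idx <- match(ped$dam, ped$animal)
  indeg <- (!is.na(sire_idx)) + (!is.na(dam_idx))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_idx[i], dam_idx[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != n) {
    stop_structure("pedigree contains a cycle (an animal is its own ancestor).")
  }
  ord
}

# keep ids plus ancestors up to `depth` generations; parents of animals at
# the truncation boundary become unknown founders
truncate_pedigree <- function(ped, ids, depth) {
  keep_depth <- stats::setNames(rep(Inf, nrow(ped)), ped$animal)
  keep_depth[ids] <- 0
  frontier <- ids
  d <- 0
  while (length(frontier) > 0 && d < depth) {
    rows <- ped[match(frontier, ped$animal), ]
    parents <- unique(stats::na.omit(c(rows$sire, rows$dam)))
    d <- d + 1
    newly <- parents[keep_depth[parents] > d]
    keep_depth[newly] <- d
    frontier <- newly
  }
  keep <- is.finite(keep_depth)
  out <- ped[keep, ]
  boundary <- names(keep_depth)[keep_depth == depth]
  cut <- out$animal %in% boundary
  out$sire[cut] <- NA_character_
  out$dam[cut] <- NA_character_
  # also drop references to pruned parents (possible when depth splits a family)
  out$sire[!is.na(out$sire) & !(out$sire %in% out$animal)] <- NA_character_
  out$dam[!is.na(out$dam) & !(out$dam %in% out$animal)] <- NA_character_
  out
}

#' Allele frequencies of the second allele
#'
#' `p_i = mean(code) / 2` over the non-missing genotype codes of the chosen
#' animal subset. With the default subset (all animals) and a combined
#' two-breed matrix, these are across-breed frequencies; frequencies over the
#' combined set equal the call-count-weighted mean of within-breed
#' frequencies.
#'
#' @param genotypes Genotype matrix (animals x SNPs, codes 0/1/2, `NA`
#'   missing).
#' @param animals Optional animal ids (or logical/integer row index) defining
#'   the subset.
#' @return Tibble with `snp_id`, `p`, `n_called` and `monomorphic`
#'   (`TRUE` when `p` is 0 or 1; `NA` when no calls at all, in which case the
#'   frequency is undefined).
#' @export
allele_frequencies <- function(genotypes, animals = NULL) {
  x <- genotypes
  if (!is.null(animals)) x <- x[animals, , drop = FALSE]
  if (nrow(x) == 0) stop_config("empty animal subset.")
  n_called <- colSums(!is.na(x))
  p <- ifelse(n_called > 0, colMeans(x, na.rm = TRUE) / 2, NA_real_)
  tibble::tibble(
    snp_id = colnames(x) %||% as.character(seq_len(ncol(x))),
    p = as.numeric(p),
    n_called = as.integer(n_called),
    monomorphic = ifelse(n_called > 0, p == 0 | p == 1, NA)
  )
}

#' Blended genomic relationship matrix
#'
#' VanRaden's marker-based relationship matrix with an identity blend that
#' guarantees invertibility:
#' \deqn{G = b \frac{S S^\top}{2 \sum_i p_i (1 - p_i)} + (1 - b) I,}
#' where `S` is the genotype matrix column-centred by `2 p_i`, `p_i` is the
#' frequency of the second allele (by default computed from all animals in
#' `genotypes`, i.e. the across-breed set) and `b` is the blend weight
#' (default 0.95). SNPs that are monomorphic at the supplied frequencies (or
#' have undefined frequency) are dropped before construction; missing
#' genotypes are mean-imputed, i.e. contribute zero after centring. The
#' smallest eigenvalue of the result is at least `1 - b` up to round-off.
#'
#' @param genotypes Genotype matrix (animals x SNPs, codes 0/1/2).
#' @param snps Optional SNP ids (or column index) restricting the panel, e.g.
#'   a selected SNP list.
#' @param freqs Optional frequencies: a tibble from [allele_frequencies()] or
#'   a numeric vector named by SNP id. Default: across-breed frequencies
#'   computed from `genotypes` itself.
#' @param blend Blend weight in `(0, 1]`; `blend = 1` is the raw VanRaden
#'   matrix.
#' @param animals Optional animal subset (rows) for the output matrix.
#' @param label Provenance label stored on the result.
#' @return A `relationship_matrix` of kind `"genomic"`.
#' @export
#' @examples
#' g <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' build_grm(g, blend = 0.95)
build_grm <- function(genotypes, snps = NULL, freqs = NULL, blend = 0.95,
                      animals = NULL, label = NULL) {
  blend <- check_proportion(blend, "blend", 0, 1, lo_open = TRUE)
  x <- genotypes
  if (!is.null(snps)) x <- x[, snps, drop = FALSE]
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))

  if (is.null(freqs)) {
    freqs <- allele_frequencies(genotypes)
  }
  if (is.data.frame(freqs)) {
    p <- stats::setNames(freqs$p, freqs$snp_id)[colnames(x)]
  } else {
    p <- freqs[colnames(x)]
  }
  if (anyNA(names(p)) || length(p) != ncol(x)) {
    stop_config("`freqs` does not cover the requested SNP subset.")
  }

  keep <- !is.na(p) & p > 0 & p < 1
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("build_grm: dropping ", n_dropped,
            " monomorphic/undefined-frequency SNP(s).")
  }
  if (!any(keep)) {
    stop_config("all SNPs in the subset are monomorphic; GRM undefined.")
  }
  x <- x[, keep, drop = FALSE]
  p <- p[keep]

  if (!is.null(animals)) x <- x[animals, , drop = FALSE]
  ids <- rownames(x)
  if (is.null(ids)) stop_structure("genotype matrix must have animal rownames.")

  s <- sweep(unclass(x) * 1.0, 2, 2 * p, "-")
  s[is.na(s)] <- 0  # mean imputation: centred contribution zero
  denom <- 2 * sum(p * (1 - p))
  ghat <- tcrossprod(s) / denom
  g <- blend * ghat
  diag(g) <- diag(g) + (1 - blend)
  dimnames(g) <- list(ids, ids)
  new_relationship_matrix(
    g, kind = "genomic", blend = blend,
    provenance = list(label = label %||% "genomic GRM",
                      n_snps = ncol(x), n_dropped = n_dropped,
                      snp_ids = colnames(x))
  )
}

#' Within- and between-breed relationship distributions
#'
#' Summarises the off-diagonal coefficients of a relationship matrix by breed
#' block (e.g. BBxBB, BBxTC, TCxTC). For a pedigree matrix over two
#' disconnected breeds the between-breed block is identically zero; a genomic
#' matrix built with across-breed allele frequencies shows non-zero spread
#' there, which is what makes the cross-breed genomic covariance estimable.
#'
#' @param matrix A `relationship_matrix` (or plain symmetric matrix with
#'   dimnames).
#' @param breeds Breed labels: a vector named by animal id, or a data frame
#'   with columns `animal` and `breed`, covering all animals in the matrix.
#' @param probs Quantiles reported per block.
#' @param keep_values Retain the raw off-diagonal values (possibly
#'   downsampled to `max_values`) for plotting.
#' @param max_values Cap on retained values per block.
#' @return A `relationship_summary`: list with `blocks` (per-block n, mean,
#'   sd, min, max and quantiles), optional `values`, and the matrix `kind`.
#' @export
relationship_summary <- function(matrix, breeds,
                                 probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                 keep_values = TRUE, max_values = 50000) {
  if (is.data.frame(breeds)) {
    breeds <- stats::setNames(breeds$breed, breeds$animal)
  }
  ids <- rownames(matrix)
  if (!all(ids %in% names(breeds))) {
    stop_config("`breeds` does not label every animal in the matrix.")
  }
  lab <- breeds[ids]
  lev <- sort(unique(lab))
  blocks <- list(); values <- list()
  for (i in seq_along(lev)) {
    for (j in i:length(lev)) {
      ri <- which(lab == lev[i]); rj <- which(lab == lev[j])
      if (i == j) {
        if (length(ri) < 2) next
        sub <- matrix[ri, ri, drop = FALSE]
        v <- sub[upper.tri(sub)]
      } else {
        v <- as.numeric(matrix[ri, rj, drop = FALSE])
      }
      name <- paste(lev[i], lev[j], sep = "x")
      qs <- stats::quantile(v, probs = probs, names = FALSE)
      blocks[[name]] <- tibble::tibble(
        block = name, n_pairs = length(v), mean = mean(v),
        sd = stats::sd(v), min = min(v), max = max(v),
        !!!stats::setNames(as.list(qs), paste0("q", probs * 100))
      )
      if (keep_values) {
        if (length(v) > max_values) v <- v[seq(1, length(v), length.out = max_values)]
        values[[name]] <- tibble::tibble(block = name, value = v)
      }
    }
  }
  structure(list(blocks = dplyr::bind_rows(blocks),
                 values = if (keep_values) dplyr::bind_rows(values) else NULL,
                 kind = attr(matrix, "kind") %||% "unknown"),
            class = "relationship_summary")
}

#' @export
print.relationship_summary <- function(x, ...) {
  cat("<relationship_summary> kind:", x$kind, "\n")
  print(x$blocks)
  invisible(x)
}
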