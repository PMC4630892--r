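#' Select the most significant sign-consistent (or discordant) SNPs
#'
#' Compares per-SNP effect estimates for one trait between two populations
#' and returns the top fraction of the panel among SNPs whose effect signs
#' agree (`direction = "same"`, a proxy for consistent linkage-disequilibrium
#' phase) or disagree (`direction = "different"`). The quota is taken on the
#' full panel size -- e.g. 10 % of a 71,726-SNP panel is 7,173 SNPs per trait
#' -- and is filled from the sign-qualifying SNPs ranked by combined
#' significance. If fewer SNPs qualify than the quota, all qualifying SNPs
#' are returned with a warning.
#'
#' The default joint ranking is the sum of `-log10(p)` across the two
#' populations; `"minp"`/`"maxp"` rank by the more/less significant of the
#' two, and `"fisher"` by the Fisher combination (order-equivalent to
#' `"sumlog"`). Ties break deterministically by the summed absolute test
#' statistic, then marker id. SNPs with an exactly zero effect in either
#' population have no defined sign and are excluded from both directions, as
#' are rows flagged `excluded`.
#'
#' @param gwas_a,gwas_b `gwas_table`s for the same trait over the same marker
#'   panel in the two populations.
#' @param fraction Fraction of the panel to select (default 0.10).
#' @param direction `"same"` or `"different"`.
#' @param rank_method Joint significance ranking.
#' @return Character vector of selected marker ids, with attributes
#'   `n_quota` and `n_qualifying`.
#' @export
select_snps <- function(gwas_a, gwas_b, fraction = 0.10,
                        direction = c("same", "different"),
                        rank_method = c("sumlog", "minp", "maxp", "fisher")) {
  direction <- match.arg(direction)
  rank_method <- match.arg(rank_method)
  fraction <- check_proportion(fraction, "fraction", 0, 1, lo_open = TRUE)
  if (!setequal(gwas_a$snp_id, gwas_b$snp_id)) {
    stop_config("the two scans do not cover the same marker panel.")
  }
  panel_size <- length(unique(gwas_a$snp_id))
  quota <- ceiling(fraction * panel_size)

  ab <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(gwas_a), "snp_id", effect_a = "effect",
                  p_a = "p_value", stat_a = "statistic", excl_a = "excluded"),
    dplyr::select(tibble::as_tibble(gwas_b), "snp_id", effect_b = "effect",
                  p_b = "p_value", stat_b = "statistic", excl_b = "excluded"),
    by = "snp_id")
  ab <- ab[!ab$excl_a & !ab$excl_b &
             ab$effect_a != 0 & ab$effect_b != 0, , drop = FALSE]
  sgn <- sign(ab$effect_a) * sign(ab$effect_b)
  qual <- ab[if (direction == "same") sgn > 0 else sgn < 0, , drop = FALSE]

  score <- switch(rank_method,
    sumlog = -log10(qual$p_a) - log10(qual$p_b),
    minp = -log10(pmin(qual$p_a, qual$p_b)),
    maxp = -log10(pmax(qual$p_a, qual$p_b)),
    fisher = -2 * (log(qual$p_a) + log(qual$p_b))
  )
  tie <- abs(qual$stat_a) + abs(qual$stat_b)
  ord <- order(-score, -tie, qual$snp_id)
  if (nrow(qual) < quota) {
    warning("select_snps: only ", nrow(qual), " sign-qualifying SNPs for a ",
            "quota of ", quota, "; returning all of them.")
  }
  picked <- qual$snp_id[ord][seq_len(min(quota, nrow(qual)))]
  structure(picked, n_quota = quota, n_qualifying = nrow(qual))
}

#' Merge per-trait selections into de-overlapped SNP lists
#'
#' Takes the per-trait sign-consistent ("same") and sign-discordant
#' ("different") selections, unions each direction across traits, and removes
#' every marker present in both unions, yielding two disjoint lists (the
#' "list-of-same" and "list-of-different"). The trait-count summary reports
#' what fraction of each final list was contributed by 1, 2, ... traits.
#'
#' @param same,different Lists (one element per trait, possibly named) of
#'   marker-id vectors from [select_snps()].
#' @return An object of class `snp_lists`: `list_of_same`,
#'   `list_of_different` (character vectors), `trait_counts` (tibble:
#'   `direction`, `n_traits`, `n_snps`, `fraction`) and `membership` (tibble:
#'   `direction`, `trait`, `snp_id`).
#' @export
merge_snp_lists <- function(same, different) {
  as_sets <- function(x, direction) {
    if (is.character(x)) x <- list(x)
    if (is.null(names(x)) || any(names(x) == "")) {
      names(x) <- paste0("trait", seq_along(x))
    }
    purrr::imap_dfr(x, function(ids, tr) {
      tibble::tibble(direction = direction, trait = tr,
                     snp_id = as.character(ids))
    })
  }
  membership <- dplyr::bind_rows(as_sets(same, "same"),
                                 as_sets(different, "different"))
  union_same <- unique(membership$snp_id[membership$direction == "same"])
  union_diff <- unique(membership$snp_id[membership$direction == "different"])
  overlap <- intersect(union_same, union_diff)
  list_of_same <- setdiff(union_same, overlap)
  list_of_different <- setdiff(union_diff, overlap)

  counts <- membership |>
    dplyr::distinct(.data$direction, .data$trait, .data$snp_id) |>
    dplyr::count(.data$direction, .data$snp_id, name = "n_traits") |>
    dplyr::filter((.data$direction == "same" & .data$snp_id %in% list_of_same) |
                    (.data$direction == "different" &
                       .data$snp_id %in% list_of_different)) |>
    dplyr::count(.data$direction, .data$n_traits, name = "n_snps") |>
    dplyr::group_by(.data$direction) |>
    dplyr::mutate(fraction = .data$n_snps / sum(.data$n_snps)) |>
    dplyr::ungroup()

  structure(list(list_of_same = list_of_same,
                 list_of_different = list_of_different,
                 trait_counts = counts,
                 membership = membership,
                 n_overlap_removed = length(overlap)),
            class = "snp_lists")
}

#' @export
print.snp_lists <- function(x, ...) {
  cat("<snp_lists> list-of-same:", length(x$list_of_same),
      "SNPs; list-of-different:", length(x$list_of_different),
      "SNPs (", x$n_overlap_removed, "overlapping removed )\n")
  invisible(x)
}

#' Build the selected-SNP genomic relationship matrices
#'
#' Materialises `G_S` (from the list-of-same) and `G_D` (from the
#' list-of-different) by delegating to [build_grm()] with across-breed allele
#' frequencies restricted to each list. Provenance on each matrix records
#' the list identity and size.
#'
#' @param genotypes Genotype matrix over all animals.
#' @param lists An [merge_snp_lists()] result.
#' @param blend,freqs,animals Passed to [build_grm()].
#' @return List with elements `G_S` and `G_D`.
#' @export
build_variant_grms <- function(genotypes, lists, blend = 0.95, freqs = NULL,
                               animals = NULL) {
  stopifnot(inherits(lists, "snp_lists"))
  one <- function(ids, label) {
    if (length(ids) == 0) {
      stop_config("SNP list `", label, "` is empty; no GRM can be built.")
    }
    tryCatch(
      build_grm(genotypes, snps = ids, freqs = freqs, blend = blend,
                animals = animals,
                label = paste0(label, " (", length(ids), " SNPs)")),
      gencor_config_error = function(e) {
        stop_config("SNP list `", label, "`: ", conditionMessage(e))
      })
  }
  list(G_S = one(lists$list_of_same, "list-of-same"),
       G_D = one(lists$list_of_different, "list-of-different"))
}
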