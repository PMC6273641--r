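#' Module count required for a backbone of given length
#'
#' Each module — the loading module included — contributes a C2 unit to the
#' polyketide backbone, so a backbone of 2k carbons requires k modules.
#'
#' @param backbone_carbons Even integer >= 2.
#' @return Required total module count (loading + extensions).
#' @examples
#' required_modules(28)  # 14
#' @export
required_modules <- function(backbone_carbons) {
  if (backbone_carbons < 2 || backbone_carbons %% 2 != 0) {
    abort("backbone_carbons must be an even integer >= 2 (C2-unit arithmetic)")
  }
  as.integer(backbone_carbons / 2)
}

#' Rank candidate PKS clusters against a target compound
#'
#' Scores each candidate by the absolute difference between its module count
#' and the count required by the compound's backbone length. Open-ended
#' counts (cluster truncated by a scaffold end, so the count is only a lower
#' bound) are scored at the bound plus a small penalty. When AT-compatibility
#' fractions are available they break score ties (higher is better);
#' remaining ties break deterministically by `cluster_id`.
#'
#' @param candidates Tibble with `cluster_id`, `module_count`, optional
#'   logical `open_ended`, optional `at_compatibility` in `[0, 1]`.
#' @param spec A [compound_spec()] with `backbone_carbons` set.
#' @param open_ended_penalty Score penalty for open-ended counts
#'   (default 0.5).
#' @return The candidates, with `required`, `score` and `rank`, ordered best
#'   first.
#' @export
rank_clusters <- function(candidates, spec, open_ended_penalty = 0.5) {
  if (nrow(candidates) == 0) {
    return(mutate(candidates, required = integer(), score = double(),
                  rank = integer()))
  }
  if (is.null(spec$backbone_carbons)) {
    abort("compound spec must include backbone_carbons for cluster ranking")
  }
  req <- required_modules(spec$backbone_carbons)
  if (!"open_ended" %in% names(candidates)) candidates$open_ended <- FALSE
  if (!"at_compatibility" %in% names(candidates)) {
    candidates$at_compatibility <- NA_real_
  }
  candidates |>
    mutate(
      cluster_id = as.character(.data$cluster_id),
      required = req,
      score = abs(.data$module_count - req) +
        open_ended_penalty * as.numeric(.data$open_ended)
    ) |>
    arrange(.data$score, desc(dplyr::coalesce(.data$at_compatibility, -Inf)),
            .data$cluster_id) |>
    mutate(rank = row_number())
}
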