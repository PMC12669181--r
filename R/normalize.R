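#' Normalize activation to percent of group mean
#'
#' Replaces every regional value by `(individual value / group mean) * 100`,
#' computed per region within each group, so that each group's mean per
#' region is exactly 100. This is the standard normalization for comparing
#' c-Fos cell counts across animals and groups, and it is idempotent: values
#' already on the percent-of-group-mean scale are unchanged.
#'
#' @param table An activation table: columns `animal_id`, `group`, then one
#'   numeric column per region.
#' @param id_cols Non-region columns; default `animal_id` and `group`.
#' @return A tibble of the same shape on the percent scale.
#' @examples
#' tab <- tibble::tibble(animal_id = letters[1:3], group = "g", R1 = c(2, 4, 6))
#' normalize_activation(tab)$R1 # 33.33, 66.67, 100 * 6/4
#' @export
normalize_activation <- function(table, id_cols = c("animal_id", "group")) {
  regions <- region_columns(table, id_cols)
  if (length(regions) == 0L) abort("no region columns found.")
  grouped <- dplyr::group_by(table, .data$group)
  means <- dplyr::summarise(
    grouped,
    dplyr::across(dplyr::all_of(regions), ~ mean(.x)),
    .groups = "drop"
  )
  bad <- means |>
    tidyr::pivot_longer(dplyr::all_of(regions),
      names_to = "region", values_to = "mean"
    ) |>
    dplyr::filter(is.na(.data$mean) | .data$mean <= 0)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "non-positive group mean for region %s in group %s: cannot normalize.",
      bad$region[1], bad$group[1]
    ))
  }
  grouped |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(regions), ~ .x / mean(.x) * 100
    )) |>
    dplyr::ungroup()
}
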