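#' Per-trial discrimination index (D1)
#'
#' `D1 = (t_novel - t_familiar) / (t_novel + t_familiar)`, the standard
#' novel-object-recognition discrimination ratio in `[-1, 1]`. A trial in
#' which the animal explored neither object has an undefined index and
#' returns `NA` (with a message) rather than a silent 0, so that
#' zero-exploration animals cannot bias inclusion decisions downstream.
#'
#' @param t_novel,t_familiar Non-negative exploration times (seconds);
#'   vectorized.
#' @return Numeric vector of D1 values in `[-1, 1]`, `NA` where both times
#'   are zero.
#' @examples
#' d1_index(30, 10) # 0.5
#' @export
d1_index <- function(t_novel, t_familiar) {
  if (any(t_novel < 0, na.rm = TRUE) || any(t_familiar < 0, na.rm = TRUE)) {
    abort("exploration times must be non-negative.")
  }
  total <- t_novel + t_familiar
  out <- ifelse(total > 0, (t_novel - t_familiar) / total, NA_real_)
  if (anyNA(out[!is.na(total)]) && any(total == 0, na.rm = TRUE)) {
    inform(sprintf(
      "%d trial(s) with zero total exploration: D1 set to NA.",
      sum(total == 0, na.rm = TRUE)
    ))
  }
  out
}

#' Cumulative discrimination index (D2) over trials
#'
#' Applies the D1 formula to exploration times summed across trials, giving
#' one cumulative index per trial and animal:
#' `D2_k = (sum tNO_1..k - sum tFO_1..k) / (sum tNO_1..k + sum tFO_1..k)`.
#' The value at the final trial is the animal's inclusion statistic. With a
#' single trial D2 equals D1.
#'
#' @param trials A data frame with columns `animal_id`, `trial`, `t_novel`,
#'   `t_familiar`. Rows are ordered by `trial` within animal internally.
#' @return The input tibble, sorted by animal and trial, with an added `d2`
#'   column (`NA` where the cumulative total exploration is zero).
#' @examples
#' tr <- tibble::tibble(animal_id = "a", trial = 1:2,
#'                      t_novel = c(30, 10), t_familiar = c(10, 30))
#' cumulative_d2(tr)$d2 # 0.5, 0.0
#' @export
cumulative_d2 <- function(trials) {
  need <- c("animal_id", "trial", "t_novel", "t_familiar")
  if (!all(need %in% names(trials))) {
    abort(paste0("`trials` must have columns ", paste(need, collapse = ", "), "."))
  }
  if (nrow(trials) == 0L) abort("`trials` is empty.")
  if (any(trials$t_novel < 0) || any(trials$t_familiar < 0)) {
    abort("exploration times must be non-negative.")
  }
  trials |>
    dplyr::arrange(.data$animal_id, .data$trial) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(
      d2 = {
        num <- cumsum(.data$t_novel) - cumsum(.data$t_familiar)
        den <- cumsum(.data$t_novel) + cumsum(.data$t_familiar)
        ifelse(den > 0, num / den, NA_real_)
      }
    ) |>
    dplyr::ungroup()
}

#' Final D2 and above-chance inclusion per animal
#'
#' Summarizes [cumulative_d2()] to one row per animal: the final cumulative
#' index and the inclusion flag `d2_final > 0` (strictly above chance).
#' Animals whose final D2 is undefined (no exploration at all) are excluded
#' and reported.
#'
#' @inheritParams cumulative_d2
#' @return A tibble with columns `animal_id`, `d2_final`, `include`.
#' @export
d2_inclusion <- function(trials) {
  traj <- cumulative_d2(trials)
  out <- traj |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(d2_final = dplyr::last(.data$d2), .groups = "drop") |>
    dplyr::mutate(include = include_by_chance(.data$d2_final))
  out
}

#' Above-chance inclusion rule for the final D2
#'
#' An animal is included when its final cumulative discrimination index is
#' strictly greater than the chance value 0. Missing values (animals that
#' never explored) are excluded with a message.
#'
#' @param final_d2 Numeric vector of final D2 values.
#' @return Logical vector.
#' @export
include_by_chance <- function(final_d2) {
  if (anyNA(final_d2)) {
    inform(sprintf(
      "%d animal(s) with undefined D2 excluded.", sum(is.na(final_d2))
    ))
  }
  !is.na(final_d2) & final_d2 > 0
}

#' One-sample t test against chance
#'
#' Tests whether discrimination indices differ from the chance value 0
#' (two-tailed one-sample t test). Degenerate samples (fewer than two
#' values, or zero variance, where t is undefined) raise an error.
#'
#' @param values Numeric vector (e.g. per-animal final D2).
#' @param mu Chance value; default 0.
#' @return A one-row tibble: `estimate`, `statistic`, `df`, `p.value`,
#'   `conf.low`, `conf.high`.
#' @export
chance_test <- function(values, mu = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) abort("need at least 2 non-missing values.")
  if (sd(values) == 0) abort("zero variance: t statistic undefined.")
  tt <- stats::t.test(values, mu = mu)
  tibble::tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2]
  )
}
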