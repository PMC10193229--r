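#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x A `uev_de` object from [nb_glm_de()].
#' @param ... Unused.
#' @return A plain tibble, one row per gene, ordered by p-value.
#' @method tidy uev_de
#' @export
tidy.uev_de <- function(x, ...) {
  as_tibble(x) |> dplyr::arrange(.data$p_value)
}

#' @rdname tidy.uev_de
#' @return For `glance()`: a one-row tibble with the test-wide summary
#'   (contrast, group sizes, genes tested, Bonferroni threshold,
#'   significant calls).
#' @method glance uev_de
#' @export
glance.uev_de <- function(x, ...) {
  tibble(
    contrast = attr(x, "contrast"),
    n_case = attr(x, "n_case"),
    n_control = attr(x, "n_control"),
    n_tested = attr(x, "n_tested"),
    alpha = attr(x, "alpha"),
    threshold = attr(x, "threshold"),
    n_significant = sum(x$significant, na.rm = TRUE)
  )
}

#' Tidy per-group eGFR slopes
#'
#' @param x A `uev_slopes` object from [group_slope()].
#' @param per_person Return the per-person slopes instead of the group
#'   slopes? Default `FALSE`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy uev_slopes
#' @export
tidy.uev_slopes <- function(x, per_person = FALSE, ...) {
  if (per_person) attr(x, "per_person") else as_tibble(x)
}

#' @rdname tidy.uev_slopes
#' @method glance uev_slopes
#' @export
glance.uev_slopes <- function(x, ...) {
  pp <- attr(x, "per_person")
  tibble(n_groups = nrow(x), n_persons = nrow(pp),
         min_years = attr(x, "min_years"))
}

#' Tidy the adjusted slope-on-score regression
#'
#' @param x A `uev_slope_reg` object.
#' @param ... Unused.
#' @return A tibble of terms with estimates (sd units), SEs and p-values.
#' @method tidy uev_slope_reg
#' @export
tidy.uev_slope_reg <- function(x, ...) as_tibble(x)

#' @rdname tidy.uev_slope_reg
#' @method glance uev_slope_reg
#' @export
glance.uev_slope_reg <- function(x, ...) {
  tibble(n = attr(x, "n"), r_squared = attr(x, "r_squared"),
         ridged = attr(x, "ridged"))
}
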