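#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns the per-class / per-subset /
#' per-threshold table as a plain tibble; `glance()` returns a one-row
#' summary.
#'
#' @param x An `iso_bias_result`, `mcw_result` or `mdmr_curve`.
#' @param ... Unused.
#' @name isobias-tidiers
NULL

#' @rdname isobias-tidiers
#' @export
tidy.iso_bias_result <- function(x, ...) {
  out <- as_tibble(unclass(x))
  out$statistic <- attr(x, "statistic") %||% NA_character_
  dplyr::relocate(out, "statistic")
}

#' @rdname isobias-tidiers
#' @export
glance.iso_bias_result <- function(x, ...) {
  tibble(
    statistic = attr(x, "statistic") %||% NA_character_,
    n_classes = nrow(x),
    n_defined = sum(!is.na(x$observed)),
    n_significant = if ("significant" %in% names(x))
      sum(x$significant, na.rm = TRUE) else NA_integer_,
    n_perm = attr(x, "n_perm") %||% 0L
  )
}

#' @rdname isobias-tidiers
#' @export
tidy.mcw_result <- function(x, ...) {
  out <- as_tibble(unclass(x))
  out$statistic <- attr(x, "statistic") %||% "mean"
  dplyr::relocate(out, "statistic")
}

#' @rdname isobias-tidiers
#' @export
glance.mcw_result <- function(x, ...) {
  tibble(
    statistic = attr(x, "statistic") %||% "mean",
    n_subsets = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_perm = attr(x, "n_perm") %||% 0L
  )
}

#' @rdname isobias-tidiers
#' @export
tidy.mdmr_curve <- function(x, ...) as_tibble(unclass(x))

#' @rdname isobias-tidiers
#' @export
glance.mdmr_curve <- function(x, ...) {
  tibble(
    n_thresholds = nrow(x),
    max_dmrs = max(x$n_dmr),
    floor = attr(x, "floor") %||% NA_real_
  )
}
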