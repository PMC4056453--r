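# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a conservation classification
#'
#' @param x A [classify_conservation()] result.
#' @param ... Unused.
#' @return Per-event tibble with `name`, coordinates, `n_species`,
#'   `members`, `class`.
#' @method tidy conservation_classification
#' @export
tidy.conservation_classification <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "conservation_classification")
  tibble::as_tibble(out)
}

#' @rdname tidy.conservation_classification
#' @return For `glance()`: one row per class with `n` and `fraction`,
#'   pivoted wide, plus `n_events` and `anchor`.
#' @method glance conservation_classification
#' @export
glance.conservation_classification <- function(x, ...) {
  fr <- conservation_fractions(x)
  wide <- tidyr::pivot_wider(fr[, c("class", "fraction")],
                             names_from = "class", values_from = "fraction")
  dplyr::bind_cols(
    tibble::tibble(anchor = attr(x, "anchor"), n_events = nrow(x)),
    wide
  )
}

#' Tidy a co-binding partition
#'
#' @param x A [classify_cobinding()] result.
#' @param ... Unused.
#' @return One row per event with `factor`, `name`, coordinates and
#'   `class` (`CTCF_ONLY`, `CTCF_YY1`, `YY1_ONLY`).
#' @method tidy cobind_partition
#' @export
tidy.cobind_partition <- function(x, ...) {
  pick <- function(df, cl) {
    if (nrow(df) == 0) return(NULL)
    dplyr::mutate(
      df[, c("species", "factor", "chrom", "start", "end", "name")],
      class = cl
    )
  }
  dplyr::bind_rows(
    pick(x$ctcf_only, "CTCF_ONLY"),
    pick(x$ctcf_cobound, "CTCF_YY1"),
    pick(x$yy1_cobound, "CTCF_YY1"),
    pick(x$yy1_only, "YY1_ONLY")
  )
}

#' @rdname tidy.cobind_partition
#' @return For `glance()`: one-row tibble with event counts and co-bound
#'   fractions per factor.
#' @method glance cobind_partition
#' @export
glance.cobind_partition <- function(x, ...) {
  n_c <- nrow(x$ctcf_only) + nrow(x$ctcf_cobound)
  n_y <- nrow(x$yy1_only) + nrow(x$yy1_cobound)
  tibble::tibble(
    species = x$species,
    n_ctcf = n_c, n_yy1 = n_y, n_pairs = nrow(x$pairs),
    ctcf_cobound_fraction = nrow(x$ctcf_cobound) / max(n_c, 1),
    yy1_cobound_fraction = nrow(x$yy1_cobound) / max(n_y, 1)
  )
}

#' Tidy a summit profile
#'
#' @param x A [summit_repeat_profile()] result.
#' @param ... Unused.
#' @return Tibble `window`, `offset_bp` (window centre relative to the
#'   summit), `value` (column mean across events).
#' @method tidy summit_profile
#' @export
tidy.summit_profile <- function(x, ...) {
  n <- x$n_windows
  centre <- (seq_len(n) - 1 - n / 2) * x$window_bp + x$window_bp / 2
  tibble::tibble(window = seq_len(n), offset_bp = centre,
                 value = x$profile)
}
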