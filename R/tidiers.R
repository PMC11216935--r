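# broom-style accessors for scan results.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a vicinity scan into its per-target table
#'
#' @param x a `pul_vicinity_scan`.
#' @param ... unused.
#' @return tibble, one row per target gene.
#' @method tidy pul_vicinity_scan
#' @export
tidy.pul_vicinity_scan <- function(x, ...) {
  as_tibble(x$results)
}

#' One-row summary of a vicinity scan
#'
#' @param x a `pul_vicinity_scan`.
#' @param ... unused.
#' @return one-row tibble: target counts, PUL-positive fraction, tier
#'   breakdown, window and cutoff used.
#' @method glance pul_vicinity_scan
#' @export
glance.pul_vicinity_scan <- function(x, ...) {
  x$summary |> mutate(window = x$params$w, cutoff = x$params$cutoff)
}
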