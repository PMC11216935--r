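# ggplot2 views of the census outputs.

#' @importFrom ggplot2 autoplot ggplot aes geom_col coord_flip labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Bar chart of a frequency table
#'
#' @param object a `pul_frequency_table`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pul_frequency_table
#' @export
autoplot.pul_frequency_table <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(key = stats::reorder(.data$key, .data$n))
  ggplot(df, aes(x = .data$key, y = .data$n)) +
    geom_col() +
    coord_flip() +
    labs(
      x = NULL,
      y = sprintf("count (%s, total %d)",
                  attr(object, "count_mode"), attr(object, "total"))
    ) +
    theme_minimal()
}

#' Tier breakdown of a vicinity scan
#'
#' @param object a `pul_vicinity_scan`.
#' @param ... unused.
#' @return a ggplot: PUL-positive targets per SusD evidence tier.
#' @method autoplot pul_vicinity_scan
#' @export
autoplot.pul_vicinity_scan <- function(object, ...) {
  df <- object$results |>
    count(tier = factor(.data$susd_tier, levels = TIER_LEVELS))
  ggplot(df, aes(x = .data$tier, y = .data$n)) +
    geom_col() +
    labs(
      x = "SusD evidence tier", y = "target genes",
      title = sprintf("%s within +/-%d genes of SusD",
                      object$params$target_domain, object$params$w)
    ) +
    theme_minimal()
}

#' Copy-number bar chart per genome
#'
#' @param copy_tab output of [copy_number_table()].
#' @param top show the `top` genomes by protein count.
#' @return a ggplot.
#' @export
plot_copy_number <- function(copy_tab, top = 15) {
  df <- head(as_tibble(copy_tab), top) |>
    mutate(genome = stats::reorder(.data$genome_id, .data$n_proteins))
  ggplot(df, aes(x = .data$genome, y = .data$n_domains)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "target-domain copies") +
    theme_minimal()
}
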