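#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_col
#'   geom_hline geom_vline labs facet_wrap theme_bw
#' @export
ggplot2::autoplot

#' Plot a fragment-similarity CDF
#'
#' Probability that a fragment lies within a given mean chord distance
#' of its loop.
#'
#' @param object an `ab_cdf` from [similarity_cdf()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot ab_cdf
#' @export
autoplot.ab_cdf <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$distance, y = .data$fraction)) +
    geom_step() +
    labs(x = "mean chord distance ⟨D⟩",
         y = "fraction of fragments within ⟨D⟩") +
    theme_bw()
}

#' Plot per-region benchmark RMSDs
#'
#' @param object an `ab_benchmark` from [benchmark_report()]
#' @param ... unused
#' @return a ggplot (bars per region, faceted by target)
#' @method autoplot ab_benchmark
#' @export
autoplot.ab_benchmark <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$region, y = .data$rmsd, fill = .data$pass)) +
    geom_col() +
    facet_wrap(~target_id) +
    labs(x = NULL, y = "backbone RMSD (Å)") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a flat-harmonic penalty curve
#'
#' @param constraint an `ab_flat_harmonic`
#' @param from,to distance range in Angstrom (defaults span x0 +/- 4 sigma)
#' @return a ggplot with the flat bottom marked
#' @export
plot_flat_harmonic <- function(constraint,
                               from = constraint$x0 - 4 * constraint$sigma,
                               to = constraint$x0 + 4 * constraint$sigma) {
  x <- seq(from, to, length.out = 400)
  df <- tibble(x = x, penalty = eval_flat_harmonic(constraint, x))
  ggplot(df, aes(x = .data$x, y = .data$penalty)) +
    geom_line() +
    geom_vline(xintercept = constraint$x0 + c(-1, 1) * constraint$dm,
               linetype = "dashed", colour = "grey50") +
    labs(x = "donor–acceptor distance (Å)",
         y = "penalty (score units)") +
    theme_bw()
}
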