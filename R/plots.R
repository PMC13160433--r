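# ggplot2 helpers for the result types: permutation-null diagnostics, the
# per-residue score track, and the domain track.

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline geom_line
#'   geom_rect geom_point geom_text labs theme_minimal annotate
NULL

#' Plot a permutation-test result
#'
#' Null-score histogram with the observed score marked; the visual companion
#' to the permutation p-value.
#'
#' @param object A `pathprox_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pathprox_result <- function(object, ...) {
  if (length(object$null_scores) == 0L)
    abort("no null scores to plot (test skipped or one-sided)")
  df <- tibble(null_score = object$null_scores)
  ggplot(df, aes(x = .data$null_score)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$score, colour = "#c0392b", linewidth = 1) +
    labs(x = "null clustering score", y = "count",
         title = sprintf("observed %.3f, p = %.3g (%d permutations)",
                         object$score, object$p_value, object$n_permutations)) +
    theme_minimal()
}

#' Plot a per-residue clustering score track
#'
#' Backbone-colourable score along the chain (low to high), one panel-worth
#' of line per chain.
#'
#' @param track Tibble from [per_residue_scores()].
#' @return A ggplot.
#' @export
plot_score_track <- function(track) {
  ggplot(track, aes(x = .data$residue, y = .data$score,
                    colour = .data$chain)) +
    geom_line() +
    labs(x = "structure residue", y = "clustering score", colour = "chain") +
    theme_minimal()
}

#' Plot a domain track with the variant marked
#'
#' Domains as boxes along the sequence, the variant position as a diamond —
#' the ggplot twin of [write_domain_track_svg()].
#'
#' @param domains Tibble `start`, `end`, `name`.
#' @param peptide_length Protein length (residues).
#' @param variant_position Residue to mark.
#' @return A ggplot.
#' @export
plot_domain_track <- function(domains, peptide_length, variant_position) {
  ggplot() +
    annotate("segment", x = 1, xend = peptide_length, y = 0, yend = 0,
             colour = "grey40") +
    geom_rect(data = domains,
              aes(xmin = .data$start, xmax = .data$end, ymin = -0.2,
                  ymax = 0.2, fill = .data$name), alpha = 0.8) +
    geom_point(aes(x = variant_position, y = 0.45), shape = 18, size = 5,
               colour = "#e6399b") +
    geom_text(data = domains,
              aes(x = (.data$start + .data$end) / 2, y = -0.45,
                  label = .data$name), size = 3) +
    labs(x = "residue", y = NULL, fill = "domain") +
    ggplot2::ylim(-0.7, 0.7) +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
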