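#' Bar chart of site counts by mismatch number
#'
#' Counts of candidate (or deleterious) sites per mismatch number, split into
#' gene-annotated and unidentified transcripts when gene identities are
#' attached.
#'
#' @param sites Site tibble; `gene_id` optional.
#' @return A ggplot object.
#' @export
plot_mismatch_profile <- function(sites) {
  sites <- as_tibble(sites)
  if (!"gene_id" %in% names(sites)) sites$gene_id <- NA_character_
  dat <- sites |>
    mutate(annotation = ifelse(is.na(.data$gene_id), "unidentified",
                               "gene-annotated")) |>
    count(.data$mm_count, .data$annotation)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$mm_count), y = .data$n,
                                    fill = .data$annotation)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mismatches", y = "sites", fill = NULL,
                  title = "Candidate sites by mismatch number") +
    ggplot2::theme_minimal()
}

#' @describeIn d_index_profile Histogram of per-term D-indices with the total
#'   and term count annotated.
#' @param object A `danger_profile`.
#' @export
autoplot.danger_profile <- function(object, ...) {
  lab <- sprintf("total D-index = %.4g\nN = %d",
                 attr(object, "total_d_index"), attr(object, "n_terms"))
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$d_index)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::facet_wrap(~category) +
    ggplot2::annotate("label", x = Inf, y = Inf, label = lab,
                      hjust = 1.05, vjust = 1.2, size = 3) +
    ggplot2::labs(x = "D-index", y = "GO terms",
                  title = "D-index distribution") +
    ggplot2::theme_minimal()
}

#' @describeIn validate_d_index D-index versus its permutation-null threshold
#'   per GO term; significant terms highlighted.
#' @param object A `danger_validation`.
#' @export
autoplot.danger_validation <- function(object, ...) {
  dat <- object$calls
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$threshold, y = .data$d_index,
                                    colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "null threshold (mean + z * sd)", y = "observed D-index",
                  colour = "significant",
                  title = sprintf("Significance at L = %g", object$config$L)) +
    ggplot2::theme_minimal()
}
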