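#' TPM ratio between edited and wild-type samples
#'
#' The ratio of the arithmetic mean TPM of edited samples to the arithmetic
#' mean TPM of wild-type samples. A transcript with zero mean WT expression
#' has an undefined ratio (`NA`): absence of WT expression cannot evidence
#' downregulation, and no pseudocount is applied.
#'
#' @param wt_values,edited_values Non-negative numeric vectors of per-sample
#'   TPM values.
#' @return A single number, or `NA` when the WT mean is zero.
#' @examples
#' tpm_ratio(c(10, 10, 10, 10), c(2, 2, 2, 2)) # 0.2
#' @export
tpm_ratio <- function(wt_values, edited_values) {
  if (length(wt_values) == 0L || length(edited_values) == 0L) {
    abort("both sample groups must be non-empty.")
  }
  if (any(wt_values < 0) || any(edited_values < 0)) {
    abort("TPM values must be >= 0.")
  }
  mw <- mean(wt_values)
  if (mw == 0) return(NA_real_)
  mean(edited_values) / mw
}

#' Flag transcripts downregulated by TPM ratio (dTPM)
#'
#' A transcript is dTPM iff its TPM ratio is defined and strictly less than
#' the threshold `t`. A ratio exactly equal to `t` is not flagged.
#'
#' @param screen Data frame with a `tpm_ratio` column.
#' @param t Threshold in (0, Inf); default 0.4.
#' @return `screen` with a logical `dtpm` column.
#' @export
flag_dtpm <- function(screen, t = 0.4) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0) abort("`t` must be > 0.")
  if (!"tpm_ratio" %in% names(screen)) abort("`screen` needs a tpm_ratio column.")
  mutate(as_tibble(screen), dtpm = !is.na(.data$tpm_ratio) & .data$tpm_ratio < t)
}

#' Flag transcripts downregulated by differential expression (dDE)
#'
#' A transcript is dDE iff its M-value (log-ratio of normalized counts,
#' edited vs WT) is negative and its p-value falls strictly below `alpha`.
#' The DE statistics come from an external analysis (e.g. TCC/edgeR) and are
#' consumed as given; no multiple-testing correction is added here.
#'
#' @param de_table Data frame with columns `transcript_id`, `m_value`,
#'   `p_value`.
#' @param alpha Threshold in (0, 1); default 0.001.
#' @return `de_table` with a logical `dde` column.
#' @export
flag_dde <- function(de_table, alpha = 0.001) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  need <- c("transcript_id", "m_value", "p_value")
  if (!all(need %in% names(de_table))) {
    abort("DE table needs columns transcript_id, m_value, p_value.")
  }
  if (any(de_table$p_value < 0 | de_table$p_value > 1, na.rm = TRUE)) {
    abort("p_value must lie in [0, 1].")
  }
  mutate(as_tibble(de_table),
         dde = !is.na(.data$m_value) & !is.na(.data$p_value) &
           .data$m_value < 0 & .data$p_value < alpha)
}

#' Screen transcripts for downregulation in edited samples
#'
#' Computes per-transcript group means, the edited/WT TPM ratio and the dTPM
#' flag, and (when a DE table is supplied) merges the external DE statistics
#' and the dDE flag. Transcripts present only in the DE table are kept with
#' `NA` expression summaries, with a warning.
#'
#' @param tpm Wide expression matrix: `transcript_id` plus one non-negative
#'   numeric column per sample (see [read_tpm_matrix()] /
#'   [read_rsem_isoforms()]).
#' @param manifest Data frame with `sample_id`, `group` (`WT`/`edited`);
#'   at least one sample per group (three or more per group recommended).
#' @param t dTPM threshold; default 0.4.
#' @param de_table Optional DE table (`transcript_id`, `m_value`, `p_value`).
#' @param alpha dDE p-value threshold; default 0.001.
#' @return A tibble with columns `transcript_id`, `mean_wt`, `mean_edited`,
#'   `tpm_ratio`, `dtpm`, `m_value`, `p_value`, `dde`.
#' @export
screen_expression <- function(tpm, manifest, t = 0.4, de_table = NULL,
                              alpha = 0.001) {
  tpm <- check_expression_matrix(tpm)
  manifest <- check_manifest(manifest)
  missing_samples <- setdiff(manifest$sample_id, names(tpm)[-1])
  if (length(missing_samples) > 0L) {
    abort(sprintf("manifest samples absent from matrix: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  wt <- manifest$sample_id[manifest$group == "WT"]
  ed <- manifest$sample_id[manifest$group == "edited"]

  mean_wt <- rowMeans(as.matrix(tpm[wt]))
  mean_edited <- rowMeans(as.matrix(tpm[ed]))
  screen <- tibble(
    transcript_id = tpm$transcript_id,
    mean_wt = mean_wt,
    mean_edited = mean_edited,
    tpm_ratio = ifelse(mean_wt > 0, mean_edited / mean_wt, NA_real_)
  )
  screen <- flag_dtpm(screen, t = t)

  if (!is.null(de_table)) {
    de <- flag_dde(de_table, alpha = alpha)
    extra <- setdiff(de$transcript_id, screen$transcript_id)
    if (length(extra) > 0L) {
      warn(sprintf(
        "%d DE-table transcript(s) absent from the expression matrix; rows kept with NA summaries.",
        length(extra)))
    }
    screen <- dplyr::full_join(screen, de, by = "transcript_id")
    screen$dtpm[is.na(screen$dtpm)] <- FALSE
    screen$dde[is.na(screen$dde)] <- FALSE
  } else {
    screen$m_value <- NA_real_
    screen$p_value <- NA_real_
    screen$dde <- FALSE
  }
  screen[c("transcript_id", "mean_wt", "mean_edited", "tpm_ratio", "dtpm",
           "m_value", "p_value", "dde")]
}
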