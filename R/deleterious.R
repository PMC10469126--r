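#' Attach gene identities to sites
#'
#' Left-joins the transcript-to-gene map onto a site table (the contig of a
#' transcript scan *is* the transcript). Sites on unmapped transcripts get
#' `NA` gene_id and are counted as unidentified.
#'
#' @param sites Site tibble (from [scan_transcriptome()] or downstream).
#' @param gene_map Data frame `transcript_id`, `gene_id` (optional `symbol`),
#'   or `NULL` to leave every site unidentified.
#' @return `sites` with `transcript_id`, `gene_id` (and `symbol` if mapped)
#'   columns added.
#' @export
attach_genes <- function(sites, gene_map = NULL) {
  sites <- as_tibble(sites)
  if (!"transcript_id" %in% names(sites)) {
    sites$transcript_id <- sites$contig_id
  }
  sites$gene_id <- NULL
  sites$symbol <- NULL
  if (is.null(gene_map)) {
    sites$gene_id <- NA_character_
    return(sites)
  }
  gene_map <- check_gene_map(gene_map)
  left_join(sites, gene_map, by = "transcript_id")
}

#' Summarise site annotation by mismatch count
#'
#' Per mismatch number: how many sites fall on gene-annotated transcripts,
#' how many on unidentified ones, and how many distinct genes are hit.
#'
#' @param sites Site tibble carrying `gene_id` (see [attach_genes()]).
#' @return A tibble with `mm_count`, `n_sites`, `n_annotated`,
#'   `n_unidentified`, `n_genes`.
#' @export
summarise_site_annotation <- function(sites) {
  sites <- as_tibble(sites)
  if (!"gene_id" %in% names(sites)) abort("run attach_genes() first.")
  if (nrow(sites) == 0L) {
    return(tibble(mm_count = integer(), n_sites = integer(),
                  n_annotated = integer(), n_unidentified = integer(),
                  n_genes = integer()))
  }
  sites |>
    group_by(.data$mm_count) |>
    summarise(
      n_sites = dplyr::n(),
      n_annotated = sum(!is.na(.data$gene_id)),
      n_unidentified = sum(is.na(.data$gene_id)),
      n_genes = dplyr::n_distinct(.data$gene_id[!is.na(.data$gene_id)]),
      .groups = "drop"
    ) |>
    arrange(.data$mm_count)
}

#' Exclude the on-target gene from a site table
#'
#' The intended target gene is removed from all downstream risk accounting:
#' the on-target (perfect-match) sites themselves are dropped, and so is
#' every site on any transcript mapping to a gene that carries an on-target
#' site (isoforms share the gene). Without a gene map, exclusion falls back
#' to the on-target transcripts. If no on-target site exists the input is
#' returned unchanged with a warning.
#'
#' @param sites Site tibble; needs `transcript_id` (or `contig_id`) and
#'   `mm_count`.
#' @param on_target_sites Sites defining the intended locus; defaults to all
#'   perfect-match (`mm_count == 0`) rows of `sites`.
#' @param gene_map Optional transcript-to-gene map.
#' @return Filtered site tibble.
#' @export
exclude_on_target <- function(sites, on_target_sites = NULL, gene_map = NULL) {
  sites <- as_tibble(sites)
  if (!"transcript_id" %in% names(sites)) sites$transcript_id <- sites$contig_id
  if (is.null(on_target_sites)) {
    on_target_sites <- filter(sites, .data$mm_count == 0L)
  }
  if (nrow(on_target_sites) == 0L) {
    warn("no on-target (0-mismatch) site found; returning sites unchanged.")
    return(sites)
  }
  on_tx <- unique(if ("transcript_id" %in% names(on_target_sites)) {
    on_target_sites$transcript_id
  } else {
    on_target_sites$contig_id
  })
  if (!is.null(gene_map)) {
    gene_map <- check_gene_map(gene_map)
    on_genes <- unique(gene_map$gene_id[gene_map$transcript_id %in% on_tx])
    excl_tx <- union(on_tx, gene_map$transcript_id[gene_map$gene_id %in% on_genes])
  } else {
    excl_tx <- on_tx
  }
  out <- filter(sites, !(.data$transcript_id %in% excl_tx))
  # drop any residual perfect matches at the on-target coordinates themselves
  key <- paste(on_target_sites$contig_id, on_target_sites$start,
               on_target_sites$strand)
  filter(out, !(paste(.data$contig_id, .data$start, .data$strand) %in% key))
}

#' Call deleterious off-target sites
#'
#' An off-target site is deleterious when its transcript is flagged as
#' downregulated — by TPM ratio (dTPM), by differential expression (dDE), or
#' by either. The `evidence` column records which flags the transcript
#' actually carries (`"dTPM"`, `"dDE"`, or `"both"`), so the union of a
#' dTPM-only run and a dDE-only run equals an `"either"` run. Sites on
#' transcripts absent from the screen are dropped with a warning.
#'
#' @param sites Site tibble; `transcript_id` (or `contig_id`) identifies the
#'   transcript.
#' @param screen Screen tibble from [screen_expression()] (needs
#'   `transcript_id`, `dtpm`, `dde`).
#' @param criterion `"dTPM"`, `"dDE"`, or `"either"`.
#' @return The retained sites with an `evidence` column.
#' @export
find_deleterious <- function(sites, screen, criterion = c("dTPM", "dDE", "either")) {
  criterion <- match.arg(criterion)
  sites <- as_tibble(sites)
  if (!"transcript_id" %in% names(sites)) sites$transcript_id <- sites$contig_id
  need <- c("transcript_id", "dtpm", "dde")
  if (!all(need %in% names(screen))) {
    abort("`screen` needs columns transcript_id, dtpm, dde.")
  }
  flags <- as_tibble(screen)[need]
  unresolved <- setdiff(sites$transcript_id, flags$transcript_id)
  if (length(unresolved) > 0L) {
    n_drop <- sum(sites$transcript_id %in% unresolved)
    warn(sprintf("%d site(s) on %d transcript(s) absent from the screen were dropped.",
                 n_drop, length(unresolved)))
  }
  joined <- inner_join(sites, flags, by = "transcript_id")
  keep <- switch(criterion,
    dTPM = joined$dtpm,
    dDE = joined$dde,
    either = joined$dtpm | joined$dde
  )
  out <- joined[keep, , drop = FALSE]
  out$evidence <- dplyr::case_when(
    out$dtpm & out$dde ~ "both",
    out$dtpm ~ "dTPM",
    TRUE ~ "dDE"
  )
  out$dtpm <- NULL
  out$dde <- NULL
  out
}
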