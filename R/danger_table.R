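#' Build the DANGER table of per-term, per-mismatch gene counts
#'
#' For every (GO term, mismatch number m) pair, `n_genes` = N(m) is the number
#' of *distinct* genes that carry at least one deleterious off-target site
#' with exactly m mismatches and are annotated with that term. A gene with
#' several sites at the same m counts once; a gene with sites at several m
#' values counts once per m. Annotations are used exactly as supplied (no
#' GO-graph propagation). Sites without a gene identity, and genes without
#' any GO annotation, contribute nothing (a message reports how many were
#' skipped).
#'
#' @param deleterious_sites Site tibble carrying `gene_id` and `mm_count`
#'   (see [find_deleterious()], [attach_genes()]).
#' @param annotation Gene-to-GO annotation tibble (`gene_id`, `go_id`,
#'   `go_term`, `category`); see [read_go_annotation()].
#' @param m_max Maximum mismatch number retained; rows with larger `mm_count`
#'   are dropped.
#' @return A tibble (`go_id`, `go_term`, `category`, `m`, `n_genes`) with
#'   `n_genes >= 1`, sorted by `go_id` then `m`.
#' @export
build_danger_table <- function(deleterious_sites, annotation, m_max = 8L) {
  annotation <- check_go_annotation(annotation)
  sites <- as_tibble(deleterious_sites)
  if (!all(c("gene_id", "mm_count") %in% names(sites))) {
    abort("`deleterious_sites` needs gene_id and mm_count columns.")
  }
  m_max <- as.integer(m_max)

  n_unidentified <- sum(is.na(sites$gene_id))
  if (n_unidentified > 0L) {
    inform(sprintf("%d site(s) without gene identity skipped.", n_unidentified))
  }
  sites <- filter(sites, !is.na(.data$gene_id), .data$mm_count <= m_max)
  if (nrow(sites) == 0L) {
    return(tibble(go_id = character(), go_term = character(),
                  category = character(), m = integer(), n_genes = integer()))
  }

  gene_m <- distinct(sites, .data$gene_id, m = .data$mm_count)
  unannotated <- setdiff(unique(gene_m$gene_id), unique(annotation$gene_id))
  if (length(unannotated) > 0L) {
    inform(sprintf("%d gene(s) without GO annotation contribute nothing.",
                   length(unannotated)))
  }
  inner_join(gene_m, annotation, by = "gene_id",
             relationship = "many-to-many") |>
    distinct(.data$go_id, .data$go_term, .data$category, .data$m,
             .data$gene_id) |>
    count(.data$go_id, .data$go_term, .data$category, .data$m,
          name = "n_genes") |>
    arrange(.data$go_id, .data$m)
}
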