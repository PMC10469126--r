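#' Read a transcriptome FASTA
#'
#' Multi-line, case-insensitive FASTA; the contig id is the first whitespace
#' token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig_id`, `sequence` (uppercase).
#' @export
read_transcriptome <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- tibble(contig_id = ids,
                sequence = unname(toupper(as.character(set))))
  check_transcriptome(out)
}

#' Write a transcriptome FASTA
#'
#' @param transcriptome Data frame with `contig_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcriptome <- function(transcriptome, path) {
  transcriptome <- check_transcriptome(transcriptome)
  set <- Biostrings::DNAStringSet(setNames(transcriptome$sequence,
                                           transcriptome$contig_id))
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

offtarget_cols <- c("query", "contig_id", "start", "site_sequence",
                    "strand", "mm_count")

#' Write sites in Cas-OFFinder tabular format
#'
#' One tab-separated row per site: query sequence (protospacer+PAM pattern),
#' contig id, 0-based start, site sequence with mismatched protospacer bases
#' lowercased, strand, mismatch count. No header unless `header = TRUE`.
#'
#' @param sites Site tibble from [scan_transcriptome()].
#' @param path Output path.
#' @param guide The [guide_spec()] used (supplies the query column).
#' @param header Write a header line.
#' @return `path`, invisibly.
#' @export
write_offtarget_table <- function(sites, path, guide, header = FALSE) {
  out <- tibble(
    query = paste0(guide$protospacer, guide$pam),
    contig_id = sites$contig_id,
    start = sites$start,
    site_sequence = sites$site_sequence,
    strand = sites$strand,
    mm_count = sites$mm_count
  )
  readr::write_tsv(out, path, col_names = isTRUE(header))
  invisible(path)
}

#' Read a Cas-OFFinder style site table
#'
#' @param path Path to a tab-separated site table written by
#'   [write_offtarget_table()] (or by compatible tools).
#' @param header Whether the file has a header line.
#' @return A tibble with columns `query`, `contig_id`, `start`, `strand`,
#'   `site_sequence`, `mm_count`, `is_on_target`.
#' @export
read_offtarget_table <- function(path, header = FALSE) {
  if (!file.exists(path)) abort(sprintf("site table not found: %s", path))
  tbl <- readr::read_tsv(path, col_names = if (header) TRUE else offtarget_cols,
                         show_col_types = FALSE)
  if (header) names(tbl) <- offtarget_cols
  tbl$start <- as.integer(tbl$start)
  tbl$mm_count <- as.integer(tbl$mm_count)
  tbl$is_on_target <- tbl$mm_count == 0L
  as_tibble(tbl[c("query", "contig_id", "start", "strand",
                  "site_sequence", "mm_count", "is_on_target")])
}

#' Read a consolidated TPM matrix (CSV)
#'
#' Rows are transcripts, columns are samples; the first column must be
#' `transcript_id`.
#'
#' @param path CSV path.
#' @return Wide tibble: `transcript_id` plus one numeric column per sample.
#' @export
read_tpm_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("TPM matrix not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (names(tbl)[1] != "transcript_id") names(tbl)[1] <- "transcript_id"
  check_expression_matrix(tbl)
}

#' Read per-sample RSEM isoform quantifications
#'
#' Each file is an RSEM `isoforms.results`-style TSV with at least
#' `transcript_id` and `TPM` columns; files are combined into a wide TPM
#' matrix, one column per sample.
#'
#' @param paths Named character vector: names are sample ids, values paths.
#' @return Wide tibble: `transcript_id` plus one column per sample.
#' @export
read_rsem_isoforms <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    abort("`paths` must be a named vector (names = sample ids).")
  }
  per_sample <- purrr::imap(paths, function(p, sample) {
    if (!file.exists(p)) abort(sprintf("RSEM file not found: %s", p))
    tbl <- readr::read_tsv(p, show_col_types = FALSE)
    if (!all(c("transcript_id", "TPM") %in% names(tbl))) {
      abort(sprintf("%s lacks transcript_id/TPM columns.", p))
    }
    tibble(transcript_id = tbl$transcript_id, sample_id = sample, tpm = tbl$TPM)
  })
  long <- bind_rows(per_sample)
  wide <- tidyr::pivot_wider(long, names_from = "sample_id", values_from = "tpm")
  check_expression_matrix(wide)
}

#' Read a sample manifest
#'
#' Two tab-separated columns (`sample_id`, `group`) with a header; group
#' values must be `WT` or `edited`.
#'
#' @param path TSV path.
#' @return A tibble with `sample_id`, `group`.
#' @export
read_sample_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  check_manifest(tbl)
}

check_manifest <- function(manifest) {
  if (!is.data.frame(manifest) ||
      !all(c("sample_id", "group") %in% names(manifest))) {
    abort("manifest needs columns sample_id, group.")
  }
  bad <- setdiff(unique(manifest$group), c("WT", "edited"))
  if (length(bad) > 0L) {
    abort(sprintf("manifest group values must be WT/edited (found: %s).",
                  paste(bad, collapse = ", ")))
  }
  if (!any(manifest$group == "WT") || !any(manifest$group == "edited")) {
    abort("manifest must contain at least one WT and one edited sample.")
  }
  as_tibble(manifest[c("sample_id", "group")])
}

check_expression_matrix <- function(tpm) {
  if (!is.data.frame(tpm) || names(tpm)[1] != "transcript_id" || ncol(tpm) < 2L) {
    abort("expression matrix needs a transcript_id column plus sample columns.")
  }
  vals <- as.matrix(tpm[-1])
  if (anyNA(vals) || any(vals < 0)) abort("expression values must be >= 0.")
  as_tibble(tpm)
}

#' Read a differential-expression table
#'
#' Tab-separated with header `transcript_id`, `m_value`, `p_value`. The
#' M-value is the log-ratio of normalized counts (edited vs WT); p-values are
#' those of the upstream DE method (e.g. TCC/edgeR) and are consumed as given.
#'
#' @param path TSV path.
#' @return A tibble with `transcript_id`, `m_value`, `p_value`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("DE table not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("transcript_id", "m_value", "p_value") %in% names(tbl))) {
    abort("DE table needs columns transcript_id, m_value, p_value.")
  }
  if (any(tbl$p_value < 0 | tbl$p_value > 1, na.rm = TRUE)) {
    abort("p_value must lie in [0, 1].")
  }
  as_tibble(tbl[c("transcript_id", "m_value", "p_value")])
}

#' Read a transcript-to-gene map
#'
#' Tab-separated with header `transcript_id`, `gene_id` and an optional
#' `symbol` column. Each transcript maps to at most one gene; transcripts
#' absent from the map are treated as unidentified downstream.
#'
#' @param path TSV path.
#' @return A tibble with `transcript_id`, `gene_id` (and `symbol` if present).
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("gene map not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  check_gene_map(tbl)
}

check_gene_map <- function(gene_map) {
  if (!is.data.frame(gene_map) ||
      !all(c("transcript_id", "gene_id") %in% names(gene_map))) {
    abort("gene map needs columns transcript_id, gene_id.")
  }
  if (anyDuplicated(gene_map$transcript_id)) {
    abort("a transcript may map to at most one gene.")
  }
  keep <- intersect(c("transcript_id", "gene_id", "symbol"), names(gene_map))
  as_tibble(gene_map[keep])
}

#' Read a gene-to-GO annotation table
#'
#' Tab-separated with header `gene_id`, `go_id`, `go_term`, `category`
#' (`BP`/`CC`/`MF`). GO ids must be well-formed (`GO:` + 7 digits).
#' Annotations are counted as supplied; no ontology-graph propagation is
#' performed.
#'
#' @param path TSV path.
#' @return A tibble with `gene_id`, `go_id`, `go_term`, `category`.
#' @export
read_go_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("GO annotation not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  check_go_annotation(tbl)
}

check_go_annotation <- function(annotation) {
  need <- c("gene_id", "go_id", "go_term", "category")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation))) {
    abort("annotation needs columns gene_id, go_id, go_term, category.")
  }
  if (any(!grepl("^GO:[0-9]{7}$", annotation$go_id))) {
    abort("go_id values must look like GO:NNNNNNN.")
  }
  bad <- setdiff(unique(annotation$category), c("BP", "CC", "MF"))
  if (length(bad) > 0L) {
    abort(sprintf("category must be BP/CC/MF (found: %s).",
                  paste(bad, collapse = ", ")))
  }
  as_tibble(annotation[need])
}
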