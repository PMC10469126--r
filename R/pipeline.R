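#' Analysis presets
#'
#' Three named parameter bundles:
#' * `approximate_dtpm` — widest screen: NRR PAM, up to 11 mismatches,
#'   dTPM with `t = 0.4`, permissive significance `L = 5e-1`.
#' * `optimized_dtpm` — NGG PAM, up to 8 mismatches, dTPM with `t = 0.4`,
#'   stringent `L = 1e-15`.
#' * `optimized_dde` — NGG PAM, up to 8 mismatches, dDE with
#'   `alpha = 0.001`, stringent `L = 1e-15`.
#'
#' @param name Preset name.
#' @return A named list: `pam`, `max_mm`, `criterion`, `t`, `alpha`, `L`.
#' @export
danger_preset <- function(name = c("optimized_dtpm", "approximate_dtpm",
                                   "optimized_dde")) {
  name <- match.arg(name)
  switch(name,
    approximate_dtpm = list(pam = "NRR", max_mm = 11L, criterion = "dTPM",
                            t = 0.4, alpha = 0.001, L = 5e-1),
    optimized_dtpm = list(pam = "NGG", max_mm = 8L, criterion = "dTPM",
                          t = 0.4, alpha = 0.001, L = 1e-15),
    optimized_dde = list(pam = "NGG", max_mm = 8L, criterion = "dDE",
                         t = 0.4, alpha = 0.001, L = 1e-15)
  )
}

#' Configure a pipeline run
#'
#' Collects input paths and parameters for [run_danger()]. A `preset`
#' supplies PAM, mismatch bound, criterion, thresholds and `L`; individual
#' arguments override it.
#'
#' @param fasta Transcriptome FASTA path.
#' @param tpm_csv Consolidated TPM matrix CSV (`transcript_id` + samples), or
#'   `NULL` when `rsem_files` is given.
#' @param rsem_files Named vector of RSEM isoforms.results-style TSVs (names
#'   = sample ids); alternative to `tpm_csv`.
#' @param manifest_tsv Sample manifest TSV (`sample_id`, `group`).
#' @param gene_map_tsv Optional transcript-to-gene map TSV.
#' @param annotation_tsv Gene-to-GO annotation TSV.
#' @param de_tsv Optional DE table TSV (required for the dDE criterion).
#' @param protospacer,pam_guide Guide definition; `pam_guide` defaults to the
#'   scan PAM.
#' @param guide_id Guide label.
#' @param preset Preset name (see [danger_preset()]) or `NULL`.
#' @param pam,max_mm,criterion,t,alpha,L Individual overrides.
#' @param n_null,n_extra Permutation counts.
#' @param seed Base seed for the permutation machinery.
#' @param out_dir Output directory.
#' @return An object of class `danger_config`.
#' @export
danger_config <- function(fasta, tpm_csv = NULL, rsem_files = NULL,
                          manifest_tsv, gene_map_tsv = NULL, annotation_tsv,
                          de_tsv = NULL, protospacer, pam_guide = NULL,
                          guide_id = "guide", preset = "optimized_dtpm",
                          pam = NULL, max_mm = NULL, criterion = NULL,
                          t = NULL, alpha = NULL, L = NULL,
                          n_null = 100L, n_extra = 10L, seed = 0L,
                          out_dir = "danger_out") {
  base <- if (is.null(preset)) danger_preset("optimized_dtpm") else danger_preset(preset)
  cfg <- list(
    fasta = fasta, tpm_csv = tpm_csv, rsem_files = rsem_files,
    manifest_tsv = manifest_tsv, gene_map_tsv = gene_map_tsv,
    annotation_tsv = annotation_tsv, de_tsv = de_tsv,
    protospacer = protospacer,
    guide_id = guide_id,
    preset = preset,
    pam = pam %||% base$pam,
    max_mm = as.integer(max_mm %||% base$max_mm),
    criterion = criterion %||% base$criterion,
    t = t %||% base$t,
    alpha = alpha %||% base$alpha,
    L = L %||% base$L,
    n_null = as.integer(n_null),
    n_extra = as.integer(n_extra),
    seed = as.integer(seed),
    out_dir = out_dir
  )
  cfg$pam_guide <- pam_guide %||% cfg$pam
  if (is.null(cfg$tpm_csv) && is.null(cfg$rsem_files)) {
    abort("supply either `tpm_csv` or `rsem_files`.")
  }
  if (cfg$criterion == "dDE" && is.null(cfg$de_tsv)) {
    abort("the dDE criterion requires `de_tsv`.")
  }
  structure(cfg, class = "danger_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage: %s] %s", stage, conditionMessage(e)))
  })
}

#' Run the full risk-assessment pipeline
#'
#' Executes, in order: site scan, expression screen, deleterious-site call
#' (with on-target gene exclusion and gene annotation), DANGER table,
#' D-index profile, permutation-null significance calls, and
#' false-detection-rate estimation. All stage outputs are written to
#' `config$out_dir` as plain-text tables plus a JSON run manifest recording
#' the configuration, the seeds and MD5 checksums of the inputs. Identical
#' configuration and inputs give byte-identical outputs.
#'
#' @param config A [danger_config()].
#' @return Invisibly, a list with every stage result (`sites`, `screen`,
#'   `deleterious`, `danger_table`, `profile`, `validation`) and the output
#'   paths.
#' @export
run_danger <- function(config) {
  if (!inherits(config, "danger_config")) abort("`config` must be a danger_config.")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  guide <- stage_try("scan", guide_spec(config$protospacer,
                                        pam = config$pam_guide,
                                        guide_id = config$guide_id))
  tx <- stage_try("scan", read_transcriptome(config$fasta))
  sites <- stage_try("scan", scan_transcriptome(
    tx, guide, scan_config(pam = config$pam, max_mm = config$max_mm)))

  tpm <- stage_try("screen", {
    if (!is.null(config$tpm_csv)) read_tpm_matrix(config$tpm_csv)
    else read_rsem_isoforms(config$rsem_files)
  })
  manifest <- stage_try("screen", read_sample_manifest(config$manifest_tsv))
  de_table <- if (!is.null(config$de_tsv)) stage_try("screen", read_de_table(config$de_tsv))
  screen <- stage_try("screen", screen_expression(
    tpm, manifest, t = config$t, de_table = de_table, alpha = config$alpha))

  gene_map <- if (!is.null(config$gene_map_tsv)) {
    stage_try("deleterious", read_gene_map(config$gene_map_tsv))
  }
  annotation <- stage_try("danger-table", read_go_annotation(config$annotation_tsv))

  candidate <- stage_try("deleterious", {
    attach_genes(sites, gene_map) |>
      exclude_on_target(gene_map = gene_map)
  })
  deleterious <- stage_try("deleterious", find_deleterious(
    candidate, screen, criterion = config$criterion))
  if (nrow(deleterious) == 0L) {
    warn("no deleterious off-target site found; downstream tables are empty.")
  }

  danger_table <- stage_try("danger-table", build_danger_table(
    deleterious, annotation, m_max = config$max_mm))
  profile <- stage_try("d-index", d_index_profile(danger_table,
                                                  m_max = config$max_mm))
  vconfig <- validation_config(n_null = config$n_null,
                               n_extra = config$n_extra, L = config$L,
                               base_seed = config$seed)
  validation <- stage_try("validate", validate_d_index(
    candidate, screen, annotation, criterion = config$criterion,
    m_max = config$max_mm, config = vconfig))

  paths <- c(
    sites = file.path(out_dir, "sites.offtargets.tsv"),
    screen = file.path(out_dir, "expression_screen.csv"),
    deleterious = file.path(out_dir, "deleterious_sites.csv"),
    mm_summary = file.path(out_dir, "deleterious_summary_by_mm.csv"),
    danger_table = file.path(out_dir, "danger_table.csv"),
    d_index = file.path(out_dir, "d_index.csv"),
    d_index_totals = file.path(out_dir, "d_index_totals.csv"),
    significance = file.path(out_dir, "significance.csv"),
    fdr = file.path(out_dir, "fdr_report.json"),
    manifest = file.path(out_dir, "run_manifest.json")
  )
  write_offtarget_table(sites, paths[["sites"]], guide)
  readr::write_csv(screen, paths[["screen"]])
  readr::write_csv(deleterious, paths[["deleterious"]])
  readr::write_csv(summarise_site_annotation(deleterious), paths[["mm_summary"]])
  readr::write_csv(danger_table, paths[["danger_table"]])
  readr::write_csv(as_tibble(profile), paths[["d_index"]])
  readr::write_csv(glance(profile), paths[["d_index_totals"]])
  readr::write_csv(validation$calls, paths[["significance"]])
  if (!is.null(validation$fdr)) {
    jsonlite::write_json(as.list(validation$fdr), paths[["fdr"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    jsonlite::write_json(list(), paths[["fdr"]], pretty = TRUE)
  }

  input_paths <- c(fasta = config$fasta, tpm_csv = config$tpm_csv,
                   manifest = config$manifest_tsv,
                   gene_map = config$gene_map_tsv,
                   annotation = config$annotation_tsv, de = config$de_tsv,
                   config$rsem_files)
  input_paths <- input_paths[!vapply(input_paths, is.null, logical(1))]
  run_manifest <- list(
    config = unclass(config)[setdiff(names(unclass(config)), "rsem_files")],
    seeds = list(base = config$seed,
                 null = config$seed + seq_len(config$n_null),
                 extra = config$seed + config$n_null + seq_len(config$n_extra)),
    input_md5 = as.list(tools::md5sum(unlist(input_paths)))
  )
  jsonlite::write_json(run_manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(sites = sites, screen = screen, deleterious = deleterious,
                 danger_table = danger_table, profile = profile,
                 validation = validation, paths = paths, guide = guide))
}

#' @export
print.danger_config <- function(x, ...) {
  cat(sprintf("<danger_config> %s: PAM %s, max_mm %d, criterion %s (t=%g, alpha=%g, L=%g), seed %d\n",
              x$preset %||% "custom", x$pam, x$max_mm, x$criterion,
              x$t, x$alpha, x$L, x$seed))
  invisible(x)
}
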