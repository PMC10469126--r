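IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Specify a guide RNA
#'
#' A guide is a 19- or 20-nt protospacer (the DNA sequence matched by the
#' sgRNA's targeting segment, mismatches are counted here) plus a PAM pattern
#' given in IUPAC code (e.g. `"NGG"` for SpCas9, `"NRR"` for a relaxed
#' search). The PAM is matched as a hard filter and never contributes to the
#' mismatch count.
#'
#' @param protospacer Character scalar, 19 or 20 bases, A/C/G/T only.
#' @param pam PAM pattern, IUPAC nucleotide code, length >= 2.
#' @param guide_id Label used in output tables.
#' @return An object of class `guide_spec`.
#' @examples
#' guide_spec("AGATTCTGGGTGGAAGCGCC", pam = "NGG", guide_id = "example")
#' @export
guide_spec <- function(protospacer, pam = "NGG", guide_id = "guide") {
  if (!is.character(protospacer) || length(protospacer) != 1L) {
    abort("`protospacer` must be a single string.")
  }
  protospacer <- toupper(protospacer)
  if (!nchar(protospacer) %in% c(19L, 20L)) {
    abort(sprintf("`protospacer` must be 19 or 20 nt (got %d).", nchar(protospacer)))
  }
  if (grepl("[^ACGT]", protospacer)) {
    abort("`protospacer` must contain only A/C/G/T (no ambiguity codes).")
  }
  check_pam_pattern(pam)
  structure(
    list(protospacer = protospacer, pam = toupper(pam),
         guide_id = as.character(guide_id)),
    class = "guide_spec"
  )
}

check_pam_pattern <- function(pam) {
  if (!is.character(pam) || length(pam) != 1L || nchar(pam) < 2L) {
    abort("`pam` must be a single IUPAC string of length >= 2.")
  }
  sym <- strsplit(toupper(pam), "")[[1]]
  bad <- setdiff(sym, names(IUPAC_SETS))
  if (length(bad) > 0L) {
    abort(sprintf("invalid IUPAC symbol(s) in PAM pattern: %s",
                  paste(unique(bad), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.guide_spec <- function(x, ...) {
  cat(sprintf("<guide_spec> %s: %s + %s (%d nt protospacer)\n",
              x$guide_id, x$protospacer, x$pam, nchar(x$protospacer)))
  invisible(x)
}

#' Configure an off-target scan
#'
#' @param pam PAM pattern (IUPAC) used for the scan; defaults to the guide's
#'   own pattern when `NULL` in [scan_transcriptome()].
#' @param max_mm Maximum number of protospacer mismatches retained.
#' @param both_strands Scan the reverse complement of each contig as well.
#' @return An object of class `scan_config`.
#' @seealso [scan_preset()] for the named search presets.
#' @export
scan_config <- function(pam = "NGG", max_mm = 8L, both_strands = TRUE) {
  check_pam_pattern(pam)
  max_mm <- as.integer(max_mm)
  if (is.na(max_mm) || max_mm < 0L) abort("`max_mm` must be a non-negative integer.")
  structure(
    list(pam = toupper(pam), max_mm = max_mm, both_strands = isTRUE(both_strands)),
    class = "scan_config"
  )
}

#' Named scan presets
#'
#' Two standard search settings: `"optimized"` (NGG PAM, up to 8 mismatches)
#' and `"approximate"` (NRR PAM, up to 11 mismatches). The approximate preset
#' casts the widest net; the optimized preset is the recommended default.
#'
#' @param name `"optimized"` or `"approximate"`.
#' @return A [scan_config()].
#' @export
scan_preset <- function(name = c("optimized", "approximate")) {
  name <- match.arg(name)
  switch(name,
    optimized = scan_config(pam = "NGG", max_mm = 8L),
    approximate = scan_config(pam = "NRR", max_mm = 11L)
  )
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf("<scan_config> PAM %s, max_mm %d, strands %s\n",
              x$pam, x$max_mm, if (x$both_strands) "both" else "+ only"))
  invisible(x)
}
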