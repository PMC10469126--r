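#' Count protospacer mismatches
#'
#' Position-by-position mismatch count between a candidate window and the
#' protospacer. Both must have equal length; any non-ACGT base in the
#' candidate counts as a mismatch. The PAM is never part of this comparison.
#'
#' @param candidate Character vector of candidate windows (protospacer part
#'   only), case-insensitive.
#' @param protospacer Single A/C/G/T string.
#' @return Integer vector of mismatch counts.
#' @examples
#' count_mismatches("GCAGACTGGTTGGAAGCACC", "AGATTCTGGGTGGAAGCGCC") # 6
#' @export
count_mismatches <- function(candidate, protospacer) {
  if (!is.character(candidate)) abort("`candidate` must be character.")
  if (!is.character(protospacer) || length(protospacer) != 1L) {
    abort("`protospacer` must be a single string.")
  }
  protospacer <- toupper(protospacer)
  if (grepl("[^ACGT]", protospacer)) {
    abort("`protospacer` must contain only A/C/G/T.")
  }
  if (any(nchar(candidate) != nchar(protospacer))) {
    abort("malformed window: candidate and protospacer lengths differ.")
  }
  .count_mismatches_cpp(toupper(candidate), protospacer)
}

#' Match a window against an IUPAC PAM pattern
#'
#' `TRUE` iff every window base is a concrete A/C/G/T contained in the IUPAC
#' set of the corresponding pattern symbol; an ambiguous window base never
#' matches. This is a hard filter with zero mismatch tolerance.
#'
#' @param window Character vector of concrete windows, same length as the
#'   pattern.
#' @param pam_pattern IUPAC pattern string (e.g. `"NGG"`, `"NRR"`).
#' @return Logical vector.
#' @examples
#' match_pam(c("AGG", "TGA", "TAG"), "NGG") # TRUE FALSE FALSE
#' @export
match_pam <- function(window, pam_pattern) {
  check_pam_pattern(pam_pattern)
  if (!is.character(window)) abort("`window` must be character.")
  if (any(nchar(window) != nchar(pam_pattern))) {
    abort("window and PAM pattern must have equal length.")
  }
  .match_pam_cpp(toupper(window), toupper(pam_pattern))
}

#' Scan a transcriptome for guide binding sites
#'
#' Slides the protospacer+PAM window over every contig (and, by default, its
#' reverse complement) and reports every locus whose PAM matches the IUPAC
#' pattern exactly and whose protospacer carries at most `max_mm` mismatches.
#' Mismatches are counted over the protospacer only. Coordinates are 0-based
#' forward-strand positions of the leftmost base of the protospacer+PAM
#' window; `site_sequence` is read 5'->3' on the binding strand with
#' mismatched protospacer bases lowercased (Cas-OFFinder style).
#'
#' @param transcriptome Data frame with columns `contig_id`, `sequence`
#'   (see [read_transcriptome()]).
#' @param guide A [guide_spec()].
#' @param config A [scan_config()]; when `NULL`, the guide's own PAM with the
#'   optimized defaults (`max_mm = 8`, both strands) is used.
#' @return A tibble with columns `guide_id`, `contig_id`, `start`, `strand`,
#'   `site_sequence`, `mm_count`, `is_on_target` (`mm_count == 0`), ordered by
#'   contig (input order), then start, then strand (`+` before `-`).
#' @examples
#' tx <- tibble::tibble(contig_id = "tx1",
#'                      sequence = paste0(strrep("T", 30),
#'                                        "AGATTCTGGGTGGAAGCGCC", "TGG",
#'                                        strrep("CA", 15)))
#' g <- guide_spec("AGATTCTGGGTGGAAGCGCC")
#' scan_transcriptome(tx, g)
#' @export
scan_transcriptome <- function(transcriptome, guide, config = NULL) {
  transcriptome <- check_transcriptome(transcriptome)
  if (!inherits(guide, "guide_spec")) abort("`guide` must be a guide_spec.")
  if (is.null(config)) config <- scan_config(pam = guide$pam)
  if (!inherits(config, "scan_config")) abort("`config` must be a scan_config.")

  res <- .scan_sequences_cpp(transcriptome$sequence, guide$protospacer,
                             config$pam, config$max_mm, config$both_strands)
  tibble(
    guide_id = rep(guide$guide_id, length(res$start)),
    contig_id = transcriptome$contig_id[res$contig_index],
    start = res$start,
    strand = res$strand,
    site_sequence = res$site_sequence,
    mm_count = res$mm_count,
    is_on_target = res$mm_count == 0L
  )
}

check_transcriptome <- function(transcriptome) {
  if (!is.data.frame(transcriptome) ||
      !all(c("contig_id", "sequence") %in% names(transcriptome))) {
    abort("`transcriptome` must be a data frame with columns contig_id, sequence.")
  }
  if (anyDuplicated(transcriptome$contig_id)) {
    abort("contig_ids must be unique.")
  }
  if (any(is.na(transcriptome$sequence) | nchar(transcriptome$sequence) == 0L)) {
    abort("contig sequences must be non-empty.")
  }
  as_tibble(transcriptome)
}

#' Reverse-complement nucleotide strings
#'
#' IUPAC-aware; unknown characters become `N`. Case is uppercased.
#'
#' @param x Character vector.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  up <- toupper(x)
  comp <- chartr("ACGTURYSWKMBDHVN", "TGCAAYRSWMKVHDBN", up)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), character(1))
}
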