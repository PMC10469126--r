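# Independent brute-force oracles, deliberately coded differently from the
# package internals: plain positional vectors, minus strand handled by
# scanning the reverse-complemented sequence and mirroring coordinates.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  b <- strsplit(toupper(seq), "")[[1]]
  cb <- comp[b]
  cb[is.na(cb)] <- "N"
  paste(rev(cb), collapse = "")
}

oracle_mm <- function(candidate, protospacer) {
  a <- strsplit(toupper(candidate), "")[[1]]
  p <- strsplit(toupper(protospacer), "")[[1]]
  stopifnot(length(a) == length(p))
  sum(a != p | !(a %in% c("A", "C", "G", "T")))
}

# all windows on one strand of one sequence; start is 0-based on the strand
# being scanned
oracle_scan_strand <- function(seq, protospacer, pam, max_mm) {
  b <- strsplit(toupper(seq), "")[[1]]
  P <- nchar(protospacer)
  K <- nchar(pam)
  L <- P + K
  n <- length(b)
  if (n < L) return(data.frame(start = integer(), mm = integer()))
  starts <- 0:(n - L)
  pb <- strsplit(protospacer, "")[[1]]
  concrete <- b %in% c("A", "C", "G", "T")
  mm <- integer(length(starts))
  for (j in seq_len(P)) {
    at <- starts + j
    mm <- mm + as.integer(b[at] != pb[j] | !concrete[at])
  }
  pamv <- strsplit(toupper(pam), "")[[1]]
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(K)) {
    at <- starts + P + j
    ok <- ok & (b[at] %in% ORACLE_IUPAC[[pamv[j]]])
  }
  keep <- ok & mm <= max_mm
  data.frame(start = starts[keep], mm = mm[keep])
}

oracle_scan <- function(transcriptome, protospacer, pam, max_mm,
                        both_strands = TRUE) {
  L <- nchar(protospacer) + nchar(pam)
  out <- lapply(seq_len(nrow(transcriptome)), function(i) {
    seq <- transcriptome$sequence[i]
    fwd <- oracle_scan_strand(seq, protospacer, pam, max_mm)
    fwd$strand <- rep("+", nrow(fwd))
    res <- fwd
    if (both_strands) {
      rev <- oracle_scan_strand(oracle_revcomp(seq), protospacer, pam, max_mm)
      if (nrow(rev) > 0) {
        rev$start <- nchar(seq) - L - rev$start
        rev$strand <- "-"
        res <- rbind(fwd, rev)
      }
    }
    if (nrow(res) == 0) return(NULL)
    res$contig_id <- transcriptome$contig_id[i]
    res
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(contig_id = character(), start = integer(),
                      strand = character(), mm = integer()))
  }
  out[order(out$contig_id, out$start, out$strand),
      c("contig_id", "start", "strand", "mm")]
}

site_key <- function(df, mm_col = "mm_count") {
  sort(paste(df$contig_id, df$start, df$strand, df[[mm_col]]))
}

# direct re-evaluation of the D-index definition by explicit looping
oracle_d_index <- function(counts, m_max = 8) {
  total <- 0
  for (m in 0:m_max) {
    nm <- counts[as.character(m)]
    if (!is.na(nm)) total <- total + as.numeric(nm) * exp(4 - m)
  }
  total
}

# triple-loop DANGER-table construction: for each GO term and mismatch
# number, count distinct genes with at least one site at that m
oracle_danger <- function(sites, annotation, m_max = 8) {
  sites <- sites[!is.na(sites$gene_id) & sites$mm_count <= m_max, ]
  rows <- list()
  for (go in sort(unique(annotation$go_id))) {
    genes_go <- unique(annotation$gene_id[annotation$go_id == go])
    for (m in 0:m_max) {
      genes_m <- unique(sites$gene_id[sites$mm_count == m])
      n <- length(intersect(genes_go, genes_m))
      if (n > 0) rows[[length(rows) + 1]] <- data.frame(go_id = go, m = m, n_genes = n)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(go_id = character(), m = integer(), n_genes = integer()))
  }
  do.call(rbind, rows)
}

random_protospacer <- function(len = 20) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_transcriptome <- function(n_contigs, len_range, prefix = "C") {
  lens <- sample(seq(len_range[1], len_range[2]), n_contigs, replace = TRUE)
  tibble::tibble(
    contig_id = sprintf("%s%03d", prefix, seq_len(n_contigs)),
    sequence = vapply(lens, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
  )
}
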