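guide <- guide_spec("AGATTCTGGGTGGAAGCGCC", pam = "NGG", guide_id = "g")

test_that("mismatch counting reproduces the published off-target comparisons", {
  proto <- "AGATTCTGGGTGGAAGCGCC"
  # ALK and GBA2 candidate protospacers vs the GRIN2B-REV guide
  expect_identical(count_mismatches("GCAGACTGGTTGGAAGCACC", proto), 6L)
  expect_identical(count_mismatches("CCCTTCCGGCCGGAAGCGCC", proto), 6L)
  expect_identical(count_mismatches(proto, proto), 0L)
})

test_that("mismatch counting equals the positional oracle on random pairs", {
  set.seed(11)
  for (i in 1:100) {
    a <- random_protospacer(20)
    b <- random_protospacer(20)
    expect_identical(count_mismatches(a, b), oracle_mm(a, b))
  }
  # ambiguous candidate bases always mismatch
  expect_identical(count_mismatches("NGATTCTGGGTGGAAGCGCC",
                                    "AGATTCTGGGTGGAAGCGCC"), 1L)
  expect_identical(count_mismatches("NGNTTCTGGGTGGAAGCGCN",
                                    "AGATTCTGGGTGGAAGCGCC"), 3L)
  expect_error(count_mismatches("ACGT", "AGATTCTGGGTGGAAGCGCC"),
               "equal length|lengths differ")
  expect_error(count_mismatches("AGATTCTGGGTGGAAGCGCC",
                                "AGATTCTGGGTGGAAGCGCN"), "A/C/G/T")
})

test_that("PAM matching follows IUPAC sets and rejects ambiguity in the window", {
  expect_true(match_pam("AGG", "NGG"))
  expect_false(match_pam("TGA", "NGG"))
  expect_true(match_pam("TAG", "NRR"))
  expect_equal(match_pam(c("AGG", "CGG", "GGG", "TGG"), "NGG"), rep(TRUE, 4))
  expect_false(match_pam("NGG", "NGG")) # N in the window never matches
  expect_error(match_pam("AGG", "XGG"), "IUPAC")
  expect_error(match_pam("AG", "NGG"), "equal length")
})

test_that("planted sites are found with correct coordinates on both strands", {
  window <- paste0(guide$protospacer, "TGG")
  set.seed(3)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  fwd <- tibble::tibble(contig_id = "f",
                        sequence = paste0(pad(100), window, pad(377)))
  hits <- scan_transcriptome(fwd, guide, scan_config("NGG", 0))
  expect_identical(hits$start, 100L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$mm_count, 0L)
  expect_true(all(hits$is_on_target))
  expect_identical(hits$site_sequence, window)

  rev <- tibble::tibble(contig_id = "r",
                        sequence = paste0(pad(60), oracle_revcomp(window), pad(40)))
  rhits <- scan_transcriptome(rev, guide, scan_config("NGG", 0))
  expect_identical(rhits$start, 60L)
  expect_identical(rhits$strand, "-")
  expect_identical(rhits$site_sequence, window)
})

test_that("mismatched protospacer bases are lowercased in the site sequence", {
  mutated <- "CGATTCTGGGTGGAAGCGCA" # positions 1 and 20 changed
  tx <- tibble::tibble(contig_id = "m",
                       sequence = paste0(strrep("T", 25), mutated, "AGG",
                                         strrep("T", 25)))
  hits <- scan_transcriptome(tx, guide, scan_config("NGG", 3))
  expect_identical(hits$mm_count, 2L)
  expect_identical(hits$site_sequence, "cGATTCTGGGTGGAAGCGCaAGG")
})

test_that("scanning equals the exhaustive sliding-window oracle", {
  set.seed(21)
  for (case in 1:12) {
    tx <- random_transcriptome(5, c(200, 500))
    proto <- random_protospacer(sample(19:20, 1))
    g <- guide_spec(proto, pam = "NGG")
    for (pam in c("NGG", "NRR")) {
      for (mm in c(3L, 8L, 11L)) {
        got <- scan_transcriptome(tx, g, scan_config(pam, mm))
        want <- oracle_scan(tx, proto, pam, mm)
        expect_identical(site_key(got), site_key(want, "mm"))
      }
    }
  }
})

test_that("site sets are monotone in max_mm", {
  set.seed(5)
  tx <- random_transcriptome(10, c(300, 600))
  prev <- NULL
  for (mm in 0:11) {
    cur <- site_key(scan_transcriptome(tx, guide, scan_config("NRR", mm)))
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("scanning the reverse-complemented transcriptome mirrors strands and coordinates", {
  set.seed(6)
  tx <- random_transcriptome(6, c(200, 400))
  cfg <- scan_config("NRR", 9)
  a <- scan_transcriptome(tx, guide, cfg)
  rc <- tx
  rc$sequence <- vapply(tx$sequence, oracle_revcomp, character(1), USE.NAMES = FALSE)
  b <- scan_transcriptome(rc, guide, cfg)
  L <- nchar(guide$protospacer) + 3L
  lens <- setNames(nchar(tx$sequence), tx$contig_id)
  mirrored <- data.frame(
    contig_id = b$contig_id,
    start = lens[b$contig_id] - L - b$start,
    strand = ifelse(b$strand == "+", "-", "+"),
    mm_count = b$mm_count
  )
  expect_identical(site_key(a), site_key(mirrored))
})

test_that("zero-mismatch sites are exactly the perfect protospacer+PAM occurrences", {
  set.seed(8)
  tx <- random_transcriptome(4, c(300, 500))
  tx$sequence[2] <- paste0(tx$sequence[2], guide$protospacer, "CGG")
  hits <- scan_transcriptome(tx, guide, scan_config("NGG", 8))
  on <- hits[hits$mm_count == 0L, ]
  want <- oracle_scan(tx, guide$protospacer, "NGG", 0)
  expect_identical(site_key(on), site_key(want, "mm"))
  expect_true(all(hits$is_on_target == (hits$mm_count == 0L)))
})

test_that("degenerate inputs are handled", {
  empty <- tibble::tibble(contig_id = character(), sequence = character())
  expect_identical(nrow(scan_transcriptome(empty, guide)), 0L)
  short <- tibble::tibble(contig_id = "s", sequence = "ACGTACGT")
  expect_identical(nrow(scan_transcriptome(short, guide)), 0L)
  # ambiguity codes in contigs: mismatch in protospacer, never a PAM match
  amb <- tibble::tibble(
    contig_id = c("pam_n", "proto_n"),
    sequence = c(paste0(guide$protospacer, "NGG"),
                 paste0("N", substr(guide$protospacer, 2, 20), "AGG")))
  hits <- scan_transcriptome(amb, guide, scan_config("NGG", 2))
  expect_identical(hits$contig_id, "proto_n")
  expect_identical(hits$mm_count, 1L)
})

test_that("guide and config validation rejects malformed input", {
  expect_error(guide_spec("ACGT"), "19 or 20")
  expect_error(guide_spec("AGATTCTGGGTGGAAGCGCN"), "A/C/G/T")
  expect_error(guide_spec("AGATTCTGGGTGGAAGCGCC", pam = "G"), "length >= 2")
  expect_error(scan_config("NGG", -1), "non-negative")
  expect_error(scan_config("QGG", 8), "IUPAC")
  p <- scan_preset("optimized")
  expect_identical(c(p$pam, p$max_mm), c("NGG", "8"))
  p <- scan_preset("approximate")
  expect_identical(c(p$pam, p$max_mm), c("NRR", "11"))
})

test_that("Cas-OFFinder tables round-trip through disk", {
  set.seed(9)
  tx <- random_transcriptome(3, c(300, 400))
  hits <- scan_transcriptome(tx, guide, scan_config("NRR", 10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_offtarget_table(hits, path, guide)
  back <- read_offtarget_table(path)
  expect_identical(site_key(back), site_key(hits))
  expect_identical(unique(back$query), paste0(guide$protospacer, guide$pam))
  expect_identical(back$site_sequence[order(back$contig_id, back$start, back$strand)],
                   hits$site_sequence[order(hits$contig_id, hits$start, hits$strand)])
  # header variant
  write_offtarget_table(hits, path, guide, header = TRUE)
  expect_identical(site_key(read_offtarget_table(path, header = TRUE)),
                   site_key(hits))
})
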