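test_that("the scanner recovers exactly the planted site list", {
  g <- example_guide()
  plant <- tibble::tibble(mm_count = c(0L, 3L, 3L, 3L, 3L, 3L),
                          strand = c("+", "+", "-", "*", "*", "*"))
  sim <- simulate_transcriptome(g, n_contigs = 12, length_range = c(300, 500),
                                plant_spec = plant, seed = 81)
  found <- scan_transcriptome(sim$transcriptome, g, scan_config("NGG", 8))
  expect_identical(site_key(found), site_key(sim$truth))
  expect_identical(sum(found$mm_count == 0L), 1L)
  expect_identical(sum(found$mm_count == 3L), 5L)
  # truth site sequences carry the planted windows
  expect_true(all(nchar(sim$truth$site_sequence) == 23L))
})

test_that("summary-form plant specs and per-contig placement work", {
  g <- example_guide()
  plant <- tibble::tibble(mm_count = c(2L, 5L), n_sites = c(3L, 2L),
                          strand = "*")
  sim <- simulate_transcriptome(g, n_contigs = 10, length_range = c(300, 400),
                                plant_spec = plant, seed = 82)
  expect_identical(sort(sim$truth$mm_count), c(2L, 2L, 2L, 5L, 5L))
  placed <- tibble::tibble(contig = c(4L, 4L), mm_count = c(1L, 2L),
                           strand = "+")
  sim2 <- simulate_transcriptome(g, n_contigs = 5, length_range = c(200, 250),
                                 plant_spec = placed, seed = 83)
  expect_identical(unique(sim2$truth$contig_id),
                   sim2$transcriptome$contig_id[4])
  crowded <- tibble::tibble(contig = c(1L, 1L), mm_count = c(1L, 2L),
                            strand = "+")
  expect_error(
    simulate_transcriptome(g, n_contigs = 2, length_range = c(40, 40),
                           plant_spec = crowded, seed = 1),
    "infeasible")
})

test_that("transcriptome generation is byte-deterministic under the seed", {
  g <- example_guide()
  plant <- tibble::tibble(mm_count = 3L, n_sites = 4L, strand = "*")
  a <- simulate_transcriptome(g, 8, c(300, 400), plant, seed = 84)
  b <- simulate_transcriptome(g, 8, c(300, 400), plant, seed = 84)
  expect_identical(a, b)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "a.fasta")
  fb <- file.path(dir, "b.fasta")
  write_transcriptome(a$transcriptome, fa)
  write_transcriptome(b$transcriptome, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
  c_ <- simulate_transcriptome(g, 8, c(300, 400), plant, seed = 85)
  expect_false(identical(a$transcriptome$sequence, c_$transcriptome$sequence))
})

test_that("noiseless expression reproduces fold changes exactly", {
  tx <- sprintf("t%02d", 1:20)
  down <- tx[1:5]
  ex <- simulate_expression(tx, down, fold_change = 0.2, noise_cv = 0,
                            seed = 86)
  scr <- screen_expression(ex$tpm, ex$manifest, t = 0.4)
  expect_equal(scr$tpm_ratio[scr$transcript_id %in% down], rep(0.2, 5),
               tolerance = 1e-12)
  expect_equal(scr$tpm_ratio[!scr$transcript_id %in% down], rep(1, 15),
               tolerance = 1e-12)
  expect_identical(scr$dtpm, scr$transcript_id %in% down)
  flat <- simulate_expression(tx, down, fold_change = 1.0, noise_cv = 0,
                              seed = 86)
  scr2 <- screen_expression(flat$tpm, flat$manifest, t = 0.4)
  expect_false(any(scr2$dtpm))
  expect_error(simulate_expression(tx, down, noise_cv = -1), ">= 0")
})

test_that("planted downregulation labels are recovered under realistic noise", {
  tx <- sprintf("t%02d", 1:20)
  down <- tx[1:8]
  hits <- 0L
  total <- 0L
  for (s in 1:40) {
    ex <- simulate_expression(tx, down, fold_change = 0.25, noise_cv = 0.1,
                              n_wt = 3, n_edited = 3, seed = 900 + s)
    scr <- screen_expression(ex$tpm, ex$manifest, t = 0.4)
    hits <- hits + sum(scr$dtpm[scr$transcript_id %in% down])
    total <- total + length(down)
  }
  expect_gte(hits / total, 0.95)
})

test_that("annotation generation plants the term on exactly the planted genes", {
  tx <- sprintf("t%02d", 1:30)
  ann <- simulate_annotations(tx, n_go_terms = 10, planted_term = "GO:0999999",
                              planted_transcripts = tx[1:4], seed = 87)
  pg <- ann$gene_map$gene_id[ann$gene_map$transcript_id %in% tx[1:4]]
  with_term <- ann$annotation$gene_id[ann$annotation$go_id == "GO:0999999"]
  expect_setequal(with_term, pg)
  again <- simulate_annotations(tx, n_go_terms = 10, planted_term = "GO:0999999",
                                planted_transcripts = tx[1:4], seed = 87)
  expect_identical(ann, again)
})

test_that("random gene-term assignment stays within binomial bounds", {
  tx <- sprintf("t%03d", 1:400)
  ann <- simulate_annotations(tx, n_go_terms = 20, terms_per_gene = c(2, 2),
                              seed = 88)
  counts <- table(ann$annotation$go_id)
  # each term: Binomial(400, 2/20), mean 40, sd ~6; +-6 sd bounds
  expect_true(all(counts > 40 - 36 & counts < 40 + 36))
  expect_identical(length(counts), 20L)
})

test_that("preset datasets are deterministic and internally consistent", {
  ds <- simulate_dataset("mixed", seed = 4)
  ds2 <- simulate_dataset("mixed", seed = 4)
  expect_identical(ds$transcriptome, ds2$transcriptome)
  expect_identical(ds$tpm, ds2$tpm)
  expect_identical(ds$annotation, ds2$annotation)
  # planted truth is re-derivable by the scanner
  found <- scan_transcriptome(ds$transcriptome, ds$guide, ds$scan)
  expect_identical(site_key(found), site_key(ds$truth))
  # exactly one on-target, on the declared transcript
  on <- found[found$is_on_target, ]
  expect_identical(on$contig_id, ds$on_target_transcript)
  # gene map and annotation reference the same universe
  expect_true(all(ds$annotation$gene_id %in% ds$gene_map$gene_id))
  expect_setequal(ds$gene_map$transcript_id, ds$transcriptome$contig_id)
})

test_that("datasets round-trip through the on-disk formats", {
  ds <- simulate_dataset("mixed", seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_identical(read_transcriptome(paths[["fasta"]]), ds$transcriptome)
  expect_equal(as.data.frame(read_tpm_matrix(paths[["tpm"]])),
               as.data.frame(ds$tpm))
  expect_equal(as.data.frame(read_gene_map(paths[["gene_map"]])),
               as.data.frame(ds$gene_map))
  expect_equal(as.data.frame(read_go_annotation(paths[["annotation"]])),
               as.data.frame(ds$annotation))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_identical(truth$planted_term, ds$planted_term)
})
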