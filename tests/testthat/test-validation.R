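val_fixture <- function(n_tx = 60, n_sites = 150, n_go = 12, seed = 71,
                        down_rate = 0.3) {
  set.seed(seed)
  tx <- sprintf("t%03d", seq_len(n_tx))
  gene_map <- tibble::tibble(transcript_id = tx,
                             gene_id = sprintf("G%03d", seq_len(n_tx)))
  sites <- tibble::tibble(
    contig_id = sample(tx, n_sites, replace = TRUE),
    start = sample.int(5000, n_sites, replace = TRUE),
    strand = sample(c("+", "-"), n_sites, replace = TRUE),
    mm_count = sample(1:8, n_sites, replace = TRUE,
                      prob = c(1, 1, 2, 3, 4, 5, 6, 6))
  )
  sites$transcript_id <- sites$contig_id
  sites <- dplyr::left_join(sites, gene_map, by = "transcript_id")
  screen <- tibble::tibble(
    transcript_id = tx,
    tpm_ratio = stats::runif(n_tx),
    dtpm = stats::runif(n_tx) < down_rate,
    dde = FALSE
  )
  go <- sprintf("GO:%07d", seq_len(n_go))
  annotation <- dplyr::distinct(dplyr::bind_rows(lapply(gene_map$gene_id, function(g) {
    k <- sample(1:3, 1)
    idx <- sample.int(n_go, k)
    tibble::tibble(gene_id = g, go_id = go[idx], go_term = paste("term", idx),
                   category = rep(c("BP", "CC", "MF"), length.out = n_go)[idx])
  })))
  list(sites = sites, screen = screen, annotation = annotation,
       gene_map = gene_map)
}

# independent pseudo-D computation: explicit shuffle + triple-loop table +
# closed-form sum, for the terms of a null distribution
oracle_pseudo_d <- function(fx, seed, terms, m_max = 8) {
  sh <- shuffle_profiles(fx$screen, fx$sites, seed)
  flagged <- sh$screen$transcript_id[sh$screen$dtpm]
  del <- sh$sites[sh$sites$transcript_id %in% flagged, ]
  tab <- oracle_danger(del, fx$annotation, m_max = m_max)
  vapply(terms, function(go) {
    sub <- tab[tab$go_id == go, ]
    if (nrow(sub) == 0) 0 else oracle_d_index(setNames(sub$n_genes, sub$m), m_max)
  }, numeric(1))
}

test_that("shuffling is deterministic and conserves both multisets", {
  fx <- val_fixture()
  a <- shuffle_profiles(fx$screen, fx$sites, 99L)
  b <- shuffle_profiles(fx$screen, fx$sites, 99L)
  expect_identical(a, b)
  expect_identical(sort(a$sites$mm_count), sort(fx$sites$mm_count))
  expect_identical(sum(a$screen$dtpm), sum(fx$screen$dtpm))
  expect_identical(sum(a$screen$dde), sum(fx$screen$dde))
  c_ <- shuffle_profiles(fx$screen, fx$sites, 100L)
  expect_false(identical(a$sites$mm_count, c_$sites$mm_count))
  # columns other than the shuffled labels stay put
  expect_identical(a$sites$contig_id, fx$sites$contig_id)
  expect_identical(a$screen$transcript_id, fx$screen$transcript_id)
})

test_that("label shuffles behave like uniform permutations", {
  n <- 100L
  screen <- tibble::tibble(transcript_id = sprintf("t%03d", 1:n),
                           dtpm = rep(FALSE, n), dde = rep(FALSE, n))
  sites <- tibble::tibble(transcript_id = "t001", contig_id = "t001",
                          mm_count = 1:n)
  fixed <- integer(150)
  for (s in seq_len(150)) {
    sh <- shuffle_profiles(screen, sites, 1000L + s)
    fixed[s] <- sum(sh$sites$mm_count == 1:n)
  }
  # a uniform permutation has on average one fixed point and is a
  # derangement with probability ~ 1/e
  expect_gt(mean(fixed), 0.65)
  expect_lt(mean(fixed), 1.35)
  expect_gt(mean(fixed == 0), 0.23)
  expect_lt(mean(fixed == 0), 0.51)
})

test_that("a flagless screen yields an all-zero null", {
  fx <- val_fixture()
  fx$screen$dtpm <- FALSE
  null <- build_null(fx$sites, fx$screen, fx$annotation, "dTPM",
                     config = validation_config(n_null = 20, base_seed = 5))
  expect_true(all(null$pseudo == 0))
  expect_true(all(null$mean == 0))
  expect_true(all(null$sd == 0))
})

test_that("the null distribution is a pure function of the seed", {
  fx <- val_fixture()
  cfg <- validation_config(n_null = 30, base_seed = 17)
  a <- build_null(fx$sites, fx$screen, fx$annotation, "dTPM", config = cfg)
  b <- build_null(fx$sites, fx$screen, fx$annotation, "dTPM", config = cfg)
  expect_identical(a$pseudo, b$pseudo)
  expect_identical(a$threshold, b$threshold)
  expect_identical(a$seeds, 17L + 1:30)
})

test_that("fast pseudo-D values equal an independently coded permutation pipeline", {
  fx <- val_fixture(n_tx = 40, n_sites = 90, n_go = 8, seed = 72)
  cfg <- validation_config(n_null = 15, base_seed = 200)
  null <- build_null(fx$sites, fx$screen, fx$annotation, "dTPM", config = cfg)
  for (j in seq_len(cfg$n_null)) {
    want <- oracle_pseudo_d(fx, cfg$base_seed + j, null$terms$go_id)
    expect_equal(unname(null$pseudo[, j]), unname(want), tolerance = 1e-12)
  }
})

test_that("significance needs strict exceedance of both threshold and mean", {
  fx <- val_fixture()
  fx$screen$dtpm <- FALSE # degenerate null: mean 0, sd 0
  null <- build_null(fx$sites, fx$screen, fx$annotation, "dTPM",
                     config = validation_config(n_null = 10, base_seed = 1))
  go <- null$terms$go_id[1:2]
  prof <- tibble::tibble(go_id = go, go_term = "x", category = "BP",
                         d_index = c(10, 0))
  calls <- call_significance(prof, null, L = 0.05)
  expect_identical(calls$significant, c(TRUE, FALSE))
  # a D-index equal to the null mean is never significant
  real_null <- build_null(val_fixture()$sites, val_fixture()$screen,
                          val_fixture()$annotation, "dTPM",
                          config = validation_config(n_null = 50, base_seed = 3))
  at_mean <- tibble::tibble(go_id = real_null$terms$go_id[1], go_term = "x",
                            category = "BP",
                            d_index = real_null$mean[1])
  expect_false(call_significance(at_mean, real_null, L = 0.5)$significant)
  # unknown terms are compared against a zero null
  ghost <- tibble::tibble(go_id = "GO:7777777", go_term = "x", category = "BP",
                          d_index = 0.1)
  expect_true(call_significance(ghost, null, L = 0.05)$significant)
})

test_that("the significant set shrinks as L shrinks", {
  fx <- val_fixture(seed = 73)
  cfg <- validation_config(n_null = 60, base_seed = 11)
  null <- build_null(fx$sites, fx$screen, fx$annotation, "dTPM", config = cfg)
  del <- find_deleterious(fx$sites, fx$screen, "dTPM")
  prof <- d_index_profile(suppressMessages(build_danger_table(del, fx$annotation)))
  for (pair in list(c(1e-15, 0.5), c(0.01, 0.2), c(1e-6, 0.05))) {
    small <- call_significance(prof, null, L = pair[1])
    large <- call_significance(prof, null, L = pair[2])
    expect_true(all(small$threshold >= large$threshold))
    expect_true(all(!small$significant | large$significant))
  }
})

test_that("false-detection accounting follows its definitions", {
  fx <- val_fixture(seed = 74, down_rate = 0.4)
  cfg <- validation_config(n_null = 40, n_extra = 10, base_seed = 7, L = 0.5)
  null <- build_null(fx$sites, fx$screen, fx$annotation, "dTPM", config = cfg)
  del <- find_deleterious(fx$sites, fx$screen, "dTPM")
  prof <- d_index_profile(suppressMessages(build_danger_table(del, fx$annotation)))
  rep1 <- estimate_false_detection(fx$sites, fx$screen, fx$annotation, null,
                                   prof, "dTPM", config = cfg)
  expect_identical(rep1$n_new_pseudo, 10L * nrow(prof))
  expect_equal(rep1$false_positive_rate,
               rep1$n_significant_pseudo / rep1$n_new_pseudo)
  expect_equal(rep1$expected_false,
               rep1$false_positive_rate * rep1$n_d_indices)
  expect_equal(rep1$expected_true_total_minus_false,
               rep1$n_d_indices - rep1$expected_false)
  expect_equal(rep1$expected_true_significant_minus_false,
               max(0, rep1$n_significant - rep1$expected_false))
  rep2 <- estimate_false_detection(fx$sites, fx$screen, fx$annotation, null,
                                   prof, "dTPM", config = cfg)
  expect_identical(rep1, rep2)
  # stricter L can only reduce the rate
  strict <- estimate_false_detection(fx$sites, fx$screen, fx$annotation, null,
                                     prof, "dTPM", config = cfg, L = 1e-15)
  expect_lte(strict$false_positive_rate, rep1$false_positive_rate)
})

test_that("configuration guards reject unusable settings", {
  expect_error(validation_config(n_null = 1), ">= 2")
  expect_error(validation_config(L = 0), "\\(0, 1\\)")
  expect_error(validation_config(L = 1), "\\(0, 1\\)")
  expect_error(validation_config(base_seed = .Machine$integer.max - 50L),
               "2\\^31")
  fx <- val_fixture()
  cfg0 <- validation_config(n_extra = 0, base_seed = 2)
  null <- build_null(fx$sites, fx$screen, fx$annotation, "dTPM", config = cfg0)
  del <- find_deleterious(fx$sites, fx$screen, "dTPM")
  prof <- d_index_profile(suppressMessages(build_danger_table(del, fx$annotation)))
  expect_error(estimate_false_detection(fx$sites, fx$screen, fx$annotation,
                                        null, prof, "dTPM", config = cfg0),
               "n_extra")
})

test_that("the whole validation is reproducible end to end", {
  fx <- val_fixture(seed = 75)
  cfg <- validation_config(n_null = 25, n_extra = 5, L = 0.5, base_seed = 9)
  a <- suppressWarnings(suppressMessages(
    validate_d_index(fx$sites, fx$screen, fx$annotation, "dTPM", config = cfg)))
  b <- suppressWarnings(suppressMessages(
    validate_d_index(fx$sites, fx$screen, fx$annotation, "dTPM", config = cfg)))
  expect_identical(glance(a), glance(b))
  expect_identical(tidy(a), tidy(b))
  expect_s3_class(tidy(a), "tbl_df")
  expect_identical(nrow(glance(a)), 1L)
})
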