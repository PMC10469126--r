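#' Validation settings for the permutation test
#'
#' @param n_null Number of shuffled datasets forming the null (default 100).
#' @param n_extra Number of additional shuffled datasets, with seeds disjoint
#'   from the null seeds, used to estimate the false-detection rate
#'   (default 10).
#' @param L Confidence level parameter in (0, 1): a D-index is significant
#'   when it exceeds the upper bound of the parametric (1 - L) confidence
#'   interval of its null, i.e. `mean + qnorm(1 - L/2) * sd`, and exceeds the
#'   null mean. Presets in use are `5e-1` (permissive) and `1e-15`
#'   (stringent).
#' @param base_seed Integer seed; null permutations use seeds
#'   `base_seed + 1 .. base_seed + n_null` and the extra datasets
#'   `base_seed + n_null + 1 .. base_seed + n_null + n_extra`, guaranteeing
#'   disjointness.
#' @return An object of class `validation_config`.
#' @export
validation_config <- function(n_null = 100L, n_extra = 10L, L = 1e-15,
                              base_seed = 0L) {
  n_null <- as.integer(n_null)
  n_extra <- as.integer(n_extra)
  if (is.na(n_null) || n_null < 2L) abort("`n_null` must be >= 2 (sd undefined below).")
  if (is.na(n_extra) || n_extra < 0L) abort("`n_extra` must be >= 0.")
  if (!is.numeric(L) || length(L) != 1L || L <= 0 || L >= 1) {
    abort("`L` must lie in (0, 1).")
  }
  base_seed <- as.integer(base_seed)
  if (is.na(base_seed) || base_seed < 0L ||
      as.numeric(base_seed) + n_null + n_extra >= 2^31) {
    abort("`base_seed` must be a non-negative integer small enough that all derived seeds stay below 2^31.")
  }
  structure(list(n_null = n_null, n_extra = n_extra, L = L,
                 base_seed = base_seed),
            class = "validation_config")
}

z_from_L <- function(L) qnorm(L / 2, lower.tail = FALSE)

with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

#' Shuffle expression and off-target profiles
#'
#' One seeded permutation breaks both associations the D-index relies on:
#' the downregulation flags (`dtpm`/`dde` rows of the screen) are permuted
#' uniformly at random across all transcripts, and the mismatch-count labels
#' are permuted uniformly at random across all site rows. The multiset of
#' flags and the multiset of mismatch counts are preserved exactly, and the
#' output is a pure function of the seed.
#'
#' @param screen Screen tibble with `transcript_id`, `dtpm`, `dde`.
#' @param sites Site tibble with an `mm_count` column.
#' @param seed Integer seed.
#' @return `list(screen = , sites = )` with shuffled columns.
#' @export
shuffle_profiles <- function(screen, sites, seed) {
  screen <- as_tibble(screen)
  sites <- as_tibble(sites)
  if (!all(c("transcript_id", "dtpm", "dde") %in% names(screen))) {
    abort("`screen` needs transcript_id, dtpm, dde columns.")
  }
  if (!"mm_count" %in% names(sites)) abort("`sites` needs an mm_count column.")
  with_seed(seed, {
    perm_tx <- sample.int(nrow(screen))
    perm_site <- sample.int(nrow(sites))
    screen$dtpm <- screen$dtpm[perm_tx]
    screen$dde <- screen$dde[perm_tx]
    sites$mm_count <- sites$mm_count[perm_site]
    if ("is_on_target" %in% names(sites)) {
      sites$is_on_target <- sites$mm_count == 0L
    }
    list(screen = screen, sites = sites)
  })
}

# Precompute the index structures needed to evaluate one pseudo-D-index
# vector per permutation in O(sites + annotation pairs).
prepare_perm_kernel <- function(sites, screen, annotation, criterion, m_max) {
  sites <- as_tibble(sites)
  if (!"transcript_id" %in% names(sites)) sites$transcript_id <- sites$contig_id
  screen <- as_tibble(screen)
  annotation <- check_go_annotation(annotation)

  fl <- switch(criterion,
    dTPM = screen$dtpm,
    dDE = screen$dde,
    either = screen$dtpm | screen$dde
  )
  sites <- filter(sites, .data$transcript_id %in% screen$transcript_id,
                  .data$mm_count <= m_max)
  tx_idx <- match(sites$transcript_id, screen$transcript_id)

  genes <- sort(unique(sites$gene_id[!is.na(sites$gene_id)]))
  gene_idx <- match(sites$gene_id, genes)

  ann <- distinct(filter(annotation, .data$gene_id %in% genes),
                  .data$go_id, .data$go_term, .data$category, .data$gene_id)
  terms <- distinct(ann, .data$go_id, .data$go_term, .data$category) |>
    arrange(.data$go_id)
  list(
    flags = fl,
    site_tx_idx = tx_idx,
    site_gene_idx = gene_idx,
    site_mm = as.integer(sites$mm_count),
    n_tx = nrow(screen),
    n_sites = nrow(sites),
    n_genes = length(genes),
    terms = terms,
    ann_term_idx = match(ann$go_id, terms$go_id),
    ann_gene_idx = match(ann$gene_id, genes)
  )
}

# Pseudo-D-index vector (one value per kernel term) for given permuted flags
# and mm labels. A gene contributes exp(4 - m) once per *distinct* m among
# its deleterious sites; a term's value is the sum over its annotated genes.
kernel_pseudo_d <- function(kernel, fl_perm, mm_perm) {
  n_terms <- nrow(kernel$terms)
  d <- numeric(n_terms)
  if (kernel$n_sites == 0L || n_terms == 0L) return(d)
  down <- fl_perm[kernel$site_tx_idx]
  keep <- which(down & !is.na(kernel$site_gene_idx))
  if (length(keep) == 0L) return(d)
  key <- unique(kernel$site_gene_idx[keep] * 32L + mm_perm[keep])
  wg <- numeric(kernel$n_genes)
  agg <- rowsum(exp(4 - (key %% 32L)), key %/% 32L)
  wg[as.integer(rownames(agg))] <- agg[, 1]
  agg2 <- rowsum(wg[kernel$ann_gene_idx], kernel$ann_term_idx)
  d[as.integer(rownames(agg2))] <- agg2[, 1]
  d
}

kernel_permute <- function(kernel, seed) {
  with_seed(seed, {
    perm_tx <- sample.int(kernel$n_tx)
    perm_site <- sample.int(max(kernel$n_sites, 1L))
    list(fl = kernel$flags[perm_tx],
         mm = if (kernel$n_sites > 0L) kernel$site_mm[perm_site] else integer())
  })
}

#' Build the permutation null of pseudo-D-indices
#'
#' For each of `n_null` seeds, shuffles the expression and off-target
#' profiles ([shuffle_profiles()] semantics), recomputes the deleterious
#' sites, the DANGER table and the per-term D-index, and stores the resulting
#' pseudo-D-index. Terms absent from a given permutation contribute a pseudo
#' value of 0. Per term the null mean, population standard deviation and the
#' significance threshold `mean + qnorm(1 - L/2) * sd` are recorded. The term
#' universe is every GO term annotated to any gene carrying a candidate site,
#' so it is identical across permutations.
#'
#' @param sites Candidate site tibble, gene-attached and with the on-target
#'   gene already excluded (`gene_id`, `mm_count`, `transcript_id`).
#' @param screen Screen tibble from [screen_expression()].
#' @param annotation Gene-to-GO annotation tibble.
#' @param criterion Downregulation criterion: `"dTPM"`, `"dDE"` or
#'   `"either"`.
#' @param m_max Maximum mismatch number.
#' @param config A [validation_config()].
#' @return An object of class `null_distribution`: per-term pseudo values
#'   (`n_null` columns), `mean`, `sd`, `threshold`, plus the seeds used.
#' @export
build_null <- function(sites, screen, annotation,
                       criterion = c("dTPM", "dDE", "either"),
                       m_max = 8L, config = validation_config()) {
  criterion <- match.arg(criterion)
  if (!inherits(config, "validation_config")) {
    abort("`config` must be a validation_config.")
  }
  kernel <- prepare_perm_kernel(sites, screen, annotation, criterion, m_max)
  seeds <- config$base_seed + seq_len(config$n_null)
  pseudo <- matrix(0, nrow = nrow(kernel$terms), ncol = config$n_null)
  for (j in seq_along(seeds)) {
    p <- kernel_permute(kernel, seeds[j])
    pseudo[, j] <- kernel_pseudo_d(kernel, p$fl, p$mm)
  }
  mu <- rowMeans(pseudo)
  sd_pop <- sqrt(pmax(0, rowMeans(pseudo^2) - mu^2))
  structure(list(
    terms = kernel$terms,
    pseudo = pseudo,
    mean = mu,
    sd = sd_pop,
    threshold = mu + z_from_L(config$L) * sd_pop,
    L = config$L,
    n_null = config$n_null,
    seeds = seeds,
    criterion = criterion,
    m_max = as.integer(m_max)
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d GO terms x %d permutations (L = %g, %s)\n",
              nrow(x$terms), x$n_null, x$L, x$criterion))
  invisible(x)
}

#' Call significant D-indices against a permutation null
#'
#' A term's D-index is significant when it lies above the upper bound of the
#' (1 - L) confidence interval of its null distribution *and* above the null
#' mean (both strict). With a degenerate null (sd = 0) this reduces to
#' `d_index > mean`. Terms without a null entry are compared against mean 0,
#' sd 0.
#'
#' @param profile A [d_index_profile()] (or any data frame with `go_id` and
#'   `d_index`).
#' @param null A `null_distribution` from [build_null()].
#' @param L Significance level parameter; defaults to the level the null was
#'   built with.
#' @return A tibble `go_id`, `go_term`, `category`, `d_index`, `null_mean`,
#'   `null_sd`, `threshold`, `significant`.
#' @export
call_significance <- function(profile, null, L = NULL) {
  if (!inherits(null, "null_distribution")) {
    abort("`null` must come from build_null().")
  }
  L <- L %||% null$L
  if (L <= 0 || L >= 1) abort("`L` must lie in (0, 1).")
  prof <- as_tibble(profile)
  idx <- match(prof$go_id, null$terms$go_id)
  mu <- ifelse(is.na(idx), 0, null$mean[idx])
  sd <- ifelse(is.na(idx), 0, null$sd[idx])
  thr <- mu + z_from_L(L) * sd
  tibble(
    go_id = prof$go_id,
    go_term = prof$go_term,
    category = prof$category,
    d_index = prof$d_index,
    null_mean = mu,
    null_sd = sd,
    threshold = thr,
    significant = prof$d_index > thr & prof$d_index > mu
  )
}

#' Estimate the false-detection rate of the permutation test
#'
#' Generates `n_extra` freshly shuffled datasets (seeds disjoint from the
#' null seeds by construction), recomputes pseudo-D-indices for the terms
#' holding an observed D-index, and counts those meeting the significance
#' criterion against the existing null ("significant pseudo-D-indices"). The
#' false-positive rate is that count divided by the number of new
#' pseudo-D-indices (`n_extra` x number of terms with a D-index). Multiplying
#' the rate by the number of original D-indices gives the expected number of
#' false D-indices. Two conventions for the expected number of *true*
#' D-indices are reported: `total_minus_false` (all original D-indices minus
#' the expected false count) and `significant_minus_false` (significant
#' D-indices minus the expected false count, clamped at zero).
#'
#' @inheritParams build_null
#' @param null The `null_distribution` built from the same inputs.
#' @param profile The observed [d_index_profile()].
#' @param L Significance level parameter; defaults to the null's.
#' @return A one-row tibble of class `fdr_report`: `false_positive_rate`,
#'   `n_significant_pseudo`, `n_new_pseudo`, `n_d_indices`, `n_significant`,
#'   `expected_false`, `expected_true_total_minus_false`,
#'   `expected_true_significant_minus_false`, `L`.
#' @export
estimate_false_detection <- function(sites, screen, annotation, null, profile,
                                     criterion = c("dTPM", "dDE", "either"),
                                     m_max = 8L, config = validation_config(),
                                     L = NULL) {
  criterion <- match.arg(criterion)
  if (!inherits(null, "null_distribution")) abort("`null` must come from build_null().")
  if (config$n_extra < 1L) abort("`n_extra` must be >= 1 to estimate the rate.")
  L <- L %||% null$L
  extra_seeds <- config$base_seed + config$n_null + seq_len(config$n_extra)
  if (length(intersect(extra_seeds, null$seeds)) > 0L) {
    abort("extra seeds overlap the null seeds.")
  }
  kernel <- prepare_perm_kernel(sites, screen, annotation, criterion, m_max)
  if (!identical(kernel$terms$go_id, null$terms$go_id)) {
    abort("the null distribution was built from different inputs (term universe differs).")
  }

  obs_idx <- match(as_tibble(profile)$go_id, null$terms$go_id)
  if (anyNA(obs_idx)) abort("observed terms missing from the null term universe.")
  n_terms <- length(obs_idx)
  z <- z_from_L(L)
  thr <- null$mean[obs_idx] + z * null$sd[obs_idx]
  mu <- null$mean[obs_idx]

  n_sig_pseudo <- 0L
  for (seed in extra_seeds) {
    p <- kernel_permute(kernel, seed)
    d <- kernel_pseudo_d(kernel, p$fl, p$mm)[obs_idx]
    n_sig_pseudo <- n_sig_pseudo + sum(d > thr & d > mu)
  }
  n_new <- config$n_extra * n_terms
  rate <- if (n_new > 0L) n_sig_pseudo / n_new else 0
  sig <- call_significance(profile, null, L = L)
  n_sig <- sum(sig$significant)
  expected_false <- rate * n_terms
  out <- tibble(
    false_positive_rate = rate,
    n_significant_pseudo = n_sig_pseudo,
    n_new_pseudo = n_new,
    n_d_indices = n_terms,
    n_significant = n_sig,
    expected_false = expected_false,
    expected_true_total_minus_false = n_terms - expected_false,
    expected_true_significant_minus_false = max(0, n_sig - expected_false),
    L = L
  )
  class(out) <- c("fdr_report", class(out))
  out
}

#' Validate D-indices end to end
#'
#' Convenience wrapper: computes the observed deleterious sites, DANGER table
#' and D-index profile, builds the permutation null, calls significance at
#' the configured level, and (when `n_extra > 0`) estimates the
#' false-detection rate. The whole procedure is a pure function of its inputs
#' and `config$base_seed`.
#'
#' @inheritParams build_null
#' @return An object of class `danger_validation` with elements `profile`,
#'   `null`, `calls`, `fdr`, `config`, `criterion`, `m_max`. Use [tidy()] for
#'   the per-term table and [glance()] for the one-row summary.
#' @export
validate_d_index <- function(sites, screen, annotation,
                             criterion = c("dTPM", "dDE", "either"),
                             m_max = 8L, config = validation_config()) {
  criterion <- match.arg(criterion)
  deleterious <- find_deleterious(sites, screen, criterion = criterion)
  danger <- build_danger_table(deleterious, annotation, m_max = m_max)
  profile <- d_index_profile(danger, m_max = m_max)
  null <- build_null(sites, screen, annotation, criterion = criterion,
                     m_max = m_max, config = config)
  calls <- call_significance(profile, null, L = config$L)
  fdr <- if (config$n_extra > 0L && nrow(profile) > 0L) {
    estimate_false_detection(sites, screen, annotation, null, profile,
                             criterion = criterion, m_max = m_max,
                             config = config)
  } else {
    NULL
  }
  structure(list(profile = profile, null = null, calls = calls, fdr = fdr,
                 config = config, criterion = criterion,
                 m_max = as.integer(m_max)),
            class = "danger_validation")
}

#' @rdname validate_d_index
#' @param x A `danger_validation`.
#' @param ... Unused.
#' @export
tidy.danger_validation <- function(x, ...) {
  x$calls
}

#' @rdname validate_d_index
#' @export
glance.danger_validation <- function(x, ...) {
  out <- tibble(
    total_d_index = attr(x$profile, "total_d_index"),
    n_terms = attr(x$profile, "n_terms"),
    n_significant = sum(x$calls$significant),
    L = x$config$L,
    n_null = x$config$n_null,
    criterion = x$criterion
  )
  if (!is.null(x$fdr)) {
    out$false_positive_rate <- x$fdr$false_positive_rate
    out$expected_false <- x$fdr$expected_false
    out$expected_true_total_minus_false <- x$fdr$expected_true_total_minus_false
    out$expected_true_significant_minus_false <-
      x$fdr$expected_true_significant_minus_false
  }
  out
}

#' @export
print.danger_validation <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<danger_validation> %s: %d GO terms, total D-index %.4g, %d significant at L = %g\n",
    x$criterion, g$n_terms, g$total_d_index, g$n_significant, g$L))
  if (!is.null(x$fdr)) {
    cat(sprintf("  false-positive rate %.4g; expected true (total - false) %.4g, (significant - false) %.4g\n",
                x$fdr$false_positive_rate,
                x$fdr$expected_true_total_minus_false,
                x$fdr$expected_true_significant_minus_false))
  }
  invisible(x)
}
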