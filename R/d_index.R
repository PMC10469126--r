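#' Mismatch weight of the D-index
#'
#' The per-gene weight at mismatch number m is `exp(4 - m)`: off-target
#' activity falls roughly exponentially with mismatch count, and reported
#' off-targets are concentrated at four or fewer mismatches, so the exponent
#' decreases from four. Successive weights decay by a factor of exactly
#' `exp(-1)`.
#'
#' @param m Non-negative integer vector of mismatch numbers.
#' @return `exp(4 - m)`.
#' @examples
#' mm_weight(4) # 1
#' mm_weight(0) # e^4
#' @export
mm_weight <- function(m) {
  if (any(is.na(m)) || any(m < 0)) abort("`m` must be >= 0.")
  exp(4 - m)
}

#' Compute the D-index from per-mismatch gene counts
#'
#' The D-index of a GO term is `sum over m of N(m) * exp(4 - m)` for
#' `m = 0 .. m_max`, where N(m) is the number of distinct genes annotated
#' with the term that carry a deleterious off-target site with exactly m
#' mismatches. Missing m values contribute zero. Summation is plain
#' double-precision in ascending m.
#'
#' @param counts Named numeric vector: names are mismatch numbers, values are
#'   non-negative gene counts N(m). An empty vector gives 0.
#' @param m_max Maximum mismatch number considered; counts at larger m are an
#'   error.
#' @return The D-index, a non-negative number.
#' @examples
#' compute_d_index(c(`4` = 1)) # 1
#' compute_d_index(c(`0` = 1, `4` = 1)) # exp(4) + 1
#' @export
compute_d_index <- function(counts, m_max = 8L) {
  if (length(counts) == 0L) return(0)
  if (is.null(names(counts)) || any(names(counts) == "")) {
    abort("`counts` must be named by mismatch number.")
  }
  m <- suppressWarnings(as.integer(names(counts)))
  if (anyNA(m) || any(m < 0)) abort("count names must be non-negative integers.")
  if (any(m > m_max)) abort("counts at m > m_max are not allowed.")
  n <- as.numeric(counts)
  if (anyNA(n) || any(n < 0)) abort("counts must be non-negative.")
  ord <- order(m)
  sum(n[ord] * exp(4 - m[ord]))
}

#' Per-term D-index profile from a DANGER table
#'
#' One record per GO term: the D-index plus the underlying N(m) counts spread
#' over columns `N_0 .. N_<m_max>`. The profile carries the total D-index
#' (sum over terms) and the number of terms N as attributes, surfaced by
#' [glance()].
#'
#' @param danger_table Tibble from [build_danger_table()].
#' @param m_max Maximum mismatch number (defines the count columns).
#' @return A tibble of class `danger_profile` with columns `go_id`, `go_term`,
#'   `category`, `d_index`, `N_0 .. N_<m_max>`, sorted by decreasing
#'   `d_index`.
#' @export
d_index_profile <- function(danger_table, m_max = 8L) {
  m_max <- as.integer(m_max)
  need <- c("go_id", "go_term", "category", "m", "n_genes")
  if (!all(need %in% names(danger_table))) {
    abort("`danger_table` needs columns go_id, go_term, category, m, n_genes.")
  }
  n_cols <- paste0("N_", 0:m_max)
  if (nrow(danger_table) == 0L) {
    empty <- tibble(go_id = character(), go_term = character(),
                    category = character(), d_index = numeric())
    for (nc in n_cols) empty[[nc]] <- integer()
    return(new_danger_profile(empty, m_max))
  }
  if (any(danger_table$m > m_max) || any(danger_table$m < 0)) {
    abort("mismatch numbers in the table must lie in [0, m_max].")
  }

  wide <- danger_table |>
    mutate(m_col = paste0("N_", .data$m)) |>
    summarise(n_genes = sum(.data$n_genes),
              .by = c("go_id", "go_term", "category", "m_col")) |>
    tidyr::pivot_wider(names_from = "m_col", values_from = "n_genes",
                       values_fill = 0L)
  for (nc in setdiff(n_cols, names(wide))) wide[[nc]] <- 0L
  counts <- as.matrix(wide[n_cols])
  wide$d_index <- as.numeric(counts %*% exp(4 - (0:m_max)))
  out <- wide[c("go_id", "go_term", "category", "d_index", n_cols)] |>
    arrange(dplyr::desc(.data$d_index), .data$go_id)
  new_danger_profile(out, m_max)
}

new_danger_profile <- function(tbl, m_max) {
  structure(tbl,
            m_max = m_max,
            total_d_index = sum(tbl$d_index),
            n_terms = nrow(tbl),
            class = c("danger_profile", class(tbl)))
}

#' @rdname d_index_profile
#' @param x A `danger_profile`.
#' @param ... Unused.
#' @export
glance.danger_profile <- function(x, ...) {
  tibble(total_d_index = attr(x, "total_d_index"),
         n_terms = attr(x, "n_terms"),
         m_max = attr(x, "m_max"))
}

#' @export
print.danger_profile <- function(x, ...) {
  cat(sprintf("# D-index profile: %d GO terms, total D-index %.4g (m_max %d)\n",
              attr(x, "n_terms"), attr(x, "total_d_index"), attr(x, "m_max")))
  NextMethod()
}
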