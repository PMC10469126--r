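DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# introduce exactly `mm` substitutions (to a different base) at uniformly
# chosen protospacer positions
mutate_protospacer <- function(protospacer, mm) {
  bases <- strsplit(protospacer, "")[[1]]
  if (mm > length(bases)) abort("more mismatches requested than protospacer positions.")
  if (mm > 0L) {
    pos <- sample.int(length(bases), mm)
    for (p in pos) bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1L)
  }
  paste(bases, collapse = "")
}

# one concrete realization of an IUPAC PAM pattern
concrete_pam <- function(pam_pattern) {
  sym <- strsplit(toupper(pam_pattern), "")[[1]]
  paste(vapply(sym, function(s) {
    set <- IUPAC_SETS[[s]]
    set[sample.int(length(set), 1L)]
  }, character(1)), collapse = "")
}

#' Example guide used throughout the package
#'
#' The SpCas9 guide targeting the reverse strand of the human GRIN2B locus
#' (protospacer `AGATTCTGGGTGGAAGCGCC`, NGG PAM), a published guide whose
#' printed off-target comparisons make a convenient worked example.
#'
#' @return A [guide_spec()].
#' @export
example_guide <- function() {
  guide_spec("AGATTCTGGGTGGAAGCGCC", pam = "NGG", guide_id = "GRIN2B-REV")
}

#' Simulate a transcriptome with planted guide-binding sites
#'
#' Generates random-base contigs and embeds protospacer+PAM windows carrying
#' exactly the requested number of protospacer mismatches (positions chosen
#' uniformly, substitutions always to a different base) and a concrete PAM
#' drawn from the guide's pattern. Each contig is rejection-checked with the
#' scanner: if any site at or below `clean_bound` mismatches other than the
#' planted ones appears (anywhere on the contig, either strand), the contig
#' is regenerated, so the returned truth is exact rather than probabilistic.
#'
#' @param guide A [guide_spec()].
#' @param n_contigs Number of contigs.
#' @param length_range Two integers: min/max contig length.
#' @param plant_spec `NULL` for a plain random transcriptome, or a data frame
#'   describing planted sites: either summary form (`mm_count`, `n_sites`,
#'   `strand`) or expanded form with one row per site (`mm_count`, `strand`,
#'   optional `contig` index; `NA`/absent means a random contig). `strand`
#'   may be `"+"`, `"-"` or `"*"` (random).
#' @param seed Integer seed; same seed, same bytes.
#' @param clean_bound Mismatch bound for the rejection check; defaults to
#'   `max(8, planted mm)` when planting, otherwise no check.
#' @param contig_prefix Prefix for contig ids.
#' @return `list(transcriptome = tibble(contig_id, sequence), truth =
#'   tibble(contig_id, start, strand, mm_count, site_sequence))`.
#' @export
simulate_transcriptome <- function(guide, n_contigs = 50L,
                                   length_range = c(1000L, 2000L),
                                   plant_spec = NULL, seed = 1L,
                                   clean_bound = NULL,
                                   contig_prefix = "TX") {
  if (!inherits(guide, "guide_spec")) abort("`guide` must be a guide_spec.")
  n_contigs <- as.integer(n_contigs)
  if (n_contigs < 1L) abort("`n_contigs` must be >= 1.")
  window_len <- nchar(guide$protospacer) + nchar(guide$pam)
  if (min(length_range) < window_len) {
    abort("contigs must be at least one window long.")
  }

  plants <- expand_plant_spec(plant_spec, n_contigs)
  if (nrow(plants) > 0L && is.null(clean_bound)) {
    clean_bound <- max(8L, max(plants$mm_count))
  }
  if (nrow(plants) > 0L && any(plants$mm_count > 11L)) {
    abort("planted mismatch counts above 11 are not supported.")
  }

  with_seed(seed, {
    plants$contig[is.na(plants$contig)] <-
      sample.int(n_contigs, sum(is.na(plants$contig)), replace = TRUE)
    plants$strand[plants$strand == "*"] <-
      sample(c("+", "-"), sum(plants$strand == "*"), replace = TRUE)
    contig_ids <- sprintf("%s_%04d", contig_prefix, seq_len(n_contigs))
    lens <- sample(seq(min(length_range), max(length_range)), n_contigs,
                   replace = TRUE)

    seqs <- character(n_contigs)
    truth <- vector("list", n_contigs)
    for (i in seq_len(n_contigs)) {
      mine <- plants[plants$contig == i, , drop = FALSE]
      built <- build_contig(guide, lens[i], mine, clean_bound, window_len)
      seqs[i] <- built$sequence
      if (nrow(built$truth) > 0L) {
        built$truth$contig_id <- contig_ids[i]
        truth[[i]] <- built$truth
      }
    }
    truth <- bind_rows(truth)
    if (nrow(truth) == 0L) {
      truth <- tibble(contig_id = character(), start = integer(),
                      strand = character(), mm_count = integer(),
                      site_sequence = character())
    } else {
      truth <- arrange(truth[c("contig_id", "start", "strand", "mm_count",
                               "site_sequence")],
                       .data$contig_id, .data$start, .data$strand)
    }
    list(transcriptome = tibble(contig_id = contig_ids, sequence = seqs),
         truth = truth)
  })
}

expand_plant_spec <- function(plant_spec, n_contigs) {
  empty <- tibble(contig = integer(), mm_count = integer(), strand = character())
  if (is.null(plant_spec) || nrow(plant_spec) == 0L) return(empty)
  ps <- as_tibble(plant_spec)
  if (!"mm_count" %in% names(ps)) abort("plant_spec needs an mm_count column.")
  if (!"strand" %in% names(ps)) ps$strand <- "*"
  if ("n_sites" %in% names(ps)) {
    ps <- ps[rep(seq_len(nrow(ps)), ps$n_sites), c("mm_count", "strand")]
  }
  if (!"contig" %in% names(ps)) ps$contig <- NA_integer_
  ps$contig <- as.integer(ps$contig)
  if (any(!is.na(ps$contig) & (ps$contig < 1L | ps$contig > n_contigs))) {
    abort("plant_spec contig indices out of range.")
  }
  ps$mm_count <- as.integer(ps$mm_count)
  if (any(ps$mm_count < 0L)) abort("planted mm_count must be >= 0.")
  if (any(!ps$strand %in% c("+", "-", "*"))) {
    abort("plant_spec strand must be '+', '-' or '*'.")
  }
  ps[c("contig", "mm_count", "strand")]
}

# build one contig with its planted windows; regenerate until the scanner
# recovers exactly the planted sites at <= clean_bound mismatches
build_contig <- function(guide, len, plants, clean_bound, window_len,
                         max_tries = 100L) {
  k <- nrow(plants)
  if (k * window_len > len) abort("infeasible plant_spec: windows do not fit the contig.")
  for (try in seq_len(max_tries)) {
    starts <- if (k > 0L) sample_nonoverlapping(len, window_len, k) else integer()
    if (k > 0L && is.null(starts)) next
    bases <- sample(DNA_BASES, len, replace = TRUE)
    truth_rows <- vector("list", k)
    ok <- TRUE
    for (j in seq_len(k)) {
      proto <- mutate_protospacer(guide$protospacer, plants$mm_count[j])
      binding <- paste0(proto, concrete_pam(guide$pam))
      forward <- if (plants$strand[j] == "+") binding else reverse_complement(binding)
      idx <- starts[j] + seq_len(window_len)
      bases[idx] <- strsplit(forward, "")[[1]]
      truth_rows[[j]] <- tibble(start = starts[j], strand = plants$strand[j],
                                mm_count = plants$mm_count[j],
                                site_sequence = binding)
    }
    sequence <- paste(bases, collapse = "")
    truth <- if (k > 0L) bind_rows(truth_rows) else {
      tibble(start = integer(), strand = character(), mm_count = integer(),
             site_sequence = character())
    }
    if (is.null(clean_bound)) {
      return(list(sequence = sequence, truth = truth))
    }
    found <- scan_transcriptome(
      tibble(contig_id = "x", sequence = sequence), guide,
      scan_config(pam = guide$pam, max_mm = clean_bound, both_strands = TRUE))
    expected <- truth[truth$mm_count <= clean_bound, , drop = FALSE]
    if (nrow(found) == nrow(expected) &&
        setequal(paste(found$start, found$strand, found$mm_count),
                 paste(expected$start, expected$strand, expected$mm_count))) {
      return(list(sequence = sequence, truth = truth))
    }
  }
  abort("infeasible plant_spec: could not build a clean contig in 100 attempts.")
}

sample_nonoverlapping <- function(len, window_len, k, tries = 200L) {
  for (i in seq_len(tries)) {
    starts <- sort(sample.int(len - window_len + 1L, k) - 1L)
    if (k == 1L || all(diff(starts) >= window_len)) return(starts)
  }
  NULL
}

#' Simulate a WT/edited expression matrix
#'
#' Baseline per-transcript abundances are drawn log-uniformly from
#' `base_tpm_range`. Wild-type replicates scatter around the baseline with
#' multiplicative log-normal noise of coefficient of variation `noise_cv`
#' (mean-preserving); edited replicates scatter around baseline x fold
#' change. Transcripts named in `downregulated` use `fold_change` (scalar or
#' per-transcript named vector); all others use 1.
#'
#' @param transcript_ids Character vector.
#' @param downregulated Transcript ids with reduced expression in edited
#'   samples.
#' @param fold_change Fold change(s) applied to downregulated transcripts;
#'   scalar or named vector.
#' @param n_wt,n_edited Replicates per group (>= 1; >= 3 recommended).
#' @param base_tpm_range Two positive numbers.
#' @param noise_cv Coefficient of variation of replicate noise (>= 0).
#' @param seed Integer seed.
#' @return `list(tpm = wide tibble, manifest = tibble(sample_id, group),
#'   truth = tibble(transcript_id, base_tpm, fold_change, downregulated))`.
#' @export
simulate_expression <- function(transcript_ids, downregulated = character(),
                                fold_change = 0.2, n_wt = 3L, n_edited = 3L,
                                base_tpm_range = c(5, 500), noise_cv = 0.1,
                                seed = 1L) {
  n_wt <- as.integer(n_wt); n_edited <- as.integer(n_edited)
  if (n_wt < 1L || n_edited < 1L) abort("`n_wt` and `n_edited` must be >= 1.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (any(base_tpm_range <= 0)) abort("`base_tpm_range` must be positive.")
  if (any(fold_change < 0)) abort("`fold_change` must be >= 0.")
  if (!all(downregulated %in% transcript_ids)) {
    abort("`downregulated` must be a subset of `transcript_ids`.")
  }
  n <- length(transcript_ids)
  fc <- rep(1, n)
  names(fc) <- transcript_ids
  if (length(downregulated) > 0L) {
    if (!is.null(names(fold_change))) {
      fc[downregulated] <- fold_change[downregulated]
    } else {
      fc[downregulated] <- fold_change
    }
  }
  sigma <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    base <- exp(runif(n, log(min(base_tpm_range)), log(max(base_tpm_range))))
    noise <- function(k) {
      if (sigma == 0) matrix(1, n, k)
      else matrix(exp(rnorm(n * k, 0, sigma) - sigma^2 / 2), n, k)
    }
    wt <- base * noise(n_wt)
    ed <- (base * fc) * noise(n_edited)
    colnames(wt) <- sprintf("WT_%d", seq_len(n_wt))
    colnames(ed) <- sprintf("ED_%d", seq_len(n_edited))
    tpm <- bind_cols(tibble(transcript_id = transcript_ids),
                     as_tibble(wt), as_tibble(ed))
    manifest <- tibble(
      sample_id = c(colnames(wt), colnames(ed)),
      group = c(rep("WT", n_wt), rep("edited", n_edited))
    )
    truth <- tibble(transcript_id = transcript_ids, base_tpm = base,
                    fold_change = unname(fc),
                    downregulated = transcript_ids %in% downregulated)
    list(tpm = tpm, manifest = manifest, truth = truth)
  })
}

#' Simulate a transcript-to-gene map and GO annotations
#'
#' Transcripts map to genes one-to-one except for `isoform_pairs` randomly
#' chosen pairs that share a gene. Each gene receives a uniformly random
#' number of GO terms in `terms_per_gene`; when `planted_term` is given it is
#' additionally attached to every gene hosting a `planted_transcripts`
#' member (and to no other gene).
#'
#' @param transcript_ids Character vector.
#' @param n_go_terms Number of background GO terms.
#' @param terms_per_gene Two integers: min/max random terms per gene.
#' @param planted_term Optional GO id (`GO:NNNNNNN`) for the planted term.
#' @param planted_transcripts Transcripts whose genes carry the planted term.
#' @param isoform_pairs Number of transcript pairs sharing one gene.
#' @param seed Integer seed.
#' @return `list(gene_map = tibble(transcript_id, gene_id), annotation =
#'   tibble(gene_id, go_id, go_term, category))`.
#' @export
simulate_annotations <- function(transcript_ids, n_go_terms = 30L,
                                 terms_per_gene = c(1L, 3L),
                                 planted_term = NULL,
                                 planted_transcripts = character(),
                                 isoform_pairs = 0L, seed = 1L) {
  n_go_terms <- as.integer(n_go_terms)
  if (n_go_terms < 1L) abort("`n_go_terms` must be >= 1.")
  if (!all(planted_transcripts %in% transcript_ids)) {
    abort("`planted_transcripts` must be a subset of `transcript_ids`.")
  }
  if (!is.null(planted_term) && !grepl("^GO:[0-9]{7}$", planted_term)) {
    abort("`planted_term` must look like GO:NNNNNNN.")
  }
  n_tx <- length(transcript_ids)
  with_seed(seed, {
    gene_of <- seq_len(n_tx)
    if (isoform_pairs > 0L) {
      # planted transcripts keep their own genes so the planted signal stays
      # concentrated where it was put
      eligible <- setdiff(seq_len(n_tx), match(planted_transcripts, transcript_ids))
      pick <- matrix(sample(eligible, 2L * isoform_pairs), ncol = 2L)
      gene_of[pick[, 2L]] <- gene_of[pick[, 1L]]
    }
    gene_levels <- sort(unique(gene_of))
    gene_ids <- sprintf("GENE_%04d", match(gene_of, gene_levels))
    gene_map <- tibble(transcript_id = transcript_ids, gene_id = gene_ids)

    terms <- tibble(
      go_id = sprintf("GO:%07d", seq_len(n_go_terms)),
      go_term = sprintf("synthetic process %d", seq_len(n_go_terms)),
      category = rep(c("BP", "CC", "MF"), length.out = n_go_terms)
    )
    genes <- unique(gene_ids)
    k <- sample(seq(min(terms_per_gene), max(terms_per_gene)),
                length(genes), replace = TRUE)
    annotation <- bind_rows(purrr::map2(genes, k, function(g, ki) {
      idx <- sample.int(n_go_terms, min(ki, n_go_terms))
      tibble(gene_id = g, go_id = terms$go_id[idx],
             go_term = terms$go_term[idx], category = terms$category[idx])
    }))
    if (!is.null(planted_term) && length(planted_transcripts) > 0L) {
      pg <- unique(gene_map$gene_id[gene_map$transcript_id %in% planted_transcripts])
      annotation <- annotation[annotation$go_id != planted_term, , drop = FALSE]
      annotation <- bind_rows(
        annotation,
        tibble(gene_id = pg, go_id = planted_term,
               go_term = "planted synthetic process", category = "BP"))
    }
    annotation <- arrange(distinct(annotation), .data$gene_id, .data$go_id)
    list(gene_map = gene_map, annotation = check_go_annotation(annotation))
  })
}

#' Simulate a complete analysis-ready dataset
#'
#' Three frozen study designs, all scanned with the NGG / 8-mismatch
#' (optimized) settings and three replicates per group:
#'
#' * `"strong"`: 120 transcripts; eight target genes each carry two planted
#'   low-mismatch sites (1 and 2 mismatches) and are strongly downregulated
#'   (fold 0.15); all eight share one planted GO term. 300 background sites
#'   at 5-8 mismatches land on random transcripts, 25% of which are
#'   downregulated (fold 0.3) independently of any GO term.
#' * `"null"`: 200 transcripts, 400 background sites at 4-8 mismatches, 30%
#'   of transcripts downregulated (fold 0.25), annotations random — no
#'   association anywhere, for type-I behaviour.
#' * `"mixed"`: 150 transcripts; four genes with single 3-mismatch sites
#'   share a planted term that is also diluted onto six random genes; 200
#'   background sites at 4-8 mismatches; moderate downregulation.
#'
#' Every preset also plants one perfect-match (on-target) site on the last
#' transcript, which is downregulated (fold 0.1) — the pipeline excludes its
#' gene. Replicate noise is log-normal with CV 0.1.
#'
#' @param preset `"strong"`, `"null"` or `"mixed"`.
#' @param seed Integer seed driving every random choice.
#' @param guide Guide; defaults to [example_guide()].
#' @return A list with `transcriptome`, `truth` (planted sites), `tpm`,
#'   `manifest`, `expression_truth`, `gene_map`, `annotation`, `guide`,
#'   `scan` (a [scan_config()]), `planted_term`, `planted_transcripts`,
#'   `preset`, `seed`.
#' @export
simulate_dataset <- function(preset = c("strong", "null", "mixed"), seed = 1L,
                             guide = example_guide()) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  p <- switch(preset,
    strong = list(n_contigs = 120L, n_planted = 8L, planted_mm = c(1L, 2L),
                  n_bg = 300L, bg_mm = 5:8, planted_fold = 0.15,
                  bg_down_rate = 0.25, bg_fold = 0.3, n_go = 30L,
                  terms_per_gene = c(1L, 3L), dilute = 0L),
    null = list(n_contigs = 200L, n_planted = 0L, planted_mm = integer(),
                n_bg = 400L, bg_mm = 4:8, planted_fold = NA_real_,
                bg_down_rate = 0.30, bg_fold = 0.25, n_go = 40L,
                terms_per_gene = c(2L, 5L), dilute = 0L),
    mixed = list(n_contigs = 150L, n_planted = 4L, planted_mm = 3L,
                 n_bg = 200L, bg_mm = 4:8, planted_fold = 0.25,
                 bg_down_rate = 0.25, bg_fold = 0.3, n_go = 35L,
                 terms_per_gene = c(1L, 4L), dilute = 6L)
  )

  planted_contigs <- seq_len(p$n_planted)
  on_target_contig <- p$n_contigs
  plant <- bind_rows(
    if (p$n_planted > 0L) {
      tidyr::expand_grid(contig = planted_contigs, mm_count = p$planted_mm) |>
        mutate(strand = "*")
    },
    tibble(contig = on_target_contig, mm_count = 0L, strand = "+"),
    with_seed(seed + 10000000L, {
      tibble(contig = sample(seq_len(p$n_contigs - 1L), p$n_bg, replace = TRUE),
             mm_count = sample(p$bg_mm, p$n_bg, replace = TRUE),
             strand = "*")
    })
  )

  tx <- simulate_transcriptome(guide, n_contigs = p$n_contigs,
                               length_range = c(400L, 700L),
                               plant_spec = plant, seed = seed,
                               clean_bound = 8L)
  ids <- tx$transcriptome$contig_id
  planted_tx <- ids[planted_contigs]
  on_target_tx <- ids[on_target_contig]

  down_bg <- with_seed(seed + 20000000L, {
    pool <- setdiff(ids, c(planted_tx, on_target_tx))
    sample(pool, round(p$bg_down_rate * length(pool)))
  })
  down <- c(planted_tx, down_bg, on_target_tx)
  fold <- setNames(rep(p$bg_fold, length(down)), down)
  fold[planted_tx] <- p$planted_fold
  fold[on_target_tx] <- 0.1
  expr <- simulate_expression(ids, downregulated = down, fold_change = fold,
                              n_wt = 3L, n_edited = 3L, noise_cv = 0.1,
                              seed = seed + 30000000L)

  planted_term <- if (p$n_planted > 0L) "GO:0999999" else NULL
  planted_for_ann <- planted_tx
  if (p$dilute > 0L) {
    planted_for_ann <- c(planted_tx, with_seed(seed + 40000000L, {
      sample(setdiff(ids, c(planted_tx, on_target_tx)), p$dilute)
    }))
  }
  ann <- simulate_annotations(ids, n_go_terms = p$n_go,
                              terms_per_gene = p$terms_per_gene,
                              planted_term = planted_term,
                              planted_transcripts = planted_for_ann,
                              isoform_pairs = 3L, seed = seed + 50000000L)

  list(transcriptome = tx$transcriptome, truth = tx$truth,
       tpm = expr$tpm, manifest = expr$manifest,
       expression_truth = expr$truth,
       gene_map = ann$gene_map, annotation = ann$annotation,
       guide = guide, scan = scan_preset("optimized"),
       planted_term = planted_term, planted_transcripts = planted_tx,
       on_target_transcript = on_target_tx,
       preset = preset, seed = seed)
}

#' Write a simulated dataset to disk
#'
#' Emits the file formats the pipeline consumes: FASTA transcriptome, TPM
#' matrix CSV, sample manifest TSV, gene map TSV, GO annotation TSV, and a
#' `truth.json` with the planted ground truth.
#'
#' @param dataset A list from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "transcriptome.fasta"),
    tpm = file.path(dir, "tpm_matrix.csv"),
    manifest = file.path(dir, "samples.tsv"),
    gene_map = file.path(dir, "gene_map.tsv"),
    annotation = file.path(dir, "go_annotation.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_transcriptome(dataset$transcriptome, paths[["fasta"]])
  readr::write_csv(dataset$tpm, paths[["tpm"]])
  readr::write_tsv(dataset$manifest, paths[["manifest"]])
  readr::write_tsv(dataset$gene_map, paths[["gene_map"]])
  readr::write_tsv(dataset$annotation, paths[["annotation"]])
  jsonlite::write_json(
    list(preset = dataset$preset, seed = dataset$seed,
         guide = list(protospacer = dataset$guide$protospacer,
                      pam = dataset$guide$pam,
                      guide_id = dataset$guide$guide_id),
         planted_term = dataset$planted_term,
         planted_transcripts = dataset$planted_transcripts,
         on_target_transcript = dataset$on_target_transcript,
         planted_sites = dataset$truth,
         expression_truth = dataset$expression_truth),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
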