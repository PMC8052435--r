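# Conserved anchor-target discovery: reciprocal best-match transcript
# pairing, genome scanning with seed + confirmation criteria, and candidate
# window extraction.

#' Reciprocal best-match transcript pairs
#'
#' Scores every transcript pair across the two sets by the number of shared
#' canonical 20-mers (a local stand-in for a blastn bit-score; an external
#' aligner can supply scores through `score_fun`). A pair is reported only
#' when each member is the other's best match in both directions; ties are
#' broken lexicographically by id.
#'
#' @param set_a,set_b Sequence tibbles (both non-empty).
#' @param config A [pipeline_config()] (uses `kmer_k`).
#' @param score_fun Optional `function(set_a, set_b)` returning a numeric
#'   score matrix (rows = `set_a`, cols = `set_b`) replacing the internal
#'   shared-k-mer score.
#' @return Tibble of reciprocal pairs: `id_a`, `id_b`, `score_ab`,
#'   `score_ba`.
#' @export
reciprocal_best_pairs <- function(set_a, set_b, config = NULL, score_fun = NULL) {
  config <- as_config(config)
  if (nrow(set_a) == 0 || nrow(set_b) == 0) abort("both transcript sets must be non-empty")
  if (is.null(score_fun)) {
    k <- config$kmer_k
    sets_a <- lapply(set_a$seq, function(s) names(enumerate_kmers(s, k, canonical = TRUE)$counts))
    sets_b <- lapply(set_b$seq, function(s) names(enumerate_kmers(s, k, canonical = TRUE)$counts))
    score <- matrix(0, nrow(set_a), nrow(set_b))
    for (i in seq_along(sets_a)) {
      for (j in seq_along(sets_b)) {
        score[i, j] <- length(intersect(sets_a[[i]], sets_b[[j]]))
      }
    }
  } else {
    score <- score_fun(set_a, set_b)
  }
  # argmax with lexicographic tie-break on the partner id
  best_of <- function(v, ids) {
    top <- which(v == max(v))
    top[order(ids[top])][1]
  }
  rows <- list()
  for (i in seq_len(nrow(set_a))) {
    if (all(score[i, ] == 0)) next  # unpaired: no shared k-mers at all
    j <- best_of(score[i, ], set_b$id)
    i_back <- best_of(score[, j], set_a$id)
    if (i_back == i && any(score[, j] > 0)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        id_a = set_a$id[i], id_b = set_b$id[j],
        score_ab = score[i, j], score_ba = score[i, j]
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          score_ab = numeric(), score_ba = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Scan a genome for anchor targets
#'
#' Both strands of every contig are scanned against the reference set with
#' the seed-and-confirm criterion (default 17-of-20 spaced k-mer seed,
#' 55-of-100 confirmation). Validated hits within `target_window` of each
#' other on the same contig and strand are merged (leftmost-first greedy)
#' into one candidate locus whose window is centred on the hit span and
#' clipped at contig ends.
#'
#' @param genome Sequence tibble of contigs.
#' @param references Sequence tibble of trimmed anchor reference sequences.
#' @param config A [pipeline_config()].
#' @return Locus target tibble: `locus_id`, `contig`, `start`, `end`
#'   (1-based closed), `strand`, `seed_reference`, `best_identities`,
#'   `n_hits`, `hit_positions` (list-column of anchor coordinates).
#' @export
scan_genome <- function(genome, references, config = NULL) {
  config <- as_config(config)
  empty <- tibble::tibble(
    locus_id = character(), contig = character(), start = integer(),
    end = integer(), strand = character(), seed_reference = character(),
    best_identities = integer(), n_hits = integer(), hit_positions = list()
  )
  hits <- list()
  for (ci in seq_len(nrow(genome))) {
    contig <- genome$seq[ci]
    L <- nchar(contig)
    if (L < config$seed_window) {
      warn(paste0("contig ", genome$id[ci], " shorter than seed window; skipped"))
      next
    }
    for (strand in c("+", "-")) {
      q <- if (strand == "+") contig else revcomp(contig)
      h <- cpp_scan_hits(q, references$seq, config$seed_window,
                         config$seed_min_matches, config$confirm_window,
                         config$confirm_min_matches)
      if (nrow(h) == 0) next
      # matched-window interval on forward-strand coordinates, 1-based closed
      if (strand == "+") {
        fstart <- h$qpos + 1L
        fend <- fstart + h$window - 1L
      } else {
        fstart <- L - (h$qpos + h$window) + 1L
        fend <- fstart + h$window - 1L
      }
      hits[[length(hits) + 1]] <- tibble::tibble(
        contig = genome$id[ci], contig_len = L, strand = strand,
        fstart = fstart, fend = fend,
        ref = references$id[h$ref], identities = h$identities
      )
    }
  }
  if (length(hits) == 0) return(empty)
  hits <- dplyr::bind_rows(hits)
  # greedy leftmost merge of hits within target_window on the same
  # contig/strand
  out <- hits |>
    dplyr::group_by(.data$contig, .data$strand) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$fstart)
      gap <- c(0, df$fstart[-1] - cummax(df$fend)[-nrow(df)])
      cluster <- cumsum(gap > 0 & gap > config$target_window)
      df$cluster <- cluster
      df |>
        dplyr::group_by(.data$cluster) |>
        dplyr::summarise(
          span_start = min(.data$fstart), span_end = max(.data$fend),
          contig_len = .data$contig_len[1],
          seed_reference = .data$ref[which.max(.data$identities)],
          best_identities = max(.data$identities),
          n_hits = dplyr::n(),
          hit_positions = list(sort(unique(.data$fstart))),
          .groups = "drop"
        )
    }) |>
    dplyr::ungroup()
  # centre the candidate window on the hit span, clip at contig ends
  win <- config$target_window
  mid <- (out$span_start + out$span_end) / 2
  start <- pmax(1L, as.integer(round(mid - win / 2)))
  end <- pmin(out$contig_len, start + win - 1L)
  start <- pmax(1L, pmin(start, end - win + 1L))
  start <- pmax(1L, start)
  out <- tibble::tibble(
    contig = out$contig, start = start, end = as.integer(end),
    strand = out$strand, seed_reference = out$seed_reference,
    best_identities = out$best_identities, n_hits = out$n_hits,
    hit_positions = out$hit_positions
  ) |>
    dplyr::arrange(.data$contig, .data$start, .data$strand)
  out$locus_id <- sprintf("tgt_%03d", seq_len(nrow(out)))
  dplyr::select(out, "locus_id", "contig", "start", "end", "strand",
                "seed_reference", "best_identities", "n_hits", "hit_positions")
}

#' Extract candidate window sequences
#'
#' One sequence per target: the genome slice, reverse-complemented for
#' minus-strand targets, named by locus id.
#'
#' @param genome Sequence tibble of contigs.
#' @param targets Locus target tibble from [scan_genome()].
#' @return Sequence tibble of candidate windows.
#' @export
extract_windows <- function(genome, targets) {
  idx <- match(targets$contig, genome$id)
  if (anyNA(idx)) abort("target contig absent from genome")
  lens <- nchar(genome$seq[idx])
  if (any(targets$start < 1 | targets$end > lens)) {
    abort("target coordinates outside contig")
  }
  s <- substring(genome$seq[idx], targets$start, targets$end)
  s[targets$strand == "-"] <- revcomp(s[targets$strand == "-"])
  seq_tbl(id = targets$locus_id, seq = s,
          contig = targets$contig, strand = targets$strand)
}
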