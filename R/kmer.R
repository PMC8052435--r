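# k-mer enumeration, spaced-seed matching, profile distances and coverage
# tracks -- the computational core shared by target discovery, read
# recruitment, orthology clustering, locus dedup and repeat masking.

#' Spaced seed pattern
#'
#' A match template over a window of `length` positions; only `care`
#' positions are compared. The default is all-care, i.e. a contiguous k-mer
#' window with a plain mismatch budget.
#'
#' @param care Logical vector (`TRUE` = position compared), or `NULL` for
#'   all-care.
#' @param length Window length, used when `care` is `NULL`.
#' @return A `spaced_seed` object.
#' @export
spaced_seed <- function(care = NULL, length = 20L) {
  if (is.null(care)) care <- rep(TRUE, length)
  if (!is.logical(care) || anyNA(care)) abort("care mask must be logical")
  structure(list(care = care, weight = sum(care)), class = "spaced_seed")
}

#' Enumerate the k-mers of a sequence
#'
#' With a fixed `k` there are `L - k + 1` k-mer occurrences. With
#' `k = "all"`, every subsequence length is enumerated, so e.g. `"GCTA"`
#' yields G, C, T, A, GC, CT, TA, GCT, CTA and GCTA. k-mers containing N are
#' skipped.
#'
#' @param seq A single sequence string (or one-row sequence tibble).
#' @param k Integer k-mer size or `"all"`.
#' @param canonical If `TRUE`, count each k-mer as the lexicographic minimum
#'   of itself and its reverse complement (strand-free identity).
#' @param source_id Label recorded on the profile.
#' @return A `kmer_profile`: list with `k`, `counts` (named integer vector),
#'   `source_id`, `canonical`.
#' @export
enumerate_kmers <- function(seq, k = "all", canonical = FALSE, source_id = NULL) {
  if (is.data.frame(seq)) {
    if (is.null(source_id)) source_id <- seq$id[1]
    seq <- seq$seq[1]
  }
  seq <- toupper(seq)
  L <- nchar(seq)
  ks <- if (identical(k, "all")) seq_len(L) else as.integer(k)
  if (!identical(k, "all") && (ks < 1)) abort("k must be >= 1")
  if (!identical(k, "all") && ks > L) {
    warn(paste0("k = ", ks, " exceeds sequence length ", L, "; empty profile"))
    ks <- integer(0)
  }
  kmers <- character(0)
  for (kk in ks) {
    starts <- seq_len(L - kk + 1)
    km <- substring(seq, starts, starts + kk - 1)
    km <- km[!grepl("[^ACGT]", km)]
    kmers <- c(kmers, km)
  }
  if (canonical && length(kmers) > 0) {
    kmers <- pmin(kmers, revcomp(kmers))
  }
  counts <- if (length(kmers) == 0) {
    stats::setNames(integer(0), character(0))
  } else {
    tb <- table(kmers)
    stats::setNames(as.integer(tb), names(tb))
  }
  structure(
    list(k = if (identical(k, "all")) "all" else as.integer(k),
         counts = counts,
         source_id = source_id %||% NA_character_,
         canonical = canonical),
    class = "kmer_profile"
  )
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("<kmer_profile> k=%s, %d distinct k-mers, %d occurrences (%s)\n",
              format(x$k), length(x$counts), sum(x$counts),
              if (x$canonical) "canonical" else "as-given strand"))
  invisible(x)
}

#' @export
tidy.kmer_profile <- function(x, ...) {
  tibble::tibble(kmer = names(x$counts), count = as.integer(x$counts))
}

#' Spaced-seed window match
#'
#' Compares two equal-length windows at the pattern's care positions and
#' passes when at least `min_matches` of them are identical. N (or any
#' non-ACGT character) never matches.
#'
#' @param window,ref Equal-length strings (the pattern's window length).
#' @param pattern A [spaced_seed()]; `NULL` means all-care over the window.
#' @param min_matches Minimum identical care positions.
#' @return Logical scalar.
#' @export
seed_match <- function(window, ref, pattern = NULL, min_matches = 17L) {
  window <- toupper(window); ref <- toupper(ref)
  if (nchar(window) != nchar(ref)) abort("window and ref lengths differ")
  if (is.null(pattern)) pattern <- spaced_seed(length = nchar(window))
  if (length(pattern$care) != nchar(window)) {
    abort("pattern length does not match window length")
  }
  a <- strsplit(window, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(pattern$care & valid & a == b) >= min_matches
}

#' Confirmation window match
#'
#' After a seed hit at `anchor` (1-based query coordinate) on the gapless
#' diagonal fixed by `ref_anchor`, the best `confirm_window`-base window
#' containing the anchor is scored by identity count. Windows clipped at
#' sequence ends scale the threshold proportionally. `mode = "consecutive"`
#' additionally requires a single exact run of `confirm_min` bases inside
#' the window (the stricter reading of a consecutive match).
#'
#' @param query,ref Sequence strings.
#' @param anchor 1-based seed position in `query`.
#' @param ref_anchor 1-based matching position in `ref`.
#' @param confirm_window Window length (default 100).
#' @param confirm_min Required identities (default 55).
#' @param mode `"aligned"` (identity count, the default) or `"consecutive"`.
#' @return Logical scalar with attributes `identities` and `window`.
#' @export
confirm_match <- function(query, ref, anchor, ref_anchor,
                          confirm_window = 100L, confirm_min = 55L,
                          mode = c("aligned", "consecutive")) {
  mode <- match.arg(mode)
  query <- toupper(query); ref <- toupper(ref)
  if (anchor < 1 || anchor > nchar(query)) abort("anchor outside query")
  res <- cpp_confirm(query, ref, anchor - 1L, ref_anchor - 1L,
                     as.integer(confirm_window), as.integer(confirm_min))
  pass <- res$pass
  if (pass && mode == "consecutive") {
    pass <- has_exact_run(query, ref, anchor, ref_anchor, confirm_min)
  }
  structure(pass, identities = res$identities, window = res$window)
}

# longest exact run on the diagonal through (anchor, ref_anchor)
has_exact_run <- function(query, ref, anchor, ref_anchor, run_len) {
  d <- anchor - ref_anchor
  lo <- max(1, 1 + d); hi <- min(nchar(query), nchar(ref) + d)
  if (hi < lo) return(FALSE)
  a <- strsplit(substr(query, lo, hi), "")[[1]]
  b <- strsplit(substr(ref, lo - d, hi - d), "")[[1]]
  eq <- a == b & a %in% c("A", "C", "G", "T")
  r <- rle(eq)
  any(r$values & r$lengths >= run_len)
}

#' Distance between two k-mer profiles
#'
#' One minus the Jaccard index of the distinct k-mer sets (the degree of
#' k-mer distribution overlap). With `weighted = TRUE`, a multiplicity-
#' weighted Jaccard (sum of minima over sum of maxima) is used instead.
#'
#' @param a,b `kmer_profile` objects with equal `k`.
#' @param weighted Use multiplicity weighting.
#' @return Distance in `[0, 1]`.
#' @export
profile_distance <- function(a, b, weighted = FALSE) {
  if (!identical(a$k, b$k)) abort("profiles have different k")
  ka <- names(a$counts); kb <- names(b$counts)
  if (length(ka) == 0 && length(kb) == 0) {
    warn("both profiles empty; distance 1")
    return(1)
  }
  if (!weighted) {
    1 - length(intersect(ka, kb)) / length(union(ka, kb))
  } else {
    keys <- union(ka, kb)
    ca <- stats::setNames(rep(0L, length(keys)), keys)
    cb <- ca
    ca[ka] <- a$counts
    cb[kb] <- b$counts
    1 - sum(pmin(ca, cb)) / sum(pmax(ca, cb))
  }
}

#' k-mer coverage track
#'
#' For each position of `target`, the mean multiplicity (in `reads`) of the
#' k-mers of `target` that cover the position. Repetitive segments of the
#' target stand out as elevated plateaus. k-mers containing N are undefined
#' and positions covered only by undefined k-mers inherit the nearest
#' defined value.
#'
#' @param target A sequence string or one-row sequence tibble.
#' @param reads Character vector of reads, or a sequence tibble.
#' @param k k-mer size (default 20).
#' @param canonical Count k-mers strand-free (default `TRUE`).
#' @return A `coverage_track` tibble with columns `pos`, `coverage`.
#' @export
coverage_track <- function(target, reads, k = 20L, canonical = TRUE) {
  id <- NA_character_
  if (is.data.frame(target)) { id <- target$id[1]; target <- target$seq[1] }
  if (is.data.frame(reads)) reads <- reads$seq
  target <- toupper(target)
  L <- nchar(target)
  if (L < k) {
    # whole-sequence lookup: the sequence itself is the only "k-mer"
    cnt <- sum(reads == target)
    out <- tibble::tibble(pos = seq_len(L), coverage = as.numeric(cnt))
    return(structure(out, class = c("coverage_track", class(out)), target_id = id))
  }
  counts <- cpp_kmer_hit_counts(target, toupper(reads), as.integer(k), canonical)
  nk <- L - k + 1
  valid <- !is.na(counts)
  cval <- ifelse(valid, counts, 0)
  # position i is covered by k-mer starts max(1, i-k+1) .. min(i, nk)
  cs <- cumsum(c(0, cval))
  cn <- cumsum(c(0, as.numeric(valid)))
  lo <- pmax(1, seq_len(L) - k + 1)
  hi <- pmin(seq_len(L), nk)
  tot <- cs[hi + 1] - cs[lo]
  nv <- cn[hi + 1] - cn[lo]
  cov <- ifelse(nv > 0, tot / nv, NA_real_)
  if (anyNA(cov)) {
    # nearest defined value
    idx <- which(!is.na(cov))
    if (length(idx) == 0) cov[] <- 0 else {
      nearest <- idx[pmax(1, findInterval(seq_len(L), idx))]
      # findInterval gives the left neighbour; compare with right neighbour
      left <- nearest
      rpos <- idx[pmin(length(idx), findInterval(seq_len(L), idx) + 1)]
      use_right <- abs(rpos - seq_len(L)) < abs(left - seq_len(L))
      fill <- ifelse(use_right, cov[rpos], cov[left])
      cov[is.na(cov)] <- fill[is.na(cov)]
    }
  }
  out <- tibble::tibble(pos = seq_len(L), coverage = cov)
  structure(out, class = c("coverage_track", class(out)), target_id = id)
}

#' @export
autoplot.coverage_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$coverage)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = stats::median(object$coverage),
                        linetype = "dashed") +
    ggplot2::labs(x = "position (bp)", y = "mean k-mer multiplicity",
                  title = attr(object, "target_id"))
}

#' Serialize a k-mer profile to TSV
#'
#' @param profile A `kmer_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(tidy(profile), path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Export a coverage track as BED
#'
#' One BED line per maximal run of equal coverage, score = the (rounded)
#' track value; coordinates follow the BED 0-based half-open convention.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @param contig Contig name for the first column (defaults to the track's
#'   target id).
#' @return `path`, invisibly.
#' @export
write_coverage_bed <- function(track, path, contig = NULL) {
  contig <- contig %||% attr(track, "target_id") %||% "track"
  r <- rle(round(track$coverage, 3))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  df <- tibble::tibble(
    chrom = contig, start = starts - 1L, end = ends,
    name = sprintf("cov_%04d", seq_along(starts)),
    score = round(r$values), strand = "."
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Scan two sequences with an arbitrary spaced-seed pattern
#'
#' Exhaustive window enumeration: every (query, reference) window pair is
#' tested with [seed_match()] under the given pattern, and passing seeds
#' are confirmed with [confirm_match()]. Quadratic in sequence length --
#' intended for custom spaced-seed templates on fixture-scale inputs; the
#' large-scale scanners ([scan_genome()], [recruit_reads()]) use the
#' default contiguous seed.
#'
#' @param query,ref Sequence strings.
#' @param pattern A [spaced_seed()].
#' @param config A [pipeline_config()].
#' @return Tibble of confirmed hits: `qpos`, `rpos` (1-based),
#'   `identities`, `window`.
#' @export
scan_with_pattern <- function(query, ref, pattern = NULL, config = NULL) {
  config <- as_config(config)
  pattern <- pattern %||% spaced_seed(length = config$seed_window)
  w <- length(pattern$care)
  query <- toupper(query); ref <- toupper(ref)
  out <- list()
  seen_diag <- integer(0)
  for (q in seq_len(max(0, nchar(query) - w + 1))) {
    qwin <- substr(query, q, q + w - 1)
    for (r in seq_len(max(0, nchar(ref) - w + 1))) {
      d <- q - r
      if (d %in% seen_diag) next
      if (!seed_match(qwin, substr(ref, r, r + w - 1), pattern,
                      config$seed_min_matches)) next
      cm <- confirm_match(query, ref, q, r,
                          confirm_window = config$confirm_window,
                          confirm_min = config$confirm_min_matches,
                          mode = config$confirm_mode)
      seen_diag <- c(seen_diag, d)
      if (cm) {
        out[[length(out) + 1]] <- tibble::tibble(
          qpos = q, rpos = r,
          identities = attr(cm, "identities"), window = attr(cm, "window")
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(qpos = integer(), rpos = integer(),
                          identities = integer(), window = integer()))
  }
  dplyr::bind_rows(out)
}
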