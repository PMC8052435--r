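# Automated alignment trimming and masking, sparse-locus filtering,
# shared-20-mer locus dedup, repeat masking by elevated k-mer coverage, and
# supermatrix concatenation. QC only masks or removes; it never edits an
# unmasked character.

#' Identify reliable alignment sites
#'
#' A site is reliable when the modal non-gap character's frequency among the
#' unmasked non-gap characters reaches `threshold` (inclusive, so an even
#' 50/50 split passes at the default 0.5). Gap-only sites are unreliable.
#'
#' @param aln An `alignment_matrix`.
#' @param threshold Modal-frequency threshold (default 0.5).
#' @return Logical vector, one element per site.
#' @export
identify_reliable_sites <- function(aln, threshold = 0.5) {
  st <- apply_site_stats(aln)
  st$modal_freq >= threshold - 1e-12 & st$n_present > 0
}

# per-site modal character/frequency over unmasked non-gap cells
apply_site_stats <- function(aln) {
  chars <- aln$chars
  chars[aln$mask] <- "-"  # masked cells never contribute
  L <- ncol(chars)
  modal_char <- character(L)
  modal_freq <- numeric(L)
  n_present <- integer(L)
  for (j in seq_len(L)) {
    col <- chars[, j]
    col <- col[col != "-"]
    n_present[j] <- length(col)
    if (length(col) == 0) {
      modal_char[j] <- NA_character_
      modal_freq[j] <- 0
    } else {
      tb <- table(col)
      modal_char[j] <- names(tb)[which.max(tb)]
      modal_freq[j] <- max(tb) / length(col)
    }
  }
  list(modal_char = modal_char, modal_freq = modal_freq, n_present = n_present)
}

#' Mask misaligned regions
#'
#' For each sequence, any maximal run of at least `run_threshold`
#' consecutive reliable sites at which the sequence disagrees with the
#' site's modal character is masked in that sequence only. Runs are broken
#' by agreement, by gaps in the sequence, by unreliable sites, and by
#' already-masked cells.
#'
#' @param aln An `alignment_matrix`.
#' @param run_threshold Minimum run length to mask (default 14, inclusive).
#' @param threshold Reliable-site threshold passed through to
#'   [identify_reliable_sites()].
#' @return The alignment with its mask extended.
#' @export
mask_misaligned_regions <- function(aln, run_threshold = 14L, threshold = 0.5) {
  stats <- apply_site_stats(aln)
  reliable <- stats$modal_freq >= threshold - 1e-12 & stats$n_present > 0
  modal <- stats$modal_char
  for (i in seq_along(aln$taxa)) {
    row <- aln$chars[i, ]
    disagree <- reliable & !aln$mask[i, ] & row != "-" & row != modal
    r <- rle(disagree)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= run_threshold)) {
      aln$mask[i, starts[k]:ends[k]] <- TRUE
    }
  }
  aln
}

#' Drop sparse sites
#'
#' Removes sites with fewer than `min_sequences` unmasked non-gap
#' characters (inclusive: a site with exactly `min_sequences` present is
#' kept). The original site coordinates of the kept columns are retained in
#' attribute `site_map`.
#'
#' @param aln An `alignment_matrix` (masking already applied).
#' @param min_sequences Minimum present sequences per site (default 25).
#' @return The trimmed alignment.
#' @export
drop_sparse_sites <- function(aln, min_sequences = 25L) {
  chars <- aln$chars
  chars[aln$mask] <- "-"
  present <- colSums(chars != "-")
  keep <- present >= min_sequences
  aln$chars <- aln$chars[, keep, drop = FALSE]
  aln$mask <- aln$mask[, keep, drop = FALSE]
  attr(aln, "site_map") <- which(keep)
  aln
}

#' Trim and mask one alignment
#'
#' The automated procedure: identify reliable sites, mask misaligned runs,
#' drop sparse sites. Idempotent on its own output for alignments whose
#' disagreement runs are not rejoined by site removal.
#'
#' @param aln An `alignment_matrix`.
#' @param config A [pipeline_config()] (`reliable_site_threshold`,
#'   `mask_run_length`, `min_sequences_per_site`).
#' @return The trimmed, masked alignment.
#' @export
trim_alignment <- function(aln, config = NULL) {
  config <- as_config(config)
  aln <- mask_misaligned_regions(aln, run_threshold = config$mask_run_length,
                                 threshold = config$reliable_site_threshold)
  drop_sparse_sites(aln, min_sequences = config$min_sequences_per_site)
}

#' Filter loci under-represented in the panel
#'
#' A locus is removed when it is represented by less than `min_fraction` of
#' the expected panel, i.e. kept iff
#' `non-empty sequences / panel_size >= min_fraction` (exactly half the
#' panel survives the default 50% rule).
#'
#' @param loci Named list of `alignment_matrix` objects.
#' @param min_fraction Minimum represented fraction (default 0.5).
#' @param panel_size Number of sequences expected per locus.
#' @return The kept subset of `loci`.
#' @export
filter_sparse_loci <- function(loci, min_fraction = 0.5, panel_size) {
  keep <- vapply(loci, function(a) {
    nonempty <- sum(apply(a$chars != "-" & !a$mask, 1, any))
    nonempty / panel_size >= min_fraction - 1e-12
  }, logical(1))
  loci[keep]
}

#' Remove loci sharing 20-mers
#'
#' Builds the canonical k-mer set of each locus (gaps stripped, all
#' sequences pooled); whenever two loci share at least one k-mer, the locus
#' with the smaller total ungapped length is removed (ties remove the
#' lexicographically later id). Repeats until the retained loci are
#' pairwise disjoint in k-mer space.
#'
#' @param loci Named list of `alignment_matrix` objects.
#' @param k k-mer size (default 20).
#' @return The retained subset of `loci`, with removed ids in attribute
#'   `removed`.
#' @export
dedup_overlapping_loci <- function(loci, k = 20L) {
  if (length(loci) == 0) return(loci)
  ids <- names(loci) %||% vapply(loci, function(a) a$locus_id, character(1))
  names(loci) <- ids
  kmer_sets <- lapply(loci, function(a) {
    seqs <- gsub("-", "", apply(a$chars, 1, paste, collapse = ""))
    seqs <- seqs[nchar(seqs) >= k]
    unique(unlist(lapply(seqs, function(s) {
      names(enumerate_kmers(s, k, canonical = TRUE)$counts)
    })))
  })
  total_len <- vapply(loci, function(a) sum(nchar(gsub("-", "", apply(a$chars, 1, paste, collapse = "")))), numeric(1))
  removed <- character(0)
  alive <- ids
  repeat {
    drop <- NULL
    n <- length(alive)
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          a <- alive[i]; b <- alive[j]
          if (length(intersect(kmer_sets[[a]], kmer_sets[[b]])) > 0) {
            drop <- if (total_len[a] < total_len[b]) a
                    else if (total_len[b] < total_len[a]) b
                    else max(a, b)  # tie: lexicographically later id
            break
          }
        }
        if (!is.null(drop)) break
      }
    }
    if (is.null(drop)) break
    removed <- c(removed, drop)
    alive <- setdiff(alive, drop)
  }
  out <- loci[alive]
  attr(out, "removed") <- removed
  out
}

#' Mask repetitive regions by elevated k-mer coverage
#'
#' Profiles each sequence's k-mers against the read set; cells whose
#' covering-k-mer coverage exceeds `elevation_factor` times the sequence's
#' median track value are masked. An all-zero track masks nothing.
#'
#' @param aln An `alignment_matrix`.
#' @param reads Character vector or sequence tibble of WGS reads.
#' @param k k-mer size (default 20).
#' @param elevation_factor Multiple of the per-sequence median regarded as
#'   substantially elevated (default 5).
#' @return The alignment with repeat cells masked.
#' @export
mask_repetitive_regions <- function(aln, reads, k = 20L, elevation_factor = 5) {
  if (is.data.frame(reads)) reads <- reads$seq
  for (i in seq_along(aln$taxa)) {
    row <- aln$chars[i, ]
    unpos <- which(row != "-")
    if (length(unpos) < k) next
    s <- paste(row[unpos], collapse = "")
    trk <- coverage_track(s, reads, k = k, canonical = TRUE)
    med <- stats::median(trk$coverage)
    if (all(trk$coverage == 0)) next
    hot <- trk$coverage > elevation_factor * med
    aln$mask[i, unpos[hot]] <- TRUE
  }
  aln
}

#' Concatenate loci into a supermatrix
#'
#' Taxa missing from a locus are padded with gaps; the partition table gives
#' 1-based inclusive column ranges per locus in the RAxML dialect.
#'
#' @param loci Named list of `alignment_matrix` objects (trimmed).
#' @param taxa_order Optional explicit taxon order; defaults to the sorted
#'   union of all taxa.
#' @return List with `supermatrix` (an `alignment_matrix`) and `partitions`
#'   (tibble `locus_id`, `start`, `end`).
#' @export
concatenate_loci <- function(loci, taxa_order = NULL) {
  ids <- names(loci) %||% vapply(loci, function(a) a$locus_id, character(1))
  for (a in loci) {
    if (anyDuplicated(a$taxa) > 0) abort("duplicate taxon within one locus")
  }
  taxa <- taxa_order %||% sort(unique(unlist(lapply(loci, function(a) a$taxa))))
  lens <- unname(vapply(loci, function(a) ncol(a$chars), integer(1)))
  total <- sum(lens)
  chars <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  mask <- matrix(FALSE, length(taxa), total)
  offset <- 0L
  parts <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    a <- loci[[i]]
    cols <- offset + seq_len(lens[i])
    rows <- match(a$taxa, taxa)
    chars[rows, cols] <- a$chars
    mask[rows, cols] <- a$mask
    parts[[i]] <- tibble::tibble(locus_id = ids[i],
                                 start = offset + 1L, end = offset + lens[i])
    offset <- offset + lens[i]
  }
  sm <- structure(list(taxa = taxa, chars = chars, mask = mask,
                       locus_id = "supermatrix"),
                  class = "alignment_matrix")
  list(supermatrix = sm, partitions = dplyr::bind_rows(parts))
}

#' Per-locus QC report
#'
#' Masked fraction and removed-site counts per locus, the automated stand-in
#' for visual alignment inspection.
#'
#' @param before,after Named lists of `alignment_matrix` objects, the same
#'   loci before and after [trim_alignment()].
#' @return Tibble with one row per locus.
#' @export
qc_report <- function(before, after) {
  ids <- names(after)
  dplyr::bind_rows(lapply(ids, function(id) {
    tibble::tibble(
      locus_id = id,
      n_taxa = length(after[[id]]$taxa),
      sites_before = ncol(before[[id]]$chars),
      sites_after = ncol(after[[id]]$chars),
      sites_removed = ncol(before[[id]]$chars) - ncol(after[[id]]$chars),
      masked_fraction = mean(after[[id]]$mask)
    )
  }))
}
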