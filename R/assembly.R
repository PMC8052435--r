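# Capture-read processing: demultiplexing, overlapping-pair merging,
# spaced-seed recruitment to loci, quasi-de novo extension assembly, and
# IUPAC ambiguity consensus calling under the binomial error model.

#' Demultiplex reads by exact index match
#'
#' A read is assigned to a sample only when its index sequence equals a map
#' entry exactly (no mismatches tolerated); every other read goes to the
#' `"undetermined"` bin.
#'
#' @param reads Sequence tibble with an `index` column.
#' @param index_map Tibble with columns `index`, `sample` (or a named
#'   character vector `sample = index`).
#' @return `reads` with a `sample` column.
#' @export
demultiplex <- function(reads, index_map) {
  if (!is.data.frame(index_map)) {
    index_map <- tibble::tibble(index = unname(index_map), sample = names(index_map))
  }
  if (anyDuplicated(index_map$index) > 0) {
    abort("duplicate index assigned to two samples")
  }
  if (!"index" %in% names(reads)) abort("reads must carry an 'index' column")
  m <- match(toupper(reads$index), toupper(index_map$index))
  reads$sample <- ifelse(is.na(m), "undetermined", index_map$sample[m])
  reads
}

#' Merge overlapping read pairs
#'
#' Finds the best gapless overlap of the reverse-complemented mate against
#' read 1 (maximizing matches); pairs with an overlap of at least
#' `min_overlap` bases and a mismatch rate at most `max_mismatch_rate` are
#' merged. Within the overlap the higher-quality base is kept, with merged
#' quality `max(q1, q2)` on agreement and `|q1 - q2|` on conflict; adapter
#' bases read through beyond the fragment ends are removed.
#'
#' @param pairs Tibble with columns `id`, `seq1`, `seq2` and optionally
#'   `qual1`, `qual2` (list-columns of integer Phred scores).
#' @param min_overlap Minimum overlap length (default 12).
#' @param max_mismatch_rate Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return Tibble with `id`, `merged` (logical), `seq`, `qual`, `overlap`,
#'   `mismatches`; unmerged pairs keep `seq = NA` and retain their inputs.
#' @export
merge_pairs <- function(pairs, min_overlap = 12L, max_mismatch_rate = 0.1) {
  n <- nrow(pairs)
  q1 <- if ("qual1" %in% names(pairs)) pairs$qual1 else rep(list(integer(0)), n)
  q2 <- if ("qual2" %in% names(pairs)) pairs$qual2 else rep(list(integer(0)), n)
  q1 <- lapply(q1, function(q) if (is.null(q)) integer(0) else as.integer(q))
  q2 <- lapply(q2, function(q) if (is.null(q)) integer(0) else as.integer(q))
  res <- cpp_merge_pairs(toupper(pairs$seq1), toupper(pairs$seq2), q1, q2,
                         as.integer(min_overlap), max_mismatch_rate)
  tibble::tibble(
    id = pairs$id,
    merged = res$merged,
    seq = as.character(res$seq),
    qual = lapply(res$qual, function(q) if (is.null(q)) integer(0) else q),
    overlap = res$overlap,
    mismatches = res$mismatches
  )
}

#' Recruit reads to loci
#'
#' Each read (either strand) is tested against every per-locus reference
#' with the seed-and-confirm criterion; a passing read is assigned to the
#' locus of its best-scoring reference. Reads passing for several loci are
#' assigned to the best and flagged (`multi_locus`); reads whose best
#' placement is tied between incompatible positions are flagged
#' `ambiguous`. Non-passing reads remain unassigned (`locus` NA).
#'
#' @param reads Sequence tibble.
#' @param references Sequence tibble of per-locus reference sequences with a
#'   `locus` column (defaults to the reference `id`).
#' @param config A [pipeline_config()].
#' @return `reads` with columns `locus`, `ref_id`, `strand`, `offset`
#'   (1-based start of the oriented read in reference coordinates; may be
#'   non-positive when the read overhangs), `identities`, `multi_locus`,
#'   `ambiguous`.
#' @export
recruit_reads <- function(reads, references, config = NULL) {
  config <- as_config(config)
  if (!"locus" %in% names(references)) references$locus <- references$id
  hits <- cpp_best_hits(toupper(reads$seq), toupper(references$seq),
                        config$seed_window, config$seed_min_matches,
                        config$confirm_window, config$confirm_min_matches,
                        config$ambiguity_margin)
  assigned <- hits$ref > 0
  ridx <- ifelse(assigned, hits$ref, NA_integer_)
  reads$locus <- references$locus[ridx]
  reads$ref_id <- references$id[ridx]
  reads$strand <- ifelse(assigned, ifelse(hits$strand > 0, "+", "-"), NA_character_)
  reads$offset <- ifelse(assigned, hits$offset + 1L, NA_integer_)
  reads$identities <- hits$identities
  nloci <- vapply(seq_len(nrow(hits)), function(i) {
    if (hits$ref[i] == 0) 0L else hits$n_refs_passed[i]
  }, integer(1))
  reads$multi_locus <- assigned & nloci > 1L
  reads$ambiguous <- hits$ambiguous
  reads
}

#' Build an assembly cluster from recruited reads
#'
#' Lays the recruited reads of one locus/sample out gaplessly at their
#' recruitment offsets and tallies per-site base counts.
#'
#' @param recruited Recruited reads (rows of [recruit_reads()] output with a
#'   non-NA `locus`), already restricted to one locus and sample.
#' @param locus_id,sample Labels recorded on the cluster.
#' @return An `assembly_cluster`: list with `locus_id`, `sample`, `reads`
#'   (tibble id/seq/offset/strand in consensus coordinates), `origin` (the
#'   reference coordinate of consensus position 1), `site_counts` (5 x L
#'   matrix, rows A,C,G,T,N) and `avg_depth`.
#' @export
assembly_cluster <- function(recruited, locus_id = recruited$locus[1],
                             sample = if ("sample" %in% names(recruited))
                               recruited$sample[1] else NA_character_) {
  stopifnot(nrow(recruited) > 0)
  oriented <- ifelse(recruited$strand == "-", revcomp(recruited$seq), recruited$seq)
  reads <- tibble::tibble(id = recruited$id, seq = oriented,
                          offset = recruited$offset, strand = recruited$strand)
  new_cluster(reads, locus_id, sample)
}

new_cluster <- function(reads, locus_id, sample) {
  reads <- dplyr::arrange(reads, .data$id, .data$offset)
  origin <- min(reads$offset)
  reads$cpos <- reads$offset - origin + 1L
  width <- max(reads$cpos + nchar(reads$seq) - 1L)
  counts <- tally_sites(reads$seq, reads$cpos, width)
  total <- sum(counts)
  structure(
    list(locus_id = locus_id, sample = sample, reads = reads,
         origin = origin, site_counts = counts,
         avg_depth = total / ncol(counts)),
    class = "assembly_cluster"
  )
}

# 5 x width base-count matrix from oriented sequences at 1-based offsets
tally_sites <- function(seqs, cpos, width) {
  bases <- c("A", "C", "G", "T", "N")
  chars <- strsplit(seqs, "")
  lens <- lengths(chars)
  pos <- unlist(lapply(seq_along(chars), function(i) cpos[i] + seq_len(lens[i]) - 1L))
  ch <- unlist(chars)
  code <- match(ch, bases)
  code[is.na(code)] <- 5L
  keep <- pos >= 1L & pos <= width
  idx <- (pos[keep] - 1L) * 5L + code[keep]
  matrix(tabulate(idx, nbins = 5L * width), nrow = 5,
         dimnames = list(bases, NULL))
}

#' @export
print.assembly_cluster <- function(x, ...) {
  cat(sprintf("<assembly_cluster> %s / %s: %d reads, %d sites, avg depth %.1f\n",
              x$sample, x$locus_id, nrow(x$reads), ncol(x$site_counts), x$avg_depth))
  invisible(x)
}

#' @export
glance.assembly_cluster <- function(x, ...) {
  tibble::tibble(locus_id = x$locus_id, sample = x$sample,
                 n_reads = nrow(x$reads), length = ncol(x$site_counts),
                 avg_depth = x$avg_depth)
}

# working consensus: plain majority over A,C,G,T (ties resolved in ACGT
# order); sites below min_depth become N (N never matches, so they cannot
# recruit during extension -- this keeps sparse off-target chains out of the
# assembly). Ambiguity codes only appear at the final call_consensus() stage.
working_consensus <- function(counts, min_depth = 1L) {
  acgt <- counts[1:4, , drop = FALSE]
  depth <- colSums(acgt)
  best <- max.col(t(acgt), ties.method = "first")
  ifelse(depth >= min_depth & depth > 0, c("A", "C", "G", "T")[best], "N") |>
    paste(collapse = "")
}

#' Extend an assembly cluster into flanking regions
#'
#' Iteratively rebuilds the working consensus, re-scans the unassigned reads
#' against it with the same seed-and-confirm criterion, adds the hits at
#' their offsets (extending the consensus ends) and stops when an iteration
#' adds no reads. The recruited set grows monotonically and the iteration
#' count is bounded by the number of unassigned reads. Reads with tied
#' incompatible placements are rejected and reported.
#'
#' @param cluster An `assembly_cluster`.
#' @param unassigned Sequence tibble of unassigned reads.
#' @param config A [pipeline_config()].
#' @return The extended `assembly_cluster`, with attribute `rejected`
#'   holding ids of ambiguous-placement reads.
#' @export
extend_assembly <- function(cluster, unassigned, config = NULL) {
  config <- as_config(config)
  res <- extend_assemblies(list(cluster), unassigned, config)
  out <- res$clusters[[1]]
  attr(out, "rejected") <- res$rejected
  out
}

#' Jointly extend all clusters of a sample
#'
#' Extends every cluster against one shared pool of unassigned reads; each
#' read joins the cluster whose working consensus it matches best, so a read
#' can never be claimed by two loci. Iteration stops when a full pass adds
#' no reads anywhere.
#'
#' @param clusters List of `assembly_cluster` objects.
#' @param unassigned Sequence tibble of unassigned reads.
#' @param config A [pipeline_config()].
#' @return List with `clusters` (extended, same order) and `rejected`
#'   (character vector of ambiguous read ids).
#' @export
extend_assemblies <- function(clusters, unassigned, config = NULL) {
  config <- as_config(config)
  rejected <- character(0)
  if (is.null(unassigned) || nrow(unassigned) == 0) {
    return(list(clusters = clusters, rejected = rejected))
  }
  pool <- dplyr::arrange(unassigned, .data$id)  # canonical order
  max_iter <- nrow(pool)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (nrow(pool) == 0 || iter > max_iter) break
    consensi <- vapply(clusters, function(cl) {
      working_consensus(cl$site_counts, min_depth = config$min_extension_depth)
    }, character(1))
    hits <- cpp_best_hits(toupper(pool$seq), consensi,
                          config$seed_window, config$seed_min_matches,
                          config$confirm_window, config$confirm_min_matches,
                          config$ambiguity_margin)
    amb <- hits$ref > 0 & hits$ambiguous
    rejected <- c(rejected, pool$id[amb])
    take <- hits$ref > 0 & !hits$ambiguous
    if (!any(take)) break
    for (ci in unique(hits$ref[take])) {
      sel <- which(take & hits$ref == ci)
      cl <- clusters[[ci]]
      oriented <- ifelse(hits$strand[sel] < 0, revcomp(pool$seq[sel]), pool$seq[sel])
      # offsets are in working-consensus coordinates; convert to the
      # cluster's reference frame
      new_reads <- tibble::tibble(
        id = pool$id[sel], seq = oriented,
        offset = hits$offset[sel] + 1L + cl$origin - 1L,
        strand = ifelse(hits$strand[sel] < 0, "-", "+")
      )
      all_reads <- dplyr::bind_rows(
        cl$reads[, c("id", "seq", "offset", "strand")], new_reads
      )
      clusters[[ci]] <- new_cluster(all_reads, cl$locus_id, cl$sample)
    }
    pool <- pool[!(take | amb), , drop = FALSE]
  }
  list(clusters = clusters, rejected = unique(rejected))
}

#' Call an ambiguity-coded consensus
#'
#' Emits a consensus only for clusters whose average depth strictly exceeds
#' `min_avg_depth` (the "greater than an average of 250 reads" gate). At
#' each site the majority base is always retained; a minority base observed
#' `c` times out of depth `n` is retained only when its count cannot be
#' explained by the sequencing-error model, i.e. the one-sided exact
#' binomial tail `P(X >= c | n, p = error_rate)` falls below `alpha`. The
#' residue is the IUPAC code of the retained base set; zero-depth sites are
#' N.
#'
#' @param cluster An `assembly_cluster`.
#' @param config A [pipeline_config()] (`min_avg_depth`, `error_rate`,
#'   `alpha`).
#' @return A `consensus_seq` object, or `NULL` when the cluster fails the
#'   depth gate.
#' @export
call_consensus <- function(cluster, config = NULL) {
  config <- as_config(config)
  if (!(cluster$avg_depth > config$min_avg_depth)) {
    return(NULL)
  }
  counts <- cluster$site_counts[1:4, , drop = FALSE]
  L <- ncol(counts)
  depth <- colSums(counts)
  residues <- character(L)
  retained <- vector("list", L)
  for (i in seq_len(L)) {
    n <- depth[i]
    if (n == 0) { residues[i] <- "N"; retained[[i]] <- character(0); next }
    cc <- counts[, i]
    keep <- retained_bases(cc, n, config$error_rate, config$alpha)
    retained[[i]] <- keep
    residues[i] <- iupac_code(keep)
  }
  structure(
    list(id = paste(cluster$sample, cluster$locus_id, sep = "_"),
         locus_id = cluster$locus_id, sample = cluster$sample,
         seq = paste(residues, collapse = ""),
         sites = tibble::tibble(site = seq_len(L), depth = as.integer(depth),
                                retained = retained),
         avg_depth = cluster$avg_depth),
    class = "consensus_seq"
  )
}

# base-retention rule at one site: majority base(s) always kept (a tie keeps
# every tied base); each minority base kept iff its count is too large for
# the error model
retained_bases <- function(cc, n, error_rate, alpha) {
  bases <- c("A", "C", "G", "T")
  mx <- max(cc)
  keep <- cc == mx
  minor <- which(!keep & cc > 0)
  for (b in minor) {
    tail_p <- stats::pbinom(cc[b] - 1, n, error_rate, lower.tail = FALSE)
    if (tail_p < alpha) keep[b] <- TRUE
  }
  bases[keep]
}

#' @export
print.consensus_seq <- function(x, ...) {
  n_amb <- sum(!strsplit(x$seq, "")[[1]] %in% c("A", "C", "G", "T"))
  cat(sprintf("<consensus_seq> %s: %d bp, avg depth %.1f, %d ambiguous site(s)\n",
              x$id, nchar(x$seq), x$avg_depth, n_amb))
  invisible(x)
}

#' @export
tidy.consensus_seq <- function(x, ...) {
  res <- strsplit(x$seq, "")[[1]]
  dplyr::mutate(x$sites, residue = res,
                n_retained = lengths(.data$retained))
}

#' @export
glance.consensus_seq <- function(x, ...) {
  res <- strsplit(x$seq, "")[[1]]
  tibble::tibble(
    id = x$id, locus_id = x$locus_id, sample = x$sample,
    length = nchar(x$seq), avg_depth = x$avg_depth,
    n_ambiguous = sum(!res %in% c("A", "C", "G", "T", "N")),
    n_undefined = sum(res == "N")
  )
}

#' Consensus sequences as a sequence tibble
#'
#' @param consensi List of `consensus_seq` objects (NULLs dropped).
#' @return Sequence tibble with `id`, `seq`, `sample`, `locus`.
#' @export
consensus_tbl <- function(consensi) {
  consensi <- purrr::compact(consensi)
  if (length(consensi) == 0) {
    return(seq_tbl(character(0), character(0), sample = character(0),
                   locus = character(0)))
  }
  seq_tbl(
    id = purrr::map_chr(consensi, "id"),
    seq = purrr::map_chr(consensi, "seq"),
    sample = purrr::map_chr(consensi, "sample"),
    locus = purrr::map_chr(consensi, "locus_id")
  )
}

#' Write per-site cluster counts as TSV
#'
#' @param cluster An `assembly_cluster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(cluster, path) {
  m <- t(cluster$site_counts)
  df <- tibble::as_tibble(m)
  df$site <- seq_len(nrow(df))
  readr::write_tsv(df[, c("site", "A", "C", "G", "T", "N")], path, progress = FALSE)
  invisible(path)
}
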