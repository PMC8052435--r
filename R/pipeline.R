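# High-level composition of the capture-processing stages, shared by the
# command-line wrapper and the acceptance checks.

#' Process one sample's capture reads into locus consensi
#'
#' Recruits merged reads to the per-locus references (seed-and-confirm),
#' seeds one assembly cluster per locus, extends all clusters jointly
#' against the unassigned pool, and calls the ambiguity-coded consensus for
#' every cluster clearing the depth gate.
#'
#' @param reads Sequence tibble of merged reads for one sample.
#' @param references Sequence tibble of per-locus reference sequences
#'   (probe-region sequences), `locus` column defaulting to `id`.
#' @param sample Sample label.
#' @param config A [pipeline_config()].
#' @return List with `clusters` (per locus), `consensi` (list of
#'   `consensus_seq`, depth-gated), `rejected` (ambiguous read ids) and
#'   `unassigned` (count).
#' @export
process_sample <- function(reads, references, sample = NA_character_,
                           config = NULL) {
  config <- as_config(config)
  rec <- recruit_reads(reads, references, config)
  assigned <- rec[!is.na(rec$locus) & !rec$ambiguous, , drop = FALSE]
  pool <- rec[is.na(rec$locus), c("id", "seq"), drop = FALSE]
  clusters <- assigned |>
    dplyr::group_by(.data$locus) |>
    dplyr::group_map(function(df, key) {
      df$locus <- key$locus
      assembly_cluster(df, locus_id = key$locus, sample = sample)
    })
  ext <- extend_assemblies(clusters, pool, config)
  consensi <- purrr::compact(lapply(ext$clusters, call_consensus, config = config))
  list(clusters = ext$clusters, consensi = consensi,
       rejected = ext$rejected, unassigned = nrow(pool))
}

#' Design-phase target discovery
#'
#' Reciprocal best-match pairing of the two transcript sets, genome
#' scanning with the paired transcripts of the genome taxon as references,
#' and candidate-window extraction.
#'
#' @param transcripts_a,transcripts_b Transcript sequence tibbles; `set_a`
#'   must come from the same taxon as `genome`.
#' @param genome Sequence tibble of the reference-taxon genome assembly.
#' @param config A [pipeline_config()].
#' @return List with `pairs`, `targets` (locus target tibble) and `windows`
#'   (extracted candidate sequences).
#' @export
discover_targets <- function(transcripts_a, transcripts_b, genome,
                             config = NULL) {
  config <- as_config(config)
  pairs <- reciprocal_best_pairs(transcripts_a, transcripts_b, config)
  refs <- transcripts_a[transcripts_a$id %in% pairs$id_a, , drop = FALSE]
  targets <- scan_genome(genome, refs, config)
  windows <- extract_windows(genome, targets)
  list(pairs = pairs, targets = targets, windows = windows)
}

#' Run the full simulated-panel recovery study
#'
#' Generates the default divergent-taxon panel, runs target discovery on the
#' reference taxon's genome (plus pure-random decoy contigs of equal
#' length), simulates enrichment reads, merges, recruits, extends and calls
#' consensi for every sample, clusters the consensi into ortholog groups,
#' and scores everything against the generator's truth tables.
#'
#' @param seed Seed controlling the panel, the reads and the decoys.
#' @param n_decoys Number of decoy contigs scanned (default 100).
#' @param config A [pipeline_config()].
#' @param panel_args Named list of overrides passed to [simulate_panel()].
#' @return List with `metrics` (one-row tibble) and the intermediate
#'   objects (`panel`, `targets`, `consensi`, `groups`).
#' @export
run_recovery_study <- function(seed = 1L, n_decoys = 100L, config = NULL,
                               panel_args = list()) {
  config <- as_config(config)
  panel <- do.call(simulate_panel, c(list(seed = seed), panel_args))
  n_loci <- panel$truth$params$n_loci
  truth <- panel$truth$loci

  # design-phase discovery on the reference taxon's genome
  disc <- discover_targets(panel$transcripts_a, panel$transcripts_b,
                           panel$genomes[1, ], config)
  lt1 <- truth[truth$taxon == panel$genomes$sample[1], ]
  discovered <- vapply(seq_len(nrow(lt1)), function(i) {
    any(disc$targets$start <= lt1$core_start[i] &
          disc$targets$end >= lt1$core_end[i] &
          disc$targets$strand == lt1$strand[i])
  }, logical(1))

  # pure-random decoy contigs of the same length as the panel contigs
  set.seed(seed + 1L)
  contig_len <- nchar(panel$genomes$seq[1])
  decoys <- seq_tbl(sprintf("decoy%03d", seq_len(n_decoys)),
                    vapply(seq_len(n_decoys), function(i) random_dna(contig_len),
                           character(1)))
  false_targets <- nrow(scan_genome(decoys, panel$transcripts_a, config))

  # capture, merge, per-sample assembly and consensus
  cap <- simulate_capture_reads(panel, seed = seed + 2L,
                                error_rate = config$error_rate)
  m <- merge_pairs(cap$pairs, config$min_overlap, config$max_mismatch_rate)
  all_cons <- list()
  for (s in unique(panel$genomes$sample)) {
    sel <- which(m$merged & cap$pairs$sample == s)
    res <- process_sample(seq_tbl(m$id[sel], m$seq[sel]),
                          panel$transcripts_a, sample = s, config = config)
    all_cons <- c(all_cons, res$consensi)
  }
  identities <- vapply(all_cons, function(x) {
    tr <- truth[truth$taxon == x$sample & truth$locus == x$locus_id, ]
    percent_identity(x$seq, tr$seq)
  }, numeric(1))

  # orthology over consensi plus reference-tagged transcript cores
  ctab <- consensus_tbl(all_cons)
  refs <- panel$transcripts_a
  refs$sample <- "ref"
  pool <- dplyr::bind_rows(
    dplyr::mutate(ctab, is_reference = FALSE, locus = NA_character_),
    dplyr::mutate(refs[, c("id", "seq", "sample", "locus")],
                  is_reference = TRUE)
  )
  dm <- build_distance_matrix(pool, k = config$kmer_k)
  groups <- cluster_orthologs(dm, pool[, c("id", "sample", "locus",
                                           "is_reference")],
                              linkage = config$cluster_linkage,
                              cutoff = config$cluster_cutoff)
  members <- groups[!groups$is_reference & !groups$paralog, ]
  member_truth <- vapply(members$id, function(id) {
    all_cons[[match(id, vapply(all_cons, `[[`, character(1), "id"))]]$locus_id
  }, character(1))
  grouped_ok <- members$locus_id == member_truth
  recovered_loci <- unique(members$locus_id[grouped_ok &
                                              members$id %in%
                                                ctab$id[identities >= 99]])

  metrics <- tibble::tibble(
    n_loci = n_loci,
    n_samples = panel$truth$params$n_taxa,
    targets_discovered = nrow(disc$targets),
    discovery_recovery_pct = 100 * mean(discovered),
    decoy_false_targets = false_targets,
    n_consensi = length(all_cons),
    consensus_recovery_pct = 100 * length(all_cons) /
      (n_loci * panel$truth$params$n_taxa),
    mean_consensus_identity_pct = mean(identities),
    frac_consensi_ge99_pct = 100 * mean(identities >= 99),
    ortholog_group_precision_pct = 100 * mean(grouped_ok),
    locus_recovery_pct = 100 * length(recovered_loci) / n_loci
  )
  list(metrics = metrics, panel = panel, targets = disc$targets,
       consensi = all_cons, groups = groups, identities = identities)
}
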