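# Seedable simulator of divergent taxon panels sharing conserved anchor
# loci with variable flanks, plus error-bearing paired reads -- with full
# truth tables, so every pipeline stage is testable without downloads.
#
# Default conditions emulate the study regime this pipeline targets: ten
# botryllid-like taxa sharing conserved anchors, ~10% sequence divergence
# (flanks at the full rate, conserved cores at half), 1% per-base
# sequencing error, and deep (hundreds-fold) capture coverage over loci.

#' Mutate a sequence by random substitutions
#'
#' Each position is substituted (to one of the three other bases) with
#' probability `rate`. Substitution-only, so truth alignments stay
#' positional.
#'
#' @param seq Sequence string.
#' @param rate Per-site substitution probability.
#' @return Mutated sequence string.
#' @export
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  L <- nchar(seq)
  hit <- which(stats::runif(L) < rate)
  if (length(hit) == 0) return(seq)
  alt <- sample(0:2, length(hit), replace = TRUE)
  cpp_apply_subs(seq, rep(1L, length(hit)), hit, alt)[1]
}

#' Simulate a panel of divergent taxa sharing anchor loci
#'
#' Generates a random root sequence per locus (conserved core plus flanks),
#' mutates a copy per taxon (core at half the requested divergence, flanks
#' at the full rate), embeds the copies on random strands in random genomic
#' background, plants exact-copy repeat families in the background, and
#' exposes the cores of the first two taxa as transcript sets. Fully
#' determined by `seed`.
#'
#' @param n_taxa Number of taxa (default 10, the design panel size).
#' @param n_loci Number of anchor loci (default 20).
#' @param locus_length Conserved core length in bp (default 400).
#' @param flank_length Flank length in bp on each side (default 400).
#' @param within_divergence Per-taxon divergence from the locus root
#'   (default 0.10; must be in `[0, 0.3]`).
#' @param background_length Background bp per taxon genome (default 400000,
#'   giving inter-locus spacing comfortably above the 10 kb candidate
#'   window so neighbouring loci are not fused during discovery).
#' @param n_repeat_families Number of repeat families (default 2).
#' @param repeat_length,repeat_copies Repeat unit length and copies per
#'   taxon genome (defaults 300 and 10).
#' @param seed RNG seed.
#' @return List with `genomes` (sequence tibble, one contig per taxon),
#'   `transcripts_a`, `transcripts_b` (core sequences of taxa 1 and 2),
#'   `roots` (per-locus root inserts) and `truth` (list of tibbles: `loci`,
#'   `repeats`; plus `params`).
#' @export
simulate_panel <- function(n_taxa = 10L, n_loci = 20L, locus_length = 400L,
                           flank_length = 400L, within_divergence = 0.10,
                           background_length = 400000L,
                           n_repeat_families = 2L, repeat_length = 300L,
                           repeat_copies = 10L, seed = 1L) {
  if (within_divergence < 0 || within_divergence > 0.3) {
    abort("within_divergence must be in [0, 0.3]")
  }
  if (min(n_taxa, n_loci, locus_length, flank_length, background_length) <= 0) {
    abort("panel parameters must be positive")
  }
  set.seed(seed)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  loci <- sprintf("locus%03d", seq_len(n_loci))

  root_core <- vapply(seq_len(n_loci), function(i) random_dna(locus_length), character(1))
  root_flankl <- vapply(seq_len(n_loci), function(i) random_dna(flank_length), character(1))
  root_flankr <- vapply(seq_len(n_loci), function(i) random_dna(flank_length), character(1))
  repeats <- if (n_repeat_families > 0) {
    vapply(seq_len(n_repeat_families), function(i) random_dna(repeat_length), character(1))
  } else character(0)

  genome_rows <- list()
  loci_truth <- list()
  rep_truth <- list()
  transcripts <- list()
  for (ti in seq_len(n_taxa)) {
    # per-taxon locus copies
    cores <- vapply(root_core, mutate_seq, character(1), rate = within_divergence / 2)
    fls <- vapply(root_flankl, mutate_seq, character(1), rate = within_divergence)
    frs <- vapply(root_flankr, mutate_seq, character(1), rate = within_divergence)
    inserts <- paste0(fls, cores, frs)
    # background chunks; repeat copies live in the first chunk, kept clear
    # of the locus inserts (anchor neighbourhoods are repeat-poor by
    # construction -- the design stage masks repetitive regions)
    n_chunks <- n_loci + 1L
    clearance <- 500L
    lead_len <- max(clearance * 2L, as.integer(round(0.4 * background_length)))
    rest <- max(0L, background_length - lead_len)
    # near-even inter-locus spacing (+/-10% jitter) keeps planted loci more
    # than a candidate window apart
    raw <- stats::runif(n_chunks - 1L, 0.9, 1.1)
    chunk_len <- c(lead_len, as.integer(round(rest * raw / sum(raw))))
    chunks <- vapply(chunk_len, random_dna, character(1))
    rep_local <- list()
    for (fi in seq_along(repeats)) {
      for (cp in seq_len(repeat_copies)) {
        hi <- max(0L, nchar(chunks[1]) - clearance)
        at <- sample(0:hi, 1)
        chunks[1] <- paste0(substr(chunks[1], 1, at), repeats[fi],
                            substring(chunks[1], at + 1))
        rep_local[[length(rep_local) + 1]] <- list(family = fi, chunk = 1L)
      }
    }
    strands <- sample(c("+", "-"), n_loci, replace = TRUE)
    placed <- ifelse(strands == "-", revcomp(inserts), inserts)
    contig <- character(2L * n_loci + 1L)
    contig[seq(1, by = 2, length.out = n_chunks)] <- chunks
    contig[seq(2, by = 2, length.out = n_loci)] <- placed
    contig_seq <- paste(contig, collapse = "")
    contig_id <- paste0(taxa[ti], "_contig")
    # coordinates
    piece_len <- nchar(contig)
    piece_end <- cumsum(piece_len)
    piece_start <- piece_end - piece_len + 1L
    locus_piece <- seq(2, by = 2, length.out = n_loci)
    loci_truth[[ti]] <- tibble::tibble(
      taxon = taxa[ti], contig = contig_id, locus = loci,
      start = piece_start[locus_piece], end = piece_end[locus_piece],
      strand = strands,
      core_start = piece_start[locus_piece] + flank_length,
      core_end = piece_end[locus_piece] - flank_length,
      seq = inserts, core_seq = cores
    )
    # repeat spans: locate inside the finished contig chunks
    if (length(rep_local) > 0) {
      rt <- lapply(rep_local, function(r) {
        chunk_piece <- seq(1, by = 2, length.out = n_chunks)[r$chunk]
        hit <- gregexpr(repeats[r$family], substr(contig_seq,
                                                  piece_start[chunk_piece],
                                                  piece_end[chunk_piece]),
                        fixed = TRUE)[[1]]
        tibble::tibble(taxon = taxa[ti], contig = contig_id,
                       family = sprintf("rep%02d", r$family),
                       start = piece_start[chunk_piece] + hit - 1L,
                       end = piece_start[chunk_piece] + hit - 1L +
                         repeat_length - 1L)
      })
      rep_truth[[length(rep_truth) + 1]] <- dplyr::bind_rows(rt)
    }
    genome_rows[[ti]] <- seq_tbl(id = contig_id, seq = contig_seq,
                                 sample = taxa[ti])
    if (ti <= 2) {
      transcripts[[ti]] <- seq_tbl(id = paste0(loci, "_", taxa[ti]),
                                   seq = cores, locus = loci,
                                   sample = taxa[ti])
    }
  }
  list(
    genomes = dplyr::bind_rows(genome_rows),
    transcripts_a = transcripts[[1]],
    transcripts_b = if (n_taxa >= 2) transcripts[[2]] else NULL,
    roots = seq_tbl(id = loci, seq = paste0(root_flankl, root_core, root_flankr),
                    locus = loci),
    truth = list(
      loci = dplyr::bind_rows(loci_truth),
      repeats = if (length(rep_truth)) dplyr::bind_rows(rep_truth) else
        tibble::tibble(taxon = character(), contig = character(),
                       family = character(), start = integer(), end = integer()),
      params = list(n_taxa = n_taxa, n_loci = n_loci,
                    locus_length = locus_length, flank_length = flank_length,
                    within_divergence = within_divergence, seed = seed)
    )
  )
}

# shared fragment -> paired-read builder
build_pairs <- function(contig_seq, contig_id, starts, flens, read_length,
                        error_rate, adapter, het_sites, id_prefix,
                        sample = NA_character_, index = NA_character_) {
  n <- length(starts)
  if (n == 0) {
    return(list(pairs = tibble::tibble(id = character(), seq1 = character(),
                                       seq2 = character(), qual1 = list(),
                                       qual2 = list(), sample = character(),
                                       index = character()),
                truth = tibble::tibble(id = character(), contig = character(),
                                       start = integer(), end = integer(),
                                       strand = character())))
  }
  ends <- starts + flens - 1L
  frags <- substring(contig_seq, starts, ends)
  # planted heterozygous sites: each fragment draws an allele per site
  if (!is.null(het_sites) && nrow(het_sites) > 0) {
    hs <- het_sites[het_sites$contig == contig_id, , drop = FALSE]
    for (k in seq_len(nrow(hs))) {
      covered <- which(starts <= hs$pos[k] & ends >= hs$pos[k])
      if (length(covered) == 0) next
      take <- covered[stats::runif(length(covered)) < 0.5]
      for (fi in take) {
        lp <- hs$pos[k] - starts[fi] + 1L
        substr(frags[fi], lp, lp) <- hs$alt[k]
      }
    }
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  frags[strand == "-"] <- revcomp(frags[strand == "-"])
  pad <- function(x) {
    short <- nchar(x) < read_length
    if (any(short)) {
      fill <- paste0(adapter, strrep("A", read_length))
      x[short] <- paste0(x[short], substr(fill, 1, read_length - nchar(x[short])))
    }
    substr(x, 1, read_length)
  }
  r1 <- pad(frags)
  r2 <- pad(revcomp(frags))
  # sequencing errors: uniform per-base substitutions
  if (error_rate > 0) {
    inject <- function(reads) {
      total <- length(reads) * read_length
      n_err <- stats::rbinom(1, total, error_rate)
      if (n_err == 0) return(reads)
      at <- sample.int(total, n_err)
      cpp_apply_subs(reads, (at - 1L) %/% read_length + 1L,
                     (at - 1L) %% read_length + 1L,
                     sample(0:2, n_err, replace = TRUE))
    }
    r1 <- inject(r1); r2 <- inject(r2)
  }
  q <- if (error_rate > 0) as.integer(round(-10 * log10(error_rate))) else 40L
  ids <- sprintf("%s_%06d", id_prefix, seq_len(n))
  list(
    pairs = tibble::tibble(
      id = ids, seq1 = r1, seq2 = r2,
      qual1 = rep(list(rep(q, read_length)), n),
      qual2 = rep(list(rep(q, read_length)), n),
      sample = sample, index = index
    ),
    truth = tibble::tibble(id = ids, contig = contig_id,
                           start = starts, end = ends, strand = strand)
  )
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are placed uniformly, sequenced from both ends at
#' `read_length`, hit by per-base substitution errors at `error_rate`, and
#' read through into the adapter when the fragment is shorter than the read.
#' Coverage is read-base coverage: `coverage * L / (2 * read_length)`
#' fragments per contig.
#'
#' @param genome Sequence tibble of contigs (a `sample` column, if present,
#'   is propagated to the reads).
#' @param coverage Requested read-base coverage (default 30, the WGS
#'   regime).
#' @param read_length Read length in bp (default 150).
#' @param fragment_mean,fragment_sd Fragment-length distribution (defaults
#'   250 and 30).
#' @param error_rate Per-base error probability (default 0.01).
#' @param adapter Adapter sequence for read-through.
#' @param het_sites Optional tibble (`contig`, `pos`, `alt`) of 50/50
#'   two-allele sites.
#' @param seed RNG seed.
#' @return List with `pairs` (tibble id/seq1/seq2/qual1/qual2/sample/index)
#'   and `truth` (per-read fragment coordinates).
#' @export
simulate_reads <- function(genome, coverage = 30, read_length = 150L,
                           fragment_mean = 250, fragment_sd = 30,
                           error_rate = 0.01,
                           adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                           het_sites = NULL, seed = 1L) {
  if (coverage <= 0) abort("coverage must be positive")
  set.seed(seed)
  out_p <- list(); out_t <- list()
  for (ci in seq_len(nrow(genome))) {
    L <- nchar(genome$seq[ci])
    n <- round(coverage * L / (2 * read_length))
    flens <- pmin(L, pmax(30L, as.integer(round(stats::rnorm(n, fragment_mean, fragment_sd)))))
    starts <- vapply(flens, function(fl) sample.int(L - fl + 1L, 1), integer(1))
    samp <- if ("sample" %in% names(genome)) genome$sample[ci] else NA_character_
    res <- build_pairs(genome$seq[ci], genome$id[ci], starts, flens,
                       read_length, error_rate, adapter, het_sites,
                       id_prefix = genome$id[ci], sample = samp)
    out_p[[ci]] <- res$pairs; out_t[[ci]] <- res$truth
  }
  list(pairs = dplyr::bind_rows(out_p), truth = dplyr::bind_rows(out_t))
}

#' Simulate capture (target-enriched) reads over the planted loci
#'
#' Emulates hybrid capture: fragments are drawn only from the planted locus
#' windows (padded by `pad` bp) of each taxon genome, at enrichment-scale
#' coverage, plus a small off-target background fraction.
#'
#' @param panel Output of [simulate_panel()].
#' @param coverage Read-base coverage over the captured windows (default
#'   600, an enrichment-scale depth).
#' @param background_fraction Fraction of additional off-target fragments
#'   (default 0.02).
#' @param pad Window padding in bp (default 150).
#' @param read_length,fragment_mean,fragment_sd,error_rate,adapter,het_sites,seed
#'   As in [simulate_reads()].
#' @return List with `pairs` and `truth`, as in [simulate_reads()].
#' @export
simulate_capture_reads <- function(panel, coverage = 600,
                                   background_fraction = 0.02, pad = 150L,
                                   read_length = 150L, fragment_mean = 250,
                                   fragment_sd = 30, error_rate = 0.01,
                                   adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                                   het_sites = NULL, seed = 1L) {
  set.seed(seed)
  out_p <- list(); out_t <- list()
  for (ci in seq_len(nrow(panel$genomes))) {
    contig_id <- panel$genomes$id[ci]
    contig <- panel$genomes$seq[ci]
    L <- nchar(contig)
    wins <- panel$truth$loci[panel$truth$loci$contig == contig_id, ]
    starts <- integer(0); flens <- integer(0)
    for (wi in seq_len(nrow(wins))) {
      lo <- max(1L, wins$start[wi] - pad)
      hi <- min(L, wins$end[wi] + pad)
      n <- round(coverage * (hi - lo + 1L) / (2 * read_length))
      fl <- pmin(hi - lo + 1L,
                 pmax(30L, as.integer(round(stats::rnorm(n, fragment_mean, fragment_sd)))))
      st <- lo + vapply(fl, function(f) sample.int(hi - lo + 1L - f + 1L, 1), integer(1)) - 1L
      starts <- c(starts, st); flens <- c(flens, fl)
    }
    n_bg <- round(background_fraction * length(starts))
    if (n_bg > 0) {
      fl <- pmin(L, pmax(30L, as.integer(round(stats::rnorm(n_bg, fragment_mean, fragment_sd)))))
      st <- vapply(fl, function(f) sample.int(L - f + 1L, 1), integer(1))
      starts <- c(starts, st); flens <- c(flens, fl)
    }
    res <- build_pairs(contig, contig_id, starts, flens, read_length,
                       error_rate, adapter, het_sites,
                       id_prefix = contig_id,
                       sample = panel$genomes$sample[ci])
    out_p[[ci]] <- res$pairs; out_t[[ci]] <- res$truth
  }
  list(pairs = dplyr::bind_rows(out_p), truth = dplyr::bind_rows(out_t))
}
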