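# Shared fixture builders. Simulated panels are cached per session so several
# test files can reuse one generation pass.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small panel: 4 taxa, 4 loci, modest background -- enough for recruitment
# and assembly tests without discovery-scale genomes
small_panel <- function() {
  cached("small_panel", simulate_panel(
    n_taxa = 4, n_loci = 4, locus_length = 400, flank_length = 300,
    within_divergence = 0.10, background_length = 30000,
    n_repeat_families = 1, repeat_length = 300, repeat_copies = 10,
    seed = 42
  ))
}

small_capture <- function() {
  cached("small_capture", simulate_capture_reads(small_panel(), coverage = 500,
                                                 seed = 43))
}

small_merged <- function() {
  cached("small_merged", merge_pairs(small_capture()$pairs))
}

# merged reads of one sample as a sequence tibble
sample_reads <- function(s) {
  m <- small_merged()
  cap <- small_capture()
  sel <- which(m$merged & cap$pairs$sample == s)
  seq_tbl(m$id[sel], m$seq[sel])
}

# build an alignment_matrix from bare strings (or one character vector)
aln_fix <- function(..., locus_id = "locusA") {
  seqs <- unlist(list(...), use.names = FALSE)
  as_alignment(seq_tbl(sprintf("t%02d", seq_along(seqs)), seqs), locus_id)
}

mutate_with_seed <- function(seq, rate, seed) {
  withr::with_seed(seed, mutate_seq(seq, rate))
}
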