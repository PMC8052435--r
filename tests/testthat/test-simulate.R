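test_that("panel simulation is deterministic and honours divergence zero", {
  p1 <- simulate_panel(n_taxa = 3, n_loci = 3, locus_length = 200,
                       flank_length = 100, background_length = 5000,
                       n_repeat_families = 1, repeat_copies = 3, seed = 90)
  p2 <- simulate_panel(n_taxa = 3, n_loci = 3, locus_length = 200,
                       flank_length = 100, background_length = 5000,
                       n_repeat_families = 1, repeat_copies = 3, seed = 90)
  expect_identical(p1$genomes, p2$genomes)
  expect_identical(p1$truth$loci, p2$truth$loci)
  # divergence zero: every taxon copy equals the root insert
  p0 <- simulate_panel(n_taxa = 3, n_loci = 2, locus_length = 150,
                       flank_length = 80, within_divergence = 0,
                       background_length = 4000, n_repeat_families = 0,
                       seed = 91)
  for (i in seq_len(nrow(p0$truth$loci))) {
    row <- p0$truth$loci[i, ]
    expect_equal(row$seq, p0$roots$seq[p0$roots$locus == row$locus])
  }
  expect_error(simulate_panel(within_divergence = 0.5), "divergence")
})

test_that("planted coordinates and strands are valid against the genomes", {
  panel <- small_panel()
  lt <- panel$truth$loci
  for (i in seq_len(nrow(lt))) {
    contig <- panel$genomes$seq[panel$genomes$id == lt$contig[i]]
    slice <- substr(contig, lt$start[i], lt$end[i])
    want <- if (lt$strand[i] == "-") revcomp(lt$seq[i]) else lt$seq[i]
    expect_equal(slice, want)
  }
  # repeat spans also match their family sequence exactly across copies
  rt <- panel$truth$repeats
  fam_seqs <- unique(vapply(seq_len(nrow(rt)), function(i) {
    substr(panel$genomes$seq[panel$genomes$id == rt$contig[i]],
           rt$start[i], rt$end[i])
  }, character(1)))
  expect_equal(length(fam_seqs),
               length(unique(rt$family)))
})

test_that("realized divergence tracks the request over many loci", {
  panel <- cached("div_panel", simulate_panel(
    n_taxa = 4, n_loci = 25, locus_length = 300, flank_length = 300,
    within_divergence = 0.10, background_length = 20000,
    n_repeat_families = 0, seed = 92
  ))
  lt <- panel$truth$loci
  roots <- stats::setNames(panel$roots$seq, panel$roots$locus)
  ham <- function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  # flanks mutate at the full rate, cores at half
  flank_d <- mean(vapply(seq_len(nrow(lt)), function(i) {
    root <- roots[[lt$locus[i]]]
    ham(substr(lt$seq[i], 1, 300), substr(root, 1, 300))
  }, numeric(1)))
  core_d <- mean(vapply(seq_len(nrow(lt)), function(i) {
    root <- roots[[lt$locus[i]]]
    ham(substr(lt$seq[i], 301, 600), substr(root, 301, 600))
  }, numeric(1)))
  expect_lt(abs(flank_d - 0.10), 0.01)
  expect_lt(abs(core_d - 0.05), 0.01)
})

test_that("error-free reads are exact genome substrings linked by the truth table", {
  set.seed(93)
  g <- seq_tbl("chr", rand_dna(20000))
  sim <- simulate_reads(g, coverage = 5, error_rate = 0, seed = 94)
  expect_equal(nrow(sim$pairs), nrow(sim$truth))
  idx <- sample(nrow(sim$pairs), 200)
  for (i in idx) {
    tr <- sim$truth[i, ]
    frag <- substr(g$seq, tr$start, tr$end)
    if (tr$strand == "-") frag <- revcomp(frag)
    r1 <- sim$pairs$seq1[i]
    expect_equal(substr(r1, 1, min(nchar(frag), 150)),
                 substr(frag, 1, min(nchar(frag), 150)))
  }
})

test_that("requested coverage is realized within 10% on a 100 kb genome", {
  set.seed(95)
  g <- seq_tbl("chr", rand_dna(100000))
  sim <- simulate_reads(g, coverage = 30, seed = 96)
  read_bases <- sum(nchar(sim$pairs$seq1)) + sum(nchar(sim$pairs$seq2))
  expect_lt(abs(read_bases / 100000 - 30) / 30, 0.1)
  # genome-origin depth census from the truth table
  frag_bases <- sum(pmin(sim$truth$end, 100000) - sim$truth$start + 1)
  expect_lt(abs(frag_bases / 100000 - 30 * 250 / 300) / 30, 0.15)
})

test_that("planted heterozygous sites draw alleles within binomial bounds", {
  set.seed(97)
  g <- seq_tbl("chr", rand_dna(600))
  hets <- tibble::tibble(contig = "chr", pos = 300L,
                         alt = setdiff(c("A", "C", "G", "T"),
                                       substr(g$seq, 300, 300))[1])
  sim <- simulate_reads(g, coverage = 300, error_rate = 0,
                        het_sites = hets, seed = 98)
  covering <- which(sim$truth$start <= 300 & sim$truth$end >= 300)
  ref_base <- substr(g$seq, 300, 300)
  obs <- vapply(covering, function(i) {
    tr <- sim$truth[i, ]
    frag_pos <- 300 - tr$start + 1
    r1 <- sim$pairs$seq1[i]
    # read the base back out of read 1 when it covers the site
    if (tr$strand == "+" && frag_pos <= nchar(r1)) {
      substr(r1, frag_pos, frag_pos)
    } else NA_character_
  }, character(1))
  obs <- obs[!is.na(obs)]
  n <- length(obs)
  expect_gt(n, 50)
  alt_count <- sum(obs == hets$alt)
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(alt_count, bounds[1])
  expect_lte(alt_count, bounds[2])
})

test_that("capture reads concentrate on the planted locus windows", {
  panel <- small_panel()
  cap <- small_capture()
  lt <- panel$truth$loci
  tr <- cap$truth
  on_target <- vapply(seq_len(nrow(tr)), function(i) {
    w <- lt[lt$contig == tr$contig[i], ]
    any(tr$start[i] >= w$start - 200 & tr$end[i] <= w$end + 200)
  }, logical(1))
  expect_gte(mean(on_target), 0.95)
})
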