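# Trimming/masking boundary behaviour, locus filters, dedup and
# concatenation.

test_that("reliable sites use an inclusive 50% modal-frequency threshold", {
  # invariant column of 10 A: reliable
  a1 <- aln_fix(rep("A", 10))
  expect_true(identify_reliable_sites(a1)[1])
  # 5 A / 5 C of 10: modal frequency exactly 0.5 -> reliable (inclusive)
  a2 <- aln_fix(c(rep("A", 5), rep("C", 5)))
  expect_true(identify_reliable_sites(a2)[1])
  # modal frequency 0.4 -> unreliable
  a3 <- aln_fix(c(rep("A", 4), rep("C", 3), rep("G", 3)))
  expect_false(identify_reliable_sites(a3)[1])
  # gap-only site unreliable
  a4 <- aln_fix("A-", "A-", "A-")
  expect_equal(identify_reliable_sites(a4), c(TRUE, FALSE))
})

test_that("misaligned runs are masked at the inclusive 14-base threshold", {
  base <- strrep("A", 40)
  mk <- function(run_len, at = 10) {
    bad <- base
    substr(bad, at, at + run_len - 1) <- strrep("C", run_len)
    aln_fix(c(rep(base, 9), bad))
  }
  # 14 consecutive disagreeing reliable sites -> masked in that row only
  m14 <- mask_misaligned_regions(mk(14))
  expect_equal(sum(m14$mask[10, ]), 14)
  expect_equal(sum(m14$mask[1:9, ]), 0)
  expect_true(all(which(m14$mask[10, ]) == 10:23))
  # 13-site run stays unmasked
  m13 <- mask_misaligned_regions(mk(13))
  expect_equal(sum(m13$mask), 0)
  # a gap inside the run breaks it
  gapped <- base
  substr(gapped, 10, 30) <- paste0(strrep("C", 10), "-", strrep("C", 10))
  mg <- mask_misaligned_regions(
    aln_fix(c(rep(base, 9), gapped)))
  expect_equal(sum(mg$mask), 0)
  # masking never alters characters
  expect_equal(m14$chars, mk(14)$chars)
})

test_that("random 5% mutation density never produces a maskable run", {
  set.seed(60)
  base <- rand_dna(500)
  n_masked <- 0
  for (i in 1:200) {
    mut <- mutate_seq(base, 0.05)
    aln <- aln_fix(c(rep(base, 9), mut))
    m <- mask_misaligned_regions(aln)
    n_masked <- n_masked + sum(m$mask)
  }
  expect_equal(n_masked, 0)
})

test_that("sparse sites are dropped below 25 present sequences (inclusive keep)", {
  mk_col <- function(n_present, n_taxa = 30) {
    c(rep("A", n_present), rep("-", n_taxa - n_present))
  }
  seqs <- vapply(seq_len(30), function(i) {
    paste0(mk_col(24)[i], mk_col(25)[i], mk_col(30)[i])
  }, character(1))
  aln <- aln_fix(seqs)
  out <- drop_sparse_sites(aln)
  expect_equal(ncol(out$chars), 2)           # 24-present site removed
  expect_equal(attr(out, "site_map"), c(2, 3))
  # 55 gapless taxa: nothing removed
  full <- aln_fix(rep(strrep("ACGT", 5), 55))
  expect_equal(ncol(drop_sparse_sites(full)$chars), 20)
})

test_that("removal counts match a brute-force per-site census on gapped fixtures", {
  set.seed(61)
  for (i in 1:5) {
    n_taxa <- 40
    L <- 60
    chars <- matrix(sample(c("A", "C", "G", "T", "-"), n_taxa * L,
                           replace = TRUE, prob = c(rep(0.15, 4), 0.4)),
                    n_taxa, L)
    aln <- as_alignment(chars)
    out <- drop_sparse_sites(aln, min_sequences = 25)
    brute_keep <- colSums(chars != "-") >= 25
    expect_equal(ncol(out$chars), sum(brute_keep))
    expect_equal(attr(out, "site_map"), which(brute_keep))
  }
})

test_that("the trim pipeline is idempotent", {
  set.seed(62)
  base <- rand_dna(300)
  seqs <- c(vapply(1:30, function(i) mutate_seq(base, 0.03), character(1)))
  # add misalignment: one sequence with a 20-base foreign block
  bad <- seqs[30]
  substr(bad, 100, 119) <- chartr("ACGT", "GTAC", substr(bad, 100, 119))
  seqs[30] <- bad
  # and some gappy columns
  for (i in 1:10) {
    substr(seqs[i], 200, 260) <- paste(rep("-", 61), collapse = "")
  }
  aln <- aln_fix(seqs)
  cfg <- pipeline_config(min_sequences_per_site = 25)
  once <- trim_alignment(aln, cfg)
  twice <- trim_alignment(once, cfg)
  expect_equal(once$chars, twice$chars)
  expect_equal(once$mask, twice$mask)
  expect_gt(sum(once$mask), 0)      # the foreign block was masked
  expect_lt(ncol(once$chars), 300)  # gappy sites were removed
})

test_that("loci represented by less than half the panel are removed", {
  mk_locus <- function(n_present, panel = 10, L = 50) {
    seqs <- c(replicate(n_present, rand_dna(L)),
              rep(strrep("-", L), panel - n_present))
    aln_fix(seqs)
  }
  set.seed(63)
  loci <- list(four = mk_locus(4), five = mk_locus(5), ten = mk_locus(10))
  kept <- filter_sparse_loci(loci, min_fraction = 0.5, panel_size = 10)
  expect_setequal(names(kept), c("five", "ten"))  # 4/10 removed, 5/10 kept
})

test_that("locus dedup leaves retained loci pairwise disjoint in 20-mers", {
  set.seed(64)
  a <- rand_dna(500)
  b_sub <- substr(a, 100, 260)             # subsequence of a -> overlaps
  c_seq <- rand_dna(400)
  loci <- list(
    locA = aln_fix(a, mutate_seq(a, 0.05)),
    locB = aln_fix(b_sub),
    locC = aln_fix(c_seq, mutate_seq(c_seq, 0.05))
  )
  out <- dedup_overlapping_loci(loci)
  expect_setequal(names(out), c("locA", "locC"))   # shorter B removed
  expect_equal(attr(out, "removed"), "locB")
  # disjoint loci both kept
  out2 <- dedup_overlapping_loci(loci[c("locA", "locC")])
  expect_setequal(names(out2), c("locA", "locC"))
  # postcondition asserted exhaustively on random + adversarial fixtures
  shared <- rand_dna(40)
  adv <- list(
    l1 = aln_fix(paste0(rand_dna(200), shared)),
    l2 = aln_fix(paste0(shared, rand_dna(150))),
    l3 = aln_fix(paste0(rand_dna(100), shared, rand_dna(100))),
    l4 = aln_fix(rand_dna(300))
  )
  out3 <- dedup_overlapping_loci(adv)
  kms <- lapply(out3, function(aln) {
    s <- gsub("-", "", paste(apply(aln$chars, 1, paste, collapse = ""), collapse = " "))
    unlist(lapply(strsplit(s, " ")[[1]], function(x) {
      names(enumerate_kmers(x, 20, canonical = TRUE)$counts)
    }))
  })
  if (length(kms) >= 2) {
    for (i in seq_len(length(kms) - 1)) {
      for (j in (i + 1):length(kms)) {
        expect_length(intersect(kms[[i]], kms[[j]]), 0)
      }
    }
  }
})

test_that("repeat-elevated coverage masks exactly the repeat span", {
  set.seed(65)
  uniq <- rand_dna(700)
  rep_unit <- rand_dna(250)
  locus_seq <- paste0(substr(uniq, 1, 350), rep_unit, substring(uniq, 351))
  genome <- paste0(locus_seq,
                   paste(replicate(9, paste0(rand_dna(50), rep_unit)),
                         collapse = ""))
  reads <- simulate_reads(seq_tbl("g", genome), coverage = 30,
                          error_rate = 0, seed = 66)
  m <- merge_pairs(reads$pairs)
  pool <- m$seq[m$merged]
  aln <- aln_fix(locus_seq, locus_id = "locus_rep")
  masked <- mask_repetitive_regions(aln, pool, elevation_factor = 5)
  hot <- which(masked$mask[1, ])
  expect_gt(length(hot), 150)
  # masked cells concentrate on the repeat span (+- k-1 edge blur)
  expect_gte(min(hot), 351 - 19)
  expect_lte(max(hot), 600 + 19)
  # unique-sequence locus: nothing masked
  clean <- mask_repetitive_regions(aln_fix(uniq), pool, elevation_factor = 5)
  expect_equal(sum(clean$mask), 0)
  # raising the factor is monotone (never masks more)
  m10 <- mask_repetitive_regions(aln, pool, elevation_factor = 10)
  expect_true(all(which(m10$mask[1, ]) %in% hot))
})

test_that("concatenation produces correct partitions and round-trips slices", {
  set.seed(67)
  l1 <- aln_fix(rand_dna(100), rand_dna(100))                  # t01 t02
  l2 <- as_alignment(seq_tbl(c("t01", "t03"),
                             c(rand_dna(200), rand_dna(200))), "L2")
  l3 <- as_alignment(seq_tbl(c("t02", "t03"),
                             c(rand_dna(300), rand_dna(300))), "L3")
  res <- concatenate_loci(list(L1 = l1, L2 = l2, L3 = l3))
  expect_equal(ncol(res$supermatrix$chars), 600)
  expect_equal(res$partitions$start, c(1L, 101L, 301L))
  expect_equal(res$partitions$end, c(100L, 300L, 600L))
  # a taxon absent from one locus gets a gap run of that locus's length
  t03_l1 <- res$supermatrix$chars["t03", 1:100]
  expect_true(all(t03_l1 == "-"))
  # per-locus slices reproduce the inputs
  expect_equal(paste(res$supermatrix$chars["t01", 101:300], collapse = ""),
               paste(l2$chars["t01", ], collapse = ""))
  expect_equal(paste(res$supermatrix$chars["t02", 301:600], collapse = ""),
               paste(l3$chars["t02", ], collapse = ""))
  # partition file text
  f <- withr::local_tempfile(fileext = ".txt")
  write_partitions(res$partitions, f)
  expect_equal(readLines(f)[2], "DNA, L2 = 101-300")
  # duplicate taxon within a locus is an error
  dup <- as_alignment(seq_tbl(c("t01", "t01"), c("ACGT", "ACGT")), "bad")
  expect_error(concatenate_loci(list(bad = dup)), "duplicate")
  # conservation: supermatrix length equals the sum of partition lengths
  expect_equal(ncol(res$supermatrix$chars),
               sum(res$partitions$end - res$partitions$start + 1))
})
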