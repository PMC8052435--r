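test_that("enumerate_kmers lists every subsequence length in 'all' mode", {
  p <- enumerate_kmers("GCTA", "all")
  expect_setequal(names(p$counts),
                  c("G", "C", "T", "A", "GC", "CT", "TA", "GCT", "CTA", "GCTA"))
  expect_length(p$counts, 10)
  expect_true(all(p$counts == 1L))
})

test_that("fixed-k enumeration counts multiplicities over every window", {
  p <- enumerate_kmers("AAAA", 2)
  expect_equal(unname(p$counts["AA"]), 3L)
  expect_length(p$counts, 1)
  # occurrence totals match the closed forms, against a brute-force window
  # count, for random sequences
  set.seed(10)
  for (L in c(5, 17, 40)) {
    s <- rand_dna(L)
    for (k in c(1, 3, L)) {
      brute <- length(substring(s, 1:(L - k + 1), k:L))
      expect_equal(sum(enumerate_kmers(s, k)$counts), brute)
      expect_equal(brute, L - k + 1)
    }
    expect_equal(sum(enumerate_kmers(s, "all")$counts),
                 sum(L - seq_len(L) + 1))
  }
  expect_warning(p0 <- enumerate_kmers("ACG", 5), "exceeds")
  expect_length(p0$counts, 0)
  # k-mers containing N are skipped
  expect_false("AN" %in% names(enumerate_kmers("ANA", 2)$counts))
})

test_that("seed_match equals a Hamming-distance test for all-care patterns", {
  a <- strrep("ACGT", 5)
  expect_true(seed_match(a, a, min_matches = 17))
  b <- a
  substr(b, 1, 4) <- "TTTT"  # 4 differences (positions 1,2,4 differ... )
  diffs <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(seed_match(a, b, min_matches = 17), 20 - diffs >= 17)
  # exhaustive equivalence on random pairs
  set.seed(11)
  for (i in 1:2000) {
    x <- rand_dna(20)
    y <- rand_dna(20)
    expect_equal(seed_match(x, y, min_matches = 17),
                 sum(strsplit(x, "")[[1]] == strsplit(y, "")[[1]]) >= 17)
  }
  # N never matches
  expect_false(seed_match(paste0("N", substr(a, 2, 20)), a, min_matches = 20))
  expect_error(seed_match("ACGT", "ACGTA"), "length")
})

test_that("a pattern with fewer care positions than min_matches never passes", {
  set.seed(12)
  pat <- spaced_seed(care = c(rep(TRUE, 16), rep(FALSE, 4)))
  expect_equal(pat$weight, 16)
  for (i in 1:200) {
    s <- rand_dna(20)
    expect_false(seed_match(s, s, pattern = pat, min_matches = 17))
  }
})

test_that("confirmation windows count identities with proportional end scaling", {
  set.seed(13)
  ref <- rand_dna(400)
  # embedded exact 100-base match
  q <- paste0(rand_dna(50), substr(ref, 101, 200), rand_dna(50))
  r <- confirm_match(q, ref, anchor = 51, ref_anchor = 101)
  expect_true(as.logical(r))
  expect_equal(attr(r, "identities"), 100)
  # exactly 54 identities in the best window fails the 55-of-100 rule
  q54 <- strsplit(substr(ref, 101, 200), "")[[1]]
  flip <- sample(100, 46)
  for (i in flip) q54[i] <- setdiff(c("A", "C", "G", "T"), q54[i])[1]
  r54 <- confirm_match(paste(q54, collapse = ""), ref, anchor = 1, ref_anchor = 101)
  expect_false(as.logical(r54))
  expect_equal(attr(r54, "identities"), 54)
  expect_error(confirm_match("ACGT", ref, anchor = 10, ref_anchor = 1), "anchor")
})

test_that("70%-identity homologs pass confirmation and 40% decoys never do", {
  set.seed(14)
  n_decoy_pass <- 0
  for (i in 1:1000) {
    ref <- rand_dna(120)
    hom <- strsplit(ref, "")[[1]]
    flip70 <- sample(120, 36)  # 70% identity
    for (j in flip70) hom[j] <- sample(setdiff(c("A", "C", "G", "T"), hom[j]), 1)
    expect_true(as.logical(confirm_match(paste(hom, collapse = ""), ref, 1, 1)))
    dec <- strsplit(ref, "")[[1]]
    flip40 <- sample(120, 72)  # 40% identity
    for (j in flip40) dec[j] <- sample(setdiff(c("A", "C", "G", "T"), dec[j]), 1)
    if (as.logical(confirm_match(paste(dec, collapse = ""), ref, 1, 1))) {
      n_decoy_pass <- n_decoy_pass + 1
    }
  }
  expect_equal(n_decoy_pass, 0)
})

test_that("profile distance is Jaccard on distinct k-mer sets", {
  a <- enumerate_kmers("ACGTACGTAC", 4)
  expect_equal(profile_distance(a, a), 0)
  b <- enumerate_kmers("GGGGGGGGGG", 4)
  expect_equal(profile_distance(a, b), 1)
  # profiles sharing 2 of 6 distinct union keys
  p1 <- enumerate_kmers("ACGTA", 2)   # AC CG GT TA
  p2 <- enumerate_kmers("ACGGC", 2)   # AC CG GG GC
  shared <- length(intersect(names(p1$counts), names(p2$counts)))
  uni <- length(union(names(p1$counts), names(p2$counts)))
  expect_equal(shared, 2)
  expect_equal(uni, 6)
  expect_equal(profile_distance(p1, p2), 1 - 2 / 6)
  expect_error(profile_distance(a, enumerate_kmers("ACGT", 2)), "different k")
  e1 <- suppressWarnings(enumerate_kmers("NNNN", 2))
  expect_warning(d <- profile_distance(e1, e1), "empty")
  expect_equal(d, 1)
})

test_that("profile distance is a semimetric on random profiles", {
  set.seed(15)
  for (i in 1:25) {
    a <- enumerate_kmers(rand_dna(60), 5)
    b <- enumerate_kmers(rand_dna(60), 5)
    dab <- profile_distance(a, b)
    expect_equal(dab, profile_distance(b, a))
    expect_gte(dab, 0)
    expect_lte(dab, 1)
    expect_equal(profile_distance(a, a), 0)
    dw <- profile_distance(a, b, weighted = TRUE)
    expect_gte(dw, 0); expect_lte(dw, 1)
  }
})

test_that("coverage tracks report mean covering k-mer multiplicity", {
  set.seed(16)
  target <- rand_dna(400)
  # target absent from reads -> all zeros
  trk0 <- coverage_track(target, c(rand_dna(300), rand_dna(300)), k = 20)
  expect_true(all(trk0$coverage == 0))
  # uniform copies: every k-mer present exactly 30 times
  trk30 <- coverage_track(target, rep(target, 30), k = 20)
  expect_true(all(abs(trk30$coverage - 30) < 1e-9))
  expect_equal(nrow(trk30), 400)
})

test_that("a planted multi-copy repeat elevates its coverage track span", {
  set.seed(17)
  unique_part <- rand_dna(600)
  rep_unit <- rand_dna(300)
  target <- paste0(substr(unique_part, 1, 300), rep_unit,
                   substring(unique_part, 301))
  # a genome carrying the target once plus 9 extra repeat copies
  genome <- paste0(target, paste(rep(paste0(rand_dna(60), rep_unit), 9),
                                 collapse = ""))
  reads <- simulate_reads(seq_tbl("g", genome), coverage = 30,
                          error_rate = 0, seed = 18)
  merged <- merge_pairs(reads$pairs)
  pool <- c(merged$seq[merged$merged],
            reads$pairs$seq1[!merged$merged], reads$pairs$seq2[!merged$merged])
  trk <- coverage_track(target, pool, k = 20)
  inside <- trk$coverage[320:580]    # repeat span interior
  outside <- trk$coverage[c(50:280, 620:850)]
  expect_gt(mean(inside) / mean(outside), 5)
  expect_gt(mean(inside) / mean(outside), 7)  # ~10x with sampling noise
})

test_that("custom spaced patterns scan fixtures and tracks export as BED", {
  set.seed(18)
  ref <- rand_dna(150)
  query <- paste0(rand_dna(30), substr(ref, 26, 125), rand_dna(30))
  # a spaced pattern ignoring two positions (18 care) still finds the
  # embedding at the default 17-match minimum
  pat <- spaced_seed(care = c(rep(TRUE, 9), FALSE, rep(TRUE, 9), FALSE))
  hits <- scan_with_pattern(query, ref, pat)
  expect_gt(nrow(hits), 0)
  expect_true(any(hits$qpos - hits$rpos == 5))
  expect_equal(nrow(scan_with_pattern(rand_dna(80), rand_dna(80), pat)), 0)
  # BED export of a coverage track round-trips coordinates
  trk <- coverage_track(ref, rep(ref, 7), k = 20)
  f <- withr::local_tempfile(fileext = ".bed")
  write_coverage_bed(trk, f, contig = "c1")
  bed <- readr::read_tsv(f, col_names = c("chrom", "start", "end", "name",
                                          "score", "strand"),
                         col_types = "ciicic", progress = FALSE)
  expect_equal(bed$start[1], 0)
  expect_equal(max(bed$end), 150)
  expect_true(all(bed$score == 7))
})
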