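test_that("demultiplexing tolerates no index mismatches", {
  imap <- tibble::tibble(index = c("ACGTACGT", "TTTTCCCC"),
                         sample = c("s1", "s2"))
  reads <- seq_tbl(c("r1", "r2", "r3"), c("AAAA", "CCCC", "GGGG"),
                   index = c("ACGTACGT", "ACGTACGA", "TTTTCCCC"))
  out <- demultiplex(reads, imap)
  expect_equal(out$sample, c("s1", "undetermined", "s2"))
  dup <- tibble::tibble(index = c("AAAA", "AAAA"), sample = c("s1", "s2"))
  expect_error(demultiplex(reads, dup), "duplicate")
})

test_that("demultiplexing recovers exact per-sample counts on a simulated pool", {
  set.seed(30)
  idx <- c(s1 = "AACCGGTT", s2 = "GGTTAACC", s3 = "CCAATTGG")
  n_per <- c(s1 = 40, s2 = 25, s3 = 35)
  reads <- seq_tbl(sprintf("r%03d", 1:100),
                   vapply(1:100, function(i) rand_dna(50), character(1)),
                   index = rep(unname(idx), n_per))
  out <- demultiplex(reads, idx)
  expect_equal(as.vector(table(out$sample)[names(n_per)]), unname(n_per))
})

test_that("pair merging reconstructs the fragment and strips adapters", {
  set.seed(31)
  adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
  # 100-base fragment sequenced as 2x70 -> 40-base overlap, merged length 100
  frag <- rand_dna(100)
  p1 <- tibble::tibble(id = "p1", seq1 = substr(frag, 1, 70),
                       seq2 = substr(revcomp(frag), 1, 70),
                       qual1 = list(rep(30L, 70)), qual2 = list(rep(35L, 70)))
  m1 <- merge_pairs(p1)
  expect_true(m1$merged)
  expect_equal(m1$overlap, 40L)
  expect_equal(m1$seq, frag)
  expect_length(m1$qual[[1]], 100)
  # fragment shorter than the read: adapter read-through removed
  frag2 <- rand_dna(50)
  r1 <- substr(paste0(frag2, adapter), 1, 70)
  r2 <- substr(paste0(revcomp(frag2), adapter), 1, 70)
  m2 <- merge_pairs(tibble::tibble(id = "p2", seq1 = r1, seq2 = r2,
                                   qual1 = list(rep(30L, 70)),
                                   qual2 = list(rep(30L, 70))))
  expect_true(m2$merged)
  expect_equal(m2$seq, frag2)
  expect_false(grepl(substr(adapter, 1, 10), m2$seq, fixed = TRUE))
  # non-overlapping pair stays unmerged
  m3 <- merge_pairs(tibble::tibble(id = "p3", seq1 = rand_dna(70),
                                   seq2 = rand_dna(70),
                                   qual1 = list(rep(30L, 70)),
                                   qual2 = list(rep(30L, 70))))
  expect_false(m3$merged)
  expect_true(is.na(m3$seq))
})

test_that("merged bases always come from one of the two reads", {
  set.seed(32)
  for (i in 1:30) {
    frag <- rand_dna(120)
    r1 <- substr(frag, 1, 80)
    r2 <- substr(revcomp(frag), 1, 80)
    # sprinkle sequencing errors on both reads
    r1 <- mutate_seq(r1, 0.03)
    r2 <- mutate_seq(r2, 0.03)
    q1 <- sample(20:40, 80, replace = TRUE)
    q2 <- sample(20:40, 80, replace = TRUE)
    m <- merge_pairs(tibble::tibble(id = "p", seq1 = r1, seq2 = r2,
                                    qual1 = list(q1), qual2 = list(q2)))
    if (!m$merged) next
    mseq <- strsplit(m$seq, "")[[1]]
    c1 <- strsplit(r1, "")[[1]]
    c2 <- strsplit(revcomp(r2), "")[[1]]
    t_shift <- length(mseq) - 80  # rc2 start within the merged fragment
    for (pos in seq_along(mseq)) {
      from1 <- pos <= 80 && mseq[pos] == c1[pos]
      from2 <- pos > t_shift && (pos - t_shift) <= 80 &&
        mseq[pos] == c2[pos - t_shift]
      expect_true(from1 || from2)
    }
  }
})

test_that("reads are recruited to the locus of their best reference", {
  panel <- small_panel()
  refs <- panel$transcripts_a
  # verbatim copy of a reference goes to its locus
  vb <- seq_tbl("verbatim", substr(refs$seq[2], 50, 250))
  rec <- recruit_reads(vb, refs)
  expect_equal(rec$locus, refs$locus[2])
  expect_equal(rec$offset, 50L)
  expect_equal(rec$strand, "+")
  # reverse-complement orientation is detected
  rc <- seq_tbl("rc", revcomp(substr(refs$seq[3], 1, 200)))
  rec_rc <- recruit_reads(rc, refs)
  expect_equal(rec_rc$locus, refs$locus[3])
  expect_equal(rec_rc$strand, "-")
})

test_that("divergent ortholog reads recruit correctly and random reads never do", {
  panel <- small_panel()
  cap <- small_capture()
  m <- small_merged()
  refs <- panel$transcripts_a
  # sample t03 reads whose fragments lie inside a planted core: known truth
  lt <- panel$truth$loci[panel$truth$loci$taxon == "t03", ]
  sel <- which(m$merged & cap$pairs$sample == "t03")
  tr <- cap$truth[match(m$id[sel], cap$truth$id), ]
  core_locus <- rep(NA_character_, nrow(tr))
  for (i in seq_len(nrow(lt))) {
    inside <- tr$start >= lt$core_start[i] & tr$end <= lt$core_end[i]
    core_locus[inside] <- lt$locus[i]
  }
  keep <- !is.na(core_locus)
  rec <- recruit_reads(seq_tbl(m$id[sel][keep], m$seq[sel][keep]), refs)
  expect_gt(sum(keep), 500)
  agree <- rec$locus == core_locus[keep]
  expect_gte(mean(agree, na.rm = TRUE), 0.99)
  expect_gte(mean(!is.na(rec$locus)), 0.99)
  # decoy reads: zero assignments
  set.seed(33)
  decoys <- seq_tbl(sprintf("d%05d", 1:10000),
                    stringi::stri_rand_strings(10000, 250, "[ACGT]"))
  rec0 <- recruit_reads(decoys, refs)
  expect_equal(sum(!is.na(rec0$locus)), 0)
})

test_that("extension assembly recovers planted flanks around an anchor", {
  set.seed(34)
  region <- rand_dna(2000)               # 2 kb genomic region
  anchor <- substr(region, 751, 1250)    # 500-base anchor reference
  reads <- simulate_reads(seq_tbl("reg", region), coverage = 30,
                          error_rate = 0, seed = 35)
  m <- merge_pairs(reads$pairs)
  pool <- seq_tbl(m$id[m$merged], m$seq[m$merged])
  rec <- recruit_reads(pool, seq_tbl("anchor", anchor))
  seeded <- rec[!is.na(rec$locus) & !rec$ambiguous, ]
  cl <- assembly_cluster(seeded, locus_id = "anchor", sample = "s1")
  unassigned <- rec[is.na(rec$locus), c("id", "seq")]
  ext <- extend_assembly(cl, unassigned)
  cons <- anchorsmith:::working_consensus(ext$site_counts)
  expect_gte(nchar(cons), 0.9 * 2000)
  pid <- percent_identity(cons, region)
  expect_gte(pid, 99)
  # fixed point: no unassigned reads leaves the cluster unchanged
  ext2 <- extend_assembly(ext, pool[0, ])
  expect_equal(ext2$site_counts, ext$site_counts)
  # monotone growth: extension never loses reads
  expect_gte(nrow(ext$reads), nrow(cl$reads))
})

test_that("extension output is independent of read order", {
  set.seed(36)
  region <- rand_dna(1200)
  anchor <- substr(region, 451, 750)
  reads <- simulate_reads(seq_tbl("reg", region), coverage = 20,
                          error_rate = 0, seed = 37)
  m <- merge_pairs(reads$pairs)
  pool <- seq_tbl(m$id[m$merged], m$seq[m$merged])
  rec <- recruit_reads(pool, seq_tbl("anchor", anchor))
  seeded <- rec[!is.na(rec$locus) & !rec$ambiguous, ]
  cl <- assembly_cluster(seeded, "anchor", "s1")
  unassigned <- rec[is.na(rec$locus), c("id", "seq")]
  e1 <- extend_assembly(cl, unassigned)
  e2 <- extend_assembly(cl, unassigned[rev(seq_len(nrow(unassigned))), ])
  expect_equal(e1$site_counts, e2$site_counts)
  expect_equal(sort(e1$reads$id), sort(e2$reads$id))
})
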