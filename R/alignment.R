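# Alignment containers and the external-aligner adapter. The multiple
# alignment itself is delegated to MAFFT when available; a naive gapless
# star alignment is the internal fallback, adequate for substitution-only
# simulated data and small fixtures.

#' Build an alignment matrix
#'
#' @param seqs Sequence tibble of equal-length aligned sequences (gaps as
#'   `-`), or a character matrix.
#' @param locus_id Locus label.
#' @return An `alignment_matrix`: list with `taxa`, `chars` (taxa x sites
#'   character matrix), `mask` (logical, `TRUE` = excluded) and `locus_id`.
#' @export
as_alignment <- function(seqs, locus_id = NA_character_) {
  if (is.matrix(seqs)) {
    chars <- seqs
    taxa <- rownames(chars)
    if (is.null(taxa)) {
      taxa <- if (nrow(chars) > 0) paste0("t", seq_len(nrow(chars))) else character(0)
    }
  } else {
    lens <- nchar(seqs$seq)
    if (length(unique(lens)) > 1) abort("aligned sequences must have equal length")
    chars <- do.call(rbind, strsplit(toupper(seqs$seq), ""))
    taxa <- seqs$id
  }
  if (nrow(chars) > 0) rownames(chars) <- taxa
  structure(
    list(taxa = taxa, chars = chars,
         mask = matrix(FALSE, nrow(chars), ncol(chars)),
         locus_id = locus_id),
    class = "alignment_matrix"
  )
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf("<alignment_matrix> %s: %d taxa x %d sites (%.1f%% masked)\n",
              x$locus_id, length(x$taxa), ncol(x$chars),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
tidy.alignment_matrix <- function(x, ...) {
  tibble::tibble(
    taxon = rep(x$taxa, times = ncol(x$chars)),
    site = rep(seq_len(ncol(x$chars)), each = length(x$taxa)),
    char = as.vector(x$chars),
    masked = as.vector(x$mask)
  )
}

#' @export
glance.alignment_matrix <- function(x, ...) {
  tibble::tibble(
    locus_id = x$locus_id, n_taxa = length(x$taxa), n_sites = ncol(x$chars),
    masked_fraction = mean(x$mask),
    gap_fraction = mean(x$chars == "-")
  )
}

#' Alignment back to a sequence tibble
#'
#' @param aln An `alignment_matrix`.
#' @param drop_masked Replace masked cells by gaps.
#' @return Sequence tibble of the aligned rows.
#' @export
alignment_tbl <- function(aln, drop_masked = FALSE) {
  chars <- aln$chars
  if (drop_masked) chars[aln$mask] <- "-"
  seq_tbl(id = aln$taxa, seq = apply(chars, 1, paste, collapse = ""),
          locus = rep(aln$locus_id, length(aln$taxa)))
}

#' Align sequences (adapter)
#'
#' Uses the external `mafft` binary when present on the PATH
#' (`method = "auto"`); otherwise falls back to an internal gapless star
#' alignment: every sequence is placed against the longest one at its best
#' overlap offset and padded with terminal gaps. The fallback introduces no
#' internal gaps and is intended for substitution-only data.
#'
#' @param seqs Sequence tibble.
#' @param method `"auto"`, `"mafft"` or `"internal"`.
#' @param locus_id Locus label for the result.
#' @return An `alignment_matrix`.
#' @export
align_sequences <- function(seqs, method = c("auto", "mafft", "internal"),
                            locus_id = NA_character_) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (nzchar(Sys.which("mafft"))) "mafft" else "internal"
  }
  if (nrow(seqs) == 1) {
    return(as_alignment(seqs, locus_id))
  }
  if (method == "mafft") {
    fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    write_sequences(seqs, fin, format = "fasta")
    status <- system2("mafft", c("--auto", "--quiet", fin), stdout = fout)
    if (!identical(status, 0L)) abort("mafft failed")
    out <- read_sequences(fout, format = "fasta")
    out <- out[match(seqs$id, out$id), ]
    return(as_alignment(out, locus_id))
  }
  # internal star alignment
  center <- which.max(nchar(seqs$seq))
  offs <- integer(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    if (i == center) { offs[i] <- 0L; next }
    bo <- cpp_best_overlap(seqs$seq[center], seqs$seq[i],
                           min(12L, nchar(seqs$seq[i])))
    offs[i] <- bo$shift
  }
  lo <- min(offs)
  width <- max(offs + nchar(seqs$seq)) - lo
  rows <- vapply(seq_len(nrow(seqs)), function(i) {
    left <- offs[i] - lo
    s <- seqs$seq[i]
    paste0(strrep("-", left), s, strrep("-", width - left - nchar(s)))
  }, character(1))
  as_alignment(seq_tbl(id = seqs$id, seq = rows), locus_id)
}

#' Summary statistics of a locus alignment panel
#'
#' Locus count, alignment-length summaries and concatenated length for a set
#' of per-locus alignments (or a directory of aligned FASTA files).
#'
#' @param loci List of `alignment_matrix` objects, or a directory containing
#'   aligned FASTA files (one locus per file).
#' @return One-row tibble: `n_loci`, `mean_length`, `median_length`,
#'   `min_length`, `max_length`, `total_length`.
#' @export
alignment_panel_stats <- function(loci) {
  if (is.character(loci)) {
    files <- list.files(loci, pattern = "\\.fa(sta)?$", full.names = TRUE)
    loci <- lapply(files, function(f) {
      as_alignment(read_sequences(f), locus_id = basename(f))
    })
  }
  lens <- vapply(loci, function(a) ncol(a$chars), numeric(1))
  tibble::tibble(
    n_loci = length(loci),
    mean_length = mean(lens), median_length = stats::median(lens),
    min_length = if (length(lens)) min(lens) else NA_real_,
    max_length = if (length(lens)) max(lens) else NA_real_,
    total_length = sum(lens)
  )
}
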