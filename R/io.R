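# Sequence I/O. Sequence sets travel through the package as tibbles with
# columns id (character), seq (character, uppercase), qual (list of integer
# Phred scores or NULL), plus optional sample/locus annotation columns.

#' Build a sequence tibble
#'
#' @param id Character vector of record names (non-empty, unique not required).
#' @param seq Character vector of nucleotide sequences.
#' @param qual Optional list of integer Phred quality vectors, each the same
#'   length as its sequence.
#' @param ... Further per-record columns (e.g. `sample`, `locus`, `index`).
#' @return A tibble with one row per record.
#' @export
seq_tbl <- function(id, seq, qual = NULL, ...) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (any(!nzchar(id)) || anyNA(id)) abort("sequence ids must be non-empty")
  if (length(id) != length(seq)) abort("id and seq lengths differ")
  if (!is.null(qual)) {
    ok <- mapply(function(q, s) is.null(q) || length(q) == nchar(s), qual, seq)
    if (!all(ok)) abort("qualities must match sequence lengths")
  }
  out <- tibble::tibble(id = id, seq = seq)
  if (!is.null(qual)) out$qual <- qual
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Read sequences from FASTA or FASTQ
#'
#' Residues are uppercased on ingestion; record order is preserved. FASTQ
#' qualities are decoded from Phred+33.
#'
#' @param path Path to the file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by extension).
#' @return A sequence tibble (see [seq_tbl()]); FASTQ input adds a `qual`
#'   list-column.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (format == "fasta") {
    xs <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)))
    )
    seq_tbl(id = names(xs), seq = as.character(xs))
  } else {
    xs <- tryCatch(
      Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
      error = function(e) abort(paste0("malformed FASTQ in ", path, ": ", conditionMessage(e)))
    )
    quals <- S4Vectors::mcols(xs)$qualities
    qlist <- lapply(seq_along(xs), function(i) {
      as.integer(charToRaw(as.character(quals[[i]]))) - 33L
    })
    bad <- which(lengths(qlist) != Biostrings::width(xs))
    if (length(bad) > 0) {
      abort(paste0("FASTQ record ", bad[1], " (", names(xs)[bad[1]],
                   "): qualities/residues length mismatch"))
    }
    seq_tbl(id = names(xs), seq = as.character(xs), qual = qlist)
  }
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTA output wraps residues at 60 columns; FASTQ encodes qualities as
#' Phred+33 (records lacking qualities get a uniform placeholder of Q40).
#'
#' @param x Sequence tibble.
#' @param path Output path.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (format == "fasta") {
    lines <- character(0)
    wrapped <- lapply(x$seq, function(s) {
      n <- nchar(s)
      if (n == 0) return("")
      substring(s, seq(1, n, 60), pmin(seq(1, n, 60) + 59, n))
    })
    lines <- unlist(mapply(function(id, w) c(paste0(">", id), w),
                           x$id, wrapped, SIMPLIFY = FALSE), use.names = FALSE)
    writeLines(lines, path)
  } else {
    qual <- if ("qual" %in% names(x)) x$qual else rep(list(NULL), nrow(x))
    lines <- unlist(mapply(function(id, s, q) {
      if (is.null(q) || length(q) == 0) q <- rep(40L, nchar(s))
      c(paste0("@", id), s, "+", rawToChar(as.raw(q + 33L)))
    }, x$id, x$seq, qual, SIMPLIFY = FALSE), use.names = FALSE)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write locus targets as BED6
#'
#' Internal coordinates are 1-based closed; the BED lines are the standard
#' 0-based half-open convention. The name column is the locus id and the
#' score column the best confirmation identity count.
#'
#' @param targets Locus target tibble from [scan_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets_bed <- function(targets, path) {
  if (nrow(targets) > 0 && any(targets$end < targets$start)) {
    abort("target with end < start")
  }
  df <- tibble::tibble(
    chrom = targets$contig,
    start = targets$start - 1L,
    end = targets$end,
    name = targets$locus_id,
    score = if ("best_identities" %in% names(targets)) targets$best_identities else 0L,
    strand = targets$strand
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6 file of locus targets
#'
#' Inverse of [write_targets_bed()]; coordinates are converted back to the
#' package's 1-based closed convention.
#'
#' @param path Path to a BED6 file.
#' @return Locus target tibble.
#' @export
read_targets_bed <- function(path) {
  if (file.size(path) == 0) {
    return(tibble::tibble(locus_id = character(), contig = character(),
                          start = integer(), end = integer(),
                          strand = character(), best_identities = integer()))
  }
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                            "score", "strand"),
                        col_types = "ciicic", progress = FALSE)
  tibble::tibble(
    locus_id = df$name, contig = df$chrom,
    start = df$start + 1L, end = df$end,
    strand = df$strand, best_identities = df$score
  )
}

#' Write a RAxML-style partition file
#'
#' @param partitions Tibble with columns `locus_id`, `start`, `end`
#'   (1-based inclusive supermatrix ranges), as produced by
#'   [concatenate_loci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(partitions, path) {
  writeLines(sprintf("DNA, %s = %d-%d", partitions$locus_id,
                     partitions$start, partitions$end), path)
  invisible(path)
}
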