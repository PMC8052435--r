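# Uniform probe tiling across final locus sequences at a requested coverage
# depth.

#' Tile probes across one sequence
#'
#' Probes of `probe_length` start at multiples of
#' `round(probe_length / density)`; a final probe is right-anchored at the
#' sequence end so coverage has no terminal gap. Gaps are stripped before
#' tiling. Away from the ends, every position is covered by
#' `floor(density)` or `ceiling(density)` probes.
#'
#' @param source One-row sequence tibble or a single string.
#' @param probe_length Probe length in bp (default 120).
#' @param density Requested coverage depth (default 3.5).
#' @param source_id Label when `source` is a bare string.
#' @return A `probe_set` tibble: `source_id`, `start`, `end` (1-based
#'   closed, on the gap-stripped source), `seq`; attributes
#'   `requested_density` and `achieved_density` (per source).
#' @export
tile_probes <- function(source, probe_length = 120L, density = 3.5,
                        source_id = NULL) {
  if (is.data.frame(source)) {
    source_id <- source_id %||% source$id[1]
    source <- source$seq[1]
  }
  source_id <- source_id %||% "source"
  s <- gsub("-", "", toupper(source))
  L <- nchar(s)
  if (probe_length <= 0) abort("probe_length must be positive")
  if (L < probe_length) {
    warn(paste0("source ", source_id, " shorter than probe length; single probe"))
    starts <- 1L
    probe_length_i <- L
  } else {
    step <- max(1L, as.integer(round(probe_length / density)))
    starts <- seq(1L, L - probe_length + 1L, by = step)
    last <- L - probe_length + 1L
    if (starts[length(starts)] != last) starts <- c(starts, last)
    probe_length_i <- probe_length
  }
  out <- tibble::tibble(
    source_id = source_id,
    start = as.integer(starts),
    end = as.integer(starts + probe_length_i - 1L),
    seq = substring(s, starts, starts + probe_length_i - 1L)
  )
  achieved <- sum(nchar(out$seq)) / L
  structure(out, class = c("probe_set", class(out)),
            requested_density = density,
            achieved_density = stats::setNames(achieved, source_id))
}

#' Tile probes across a locus alignment
#'
#' Applies [tile_probes()] to the gap-stripped sequence of each alignment
#' row and pools the result; probes that would contain a masked or N
#' position are dropped and reported in attribute `dropped`.
#'
#' @param aln An `alignment_matrix`.
#' @param config A [pipeline_config()] (`probe_length`, `tiling_density`).
#' @return A pooled `probe_set` with per-sequence provenance (`source_id`).
#' @export
tile_locus <- function(aln, config = NULL) {
  config <- as_config(config)
  sets <- list()
  dens <- numeric(0)
  dropped <- list()
  for (i in seq_along(aln$taxa)) {
    row <- aln$chars[i, ]
    keep <- row != "-"
    if (sum(keep) == 0) next
    s <- paste(row[keep], collapse = "")
    masked_unpos <- which(aln$mask[i, ] & keep)          # alignment columns
    masked_local <- match(masked_unpos, which(keep))     # gap-stripped coords
    ps <- suppressWarnings(
      tile_probes(s, probe_length = config$probe_length,
                  density = config$tiling_density,
                  source_id = paste0(aln$taxa[i], "_", aln$locus_id))
    )
    bad <- vapply(seq_len(nrow(ps)), function(pi) {
      span <- ps$start[pi]:ps$end[pi]
      grepl("N", ps$seq[pi], fixed = TRUE) || any(masked_local %in% span)
    }, logical(1))
    if (any(bad)) dropped[[length(dropped) + 1]] <- ps[bad, ]
    ps <- ps[!bad, ]
    dens <- c(dens, attr(ps, "achieved_density") %||%
                stats::setNames(sum(nchar(ps$seq)) / nchar(s),
                                paste0(aln$taxa[i], "_", aln$locus_id)))
    sets[[length(sets) + 1]] <- tibble::as_tibble(ps)
  }
  out <- if (length(sets) == 0) {
    tibble::tibble(source_id = character(), start = integer(),
                   end = integer(), seq = character())
  } else {
    dplyr::bind_rows(sets)
  }
  structure(out, class = c("probe_set", class(tibble::tibble())),
            requested_density = config$tiling_density,
            achieved_density = dens,
            dropped = if (length(dropped)) dplyr::bind_rows(dropped) else NULL)
}

#' Per-position probe coverage of one source
#'
#' @param probes A `probe_set`.
#' @param source_id Which source to profile.
#' @param length Source length (defaults to the largest probe end).
#' @return Integer vector of per-position covering-probe counts.
#' @export
probe_coverage <- function(probes, source_id, length = NULL) {
  p <- probes[probes$source_id == source_id, ]
  L <- length %||% if (nrow(p)) max(p$end) else 0L
  cov <- integer(L)
  for (i in seq_len(nrow(p))) {
    cov[p$start[i]:p$end[i]] <- cov[p$start[i]:p$end[i]] + 1L
  }
  cov
}

#' @export
autoplot.probe_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$row <- stats::ave(seq_len(nrow(df)), df$source_id, FUN = seq_along)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$row, yend = .data$row)) +
    ggplot2::geom_segment(linewidth = 1) +
    ggplot2::facet_wrap(~source_id, scales = "free") +
    ggplot2::labs(x = "position (bp, gap-stripped)", y = "probe",
                  title = sprintf("probe tiling (requested density %.1fx)",
                                  attr(object, "requested_density")))
}

#' Write probes as FASTA and TSV
#'
#' @param probes A `probe_set`.
#' @param fasta,tsv Output paths (`NULL` to skip either).
#' @return `probes`, invisibly.
#' @export
write_probes <- function(probes, fasta = NULL, tsv = NULL) {
  if (!is.null(fasta)) {
    ids <- sprintf("%s:%d-%d", probes$source_id, probes$start, probes$end)
    write_sequences(seq_tbl(ids, probes$seq), fasta, format = "fasta")
  }
  if (!is.null(tsv)) {
    readr::write_tsv(tibble::as_tibble(probes)[, c("source_id", "start", "end")],
                     tsv, progress = FALSE)
  }
  invisible(probes)
}
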