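# Alignment-free orthology: the 20-mer overlap distance matrix across
# consensus sequences and its agglomerative clustering into per-locus
# ortholog groups.

#' Alignment-free distance matrix
#'
#' Pairwise distances are one minus the Jaccard overlap of canonical k-mer
#' sets (see [profile_distance()]). Sequences shorter than `k` receive an
#' all-1 row (nothing to compare) with a warning.
#'
#' @param consensi Sequence tibble (at least two rows).
#' @param k k-mer size (default 20).
#' @param weighted Multiplicity-weighted overlap instead of set Jaccard.
#' @return An `anchors_dist` object: square symmetric matrix with zero
#'   diagonal, labelled by sequence id, with the input metadata attached.
#' @export
build_distance_matrix <- function(consensi, k = 20L, weighted = FALSE) {
  if (nrow(consensi) < 2) abort("need at least two sequences")
  profs <- lapply(seq_len(nrow(consensi)), function(i) {
    s <- gsub("-", "", consensi$seq[i])
    if (nchar(s) < k) {
      warn(paste0("sequence ", consensi$id[i], " shorter than k; all-1 row"))
      NULL
    } else {
      enumerate_kmers(s, k, canonical = TRUE, source_id = consensi$id[i])
    }
  })
  n <- nrow(consensi)
  m <- matrix(0, n, n, dimnames = list(consensi$id, consensi$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- if (is.null(profs[[i]]) || is.null(profs[[j]])) 1 else {
        suppressWarnings(profile_distance(profs[[i]], profs[[j]], weighted = weighted))
      }
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  structure(m, class = c("anchors_dist", "matrix"), meta = consensi[, setdiff(names(consensi), "seq")])
}

#' @export
tidy.anchors_dist <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    from = rep(rownames(m), times = ncol(m)),
    to = rep(colnames(m), each = nrow(m)),
    distance = as.vector(m)
  )
}

#' @export
autoplot.anchors_dist <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "k-mer distance")
}

#' Write a distance matrix to TSV
#'
#' @param dm An `anchors_dist` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  df <- tibble::as_tibble(unclass(dm), rownames = "id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Cluster consensus sequences into ortholog groups
#'
#' Agglomerative clustering (base `hclust`) of the alignment-free distance
#' matrix, cut at `cutoff`. Each cluster that contains a reference-linked
#' member becomes an ortholog group named by that reference's locus; a
#' cluster holding two sequences from one sample keeps the member nearer (by
#' mean distance) to the rest and flags the other as a paralog. Clusters
#' without any reference member are dropped and reported.
#'
#' The default cutoff (0.995) reflects how exact-20-mer Jaccard distances
#' behave: orthologs diverged by p share roughly a (1-p)^20 fraction of
#' their 20-mers, so true ortholog pairs at 10-15% divergence sit at
#' distances of ~0.92-0.99 while unrelated loci sit at ~1 exactly; the cut
#' separates "shares a conserved core's worth of 20-mers" from "shares
#' nothing".
#'
#' @param dm An `anchors_dist` matrix from [build_distance_matrix()].
#' @param meta Tibble with columns `id`, `sample`, and for reference rows
#'   `locus` + `is_reference = TRUE`. Defaults to the metadata attached to
#'   `dm` (requires `sample` and `is_reference` columns there).
#' @param linkage `"average"` (default) or `"single"`.
#' @param cutoff Tree cut height in distance units (default 0.995).
#' @return Tibble of members: `locus_id`, `id`, `sample`, `is_reference`,
#'   `paralog` (flagged members are excluded from the group but reported),
#'   with dropped cluster ids in attribute `dropped`.
#' @export
cluster_orthologs <- function(dm, meta = NULL,
                              linkage = c("average", "single"),
                              cutoff = 0.995) {
  linkage <- match.arg(linkage)
  meta <- meta %||% attr(dm, "meta")
  if (is.null(meta) || !all(c("id", "sample") %in% names(meta))) {
    abort("need member metadata with id and sample columns")
  }
  if (!"is_reference" %in% names(meta)) meta$is_reference <- FALSE
  if (!"locus" %in% names(meta)) meta$locus <- NA_character_
  m <- unclass(dm)
  ids <- rownames(m)
  # label-order invariance: cluster in a canonical label order
  ord <- order(ids)
  m <- m[ord, ord, drop = FALSE]
  ids <- ids[ord]
  if (length(ids) == 1) {
    cl <- stats::setNames(1L, ids)
  } else if (cutoff <= 0) {
    cl <- stats::setNames(seq_along(ids), ids)
  } else {
    hc <- stats::hclust(stats::as.dist(m), method = linkage)
    cl <- stats::cutree(hc, h = cutoff)
    names(cl) <- ids
  }
  meta <- meta[match(ids, meta$id), ]
  meta$cluster <- unname(cl[meta$id])
  dropped <- character(0)
  groups <- list()
  for (g in sort(unique(meta$cluster))) {
    mem <- meta[meta$cluster == g, ]
    refs <- mem[isTRUE_v(mem$is_reference), ]
    if (nrow(refs) == 0) {
      dropped <- c(dropped, mem$id)
      next
    }
    locus_id <- refs$locus[1]
    mem$paralog <- FALSE
    # resolve duplicated samples: keep the member nearer to the rest
    dup_samples <- unique(mem$sample[duplicated(mem$sample) & !is.na(mem$sample)])
    for (s in dup_samples) {
      cand <- which(mem$sample == s & !mem$is_reference)
      if (length(cand) < 2) next
      others <- setdiff(mem$id, mem$id[cand])
      if (length(others) == 0) others <- mem$id
      mean_d <- vapply(mem$id[cand], function(id) {
        mean(m[id, others])
      }, numeric(1))
      keep <- cand[which.min(mean_d)]
      mem$paralog[setdiff(cand, keep)] <- TRUE
    }
    mem$locus_id <- locus_id
    groups[[length(groups) + 1]] <-
      mem[, c("locus_id", "id", "sample", "is_reference", "paralog")]
  }
  out <- if (length(groups) == 0) {
    tibble::tibble(locus_id = character(), id = character(), sample = character(),
                   is_reference = logical(), paralog = logical())
  } else {
    dplyr::bind_rows(groups)
  }
  out <- dplyr::arrange(out, .data$locus_id, .data$id)
  attr(out, "dropped") <- dropped
  out
}

isTRUE_v <- function(x) !is.na(x) & x

#' Write ortholog groups to TSV
#'
#' @param groups Output of [cluster_orthologs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups_tsv <- function(groups, path) {
  readr::write_tsv(groups[!groups$paralog, c("locus_id", "id")], path,
                   progress = FALSE)
  invisible(path)
}
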