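#' Order CpG annotation genomically
#'
#' Sorts a CpG annotation table by chromosome (natural order: chr1, chr2, ...,
#' chr10, ..., chrX, chrY, chrM; a leading "chr" prefix is optional), then by
#' ascending position, with ties in position broken by CpG ID.
#'
#' @param annotation data frame with columns `cpg_id`, `chromosome`,
#'   `position` (1-based base-pair coordinate).
#' @return the annotation, row-reordered, with row names dropped.
#' @export
sort_annotation <- function(annotation) {
  annotation <- check_annotation(annotation)
  ord <- order(chromosome_rank(annotation$chromosome),
               annotation$position,
               annotation$cpg_id, method = "radix")
  out <- annotation[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# numeric rank for natural chromosome ordering; unknown names sort after
# the canonical ones, alphabetically (encoded in the fractional part).
chromosome_rank <- function(chrom) {
  core <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  r <- suppressWarnings(as.numeric(core))
  r[toupper(core) == "X"] <- 23
  r[toupper(core) == "Y"] <- 24
  r[toupper(core) %in% c("M", "MT")] <- 25
  unk <- is.na(r)
  if (any(unk)) r[unk] <- 1000 + as.integer(factor(core[unk], levels = sort(unique(core[unk]))))
  r
}

check_annotation <- function(annotation) {
  annotation <- as.data.frame(annotation)
  need <- c("cpg_id", "chromosome", "position")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(annotation$cpg_id))
    stop("duplicated cpg_id in annotation")
  if (any(!is.finite(annotation$position)) || any(annotation$position < 1))
    stop("annotation positions must be >= 1")
  annotation$cpg_id <- as.character(annotation$cpg_id)
  annotation$chromosome <- as.character(annotation$chromosome)
  annotation$position <- as.integer(annotation$position)
  annotation
}

#' Pearson correlations between genomically adjacent CpG sites
#'
#' Computes, for each pair of neighbouring CpGs in coordinate-sorted order, the
#' Pearson correlation of their beta values across samples (pairwise-complete
#' observations). Pairs that span a chromosome boundary receive `-Inf`, a
#' sentinel that can never exceed any correlation threshold, as does any pair
#' involving a zero-variance CpG (with a warning).
#'
#' @param beta_matrix numeric `n x m` matrix of beta values, samples in rows,
#'   CpGs in columns, columns aligned with the (sorted) annotation.
#' @param annotation coordinate-sorted annotation data frame (see
#'   [sort_annotation()]) with one row per column of `beta_matrix`.
#' @return numeric vector of length `m - 1`.
#' @export
adjacent_cor <- function(beta_matrix, annotation) {
  annotation <- check_annotation(annotation)
  beta_matrix <- as.matrix(beta_matrix)
  m <- ncol(beta_matrix)
  if (nrow(annotation) != m)
    stop("annotation rows must match beta_matrix columns")
  if (nrow(beta_matrix) < 3L)
    stop("need at least 3 samples to compute correlations")
  if (m < 2L) return(numeric(0))

  r <- rep(-Inf, m - 1L)
  same_chrom <- annotation$chromosome[-m] == annotation$chromosome[-1L]
  idx <- which(same_chrom)
  if (length(idx)) {
    rr <- suppressWarnings(vapply(idx, function(j) {
      cor(beta_matrix[, j], beta_matrix[, j + 1L], use = "pairwise.complete.obs")
    }, numeric(1)))
    bad <- !is.finite(rr)
    if (any(bad)) {
      warning(sum(bad), " adjacent pair(s) with undefined correlation ",
              "(zero variance); treated as uncorrelated boundaries")
      rr[bad] <- -Inf
    }
    r[idx] <- rr
  }
  r
}

#' Segment coordinate-sorted CpGs into correlation blocks
#'
#' A maximal run of consecutive CpGs whose every internal adjacent correlation
#' is strictly greater than `threshold` forms one block; every other CpG forms
#' a block by itself. Blocks never span chromosomes, and the blocks partition
#' all CpGs: block sizes sum to `m`.
#'
#' @param correlations adjacent correlations as returned by [adjacent_cor()]
#'   (length `m - 1`, `-Inf` at chromosome boundaries).
#' @param annotation coordinate-sorted annotation with `m` rows.
#' @param threshold correlation threshold; the default 0.5 is the recommended
#'   value. Ties at exactly the threshold break the chain.
#' @param max_gap optional maximum base-pair distance between adjacent CpGs in
#'   one block; `NULL` (the default) applies no distance cap, so correlation
#'   alone decides the chains.
#' @return data frame with one row per block: `block_id`, `chromosome`,
#'   `start`, `end` (1-based inclusive), `block_size`, and list columns
#'   `cpg_ids` and `adjacent_cor`.
#' @export
segment_blocks <- function(correlations, annotation, threshold = 0.5,
                           max_gap = NULL) {
  annotation <- check_annotation(annotation)
  m <- nrow(annotation)
  if (m == 0L)
    return(data.frame(block_id = integer(0), chromosome = character(0),
                      start = integer(0), end = integer(0),
                      block_size = integer(0)))
  if (length(correlations) != m - 1L)
    stop("correlations must have length nrow(annotation) - 1")
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("'threshold' must be a single value in (0, 1)")

  link <- if (m > 1L) correlations > threshold else logical(0)
  if (!is.null(max_gap) && m > 1L) {
    gaps <- diff(annotation$position)
    same <- annotation$chromosome[-m] == annotation$chromosome[-1L]
    link <- link & (!same | gaps <= max_gap)
  }
  # block starts where the chain to the previous CpG is broken
  starts <- which(c(TRUE, !link))
  ends <- c(starts[-1L] - 1L, m)

  out <- data.frame(
    block_id = seq_along(starts),
    chromosome = annotation$chromosome[starts],
    start = annotation$position[starts],
    end = annotation$position[ends],
    block_size = ends - starts + 1L
  )
  out$cpg_ids <- I(lapply(seq_along(starts), function(b)
    annotation$cpg_id[starts[b]:ends[b]]))
  out$adjacent_cor <- I(lapply(seq_along(starts), function(b) {
    if (starts[b] == ends[b]) numeric(0)
    else correlations[starts[b]:(ends[b] - 1L)]
  }))
  attr(out, "first_index") <- starts
  out
}
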