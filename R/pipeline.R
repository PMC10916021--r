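# End-to-end DMR pipeline: assemble data, clip boundaries, segment, fit,
# test, adjust, classify, export.

BOUNDARY_CLIP <- 1e-6

#' Assemble a methylation dataset in memory
#'
#' Validates and aligns a beta-value matrix, a CpG annotation table and a
#' per-sample phenotype table. Beta values exactly 0 or 1 are clipped to
#' `[1e-6, 1 - 1e-6]` (the generalized beta density is undefined at the
#' boundary); the number of clipped values is reported.
#'
#' @param beta numeric matrix of beta values with samples in rows and CpGs in
#'   columns; row names are sample IDs, column names CpG IDs.
#' @param annotation data frame with columns `cpg_id`, `chromosome`,
#'   `position` covering every column of `beta`.
#' @param pheno data frame of phenotypes/covariates, one row per sample,
#'   with sample IDs in a `sample_id` column or as row names.
#' @return an object of class `"methylation_dataset"`: a list with elements
#'   `beta` (samples x CpGs, coordinate-sorted columns), `annotation`
#'   (sorted), `pheno`, and `n_clipped`.
#' @export
methylation_dataset <- function(beta, annotation, pheno) {
  beta <- as.matrix(beta)
  if (!is.numeric(beta)) stop("beta matrix must be numeric")
  if (is.null(colnames(beta))) stop("beta matrix needs CpG IDs as column names")
  if (is.null(rownames(beta))) stop("beta matrix needs sample IDs as row names")
  annotation <- check_annotation(annotation)

  pheno <- as.data.frame(pheno)
  if ("sample_id" %in% names(pheno)) {
    rownames(pheno) <- as.character(pheno$sample_id)
    pheno$sample_id <- NULL
  }
  samples <- intersect(rownames(beta), rownames(pheno))
  if (length(samples) == 0L)
    stop("no overlapping samples between beta matrix and phenotype table")
  dropped <- (nrow(beta) - length(samples)) + (nrow(pheno) - length(samples))
  if (dropped > 0L)
    warning(dropped, " sample record(s) without a match in the other table; dropped")
  beta <- beta[samples, , drop = FALSE]
  pheno <- pheno[samples, , drop = FALSE]

  keep <- colnames(beta) %in% annotation$cpg_id
  if (!any(keep)) stop("no CpG in the beta matrix is present in the annotation")
  if (!all(keep)) {
    warning(sum(!keep), " CpG(s) missing from the annotation; dropped")
    beta <- beta[, keep, drop = FALSE]
  }
  annotation <- sort_annotation(annotation[annotation$cpg_id %in% colnames(beta), ])
  beta <- beta[, annotation$cpg_id, drop = FALSE]

  if (anyNA(beta)) stop("beta matrix contains missing values")
  out_of_range <- beta < 0 | beta > 1
  if (any(out_of_range)) stop("beta values outside [0, 1]")
  clipped <- beta <= 0 | beta >= 1
  n_clipped <- sum(clipped)
  if (n_clipped > 0L) {
    message("clipped ", n_clipped, " boundary beta value(s) into [",
            BOUNDARY_CLIP, ", 1 - ", BOUNDARY_CLIP, "]")
    beta <- pmin(pmax(beta, BOUNDARY_CLIP), 1 - BOUNDARY_CLIP)
  }

  structure(list(beta = beta, annotation = annotation, pheno = pheno,
                 n_clipped = n_clipped),
            class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat("Methylation dataset: ", nrow(x$beta), " samples x ", ncol(x$beta),
      " CpGs on ", length(unique(x$annotation$chromosome)), " chromosome(s)\n",
      sep = "")
  cat("Phenotype columns:", paste(names(x$pheno), collapse = ", "), "\n")
  if (x$n_clipped) cat("Boundary values clipped:", x$n_clipped, "\n")
  invisible(x)
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    read.delim(path, sep = ",", check.names = FALSE, stringsAsFactors = FALSE)
  else
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a methylation dataset from delimited files
#'
#' Reads a CpG-by-sample beta-value table (first column CpG IDs, remaining
#' columns one per sample), a phenotype table (sample IDs in the first column
#' or a `sample_id` column), and a CpG annotation table with columns
#' `cpg_id`, `chromosome`, `position`. Files ending in `.csv` are read as
#' comma-separated, anything else as tab-separated. Samples missing from
#' either table are dropped with a warning; boundary beta values are clipped
#' as in [methylation_dataset()].
#'
#' @param beta_path,phenotype_path,annotation_path file paths.
#' @return a `"methylation_dataset"` object (samples x CpGs internally).
#' @export
read_methylation <- function(beta_path, phenotype_path, annotation_path) {
  bt <- read_table_auto(beta_path)
  ids <- as.character(bt[[1L]])
  bm <- as.matrix(bt[, -1L, drop = FALSE])
  if (!is.numeric(bm)) {
    bad <- which(!vapply(bt[, -1L, drop = FALSE], is.numeric, logical(1)))
    badrow <- which(is.na(suppressWarnings(as.numeric(bt[[bad[1L] + 1L]]))))[1L]
    stop("non-numeric beta value near row ", badrow, " (CpG ", ids[badrow],
         "), column '", names(bt)[bad[1L] + 1L], "'")
  }
  rownames(bm) <- ids

  ph <- read_table_auto(phenotype_path)
  if (!"sample_id" %in% names(ph)) names(ph)[1L] <- "sample_id"
  an <- read_table_auto(annotation_path)

  methylation_dataset(beta = t(bm), annotation = an, pheno = ph)
}

#' Adjust p-values for multiple testing across blocks
#'
#' Thin wrapper around [stats::p.adjust()] restricted to the methods the
#' pipeline supports. Missing p-values stay missing and are excluded from the
#' number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]` (may contain `NA`).
#' @param method one of `"bonferroni"` (default), `"holm"`, `"bh"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "holm", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = c(bonferroni = "bonferroni", holm = "holm", bh = "BH")[[method]])
}

# Build the (intercept, phenotype, covariates) design matrix from the
# phenotype table. The phenotype of interest is always column 2, so its
# coefficient is the one the LRT drops. Two-level factors are coded 0/1;
# factors with more levels are rejected (the test has one degree of freedom).
build_design <- function(pheno, phenotype, covariates = NULL) {
  if (!phenotype %in% names(pheno))
    stop("phenotype '", phenotype, "' not found in the phenotype table")
  x1 <- pheno[[phenotype]]
  if (is.character(x1)) x1 <- factor(x1)
  if (is.factor(x1)) {
    if (nlevels(droplevels(x1)) != 2L)
      stop("phenotype '", phenotype, "' must be binary or continuous")
    x1 <- as.numeric(droplevels(x1)) - 1
  }
  x1 <- as.numeric(x1)
  X <- cbind("(Intercept)" = 1, x1)
  colnames(X)[2L] <- phenotype
  if (length(covariates)) {
    missing_cov <- setdiff(covariates, names(pheno))
    if (length(missing_cov))
      stop("covariate(s) not found: ", paste(missing_cov, collapse = ", "))
    Xc <- model.matrix(~ ., data = pheno[, covariates, drop = FALSE])[, -1L, drop = FALSE]
    X <- cbind(X, Xc)
  }
  if (anyNA(X)) stop("missing values in phenotype or covariates")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}

#' Run the full DMR detection pipeline
#'
#' Segments coordinate-sorted CpGs into correlation blocks
#' ([segment_blocks()]), fits each block with a generalized beta regression
#' and tests the phenotype coefficient by likelihood ratio, adjusts p-values
#' for multiple testing across blocks, and classifies significant blocks as
#' DMRs (two or more CpGs) or DMPs (single CpGs).
#'
#' Correlations are computed on the beta values, and blocks are modelled on
#' the beta scale; no M-value transform is involved. The run is deterministic
#' given `seed`: every block's optimizer restarts use a seed derived from
#' `seed` and the block index, so results do not depend on the number of
#' workers.
#'
#' @param dataset a `"methylation_dataset"` from [methylation_dataset()] or
#'   [read_methylation()].
#' @param phenotype name of the phenotype of interest in the phenotype table
#'   (binary or continuous).
#' @param covariates optional character vector of covariate column names.
#' @param threshold adjacent-correlation threshold for block formation
#'   (default 0.5).
#' @param alpha_level significance level applied to adjusted p-values.
#' @param correction multiple-testing correction across blocks: `"bonferroni"`
#'   (default), `"holm"` or `"bh"`.
#' @param seed integer seed for the per-block optimizer restarts.
#' @param n_cores number of worker processes for block fitting (forked via
#'   the parallel package; results are identical for any value).
#' @return an object of class `"gbdmr"`; its `$results` data frame has one
#'   row per block with columns `block_id`, `chromosome`, `start`, `end`,
#'   `block_size`, `cpg_ids` (comma-separated), `gamma1`, `lrt_stat`,
#'   `p_value`, `p_adjusted`, `converged`, `significant`, `label`.
#' @export
gbdmr <- function(dataset, phenotype, covariates = NULL, threshold = 0.5,
                  alpha_level = 0.05,
                  correction = c("bonferroni", "holm", "bh"),
                  seed = NULL, n_cores = 1L) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  correction <- match.arg(correction)
  X <- build_design(dataset$pheno, phenotype, covariates)
  ann <- dataset$annotation
  beta <- dataset$beta

  r <- adjacent_cor(beta, ann)
  blocks <- segment_blocks(r, ann, threshold = threshold)
  first <- attr(blocks, "first_index")

  fit_one <- function(b) {
    i0 <- first[b]
    Lb <- blocks$block_size[b]
    Z <- beta[, i0:(i0 + Lb - 1L), drop = FALSE]
    bseed <- if (is.null(seed)) NULL else (seed + 2L * b) %% .Machine$integer.max
    res <- lrt_block(Z, X, seed = bseed)
    c(gamma1 = unname(res$fit_full$slopes[1L]),
      lrt_stat = res$statistic, p_value = res$p_value,
      converged = as.numeric(res$converged))
  }
  B <- nrow(blocks)
  rows <- if (n_cores > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(B), fit_one, mc.cores = n_cores)
  } else {
    lapply(seq_len(B), fit_one)
  }
  rows <- do.call(rbind, rows)

  results <- data.frame(
    block_id = blocks$block_id,
    chromosome = blocks$chromosome,
    start = blocks$start,
    end = blocks$end,
    block_size = blocks$block_size,
    cpg_ids = vapply(blocks$cpg_ids, paste, character(1), collapse = ","),
    gamma1 = rows[, "gamma1"],
    lrt_stat = rows[, "lrt_stat"],
    p_value = rows[, "p_value"],
    stringsAsFactors = FALSE
  )
  results$p_adjusted <- adjust_pvalues(results$p_value, correction)
  results$converged <- rows[, "converged"] > 0
  results$significant <- !is.na(results$p_adjusted) & results$p_adjusted < alpha_level
  results$label <- ifelse(results$significant,
                          ifelse(results$block_size >= 2L, "DMR", "DMP"),
                          "null")
  ord <- order(chromosome_rank(results$chromosome), results$start)
  results <- results[ord, ]
  rownames(results) <- NULL

  n_unconverged <- sum(!results$converged)
  if (n_unconverged > 0L)
    warning(n_unconverged, " block(s) did not converge; their p-values are NA")

  structure(list(results = results, blocks = blocks, threshold = threshold,
                 alpha_level = alpha_level, correction = correction,
                 phenotype = phenotype, covariates = covariates,
                 n_samples = nrow(beta), n_cpgs = ncol(beta),
                 seed = seed, call = match.call()),
            class = "gbdmr")
}

#' @export
print.gbdmr <- function(x, ...) {
  r <- x$results
  cat("gbdmr run: ", x$n_cpgs, " CpGs in ", nrow(r), " blocks, ",
      x$n_samples, " samples\n", sep = "")
  cat("Phenotype: ", x$phenotype,
      if (length(x$covariates)) paste0(" (+ ", paste(x$covariates, collapse = ", "), ")"),
      "; threshold ", x$threshold, "; ", x$correction, " at ",
      x$alpha_level, "\n", sep = "")
  cat("DMRs: ", sum(r$label == "DMR"), " (", dmr_cpg_count(x), " DMR CpGs); DMPs: ",
      sum(r$label == "DMP"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gbdmr <- function(object, ...) {
  r <- object$results
  sig <- r[r$significant, , drop = FALSE]
  out <- list(n_blocks = nrow(r), n_cpgs = object$n_cpgs,
              n_dmr = sum(r$label == "DMR"), n_dmp = sum(r$label == "DMP"),
              n_dmr_cpgs = dmr_cpg_count(object),
              n_significant_cpgs = sum(sig$block_size),
              n_unconverged = sum(!r$converged),
              top = head(sig[order(sig$p_value), ], 10L))
  class(out) <- "summary.gbdmr"
  out
}

#' @export
print.summary.gbdmr <- function(x, ...) {
  cat(x$n_blocks, "blocks over", x$n_cpgs, "CpGs;",
      x$n_dmr, "DMRs containing", x$n_dmr_cpgs, "CpGs;",
      x$n_dmp, "DMPs;", x$n_unconverged, "unconverged\n")
  if (nrow(x$top)) {
    cat("\nTop significant blocks:\n")
    print(x$top[, c("block_id", "chromosome", "start", "end", "block_size",
                    "gamma1", "lrt_stat", "p_adjusted", "label")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Count the CpG sites inside significant regions
#'
#' `dmr_cpg_count` counts CpGs inside significant multi-CpG blocks (DMR CpGs);
#' `significant_cpg_count` counts all CpGs inside significant blocks (DMR plus
#' DMP CpGs), the quantity power calculations are built on.
#'
#' @param x a [gbdmr()] result.
#' @return an integer count.
#' @export
dmr_cpg_count <- function(x) {
  r <- x$results
  sum(r$block_size[r$label == "DMR"])
}

#' @rdname dmr_cpg_count
#' @export
significant_cpg_count <- function(x) {
  r <- x$results
  sum(r$block_size[r$significant])
}

#' Plot a gbdmr result
#'
#' Draws -log10 adjusted p-values against genomic position, one point per
#' block (area proportional to block size), with chromosomes laid end to end
#' and the significance level marked.
#'
#' @param x a [gbdmr()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gbdmr <- function(x, ...) {
  r <- x$results
  chroms <- unique(r$chromosome)
  offset <- 0
  xs <- numeric(nrow(r))
  mids <- numeric(length(chroms))
  for (k in seq_along(chroms)) {
    sel <- r$chromosome == chroms[k]
    span <- max(r$end[sel])
    xs[sel] <- offset + (r$start[sel] + r$end[sel]) / 2
    mids[k] <- offset + span / 2
    offset <- offset + span * 1.05
  }
  y <- -log10(pmax(r$p_adjusted, 1e-300))
  graphics::plot(xs, y, pch = 16, cex = 0.5 + 0.3 * sqrt(r$block_size),
                 col = ifelse(r$significant, "firebrick", "grey40"),
                 xlab = "genomic position", ylab = "-log10 adjusted p",
                 xaxt = "n", ...)
  graphics::axis(1, at = mids, labels = chroms)
  graphics::abline(h = -log10(x$alpha_level), lty = 2)
  invisible(x)
}

#' Write DMR results to disk
#'
#' `format = "tsv"` writes the full result table; re-reading it with
#' [utils::read.delim()] reproduces the table exactly (numbers are written
#' with 17 significant digits). `format = "bed"` writes a BED5 file
#' (0-based half-open coordinates converted from the 1-based inclusive
#' internal representation) with the block name and a score of
#' -log10(p-value) capped at 1000.
#'
#' @param x a [gbdmr()] result.
#' @param path output file path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  r <- x$results
  if (format == "tsv") {
    out <- r
    for (j in names(out))
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    score <- pmin(1000, round(-log10(pmax(r$p_value, 1e-300)), 3))
    score[is.na(r$p_value)] <- 0
    bed <- data.frame(chrom = r$chromosome,
                      chromStart = r$start - 1L,
                      chromEnd = r$end,
                      name = paste0("block_", r$block_id),
                      score = score)
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
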