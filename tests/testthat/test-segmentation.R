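test_that("adjacent correlations recover exact and null relationships", {
  set.seed(5)
  z <- runif(50, 0.1, 0.9)
  ann <- make_annotation(2)
  expect_equal(adjacent_cor(cbind(z, z), ann), 1.0)
  expect_equal(adjacent_cor(cbind(z, 1 - z), ann), -1.0)

  set.seed(6)
  big <- cbind(runif(10000), runif(10000))
  expect_lt(abs(adjacent_cor(big, ann)), 0.05)
})

test_that("chromosome boundaries and zero variance yield the sentinel", {
  ann <- make_annotation(2, chrom = c("chr1", "chr2"))
  set.seed(7)
  z <- matrix(runif(40), 20, 2)
  z[, 2] <- z[, 1]  # perfectly correlated, but on different chromosomes
  expect_identical(adjacent_cor(z, ann), -Inf)

  ann1 <- make_annotation(2)
  zc <- cbind(z[, 1], rep(0.5, 20))
  expect_warning(r <- adjacent_cor(zc, ann1), "zero variance")
  expect_identical(r, -Inf)
})

test_that("segmentation reproduces the canonical five-CpG example", {
  ann <- make_annotation(5)
  blocks <- segment_blocks(c(0.6, 0.7, 0.2, 0.55), ann, threshold = 0.5)
  expect_equal(nrow(blocks), 2L)
  expect_equal(blocks$block_size, c(3L, 2L))
  expect_equal(blocks$cpg_ids[[1]], ann$cpg_id[1:3])
  expect_equal(blocks$cpg_ids[[2]], ann$cpg_id[4:5])
  expect_equal(blocks$adjacent_cor[[1]], c(0.6, 0.7))

  # all correlations below threshold: every CpG forms a block by itself
  singles <- segment_blocks(c(0.1, 0.4, 0.3, 0.49), ann)
  expect_equal(nrow(singles), 5L)
  expect_true(all(singles$block_size == 1L))

  # a tie at exactly the threshold breaks the chain
  tied <- segment_blocks(c(0.5, 0.5, 0.5, 0.5), ann, threshold = 0.5)
  expect_equal(nrow(tied), 5L)
})

test_that("high correlation across a chromosome boundary still splits", {
  ann <- make_annotation(4, chrom = c("chr1", "chr1", "chr2", "chr2"))
  set.seed(8)
  z <- matrix(rep(runif(30, 0.2, 0.8), 4), 30, 4)
  z <- z + matrix(rnorm(120, sd = 0.01), 30, 4)
  z <- pmin(pmax(z, 0.01), 0.99)
  r <- adjacent_cor(z, ann)
  expect_identical(r[2], -Inf)
  blocks <- segment_blocks(r, ann)
  expect_true(all(vapply(blocks$cpg_ids, function(ids)
    length(unique(ann$chromosome[match(ids, ann$cpg_id)])) == 1L, logical(1))))
})

test_that("blocks partition all CpGs for random inputs", {
  set.seed(9)
  for (rep in 1:20) {
    m <- sample(1:40, 1)
    ann <- make_annotation(m, chrom = sample(c("chr1", "chr2"), m,
                                             replace = TRUE, prob = c(0.8, 0.2)))
    ann <- sort_annotation(ann)
    r <- ifelse(ann$chromosome[-m] == ann$chromosome[-1],
                runif(max(m - 1, 0), -1, 1), -Inf)
    blocks <- segment_blocks(r, ann, threshold = 0.5)
    expect_equal(sum(blocks$block_size), m)
    expect_equal(sort(unlist(blocks$cpg_ids)), sort(ann$cpg_id))
  }
})

test_that("re-segmenting each block leaves it unchanged", {
  set.seed(10)
  base <- runif(200, 0.2, 0.8)
  z <- vapply(1:6, function(j) pmin(pmax(0.7 * base + 0.3 * runif(200, 0.2, 0.8),
                                         0.01), 0.99), numeric(200))
  ann <- make_annotation(6)
  blocks <- segment_blocks(adjacent_cor(z, ann), ann)
  for (b in seq_len(nrow(blocks))) {
    ids <- blocks$cpg_ids[[b]]
    idx <- match(ids, ann$cpg_id)
    sub_ann <- ann[idx, ]
    sub <- segment_blocks(adjacent_cor(z[, idx, drop = FALSE], sub_ann), sub_ann)
    expect_equal(nrow(sub), 1L)
    expect_equal(sub$cpg_ids[[1]], ids)
  }
})

test_that("raising the threshold never enlarges a block", {
  set.seed(11)
  ann <- make_annotation(30)
  r <- runif(29, -0.2, 1)
  prev_max <- Inf
  for (th in c(0.2, 0.4, 0.6, 0.8)) {
    blocks <- segment_blocks(r, ann, threshold = th)
    expect_lte(max(blocks$block_size), prev_max)
    prev_max <- max(blocks$block_size)
  }
})

test_that("the optional distance cap breaks chains across large gaps", {
  ann <- make_annotation(3)
  ann$position <- c(100L, 200L, 5000L)
  r <- c(0.9, 0.9)
  expect_equal(nrow(segment_blocks(r, ann)), 1L)                   # no cap
  capped <- segment_blocks(r, ann, max_gap = 1000)
  expect_equal(capped$block_size, c(2L, 1L))
})

test_that("annotation sorting is natural by chromosome then position then ID", {
  ann <- data.frame(
    cpg_id = c("cg5", "cg2", "cg9", "cg1", "cg3", "cg4"),
    chromosome = c("chr10", "chr2", "chrX", "chr2", "chr1", "chr2"),
    position = c(50L, 100L, 10L, 500L, 7L, 100L))
  s <- sort_annotation(ann)
  expect_equal(s$chromosome, c("chr1", "chr2", "chr2", "chr2", "chr10", "chrX"))
  # tie at chr2:100 broken by CpG ID
  expect_equal(s$cpg_id[2:3], c("cg2", "cg4"))
  expect_error(sort_annotation(rbind(ann, ann[1, ])), "duplicated")
})
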