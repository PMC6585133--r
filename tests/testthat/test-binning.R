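test_that("frequency vectors are per-site nucleotide proportions", {
  chars <- rbind(a = c("A", "G", "A"), b = c("C", "G", "A"),
                 c = c("C", "G", "C"), d = c("A", "G", "T"))
  F <- frequency_matrix(dna_alignment(chars))
  expect_equal(F[1, ], c(A = 0.5, C = 0.5, G = 0, T = 0))
  expect_equal(F[2, ], c(A = 0, C = 0, G = 1, T = 0))
  expect_equal(unname(rowSums(F)), rep(1, 3))
  ## 10-taxon site with 5 A, 3 C, 2 T
  col10 <- matrix(c(rep("A", 5), rep("C", 3), rep("T", 2)), 10, 1,
                  dimnames = list(paste0("s", 1:10), NULL))
  expect_equal(frequency_matrix(dna_alignment(col10))[1, ],
               c(A = 0.5, C = 0.3, G = 0, T = 0.2))
})

test_that("equal-frequency binning partitions the 256 patterns into the
           35 bins with the expected type structure", {
  sch <- equal_frequency_bins()
  expect_equal(sch$K, 35L)
  expect_equal(as.vector(table(sch$table$type)),
               c(4L, 6L, 12L, 12L, 1L))  # A B C D E
  ## enumerate all 256 patterns: each maps to exactly one bin
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), 4),
                      stringsAsFactors = FALSE)
  patmat <- t(as.matrix(grid))
  rownames(patmat) <- paste0("t", 1:4)
  idx <- bin_of(dna_alignment(patmat), sch)
  expect_length(idx, 256)
  expect_equal(sort(unique(idx)), 1:35)
  sizes <- tabulate(idx, 35)
  bytype <- split(sizes, sch$table$type)
  expect_true(all(bytype$A == 1))
  expect_true(all(bytype$B == 6))
  expect_true(all(bytype$C == 4))
  expect_true(all(bytype$D == 12))
  expect_true(all(bytype$E == 24))
})

test_that("patterns with equal count multisets share a bin; AAAA is
           alone; taxon order is irrelevant", {
  sch <- equal_frequency_bins()
  pats <- c("ACCA", "CACA", "ACAC")
  pm <- do.call(cbind, strsplit(pats, ""))
  rownames(pm) <- paste0("t", 1:4)
  idx <- bin_of(dna_alignment(pm), sch)
  expect_equal(length(unique(idx)), 1)
  ## {A:2,C:2} and {A:2,G:2} are different bins
  pm2 <- do.call(cbind, strsplit(c("AACC", "AAGG"), ""))
  rownames(pm2) <- paste0("t", 1:4)
  expect_equal(length(unique(bin_of(dna_alignment(pm2), sch))), 2)
  ## constant-A pattern shares its bin with no other pattern
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), 4),
                      stringsAsFactors = FALSE)
  patmat <- t(as.matrix(grid)); rownames(patmat) <- paste0("t", 1:4)
  all_idx <- bin_of(dna_alignment(patmat), sch)
  aaaa <- all_idx[apply(patmat, 2, paste, collapse = "") == "AAAA"]
  expect_equal(sum(all_idx == aaaa), 1)
})

test_that("kmeans binning is deterministic, validates K, and its
           assignment reproduces the clustering", {
  tr <- study_tree("hard10")
  aln <- simulate_alignment(tr, gtr_paper(), 400, seed = 21)
  F <- frequency_matrix(aln)
  s1 <- kmeans_bins(F, 10, seed = 99)
  s2 <- kmeans_bins(F, 10, seed = 99)
  expect_identical(s1$centers, s2$centers)
  cnt <- assign_bins(F, s1)
  expect_equal(sum(cnt), nrow(F))
  ## nearest-center assignment attains (at most) the recorded
  ## within-cluster SS
  idx <- attr(cnt, "assignment")
  ss <- sum((F - s1$centers[idx, ])^2)
  expect_lte(ss, s1$tot_withinss + 1e-8)
  expect_gt(ss, s1$tot_withinss - 1e-3)
  ## restarts cannot worsen the objective
  s10 <- kmeans_bins(F, 10, seed = 7, nstart = 1)
  s20 <- kmeans_bins(F, 10, seed = 7, nstart = 20)
  expect_lte(s20$tot_withinss, s10$tot_withinss + 1e-9)
  expect_error(kmeans_bins(F, 1, seed = 1), ">= 2")
  expect_error(kmeans_bins(matrix(0.25, 50, 4), 3, seed = 1), "distinct")
  ## two distinct rows, K = 2: centers are the rows themselves
  F2 <- rbind(matrix(c(1, 0, 0, 0), 10, 4, byrow = TRUE),
              matrix(c(0, 0, 0, 1), 5, 4, byrow = TRUE))
  colnames(F2) <- c("A", "C", "G", "T")
  s3 <- kmeans_bins(F2, 2, seed = 1)
  expect_equal(s3$tot_withinss, 0)
  expect_equal(sort(s3$centers[, 1]), c(0, 1))
})

test_that("equidistant frequency vectors go to the lowest bin index", {
  sch <- structure(list(method = "kmeans", K = 3L,
                        centers = rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                                        c(0, 0, 1, 0))),
                   class = "binning_scheme")
  F <- rbind(c(0.5, 0.5, 0, 0),   # equidistant from centers 1 and 2
             c(0, 0.5, 0.5, 0))   # equidistant from centers 2 and 3
  expect_equal(unname(bin_of(F, sch)), c(1L, 2L))
})

test_that("random binning reproduces the reference worked example", {
  scores <- matrix(c(2, 4, 3, 3,
                     3, 4, 6, 0,
                     1, 6, 3, 1,
                     5, 2, 0, 5), 4, 4, byrow = TRUE,
                   dimnames = list(paste0("tx", 1:4),
                                   c("A", "C", "G", "T")))
  seqs <- rbind(tx1 = strsplit("ACTG", "")[[1]],
                tx2 = strsplit("AATC", "")[[1]],
                tx3 = strsplit("GCTC", "")[[1]],
                tx4 = strsplit("GCAG", "")[[1]])
  sch <- random_bins(7, score_table = scores)
  cnt <- assign_bins(dna_alignment(seqs), sch)
  bins0 <- attr(cnt, "assignment") - 1L   # labels are 0-based
  expect_equal(bins0, c(1L, 1L, 2L, 6L))
  expect_equal(sum(cnt), 4)
  ## all-zero scores put every site in bin 0
  sch0 <- random_bins(7, score_table = matrix(0, 4, 4,
                                              dimnames = dimnames(scores)))
  expect_equal(unname(assign_bins(dna_alignment(seqs), sch0)[1]), 4)
  ## drawn score tables are reproducible and cover 0..K-1
  r1 <- random_bins(5, taxa = paste0("t", 1:6), seed = 4)
  r2 <- random_bins(5, taxa = paste0("t", 1:6), seed = 4)
  expect_identical(r1$scores, r2$scores)
  expect_true(all(r1$scores %in% 0:4))
})
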