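## Binning of site patterns: exact equal-frequency binning (4 taxa),
## K-means clustering of per-site nucleotide frequency vectors (general),
## and the random-binning baseline.

#' Per-site nucleotide frequency vectors
#'
#' Summarises each site (column) of an alignment by the proportions of
#' A, C, G, T among its m characters: an n x 4 matrix F whose rows sum
#' to 1 and whose entries are multiples of 1/m.
#'
#' @param x A [dna_alignment()], [compress_patterns()] table, or an m x P
#'   character matrix of site patterns.
#' @return n x 4 numeric matrix with columns `A`, `C`, `G`, `T`.
#' @export
frequency_matrix <- function(x) {
  chars <- if (inherits(x, "site_patterns")) x$patterns else unclass(x)
  m <- nrow(chars)
  F <- vapply(.NUC_ABC, function(b) colSums(chars == b) / m,
              numeric(ncol(chars)))
  if (ncol(chars) == 1) F <- matrix(F, 1, 4)  # vapply drops to vector
  colnames(F) <- .NUC_ABC
  F
}

.new_scheme <- function(.method, .K, ...) {
  structure(c(list(method = .method, K = as.integer(.K)), list(...)),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat("Binning scheme:", x$method, "with K =", x$K, "bins\n")
  invisible(x)
}

#' Equal-frequency binning for 4-taxon site patterns
#'
#' Partitions the 256 possible 4-taxon site patterns into 35 bins: two
#' patterns share a bin iff they have the same nucleotide count vector
#' (equivalently, the same per-site frequency vector).  The bins fall
#' into five types by the multiset of counts: type A (one nucleotide four
#' times; 4 bins of 1 pattern), B (2+2; 6 bins of 6), C (3+1; 12 bins of
#' 4), D (2+1+1; 12 bins of 12), E (all four distinct; 1 bin of 24).
#'
#' @return A `binning_scheme` with `K = 35`, a `table` data frame of the
#'   count vectors with their type letters, and a key-to-bin lookup.
#' @export
equal_frequency_bins <- function() {
  g <- expand.grid(A = 0:4, C = 0:4, G = 0:4, T = 0:4)
  g <- g[rowSums(g) == 4, ]
  g <- g[order(-g$A, -g$C, -g$G, -g$T), ]
  rownames(g) <- NULL
  sig <- apply(g, 1, function(r) paste(sort(r[r > 0], decreasing = TRUE),
                                       collapse = "+"))
  g$type <- c("4" = "A", "2+2" = "B", "3+1" = "C",
              "2+1+1" = "D", "1+1+1+1" = "E")[sig]
  key <- paste(g$A, g$C, g$G, g$T)
  .new_scheme("equal_frequency", nrow(g), m = 4L, table = g,
              key = setNames(seq_len(nrow(g)), key))
}

#' K-means binning of frequency vectors
#'
#' Clusters the rows of a frequency matrix into K bins by K-means under
#' Euclidean distance (multiple random restarts; deterministic given
#' `seed`).  Cluster centers are reordered lexicographically so bin
#' indices do not depend on K-means' internal labelling.
#'
#' @param F Frequency matrix from [frequency_matrix()].
#' @param K Number of bins (>= 2, at most the number of distinct rows).
#' @param seed Integer seed recorded in the scheme.
#' @param nstart Number of random restarts (default 10).
#' @param iter.max Iteration cap per restart (default 300).
#' @return A `binning_scheme` with the K x 4 matrix of `centers`.
#' @export
kmeans_bins <- function(F, K, seed = 1L, nstart = 10, iter.max = 300) {
  K <- as.integer(K)
  ux <- unique(F)
  if (K < 2) stop("'K' must be >= 2")
  if (K > nrow(ux))
    stop("K = ", K, " exceeds the ", nrow(ux), " distinct frequency vectors")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    ctr <- ux[sample.int(nrow(ux), K), , drop = FALSE]
    ## convergence warnings from single restarts are benign: the best
    ## objective over restarts is kept
    km <- tryCatch(suppressWarnings(
      stats::kmeans(F, centers = ctr, iter.max = iter.max)),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12)
      best <- km
  }
  if (is.null(best)) stop("K-means failed for all restarts")
  centers <- best$centers
  ord <- do.call(order, as.data.frame(centers))
  centers <- centers[ord, , drop = FALSE]
  rownames(centers) <- NULL
  colnames(centers) <- .NUC_ABC
  .new_scheme("kmeans", K, centers = centers, seed = seed,
              tot_withinss = best$tot.withinss)
}

#' Random binning of site patterns
#'
#' Assigns each taxon a score in `0..K-1` for each nucleotide; a site's
#' bin is the sum of the scores of its nucleotides, modulo K.  Used as a
#' baseline binning against which frequency-based binning is compared.
#' Bin labels are `0..K-1`.
#'
#' @param K Number of bins.
#' @param score_table Optional m x 4 integer matrix of scores (columns
#'   A, C, G, T; rows named by taxon).  If omitted, scores are drawn
#'   uniformly from `0..K-1` (requires `taxa` and, for reproducibility,
#'   `seed`).
#' @param taxa Taxon names (needed when `score_table` is drawn).
#' @param seed Optional integer seed for drawing the score table.
#' @return A `binning_scheme` with the `scores` table.
#' @export
random_bins <- function(K, score_table = NULL, taxa = NULL, seed = NULL) {
  K <- as.integer(K)
  if (is.null(score_table)) {
    if (is.null(taxa)) stop("'taxa' required to draw a random score table")
    if (!is.null(seed)) set.seed(seed)
    score_table <- matrix(sample.int(K, 4 * length(taxa), replace = TRUE) - 1L,
                          length(taxa), 4,
                          dimnames = list(taxa, .NUC_ABC))
  } else {
    score_table <- as.matrix(score_table)
    if (ncol(score_table) != 4)
      stop("'score_table' must have 4 columns (A, C, G, T)")
    colnames(score_table) <- .NUC_ABC
    if (is.null(rownames(score_table)) && !is.null(taxa))
      rownames(score_table) <- taxa
  }
  .new_scheme("random", K, scores = score_table, seed = seed)
}

#' Assign sites to bins under a binning scheme
#'
#' Maps every site of an alignment (or every pattern of a pattern table)
#' to its bin and tallies counts per bin.  For K-means schemes a site is
#' assigned to the nearest center under Euclidean distance, ties broken
#' towards the lowest bin index; equal-frequency and random schemes are
#' exact lookups.
#'
#' @param x A [dna_alignment()], [compress_patterns()] table, or (for
#'   equal-frequency and K-means schemes) a [frequency_matrix()].
#' @param scheme A `binning_scheme`.
#' @return Integer vector of per-bin counts (length K, summing to the
#'   number of sites) with attribute `"assignment"` giving each site's
#'   bin index in `1..K`.  For random schemes the user-facing bin label
#'   is `index - 1`.
#' @export
assign_bins <- function(x, scheme) {
  idx <- bin_of(x, scheme)
  counts <- tabulate(idx, nbins = scheme$K)
  names(counts) <- if (scheme$method == "random") 0:(scheme$K - 1)
                   else seq_len(scheme$K)
  attr(counts, "assignment") <- idx
  counts
}

#' Per-site bin indices under a binning scheme
#'
#' @inheritParams assign_bins
#' @return Integer vector of bin indices in `1..K`, one per site.
#' @export
bin_of <- function(x, scheme) {
  switch(scheme$method,
    equal_frequency = {
      F <- if (is.matrix(x) && !inherits(x, "dna_alignment")) x
           else frequency_matrix(x)
      cnt <- round(F * 4)
      if (!is.null(scheme$m) && any(abs(rowSums(cnt) - scheme$m) > 1e-9))
        stop("equal-frequency binning requires 4-taxon data")
      key <- paste(cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4])
      idx <- unname(scheme$key[key])
      if (anyNA(idx)) stop("pattern outside the equal-frequency bin space")
      idx
    },
    kmeans = {
      F <- if (is.matrix(x) && !inherits(x, "dna_alignment")) x
           else frequency_matrix(x)
      C <- scheme$centers
      d2 <- outer(rowSums(F^2), rowSums(C^2), "+") - 2 * F %*% t(C)
      max.col(-d2, ties.method = "first")
    },
    random = {
      chars <- if (inherits(x, "site_patterns")) x$patterns else unclass(x)
      if (!is.matrix(chars) || !all(chars %in% .NUC_ABC))
        stop("random binning needs the alignment characters, not ",
             "frequency vectors")
      sc <- scheme$scores
      if (!is.null(rownames(sc)) && !is.null(rownames(chars))) {
        if (!setequal(rownames(sc), rownames(chars)))
          stop("score table taxa do not match the alignment")
        sc <- sc[rownames(chars), , drop = FALSE]
      }
      if (nrow(sc) != nrow(chars))
        stop("score table rows do not match the number of taxa")
      tot <- numeric(ncol(chars))
      for (i in seq_len(nrow(chars)))
        tot <- tot + sc[i, match(chars[i, ], .NUC_ABC)]
      as.integer(tot %% scheme$K) + 1L
    },
    stop("unknown binning method: ", scheme$method))
}
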