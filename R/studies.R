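## Simulation studies: size/power of the adequacy test and comparators,
## sensitivity to the number of bins K, the random-binning baseline, and
## the per-bin bias assessment.

.as_gen_model <- function(gen_model) {
  if (inherits(gen_model, "subst_model")) gen_model
  else substitution_model(gen_model)
}

#' Size/power simulation for the adequacy test
#'
#' Simulates `reps` alignments under a generating model on a tree, runs
#' the goodness-of-fit test for each requested null model (and optionally
#' the likelihood-ratio test between a nested pair), and reports the
#' fraction of replicates rejected at level `alpha` with a binomial
#' standard error.  When the generator equals the tested model the
#' rejection rate estimates the size of the test; otherwise its power.
#'
#' @param gen_model Generating model (`subst_model` or spec string).
#' @param gen_tree Generating tree ([ape::phylo]).
#' @param test_models Character vector of null models to test.
#' @param reps Number of simulated data sets (>= 50 recommended).
#' @param n Sites per alignment.
#' @param binning,K,M Passed to [gof_test()].
#' @param alpha Significance level.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param two_rate_ratio If non-`NULL`, generate with
#'   [simulate_two_rate()] at this ratio (e.g. 10 for the "+D" two-rate
#'   construction).
#' @param lrt_alt If non-`NULL`, also fit this alternative model on each
#'   replicate and report the LRT of each tested null against it.
#' @return An object of class `"padeq_power"`: data frame `rates` (one
#'   row per test with `reject` rate and `se`), matrix `p` of per-rep
#'   p-values, and the call settings.
#' @export
size_power <- function(gen_model, gen_tree, test_models, reps = 200,
                       n = 500, binning = "auto", K = "auto", M = "auto",
                       alpha = 0.05, seed = 1, two_rate_ratio = NULL,
                       lrt_alt = NULL) {
  gen_model <- .as_gen_model(gen_model)
  tests <- c(paste0("GoF:", test_models),
             if (!is.null(lrt_alt)) paste0("LRT:", test_models, "/", lrt_alt))
  pmat <- matrix(NA_real_, reps, length(tests),
                 dimnames = list(NULL, tests))
  for (r in seq_len(reps)) {
    aln <- if (is.null(two_rate_ratio))
      simulate_alignment(gen_tree, gen_model, n, seed = seed + r)
    else
      simulate_two_rate(gen_tree, gen_model, n, two_rate_ratio,
                        seed = seed + r)
    fits <- list()
    get_fit <- function(spec) {
      if (is.null(fits[[spec]]))
        fits[[spec]] <<- ml_tree_search(compress_patterns(aln), spec)
      fits[[spec]]
    }
    for (tm in test_models) {
      ## rule-of-thumb marginality is tallied per rep, not re-warned
      g <- suppressWarnings(
        gof_test(aln, tm, binning = binning, K = K, M = M,
                 alpha = alpha, seed = seed + r, fit = get_fit(tm)))
      pmat[r, paste0("GoF:", tm)] <- g$p.value
      if (!is.null(lrt_alt)) {
        l <- lrt(get_fit(tm), get_fit(lrt_alt))
        pmat[r, paste0("LRT:", tm, "/", lrt_alt)] <- l$p.value
      }
    }
  }
  rej <- colMeans(pmat < alpha)
  rates <- data.frame(test = tests, reject = rej,
                      se = sqrt(rej * (1 - rej) / reps),
                      row.names = NULL)
  structure(list(rates = rates, p = pmat, reps = reps, n = n,
                 alpha = alpha, generator = gen_model$family,
                 two_rate_ratio = two_rate_ratio),
            class = "padeq_power")
}

#' @export
print.padeq_power <- function(x, ...) {
  cat("Size/power study: generator ", x$generator,
      if (!is.null(x$two_rate_ratio))
        paste0("+D (ratio 1:", x$two_rate_ratio, ")"),
      ", ", x$reps, " replicates of n = ", x$n, " sites, alpha = ",
      x$alpha, "\n", sep = "")
  df <- x$rates
  df$reject <- sprintf("%.1f%%", 100 * df$reject)
  df$se <- sprintf("%.1f%%", 100 * df$se)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Rejection rates across a range of bin counts K
#'
#' Simulates `reps` alignments under the generating model, fits the null
#' model once per replicate, and evaluates the goodness-of-fit test over
#' a grid of K values, reusing the same data sets (and the same stream of
#' simulated expected frequencies) across K to isolate the effect of the
#' bin count.  Optionally repeats the scan with the random-binning
#' baseline on the same data for contrast.
#'
#' @inheritParams size_power
#' @param test_model Null model to test.
#' @param K_range Grid of bin counts.
#' @param compare_random Also evaluate random binning at each K?
#' @return An object of class `"padeq_ksweep"`: `rates` (and
#'   `rates_random`), the per-rep p-value matrices, and settings.
#' @export
k_sweep <- function(gen_model, gen_tree, test_model, reps = 200, n = 500,
                    K_range = c(5, 10, 15, 20, 25, 30), M = "auto",
                    alpha = 0.05, seed = 1, compare_random = FALSE) {
  gen_model <- .as_gen_model(gen_model)
  K_range <- sort(unique(as.integer(K_range)))
  pk <- matrix(NA_real_, reps, length(K_range),
               dimnames = list(NULL, K_range))
  pr <- if (compare_random) pk else NULL
  M_used <- if (identical(M, "auto")) choose_M(n, max(K_range))
            else as.integer(M)
  for (r in seq_len(reps)) {
    aln <- simulate_alignment(gen_tree, gen_model, n, seed = seed + r)
    fit <- ml_tree_search(compress_patterns(aln), test_model)
    set.seed(seed + r)
    sim <- simulate_alignment(fit$tree, fit$model, M_used)
    F_obs <- frequency_matrix(aln)
    F_sim <- frequency_matrix(sim)
    n_distinct <- nrow(unique(F_obs))
    for (ki in seq_along(K_range)) {
      Kv <- K_range[ki]
      if (Kv > n_distinct) next
      scheme <- kmeans_bins(F_obs, Kv, seed = seed + r)
      O <- assign_bins(F_obs, scheme)
      S <- assign_bins(F_sim, scheme)
      E <- n * as.numeric(S) / M_used
      if (any(E == 0)) next
      pk[r, ki] <- pchisq(pearson_statistic(O, E), Kv - 1,
                          lower.tail = FALSE)
      if (compare_random) {
        rsch <- random_bins(Kv, taxa = rownames(aln), seed = seed + r)
        Or <- assign_bins(aln, rsch)
        Sr <- assign_bins(sim, rsch)
        Er <- n * as.numeric(Sr) / M_used
        if (any(Er == 0)) next
        pr[r, ki] <- pchisq(pearson_statistic(Or, Er), Kv - 1,
                            lower.tail = FALSE)
      }
    }
  }
  rate <- function(p) colMeans(p < alpha, na.rm = TRUE)
  structure(list(K_range = K_range, rates = rate(pk),
                 rates_random = if (compare_random) rate(pr),
                 p = pk, p_random = pr, reps = reps, n = n, alpha = alpha,
                 generator = gen_model$family, test_model = test_model),
            class = "padeq_ksweep")
}

#' @export
print.padeq_ksweep <- function(x, ...) {
  cat("K sweep: ", x$generator, " data tested as ", x$test_model, ", ",
      x$reps, " reps, n = ", x$n, "\n", sep = "")
  df <- data.frame(K = x$K_range,
                   kmeans = sprintf("%.1f%%", 100 * x$rates))
  if (!is.null(x$rates_random))
    df$random <- sprintf("%.1f%%", 100 * x$rates_random)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.padeq_ksweep <- function(x, ...) {
  ylim <- c(0, 1)
  plot(x$K_range, x$rates, type = "b", pch = 19, ylim = ylim,
       xlab = "number of bins K", ylab = "rejection rate",
       main = paste0(x$generator, " data, ", x$test_model, " null"), ...)
  if (!is.null(x$rates_random)) {
    graphics::lines(x$K_range, x$rates_random, type = "b", pch = 1,
                    lty = 2)
    graphics::legend("right", legend = c("K-means", "random"),
                     pch = c(19, 1), lty = c(1, 2), bty = "n")
  }
  graphics::abline(h = x$alpha, col = "grey")
  invisible(x)
}

#' Per-bin direction of bias in estimated pattern probabilities
#'
#' For each generating parameter set: simulates `reps` alignments, fits
#' the (typically mis-specified) `fit_model` to each, averages the exact
#' site-pattern probabilities under the fitted models, and subtracts the
#' exact probabilities under the generator.  Within each equal-frequency
#' bin the member-pattern biases are checked for a common sign — the
#' property that gives the binned test its power.
#'
#' @param gen_models A list of generating models (`subst_model`s).
#' @param fit_model Model family fitted to each replicate.
#' @param reps Replicates per generating model.
#' @param n Sites per alignment.
#' @param tree 4-taxon generating tree.
#' @param seed Integer seed.
#' @return A list of class `"padeq_bias"`: per generator, the 256-vector
#'   of biases and a data frame `bins` (bin, type, size,
#'   `sign_consistent`).
#' @export
pattern_bias <- function(gen_models, fit_model = "F81", reps = 1000,
                         n = 1000, tree, seed = 1) {
  if (ape::Ntip(tree) != 4) stop("the bias assessment uses a 4-taxon tree")
  if (inherits(gen_models, "subst_model")) gen_models <- list(gen_models)
  scheme <- equal_frequency_bins()
  out <- lapply(seq_along(gen_models), function(gi) {
    gen <- gen_models[[gi]]
    truth <- exact_pattern_probs(tree, gen)
    acc <- 0
    for (r in seq_len(reps)) {
      aln <- simulate_alignment(tree, gen, n, seed = seed + 1000 * gi + r)
      fit <- ml_tree_search(compress_patterns(aln), fit_model)
      acc <- acc + exact_pattern_probs(fit$tree, fit$model)[names(truth)]
    }
    bias <- acc / reps - truth
    patmat <- do.call(cbind, strsplit(names(truth), ""))
    rownames(patmat) <- tree$tip.label
    idx <- bin_of(structure(list(patterns = patmat, taxa = tree$tip.label,
                                 m = 4L), class = "site_patterns"), scheme)
    bins <- data.frame(
      bin = seq_len(scheme$K), type = scheme$table$type,
      size = as.integer(tabulate(idx, scheme$K)),
      sign_consistent = vapply(seq_len(scheme$K), function(j) {
        b <- bias[idx == j]
        all(b > 0) || all(b < 0)
      }, TRUE))
    list(bias = bias, bins = bins)
  })
  names(out) <- vapply(gen_models, function(g) g$family, "")
  structure(out, class = "padeq_bias")
}

#' Topology recovery under different fitted models
#'
#' Simulates alignments under a generating model/tree and tabulates, for
#' each candidate fitting family, the Robinson-Foulds distances between
#' the ML trees and the generating topology.
#'
#' @inheritParams size_power
#' @param test_families Character vector of families to fit.
#' @return A list of class `"padeq_topacc"` with a count table per
#'   family (named by RF distance) and the settings.
#' @export
topology_accuracy <- function(gen_model, gen_tree, test_families,
                              reps = 100, n = 500, seed = 1) {
  gen_model <- .as_gen_model(gen_model)
  maxrf <- 2 * (ape::Ntip(gen_tree) - 3)
  res <- sapply(test_families, function(fam) {
    rf <- vapply(seq_len(reps), function(r) {
      aln <- simulate_alignment(gen_tree, gen_model, n, seed = seed + r)
      fit <- ml_tree_search(compress_patterns(aln), fam)
      rf_distance(fit$tree, gen_tree)
    }, 0L)
    tabulate(rf / 2 + 1, nbins = maxrf / 2 + 1)
  })
  rownames(res) <- seq(0, maxrf, by = 2)
  structure(list(counts = t(res), reps = reps, n = n,
                 generator = gen_model$family),
            class = "padeq_topacc")
}

#' @export
print.padeq_topacc <- function(x, ...) {
  cat("ML topology accuracy: ", x$generator, " data, ", x$reps,
      " reps, n = ", x$n, " (columns: RF distance to truth)\n", sep = "")
  print(x$counts)
  invisible(x)
}
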