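## The binned Pearson goodness-of-fit adequacy test, helpers for choosing
## the number of simulated sites M and the number of bins K, and the
## likelihood-ratio and Goldman-Cox comparator tests.

#' Exact expected bin frequencies
#'
#' \eqn{E_j = n \sum_{\mathrm{patterns}\ i \in j} P_i} from exact pattern
#' probabilities ([exact_pattern_probs()]); the expectations sum to n.
#'
#' @param scheme A `binning_scheme`.
#' @param pattern_probs Named probability vector over all patterns (names
#'   are pattern strings; must sum to 1).
#' @param n Observed sequence length.
#' @param taxa Taxon names for the pattern rows (needed for random
#'   schemes; defaults to the scheme's score-table taxa).
#' @return Numeric vector E of length K.
#' @export
expected_exact <- function(scheme, pattern_probs, n, taxa = NULL) {
  if (abs(sum(pattern_probs) - 1) > 1e-6)
    stop("pattern probabilities must sum to 1")
  m <- unique(nchar(names(pattern_probs)))
  if (length(m) != 1) stop("inconsistent pattern names")
  patmat <- do.call(cbind, strsplit(names(pattern_probs), ""))
  if (is.null(taxa)) taxa <- rownames(scheme$scores)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(m))
  rownames(patmat) <- taxa
  sp <- structure(list(patterns = patmat,
                       counts = rep(1L, ncol(patmat)),
                       taxa = taxa, n = ncol(patmat), m = m),
                  class = "site_patterns")
  idx <- bin_of(sp, scheme)
  E <- numeric(scheme$K)
  for (j in seq_len(scheme$K)) E[j] <- sum(pattern_probs[idx == j])
  n * E
}

#' Simulated expected bin frequencies
#'
#' Simulates M sites under the (fitted) model on the tree, assigns each
#' simulated site to a bin, and returns \eqn{E_j = n S_j / M} where
#' \eqn{S_j} is the number of simulated sites in bin j.  Generation is
#' streamed in blocks so only per-bin tallies are held.
#'
#' @param scheme A `binning_scheme`.
#' @param tree,model Tree and model to simulate under (typically the ML
#'   fit under the null).
#' @param n Observed sequence length.
#' @param M Number of sites to simulate (>= n); see [choose_M()].
#' @param seed Optional integer seed.
#' @param block Sites per generation block.
#' @return Numeric vector E of length K with attribute `"S"` (simulated
#'   tallies) and `"M"`.
#' @export
expected_simulated <- function(scheme, tree, model, n, M, seed = NULL,
                               block = 1e5) {
  if (M < n) stop("'M' must be at least the observed sequence length")
  if (!is.null(seed)) set.seed(seed)
  S <- integer(scheme$K)
  left <- as.integer(M)
  while (left > 0) {
    b <- min(left, as.integer(block))
    aln <- simulate_alignment(tree, model, b)
    S <- S + assign_bins(aln, scheme)
    left <- left - b
  }
  E <- n * as.numeric(S) / M
  attr(E, "S") <- as.integer(S)
  attr(E, "M") <- as.integer(M)
  E
}

#' Pearson chi-square statistic
#'
#' \eqn{X^2 = \sum_j (O_j - E_j)^2 / E_j}.
#'
#' @param O Observed bin counts.
#' @param E Expected bin counts (all positive).
#' @return The statistic (nonnegative scalar).
#' @export
pearson_statistic <- function(O, E) {
  if (length(O) != length(E)) stop("'O' and 'E' must have equal length")
  if (any(E <= 0))
    stop("some expected frequencies are zero; merge bins (smaller K) ",
         "or simulate more sites (larger M)")
  sum((O - E)^2 / E)
}

#' Rule of thumb for the chi-square approximation
#'
#' TRUE iff no more than 20% of the bins have expected frequency below 5.
#'
#' @param E Expected bin counts.
#' @return Logical flag.
#' @export
rule_of_thumb <- function(E) {
  sum(E < 5) <= 0.2 * length(E)
}

#' Number of sites to simulate for expected frequencies
#'
#' Returns \eqn{M = 22 K n / (K - 1)}, floor-guarded at 100,000 — enough
#' that the root-mean-squared error this simulation induces in p-values
#' near 0.05 is about 0.005 (see [mse_bound()]).
#'
#' @param n Observed sequence length.
#' @param K Number of bins (>= 2).
#' @param floor_M Lower guard (default 1e5).
#' @return Integer M.
#' @export
choose_M <- function(n, K, floor_M = 1e5) {
  if (K < 2) stop("'K' must be >= 2")
  max(ceiling(22 * K * n / (K - 1)), as.integer(floor_M))
}

#' Bound on the simulation-induced MSE of the statistic
#'
#' Upper bound \eqn{16 K n / (25 M)} on the mean squared error in the
#' chi-square statistic caused by estimating expected frequencies from M
#' simulated sites, valid when the rule of thumb holds.
#'
#' @param K Number of bins.
#' @param n Observed sequence length.
#' @param M Simulated sites.
#' @return The bound (numeric scalar).
#' @export
mse_bound <- function(K, n, M) {
  stopifnot(K > 0, n > 0, M > 0)
  16 * K * n / (25 * M)
}

#' Goodness-of-fit adequacy test for a DNA substitution model
#'
#' Tests the absolute adequacy of a substitution model for an alignment:
#' the null hypothesis is that the model (with its ML tree and parameter
#' estimates, both nuisance parameters) generated the data.  Sites are
#' binned by their nucleotide frequency vectors — exactly (35
#' equal-frequency bins, 4 taxa) or by K-means clustering — and observed
#' bin counts are compared with expected counts under the fitted null by
#' the Pearson statistic, referred to a chi-square distribution with
#' K - 1 degrees of freedom (a deliberately conservative choice).
#'
#' Expected frequencies are computed exactly for the 4-taxon
#' equal-frequency scheme, otherwise by parametric-bootstrap simulation
#' of M sites under the fitted model (`M = choose_M(n, K)` by default).
#'
#' @param aln A [dna_alignment()] with at least 4 taxa.
#' @param model Model specification string (e.g. `"GTR+I+G"`).
#' @param binning `"auto"` (equal-frequency for 4 taxa, else K-means),
#'   `"equal"`, `"kmeans"`, or `"random"`.
#' @param K Number of bins for K-means/random binning, or `"auto"` (the
#'   largest K in `K_range` whose expected frequencies satisfy the rule
#'   of thumb).
#' @param K_range Candidate K values scanned when `K = "auto"`.
#' @param M Simulated sites for expected frequencies, or `"auto"`.
#' @param alpha Significance level recorded on the result (default 0.05).
#' @param seed Optional integer seed (K-means restarts, bootstrap
#'   simulation, random score tables).
#' @param fit Optional precomputed `"ml_fit"` under the null model,
#'   bypassing [ml_tree_search()].
#' @return An object of class `"gof_test"`: observed and expected counts
#'   `O`, `E`, the statistic `X2`, `df = K - 1`, `p.value`, `K`, `M` used
#'   (0 when exact), the rule-of-thumb flag `rule_ok`, the `scheme`, and
#'   the underlying `fit`.
#' @examples
#' \donttest{
#' tr <- read_newick("((t1:0.1,t2:0.1):0.1,t3:0.1,t4:0.1);")
#' aln <- simulate_alignment(tr, substitution_model("JC69"), 500, seed = 1)
#' gof_test(aln, "JC69")
#' }
#' @export
gof_test <- function(aln, model,
                     binning = c("auto", "equal", "kmeans", "random"),
                     K = "auto", K_range = 2:30, M = "auto",
                     alpha = 0.05, seed = NULL, fit = NULL) {
  binning <- match.arg(binning)
  sp <- compress_patterns(aln)
  n <- sp$n; m <- sp$m
  if (m < 4) stop("the adequacy test needs at least 4 taxa")
  if (binning == "auto") binning <- if (m == 4) "equal" else "kmeans"
  if (binning == "equal" && m != 4)
    stop("equal-frequency binning is defined for 4 taxa only")
  if (is.null(fit)) fit <- ml_tree_search(sp, model)
  if (!is.null(seed)) set.seed(seed)

  if (binning == "equal") {
    scheme <- equal_frequency_bins()
    O <- assign_bins(aln, scheme)
    probs <- exact_pattern_probs(fit$tree, fit$model)
    E <- expected_exact(scheme, probs, n, taxa = fit$tree$tip.label)
    M_used <- 0L
  } else {
    F_obs <- frequency_matrix(aln)
    if (binning == "kmeans") {
      km_seed <- if (is.null(seed)) 1L else seed
      if (identical(K, "auto")) {
        sel <- select_K(aln, model, K_range = K_range, M = M,
                        seed = seed, fit = fit)
        K <- sel$K
        scheme <- sel$scheme
        E <- sel$E
      } else {
        scheme <- kmeans_bins(F_obs, K, seed = km_seed)
        E <- NULL
      }
    } else {
      if (identical(K, "auto"))
        stop("random binning needs an explicit K")
      scheme <- random_bins(K, taxa = sp$taxa, seed = seed)
      E <- NULL
    }
    K <- scheme$K
    if (is.null(E)) {
      M_used <- if (identical(M, "auto")) choose_M(n, K) else as.integer(M)
      E <- expected_simulated(scheme, fit$tree, fit$model, n, M_used)
    } else M_used <- attr(E, "M")
    O <- if (binning == "random") assign_bins(aln, scheme)
         else assign_bins(F_obs, scheme)
  }

  rule_ok <- rule_of_thumb(E)
  if (!rule_ok)
    warning("more than 20% of bins have expected frequency < 5; the ",
            "chi-square approximation may be poor - consider a smaller K")
  X2 <- pearson_statistic(O, E)
  df <- scheme$K - 1
  structure(list(O = O, E = as.numeric(E), K = scheme$K, X2 = X2, df = df,
                 p.value = pchisq(X2, df, lower.tail = FALSE),
                 M = M_used, rule_ok = rule_ok, alpha = alpha,
                 scheme = scheme, fit = fit, n = n, m = m,
                 model = fit$family),
            class = "gof_test")
}

#' @export
print.gof_test <- function(x, ...) {
  cat("Binned Pearson goodness-of-fit adequacy test\n")
  cat("  null model: ", x$model, "   (", x$m, " taxa, n = ", x$n,
      " sites)\n", sep = "")
  cat("  binning: ", x$scheme$method, ", K = ", x$K,
      if (x$M > 0) paste0(", expected frequencies from M = ", x$M,
                          " simulated sites") else
        ", exact expected frequencies",
      "\n", sep = "")
  cat("  X-squared = ", format(x$X2, digits = 6), ", df = ", x$df,
      ", p-value = ", format.pval(x$p.value, digits = 4), "\n", sep = "")
  if (!x$rule_ok)
    cat("  NOTE: rule of thumb violated (>20% of bins with E < 5)\n")
  invisible(x)
}

#' Choose the number of bins K
#'
#' Scans candidate K values, computing expected bin frequencies under the
#' fitted null for each, and returns the largest K whose expectations
#' satisfy the rule of thumb, together with the p-value trace over the
#' whole range.  One stream of M simulated sites is shared across the
#' scan.  If no K passes, the smallest candidate is returned with a
#' warning.
#'
#' @inheritParams gof_test
#' @param K_range Candidate K values (each >= 2).
#' @return A list of class `"select_K"`: chosen `K`, its `scheme` and
#'   expected frequencies `E`, and a data frame `trace` with columns
#'   `K`, `X2`, `p`, `rule_ok`.
#' @export
select_K <- function(aln, model, K_range = 2:30, M = "auto", seed = NULL,
                     fit = NULL) {
  sp <- compress_patterns(aln)
  if (is.null(fit)) fit <- ml_tree_search(sp, model)
  F_obs <- frequency_matrix(aln)
  n_distinct <- nrow(unique(F_obs))
  K_range <- sort(unique(as.integer(K_range)))
  K_range <- K_range[K_range >= 2 & K_range <= n_distinct]
  if (length(K_range) == 0) stop("no feasible K in 'K_range'")
  n <- sp$n
  M_used <- if (identical(M, "auto")) choose_M(n, max(K_range))
            else as.integer(M)
  km_seed <- if (is.null(seed)) 1L else seed
  set.seed(km_seed)
  ## one big simulated sample shared across the K scan
  Fsim <- frequency_matrix(simulate_alignment(fit$tree, fit$model, M_used))
  rows <- lapply(K_range, function(K) {
    scheme <- kmeans_bins(F_obs, K, seed = km_seed)
    S <- assign_bins(Fsim, scheme)
    E <- n * as.numeric(S) / M_used
    O <- assign_bins(F_obs, scheme)
    ok <- rule_of_thumb(E)
    if (any(E == 0))
      return(list(scheme = scheme, E = E, X2 = NA_real_, p = NA_real_,
                  rule_ok = FALSE))
    X2 <- pearson_statistic(O, E)
    list(scheme = scheme, E = E, X2 = X2,
         p = pchisq(X2, K - 1, lower.tail = FALSE), rule_ok = ok)
  })
  trace <- data.frame(K = K_range,
                      X2 = vapply(rows, `[[`, 0, "X2"),
                      p = vapply(rows, `[[`, 0, "p"),
                      rule_ok = vapply(rows, `[[`, TRUE, "rule_ok"))
  pass <- which(trace$rule_ok & !is.na(trace$X2))
  if (length(pass) == 0) {
    warning("no candidate K satisfies the rule of thumb; using the ",
            "smallest K = ", K_range[1])
    pick <- 1L
  } else pick <- max(pass)
  E <- rows[[pick]]$E
  attr(E, "M") <- M_used
  structure(list(K = K_range[pick], scheme = rows[[pick]]$scheme,
                 E = E, M = M_used, trace = trace, fit = fit),
            class = "select_K")
}

#' @export
print.select_K <- function(x, ...) {
  cat("Bin-count selection: chose K =", x$K, "(largest K passing the",
      "rule of thumb)\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test between nested model fits
#'
#' Compares two ML fits of nested families on the same data:
#' \eqn{2(\ell_{\mathrm{alt}} - \ell_{\mathrm{null}})} referred to a
#' chi-square with degrees of freedom equal to the difference in free
#' parameter counts (e.g. 3 for SYM vs GTR — the free base frequencies).
#'
#' @param null_fit,alt_fit `"ml_fit"` objects; `null_fit`'s family must
#'   be nested in `alt_fit`'s.
#' @return A list of class `"padeq_lrt"` with `statistic`, `df`,
#'   `p.value`.
#' @export
lrt <- function(null_fit, alt_fit) {
  if (!.is_nested(null_fit$family, alt_fit$family))
    stop(null_fit$family, " is not nested in ", alt_fit$family)
  df <- alt_fit$n_free_params - null_fit$n_free_params
  if (df < 1) stop("alternative has no extra free parameters")
  stat <- 2 * (alt_fit$loglik - null_fit$loglik)
  if (stat < 0) {
    if (stat < -1e-3)
      warning("alternative fit has lower likelihood than the null ",
              "(optimizer artefact); statistic clamped at 0")
    stat <- 0
  }
  structure(list(statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE),
                 null = null_fit$family, alt = alt_fit$family),
            class = "padeq_lrt")
}

.is_nested <- function(null, alt) {
  pn <- parse_model_spec(null); pa <- parse_model_spec(alt)
  fam_ok <- {
    ord <- list(JC69 = character(), F81 = "JC69", HKY = c("JC69", "F81"),
                SYM = "JC69", GTR = c("JC69", "F81", "HKY", "SYM"))
    pn$family == pa$family || pn$family %in% ord[[pa$family]]
  }
  fam_ok && (!pn$has_inv || pa$has_inv) && (!pn$has_gamma || pa$has_gamma)
}

#' @export
print.padeq_lrt <- function(x, ...) {
  cat("Likelihood ratio test: ", x$null, " (null) vs ", x$alt,
      " (alternative)\n", sep = "")
  cat("  LR = ", format(x$statistic, digits = 6), ", df = ", x$df,
      ", p-value = ", format.pval(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Goldman-Cox adequacy test
#'
#' The likelihood-ratio statistic between the unconstrained multinomial
#' distribution over site patterns and the substitution model,
#' \eqn{\delta = 2(\ell_{\mathrm{multinomial}} - \ell_{\mathrm{model}})},
#' calibrated by a parametric bootstrap: each of B replicates is simulated
#' under the fitted null and fully re-estimated (tree search and all
#' parameters).  The p-value uses the add-one convention
#' \eqn{(1 + \#\{\delta_b \ge \delta\}) / (B + 1)}.
#'
#' @inheritParams gof_test
#' @param B Number of bootstrap replicates (>= 19).
#' @return A list of class `"padeq_gc"` with `statistic`, `p.value`, `B`,
#'   the bootstrap statistics `boot`, and the `fit`.
#' @export
gc_test <- function(aln, model, B = 99, seed = NULL, fit = NULL) {
  if (B < 19) stop("'B' must be >= 19")
  sp <- compress_patterns(aln)
  if (is.null(fit)) fit <- ml_tree_search(sp, model)
  if (!is.null(seed)) set.seed(seed)
  delta <- 2 * (multinomial_loglik(sp) - fit$loglik)
  boot <- vapply(seq_len(B), function(b) {
    sim <- simulate_alignment(fit$tree, fit$model, sp$n)
    spb <- compress_patterns(sim)
    fb <- ml_tree_search(spb, model)
    2 * (multinomial_loglik(spb) - fb$loglik)
  }, 0)
  structure(list(statistic = delta, B = B, boot = boot,
                 p.value = (1 + sum(boot >= delta)) / (B + 1),
                 fit = fit, model = fit$family),
            class = "padeq_gc")
}

#' Unconstrained multinomial log-likelihood of a pattern table
#'
#' \eqn{\sum_i n_i \log(n_i / n)} over the observed site patterns — the
#' saturated model against which the Goldman-Cox statistic is formed.
#'
#' @param sp A [compress_patterns()] table (or alignment).
#' @return Numeric scalar.
#' @export
multinomial_loglik <- function(sp) {
  if (inherits(sp, "dna_alignment")) sp <- compress_patterns(sp)
  sum(sp$counts * log(sp$counts / sp$n))
}

#' @export
print.padeq_gc <- function(x, ...) {
  cat("Goldman-Cox adequacy test (", x$model, ")\n", sep = "")
  cat("  delta = ", format(x$statistic, digits = 6), ", bootstrap B = ",
      x$B, ", p-value = ", format.pval(x$p.value, digits = 4), "\n",
      sep = "")
  invisible(x)
}
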