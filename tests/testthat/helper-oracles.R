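## Shared fixtures and independent oracles used across the test files.

## pseudogene-derived GTR parameters (frequencies T, C, A, G)
gtr_paper <- function()
  substitution_model("GTR",
                     freqs = c(0.308, 0.185, 0.308, 0.199),
                     exch = c(0.987, 0.11, 0.218, 0.243, 0.395, 1))

sym_paper <- function()
  substitution_model("SYM", exch = c(0.987, 0.11, 0.218, 0.243, 0.395, 1))

easy4 <- function() study_tree("easy4")

## Brute-force likelihood of one site pattern: explicit sum over all
## internal-node state combinations, independent of the pruning recursion.
brute_force_site_lik <- function(tree, model, pattern) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  Q <- rate_matrix(model)
  pi <- attr(Q, "pi")
  rc <- discretize_gamma(model$alpha,
                         if (is.null(model$ncat)) 4L else model$ncat,
                         model$p_inv)
  tipstate <- match(pattern[tree$tip.label], c("T", "C", "A", "G"))
  root <- ntip + 1L
  total <- 0
  for (k in seq_along(rc$rate)) {
    P <- lapply(seq_len(nrow(tree$edge)), function(e)
      transition_probabilities(Q, tree$edge.length[e], rc$rate[k]))
    lik_k <- 0
    grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
    for (g in seq_len(nrow(grid))) {
      st <- c(tipstate, grid[g, ])
      term <- pi[st[root]]
      for (e in seq_len(nrow(tree$edge)))
        term <- term * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      lik_k <- lik_k + term
    }
    total <- total + rc$weight[k] * lik_k
  }
  unname(total)
}

## Nontrivial bipartitions of an unrooted tree as a set of canonical
## strings; RF distance by symmetric difference.
brute_force_rf <- function(t1, t2) {
  splits <- function(tr) {
    tr <- ape::unroot(tr)
    ntip <- ape::Ntip(tr)
    out <- character(0)
    for (e in seq_len(nrow(tr$edge))) {
      ch <- tr$edge[e, 2]
      if (ch <= ntip) next
      below <- ape::extract.clade(tr, ch)$tip.label
      side <- sort(below)
      other <- sort(setdiff(tr$tip.label, below))
      if (length(side) < 2 || length(other) < 2) next
      canon <- if (paste(side, collapse = ",") <
                   paste(other, collapse = ","))
        paste(side, collapse = ",") else paste(other, collapse = ",")
      out <- c(out, canon)
    }
    unique(out)
  }
  s1 <- splits(t1); s2 <- splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

## Gamma-category rates by direct numeric integration of the density over
## each quantile slice of Gamma(alpha, alpha).
gamma_rates_by_integration <- function(alpha, ncat) {
  qb <- qgamma(seq(0, 1, length.out = ncat + 1), alpha, rate = alpha)
  vapply(seq_len(ncat), function(i) {
    ncat * integrate(function(x) x * dgamma(x, alpha, rate = alpha),
                     qb[i], qb[i + 1], rel.tol = 1e-10)$value
  }, 0)
}
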