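## Alignment simulation under a substitution model on a tree: the
## parametric-bootstrap engine of the adequacy test.

## integer-state simulation; returns ntip x n matrix of states 1..4 (TCAG)
.simulate_states <- function(tree, model, n) {
  tree <- stats::reorder(tree, "cladewise")  # parents before children
  edge <- tree$edge
  len <- tree$edge.length
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L

  Q <- rate_matrix(model)
  pi <- attr(Q, "pi")
  eg <- .q_eigen(Q)
  rc <- .model_rates(model)
  ncat <- length(rc$rate)

  cat_of <- if (ncat == 1) rep(1L, n)
            else sample.int(ncat, n, replace = TRUE, prob = rc$weight)
  state <- matrix(0L, nnode, n)
  state[root, ] <- sample.int(4, n, replace = TRUE, prob = pi)

  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    for (k in seq_len(ncat)) {
      idx <- if (ncat == 1) seq_len(n) else which(cat_of == k)
      if (length(idx) == 0) next
      Pm <- eg$right %*% (exp(eg$values * len[e] * rc$rate[k]) * eg$left)
      Pm[Pm < 0] <- 0
      Pm <- Pm / rowSums(Pm)
      ps <- state[par, idx]
      for (s in 1:4) {
        ii <- idx[ps == s]
        if (length(ii))
          state[ch, ii] <- sample.int(4, length(ii), replace = TRUE,
                                      prob = Pm[s, ])
      }
    }
  }
  out <- state[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate a DNA alignment under a model on a tree
#'
#' For each site a rate category is drawn from the model's site-rate
#' distribution, the root state is drawn from the stationary distribution
#' \eqn{\pi}, and states evolve along the branches with transition
#' probabilities \eqn{P(Q, t \cdot \mathrm{rate})}.  Reproducible given
#' `seed`.
#'
#' @param tree An [ape::phylo] tree with branch lengths (expected
#'   substitutions per site).
#' @param model A [substitution_model()].
#' @param n Number of sites (>= 1).
#' @param seed Optional integer seed.
#' @return A [dna_alignment()].
#' @export
simulate_alignment <- function(tree, model, n, seed = NULL) {
  if (n < 1) stop("'n' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  st <- .simulate_states(tree, model, as.integer(n))
  chars <- matrix(.NUC[st], nrow(st), ncol(st),
                  dimnames = list(rownames(st), NULL))
  dna_alignment(chars)
}

#' Simulate under a two-rate-class construction
#'
#' Generates half of the sites on the tree with all branch lengths scaled
#' by \eqn{2/(1+\rho)} and the other half scaled by \eqn{2\rho/(1+\rho)}
#' (so the mean scale is 1 and the two classes have branch-length ratio
#' \eqn{1:\rho}), then concatenates the halves.  With the SYM model this
#' is the "SYM+D" discrete two-rate generator used in the size/power
#' studies.
#'
#' @inheritParams simulate_alignment
#' @param ratio Rate ratio \eqn{\rho > 0} between the two halves.
#' @return A [dna_alignment()] with `n` sites.
#' @export
simulate_two_rate <- function(tree, model, n, ratio, seed = NULL) {
  if (ratio <= 0) stop("'ratio' must be positive")
  if (!is.null(seed)) set.seed(seed)
  n1 <- floor(n / 2); n2 <- n - n1
  s1 <- 2 / (1 + ratio); s2 <- 2 * ratio / (1 + ratio)
  t1 <- tree; t1$edge.length <- tree$edge.length * s1
  t2 <- tree; t2$edge.length <- tree$edge.length * s2
  a1 <- simulate_alignment(t1, model, n1)
  a2 <- simulate_alignment(t2, model, n2)
  dna_alignment(cbind(unclass(a1), unclass(a2)))
}
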