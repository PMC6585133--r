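## Felsenstein pruning likelihood and exact site-pattern probabilities.

## Per-pattern log-likelihoods by pruning, vectorised across patterns.
## `patmat` is an m x P character matrix (rows in tree tip-label order is
## not required; rows are matched by name).  Returns a length-P vector of
## log pattern probabilities.
.pattern_loglik <- function(tree, model, patmat) {
  if (is.null(rownames(patmat)))
    stop("pattern matrix must carry taxon names")
  if (!setequal(rownames(patmat), tree$tip.label))
    stop("taxa of data and tree disagree")
  patmat <- patmat[tree$tip.label, , drop = FALSE]
  ntip <- nrow(patmat)
  P <- ncol(patmat)
  state <- matrix(match(patmat, .NUC), ntip, P)
  if (anyNA(state)) stop("non-ACGT symbol in pattern matrix")

  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  len <- tree$edge.length
  if (is.null(len)) stop("tree lacks branch lengths")
  if (any(len < 0)) stop("negative branch length")
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L

  Q <- rate_matrix(model)
  pi <- attr(Q, "pi")
  eg <- .q_eigen(Q)
  rc <- .model_rates(model)

  ## tip partials are shared across categories
  tip_part <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    tp <- matrix(0, 4, P)
    tp[cbind(state[i, ], seq_len(P))] <- 1
    tip_part[[i]] <- tp
  }

  cat_loglik <- matrix(0, length(rc$rate), P)
  for (k in seq_along(rc$rate)) {
    partial <- vector("list", nnode)
    logsc <- numeric(P)
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1]; ch <- edge[e, 2]
      Pm <- eg$right %*% (exp(eg$values * len[e] * rc$rate[k]) * eg$left)
      Pm[Pm < 0] <- 0
      cp <- if (ch <= ntip) tip_part[[ch]] else partial[[ch]]
      contrib <- Pm %*% cp
      if (is.null(partial[[par]])) partial[[par]] <- contrib
      else partial[[par]] <- partial[[par]] * contrib
      if (ch > ntip) partial[[ch]] <- NULL
      ## per-pattern rescaling against underflow on deep trees
      pp <- partial[[par]]
      cm <- pmax(pp[1, ], pp[2, ], pp[3, ], pp[4, ])
      if (min(cm) < 1e-200) {
        cm[cm == 0] <- 1
        partial[[par]] <- pp / rep(cm, each = 4)
        logsc <- logsc + log(cm)
      }
    }
    lik <- colSums(pi * partial[[root]])
    ## guard log(0): impossible patterns only when some rate is 0 and the
    ## pattern is variable; handled by the log below yielding -Inf
    cat_loglik[k, ] <- log(lik) + logsc
  }
  ## combine rate categories: log sum_k w_k exp(cat_loglik[k, ])
  if (nrow(cat_loglik) == 1) {
    drop(cat_loglik) + log(rc$weight)
  } else {
    mx <- apply(cat_loglik, 2, max)
    mx[!is.finite(mx)] <- 0
    log(colSums(rc$weight * exp(sweep(cat_loglik, 2, mx)))) + mx
  }
}

#' Log-likelihood of an alignment under a model on a tree
#'
#' Computes the pruning (Felsenstein) log-likelihood
#' \eqn{\sum_i c_i \log p(\mathrm{pattern}_i)}, where pattern probabilities
#' integrate over the discrete site-rate categories of the model.  Under a
#' reversible model the value is invariant to root placement.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param model A [substitution_model()].
#' @param data A [dna_alignment()] or [compress_patterns()] table.
#' @return The log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(tree, model, data) {
  sp <- if (inherits(data, "site_patterns")) data else compress_patterns(data)
  ll <- .pattern_loglik(tree, model, sp$patterns)
  sum(sp$counts * ll)
}

#' Exact site-pattern probabilities on a small tree
#'
#' Enumerates all \eqn{4^m} site patterns and returns their probabilities
#' under the model (probabilities sum to 1).  Feasible for m <= 8 taxa;
#' for larger trees use simulation-based expected frequencies
#' ([expected_simulated()]).
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param model A [substitution_model()].
#' @return Named numeric vector of length \eqn{4^m}; names are the patterns
#'   (taxa in `tree$tip.label` order, alphabet A, C, G, T varying fastest
#'   in the last taxon).
#' @export
exact_pattern_probs <- function(tree, model) {
  m <- ape::Ntip(tree)
  if (m > 8)
    stop("exact enumeration of 4^m patterns is not feasible for m = ", m,
         "; use simulation-based expected frequencies instead")
  grid <- expand.grid(rep(list(.NUC_ABC), m), stringsAsFactors = FALSE)
  ## order: last taxon varies fastest
  patmat <- t(as.matrix(grid[, rev(seq_len(m)), drop = FALSE]))
  rownames(patmat) <- tree$tip.label
  p <- exp(.pattern_loglik(tree, model, patmat))
  names(p) <- apply(patmat, 2, paste, collapse = "")
  p
}
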