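## Maximum-likelihood fitting and tree search.  The numerical optimisation
## of branch lengths and model parameters is delegated to phangorn's
## pml()/optim.pml() machinery; results are converted back into the
## package's model representation (states T, C, A, G; AG exchangeability
## fixed at 1; mean substitution rate 1).

## phangorn orders states (A, C, G, T) and rate parameters
## (AC, AG, AT, CG, CT, GT) with GT fixed at 1.
.to_phangorn_Q <- function(exch) {
  ## exch pairs: TC, TA, TG, CA, CG, AG
  q <- c(exch[4], exch[6], exch[2], exch[5], exch[1], exch[3])
  unname(q / q[6])
}

.from_phangorn <- function(family, bf, Q, inv, shape, k, has_inv, has_gamma) {
  exch <- c(Q[5], Q[3], Q[6], Q[1], Q[4], Q[2])  # TC TA TG CA CG AG
  substitution_model(family,
                     freqs = bf[c(4, 2, 1, 3)],  # ACGT -> TCAG
                     exch = exch / exch[6],
                     p_inv = if (has_inv) inv else NULL,
                     alpha = if (has_gamma) shape else NULL,
                     ncat = k)
}

.as_phyDat <- function(data) {
  x <- if (inherits(data, "site_patterns")) .expand_patterns(data) else data
  phangorn::phyDat(unclass(x), type = "DNA")
}

.phangorn_model_name <- function(family)
  switch(family, JC69 = "JC", family)

#' Fit model parameters and branch lengths on a fixed topology
#'
#' Jointly maximises the likelihood over branch lengths and the free
#' parameters of the model family (exchangeabilities, base frequencies,
#' `+I`/`+G` parameters as applicable).  Base frequencies of F81/HKY/GTR
#' are estimated by maximum likelihood, not by empirical counts.
#'
#' @param topology An [ape::phylo] tree giving the (fixed) topology;
#'   branch lengths, if present, are used as starting values.
#' @param model Model specification string (e.g. `"GTR+G"`) or a
#'   `subst_model` giving the family and modifiers.
#' @param data A [dna_alignment()] or [compress_patterns()] table.
#' @return An object of class `"ml_fit"`: list with `tree` (with ML branch
#'   lengths), `model` (fitted `subst_model`), `loglik`, `converged`,
#'   `n_free_params` (model parameters plus branch lengths), `family`.
#' @export
fit_parameters <- function(topology, model, data) {
  sp <- if (inherits(data, "site_patterns")) data else compress_patterns(data)
  if (length(sp$counts) < 2)
    stop("need at least 2 distinct site patterns to fit")
  if (!setequal(topology$tip.label, sp$taxa))
    stop("taxa of data and tree disagree")
  spec <- parse_model_spec(model)
  dat <- .as_phyDat(sp)
  .optim_fit(topology, spec, dat, optNni = FALSE)
}

## shared driver for fixed-topology and NNI-search fits
.optim_fit <- function(topology, spec, dat, optNni = FALSE) {
  tr <- topology
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
  tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
  fam <- spec$family
  equal_bf <- fam %in% c("JC69", "SYM")
  k <- if (spec$has_gamma) {
    if (is.null(spec$ncat)) 4L else spec$ncat
  } else 1L
  fit0 <- phangorn::pml(tr, dat,
                        bf = if (equal_bf) rep(0.25, 4) else NULL,
                        Q = rep(1, 6),
                        inv = if (spec$has_inv) 0.1 else 0,
                        k = k, shape = 1)
  res <- tryCatch(
    phangorn::optim.pml(fit0,
                        model = .phangorn_model_name(fam),
                        optBf = fam %in% c("F81", "HKY", "GTR"),
                        optQ = fam %in% c("HKY", "SYM", "GTR"),
                        optInv = spec$has_inv,
                        optGamma = spec$has_gamma,
                        optEdge = TRUE,
                        optNni = optNni,
                        rearrangement = if (optNni) "NNI" else "none",
                        control = phangorn::pml.control(trace = 0)),
    error = function(e) e)
  if (inherits(res, "error")) {
    warning("ML optimisation failed: ", conditionMessage(res))
    return(.as_ml_fit(fit0, spec, converged = FALSE,
                      diagnostics = conditionMessage(res)))
  }
  .as_ml_fit(res, spec, converged = TRUE)
}

.as_ml_fit <- function(pml_fit, spec, converged, diagnostics = NULL) {
  model <- .from_phangorn(spec$family, pml_fit$bf, pml_fit$Q,
                          pml_fit$inv, pml_fit$shape, pml_fit$k,
                          spec$has_inv, spec$has_gamma)
  tree <- pml_fit$tree
  nfree <- n_model_params(.spec_string(spec)) + nrow(tree$edge)
  structure(list(tree = tree, model = model,
                 loglik = as.numeric(stats::logLik(pml_fit)),
                 converged = converged,
                 n_free_params = nfree,
                 family = .spec_string(spec),
                 diagnostics = diagnostics),
            class = "ml_fit")
}

.spec_string <- function(spec) {
  paste0(spec$family,
         if (spec$has_inv) "+I" else "",
         if (spec$has_gamma) paste0("+G", if (is.null(spec$ncat)) ""
                                    else spec$ncat) else "")
}

#' Maximum-likelihood tree and model estimation
#'
#' Finds the ML tree topology together with the MLEs of all branch lengths
#' and model parameters under the null model.  For m <= 6 taxa every
#' unrooted topology is fitted exhaustively (ties broken towards the
#' lowest-index topology); for larger trees a BioNJ starting tree built
#' from ML distances is improved by nearest-neighbour-interchange hill
#' climbing.
#'
#' @inheritParams fit_parameters
#' @param data A [dna_alignment()] or [compress_patterns()] table with
#'   at least 4 taxa.
#' @return An `"ml_fit"` object (see [fit_parameters()]).
#' @export
ml_tree_search <- function(data, model) {
  sp <- if (inherits(data, "site_patterns")) data else compress_patterns(data)
  if (sp$m < 4) stop("tree search needs at least 4 taxa")
  spec <- parse_model_spec(model)
  dat <- .as_phyDat(sp)
  if (sp$m <= 6) {
    trees <- phangorn::allTrees(sp$m, tip.label = sp$taxa)
    best <- NULL
    for (i in seq_along(trees)) {
      tr <- trees[[i]]  # [[ restores tip labels on a compressed multiPhylo
      if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
      tr$edge.length <- rep(0.1, nrow(tr$edge))
      fit <- .optim_fit(tr, spec, dat, optNni = FALSE)
      if (is.null(best) || fit$loglik > best$loglik + 1e-8) best <- fit
    }
    best
  } else {
    d <- phangorn::dist.ml(dat)
    start <- ape::unroot(ape::bionj(d))
    start$edge.length[start$edge.length < 1e-8] <- 1e-8
    .optim_fit(start, spec, dat, optNni = TRUE)
  }
}

#' Robinson-Foulds distance between two trees
#'
#' Number of nontrivial bipartitions present in exactly one of the two
#' unrooted trees (symmetric difference); 0 iff the topologies agree.
#'
#' @param t1,t2 [ape::phylo] trees on the same leaf set.
#' @return Even nonnegative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("Maximum-likelihood fit (", x$family, ")\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 8), "\n")
  cat("  free parameters:", x$n_free_params,
      "(incl.", nrow(x$tree$edge), "branch lengths )\n")
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  print(x$model)
  cat("  tree:", write_newick(x$tree), "\n")
  invisible(x)
}

#' @export
logLik.ml_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free_params, class = "logLik")
}

#' @export
coef.ml_fit <- function(object, ...) {
  m <- object$model
  c(setNames(m$freqs, paste0("pi_", names(m$freqs))),
    setNames(m$exch, paste0("r_", names(m$exch))),
    if (!is.null(m$p_inv)) c(p_inv = m$p_inv),
    if (!is.null(m$alpha)) c(alpha = m$alpha))
}
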