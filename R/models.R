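## DNA substitution models: JC69, F81, HKY, SYM, GTR with optional +I
## (proportion of invariant sites) and +G (discrete-gamma rate variation).

.FAMILIES <- c("JC69", "F81", "HKY", "SYM", "GTR")

#' Construct a DNA substitution model
#'
#' Builds a time-reversible DNA substitution model of one of the families
#' JC69, F81, HKY, SYM or GTR, optionally with a proportion of invariant
#' sites (`+I`) and discrete-gamma rate variation among sites (`+G`).
#'
#' The model is parameterised by base frequencies
#' \eqn{\pi = (\pi_T, \pi_C, \pi_A, \pi_G)} and six exchangeabilities
#' \eqn{r_1, \ldots, r_6} for the unordered pairs (TC, TA, TG, CA, CG, AG),
#' with \eqn{r_6} (the A--G rate) fixed at 1.  Family constraints are
#' enforced: JC69 and SYM force equal base frequencies; JC69 and F81 force
#' equal exchangeabilities; HKY allows one transition and one transversion
#' rate.
#'
#' @param family Character; one of `"JC69"`, `"F81"`, `"HKY"`, `"SYM"`,
#'   `"GTR"`.
#' @param freqs Base frequencies in the order (T, C, A, G); must be positive
#'   and sum to 1.  Ignored (forced to 1/4) for JC69 and SYM.
#' @param exch Six positive exchangeabilities for the pairs
#'   (TC, TA, TG, CA, CG, AG).  Rescaled so the last (AG) equals 1.
#'   Ignored for JC69/F81 (all equal).  For HKY, supply `kappa` instead.
#' @param kappa Transition/transversion rate ratio (HKY only).
#' @param p_inv Proportion of invariant sites in `[0, 1)`, or `NULL`.
#' @param alpha Shape of the gamma distribution of site rates, or `NULL`.
#' @param ncat Number of discrete gamma categories (default 4).
#'
#' @return An object of class `"subst_model"`.
#' @examples
#' substitution_model("GTR",
#'   freqs = c(0.308, 0.185, 0.308, 0.199),
#'   exch  = c(0.987, 0.11, 0.218, 0.243, 0.395, 1))
#' substitution_model("JC69+G", alpha = 0.5)
#' @export
substitution_model <- function(family, freqs = NULL, exch = NULL,
                               kappa = NULL, p_inv = NULL, alpha = NULL,
                               ncat = 4L) {
  spec <- parse_model_spec(family)
  fam <- spec$family
  if (spec$has_inv && is.null(p_inv)) p_inv <- 0.1
  if (spec$has_gamma) {
    if (is.null(alpha)) alpha <- 1
    if (!is.null(spec$ncat)) ncat <- spec$ncat
  }

  if (fam %in% c("JC69", "SYM")) {
    freqs <- rep(0.25, 4)
  } else if (is.null(freqs)) {
    freqs <- rep(0.25, 4)
  }
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4 || any(freqs <= 0))
    stop("'freqs' must be 4 positive numbers (order T, C, A, G)")
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("'freqs' must sum to 1")
  freqs <- freqs / sum(freqs)

  if (fam %in% c("JC69", "F81")) {
    exch <- rep(1, 6)
  } else if (fam == "HKY") {
    if (is.null(kappa)) {
      if (!is.null(exch)) {
        ## accept a 6-vector with HKY structure
        exch <- as.numeric(exch)
        kappa <- exch[1] / exch[2]
      } else kappa <- 2
    }
    if (kappa <= 0) stop("'kappa' must be positive")
    ## transitions: TC and AG; transversions: the rest
    exch <- c(kappa, 1, 1, 1, 1, kappa)
  } else {
    if (is.null(exch)) exch <- rep(1, 6)
    exch <- as.numeric(exch)
    if (length(exch) != 6 || any(exch <= 0))
      stop("'exch' must be 6 positive numbers (pairs TC, TA, TG, CA, CG, AG)")
  }
  exch <- exch / exch[6]

  if (!is.null(p_inv)) {
    if (p_inv < 0 || p_inv >= 1) stop("'p_inv' must be in [0, 1)")
    if (p_inv == 0) p_inv <- NULL
  }
  if (!is.null(alpha) && alpha <= 0) stop("'alpha' must be positive")

  structure(list(family = fam,
                 freqs = setNames(freqs, .NUC),
                 exch = setNames(exch, paste0(.PAIRS[, 1], .PAIRS[, 2])),
                 kappa = if (fam == "HKY") kappa else NULL,
                 p_inv = p_inv,
                 alpha = alpha,
                 ncat = if (!is.null(alpha)) as.integer(ncat) else NULL),
            class = "subst_model")
}

#' Parse a model specification string
#'
#' Understands strings such as `"GTR"`, `"HKY+G"`, `"JC+I+G4"`: a family
#' name (`JC`/`JC69`, `F81`, `HKY`, `SYM`, `GTR`) with optional `+I` and
#' `+G[ncat]` modifiers.
#'
#' @param spec Model string.
#' @return A list with elements `family`, `has_inv`, `has_gamma`, `ncat`.
#' @export
parse_model_spec <- function(spec) {
  if (inherits(spec, "subst_model"))
    return(list(family = spec$family, has_inv = !is.null(spec$p_inv),
                has_gamma = !is.null(spec$alpha), ncat = spec$ncat))
  parts <- strsplit(toupper(spec), "+", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  fam <- parts[1]
  if (fam == "JC") fam <- "JC69"
  if (!fam %in% .FAMILIES)
    stop("unknown model family: ", parts[1])
  has_inv <- FALSE; has_gamma <- FALSE; ncat <- NULL
  for (p in parts[-1]) {
    if (p == "I") has_inv <- TRUE
    else if (grepl("^G[0-9]*$", p)) {
      has_gamma <- TRUE
      if (nchar(p) > 1) ncat <- as.integer(substring(p, 2))
    } else if (p == "D") {
      stop("'+D' two-rate generation is a simulation construction; ",
           "use simulate_two_rate()")
    } else stop("unknown model modifier: +", p)
  }
  list(family = fam, has_inv = has_inv, has_gamma = has_gamma, ncat = ncat)
}

#' Instantaneous rate matrix of a substitution model
#'
#' Returns the 4x4 rate matrix Q with entries
#' \eqn{Q_{ij} = r_{(i,j)} \pi_j} for \eqn{i \ne j} (states ordered
#' T, C, A, G), diagonal set so rows sum to zero, rescaled so the mean
#' substitution rate \eqn{\sum_i \pi_i (-Q_{ii})} equals 1.  Branch lengths
#' are then expected substitutions per site.
#'
#' @param model A `subst_model`.
#' @return 4x4 matrix with a `"pi"` attribute holding the stationary
#'   distribution.
#' @export
rate_matrix <- function(model) {
  stopifnot(inherits(model, "subst_model"))
  pi <- model$freqs
  r <- model$exch
  Q <- matrix(0, 4, 4, dimnames = list(.NUC, .NUC))
  for (k in seq_len(6)) {
    i <- .PAIRS[k, 1]; j <- .PAIRS[k, 2]
    Q[i, j] <- r[k] * pi[j]
    Q[j, i] <- r[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix")
  Q <- Q / mu
  attr(Q, "pi") <- pi
  Q
}

## Spectral decomposition of a reversible Q via the symmetrised matrix
## B = D^{1/2} Q D^{-1/2} with D = diag(pi); exact and stable.
.q_eigen <- function(Q) {
  pi <- attr(Q, "pi")
  if (is.null(pi)) stop("rate matrix lacks stationary distribution")
  s <- sqrt(pi)
  B <- (Q * rep(s, times = 4)) * rep(1 / s, each = 4)  # diag(s) Q diag(1/s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       right = e$vectors / s,          # diag(1/s) V
       left = t(e$vectors * s))        # t(V) diag(s)
}

#' Transition probability matrix P(t)
#'
#' Computes \eqn{P(t) = \exp(Q t \cdot \mathrm{rate})} by spectral
#' decomposition of the reversible rate matrix.
#'
#' @param Q Rate matrix from [rate_matrix()].
#' @param t Branch length (expected substitutions per site); must be >= 0.
#' @param rate Site-rate multiplier (default 1); must be >= 0.
#' @return 4x4 row-stochastic matrix.
#' @export
transition_probabilities <- function(Q, t, rate = 1) {
  if (t < 0) stop("branch length must be nonnegative")
  if (rate < 0) stop("rate multiplier must be nonnegative")
  eg <- .q_eigen(Q)
  P <- eg$right %*% (exp(eg$values * t * rate) * eg$left)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete site-rate distribution
#'
#' Discretises a Gamma(`alpha`, `alpha`) distribution (mean 1) into `ncat`
#' equal-weight categories whose rates are the conditional means of the
#' quantile slices.  If `p_inv` is given, a rate-0 category with weight
#' `p_inv` is prepended, the gamma weights are scaled by `1 - p_inv`, and
#' the positive rates are rescaled so the weighted mean rate remains 1.
#'
#' @param alpha Gamma shape (> 0), or `NULL` for no rate variation.
#' @param ncat Number of gamma categories (>= 1).
#' @param p_inv Proportion of invariant sites, or `NULL`.
#' @return A list with numeric vectors `rate` and `weight` (weights sum
#'   to 1; weighted mean rate 1).
#' @export
discretize_gamma <- function(alpha, ncat = 4L, p_inv = NULL) {
  if (is.null(alpha)) {
    rate <- 1; weight <- 1
  } else {
    if (alpha <= 0) stop("'alpha' must be positive")
    if (ncat < 1) stop("'ncat' must be >= 1")
    k <- as.integer(ncat)
    ## mean of Gamma(a, a) on quantile slice (q_{i-1}, q_i] is
    ## k * (F_{a+1}(q_i) - F_{a+1}(q_{i-1})) where F_{a+1} is the cdf of
    ## Gamma(a + 1, a)
    qb <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
    Fb <- pgamma(qb, shape = alpha + 1, rate = alpha)
    rate <- k * diff(Fb)
    weight <- rep(1 / k, k)
    rate <- rate / sum(rate * weight)   # guard tiny numeric drift
  }
  if (!is.null(p_inv) && p_inv > 0) {
    if (p_inv >= 1) stop("'p_inv' must be < 1")
    rate <- c(0, rate / (1 - p_inv))
    weight <- c(p_inv, weight * (1 - p_inv))
  }
  list(rate = rate, weight = weight)
}

## rate categories of a model, as used by likelihood and simulation
.model_rates <- function(model) {
  discretize_gamma(model$alpha, if (is.null(model$ncat)) 4L else model$ncat,
                   model$p_inv)
}

#' Number of free parameters of a model family
#'
#' Counts the free substitution-model parameters (not branch lengths):
#' JC69 0, F81 3, HKY 4, SYM 5, GTR 8, plus 1 for `+I` and 1 for `+G`.
#'
#' @param model A `subst_model` or specification string.
#' @return Integer count.
#' @export
n_model_params <- function(model) {
  spec <- parse_model_spec(model)
  base <- switch(spec$family, JC69 = 0L, F81 = 3L, HKY = 4L,
                 SYM = 5L, GTR = 8L)
  base + as.integer(spec$has_inv) + as.integer(spec$has_gamma)
}

#' @export
print.subst_model <- function(x, ...) {
  mods <- paste0(c(if (!is.null(x$p_inv)) "+I",
                   if (!is.null(x$alpha)) paste0("+G", x$ncat)),
                 collapse = "")
  cat("DNA substitution model: ", x$family, mods, "\n", sep = "")
  cat("  base frequencies (T C A G): ",
      paste(formatC(x$freqs, digits = 4, format = "f"), collapse = " "),
      "\n", sep = "")
  if (!x$family %in% c("JC69", "F81"))
    cat("  exchangeabilities (TC TA TG CA CG AG): ",
        paste(formatC(x$exch, digits = 4, format = "f"), collapse = " "),
        "\n", sep = "")
  if (!is.null(x$p_inv))
    cat("  proportion invariant:", formatC(x$p_inv, digits = 4), "\n")
  if (!is.null(x$alpha))
    cat("  gamma shape:", formatC(x$alpha, digits = 4),
        "(", x$ncat, "categories )\n")
  invisible(x)
}
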