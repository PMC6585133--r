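test_that("rate matrices satisfy reversibility and normalisation", {
  models <- list(substitution_model("JC69"),
                 substitution_model("F81",
                                    freqs = c(0.1, 0.2, 0.3, 0.4)),
                 substitution_model("HKY",
                                    freqs = c(0.3, 0.2, 0.3, 0.2),
                                    kappa = 3),
                 sym_paper(), gtr_paper())
  for (m in models) {
    Q <- rate_matrix(m)
    pi <- attr(Q, "pi")
    expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
    ## detailed balance pi_i Q_ij = pi_j Q_ji
    F <- sweep(Q, 1, pi, "*")
    expect_lt(max(abs(F - t(F))), 1e-12)
    offdiag <- Q[row(Q) != col(Q)]
    expect_true(all(offdiag >= 0))
  }
})

test_that("JC69 rate matrix has the forced closed form", {
  Q <- rate_matrix(substitution_model("JC69"))
  expect_equal(unname(Q[row(Q) != col(Q)]), rep(1 / 3, 12))
  expect_equal(unname(diag(Q)), rep(-1, 4))
})

test_that("printed GTR parameters give a reversible matrix and SYM is
           stationary at 1/4", {
  Q <- rate_matrix(gtr_paper())
  pi <- attr(Q, "pi")
  F <- sweep(Q, 1, pi, "*")
  expect_lt(max(abs(F - t(F))), 1e-12)
  ## stationary distribution = left null vector of Q
  Qs <- rate_matrix(sym_paper())
  ns <- eigen(t(unclass(Qs)))
  v <- Re(ns$vectors[, which.min(abs(ns$values))])
  expect_equal(v / sum(v), unname(rep(0.25, 4)), tolerance = 1e-10)
})

test_that("model nesting: JC69 parameters reproduce the other families", {
  Qjc <- rate_matrix(substitution_model("JC69"))
  for (fam in c("F81", "HKY", "SYM", "GTR")) {
    m <- substitution_model(fam, freqs = rep(0.25, 4),
                            exch = rep(1, 6), kappa = 1)
    expect_equal(unclass(rate_matrix(m)), unclass(Qjc), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("transition probabilities are stochastic and satisfy
           Chapman-Kolmogorov", {
  Q <- rate_matrix(gtr_paper())
  expect_equal(transition_probabilities(Q, 0), diag(4),
               ignore_attr = TRUE)
  set.seed(42)
  for (r in 1:5) {
    s <- runif(1, 0, 2); t <- runif(1, 0, 2)
    Ps <- transition_probabilities(Q, s)
    Pt <- transition_probabilities(Q, t)
    Pst <- transition_probabilities(Q, s + t)
    expect_equal(unname(rowSums(Ps)), rep(1, 4), tolerance = 1e-12)
    expect_lt(max(abs(Ps %*% Pt - Pst)), 1e-10)
  }
  ## ergodic limit: rows approach pi
  Pinf <- transition_probabilities(Q, 500)
  pi <- attr(Q, "pi")
  expect_lt(max(abs(sweep(Pinf, 2, pi))), 1e-10)
  expect_error(transition_probabilities(Q, -1), "nonnegative")
})

test_that("JC transition probability matches its closed form", {
  Q <- rate_matrix(substitution_model("JC69"))
  for (t in c(0.01, 0.1, 0.5, 2)) {
    P <- transition_probabilities(Q, t)
    same <- 0.25 + 0.75 * exp(-4 * t / 3)
    diff <- 0.25 - 0.25 * exp(-4 * t / 3)
    expect_equal(unname(diag(P)), rep(same, 4), tolerance = 1e-12)
    expect_equal(unname(P[row(P) != col(P)]), rep(diff, 12),
                 tolerance = 1e-12)
  }
})

test_that("gamma discretisation matches numeric integration and its
           limits", {
  d <- discretize_gamma(0.5, 4)
  expect_equal(d$rate, gamma_rates_by_integration(0.5, 4),
               tolerance = 1e-8)
  expect_equal(sum(d$rate * d$weight), 1, tolerance = 1e-12)
  ## no-variation limit
  d2 <- discretize_gamma(1e6, 4)
  expect_equal(d2$rate, rep(1, 4), tolerance = 1e-2)
  ## single category
  d3 <- discretize_gamma(1.3, 1)
  expect_equal(d3$rate, 1, tolerance = 1e-12)
  ## invariant category bookkeeping
  d4 <- discretize_gamma(0.7, 4, p_inv = 0.2)
  expect_equal(d4$weight[1], 0.2)
  expect_equal(d4$rate[1], 0)
  expect_equal(sum(d4$rate * d4$weight), 1, tolerance = 1e-10)
  expect_error(discretize_gamma(-1, 4), "positive")
})

test_that("model strings parse with modifiers and count parameters", {
  s <- parse_model_spec("JC+I+G4")
  expect_equal(s$family, "JC69")
  expect_true(s$has_inv && s$has_gamma)
  expect_equal(s$ncat, 4L)
  expect_equal(n_model_params("JC69"), 0L)
  expect_equal(n_model_params("GTR"), 8L)
  expect_equal(n_model_params("SYM"), 5L)
  expect_equal(n_model_params("GTR+I+G"), 10L)
  expect_error(parse_model_spec("XYZ"), "unknown")
})
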