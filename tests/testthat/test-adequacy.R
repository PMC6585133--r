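test_that("expected frequencies: exact aggregation and conservation", {
  sch <- equal_frequency_bins()
  ## uniform law over the 256 patterns: the E bin holds 24 patterns
  pp <- setNames(rep(1 / 256, 256),
                 names(exact_pattern_probs(easy4(),
                                           substitution_model("JC69"))))
  E <- expected_exact(sch, pp, 256, taxa = easy4()$tip.label)
  expect_equal(sum(E), 256)
  expect_equal(E[sch$table$type == "E"], 24)
  ## JC on the symmetric easy tree gives equal E across the 4 type-A bins
  ppj <- exact_pattern_probs(easy4(), substitution_model("JC69"))
  Ej <- expected_exact(sch, ppj, 500, taxa = easy4()$tip.label)
  expect_lt(diff(range(Ej[sch$table$type == "A"])), 1e-9)
  expect_equal(sum(Ej), 500, tolerance = 1e-9)
})

test_that("simulated expectations converge to the exact ones and are
           seed-reproducible", {
  tr <- easy4()
  model <- sym_paper()
  sch <- equal_frequency_bins()
  n <- 500
  Eex <- expected_exact(sch, exact_pattern_probs(tr, model), n,
                        taxa = tr$tip.label)
  M <- 2e5
  E1 <- expected_simulated(sch, tr, model, n, M, seed = 41)
  E2 <- expected_simulated(sch, tr, model, n, M, seed = 41)
  expect_equal(as.numeric(E1), as.numeric(E2))
  expect_equal(sum(E1), n, tolerance = 1e-9)
  ## within 4 binomial standard errors of the exact value, per bin
  p <- Eex / n
  se <- n * sqrt(p * (1 - p) / M)
  expect_true(all(abs(E1 - Eex) <= 4 * se + 1e-9))
})

test_that("the Pearson statistic and the rule of thumb behave as
           specified", {
  expect_equal(pearson_statistic(c(10, 10, 20), c(8, 12, 20)),
               4 / 8 + 4 / 12, tolerance = 1e-12)
  expect_equal(pearson_statistic(c(5, 5), c(5, 5)), 0)
  expect_error(pearson_statistic(c(1, 2), c(1, 0)), "zero")
  expect_true(rule_of_thumb(rep(5, 5)))
  expect_false(rule_of_thumb(c(4.9, 6, 6, 6)))       # 25% below 5
  expect_true(rule_of_thumb(c(1, 1, rep(10, 8))))    # exactly 20%
})

test_that("M selection applies the formula with its floor guard", {
  expect_equal(choose_M(1000, 10), 1e5)               # guard binds
  expect_equal(choose_M(1e6, 50), ceiling(22 * 50 * 1e6 / 49))
  expect_gte(choose_M(3000, 35), 1e5)
  expect_error(choose_M(100, 1), ">= 2")
})

test_that("the simulation-error bound is the stated formula", {
  expect_equal(mse_bound(35, 500, 1e5), 16 * 35 * 500 / (25 * 1e5))
  expect_equal(mse_bound(35, 500, 1e5), 0.112)
  expect_equal(mse_bound(10, 100, 2e5), mse_bound(10, 100, 1e5) / 2)
})

test_that("gof_test on 4 taxa uses 35 equal-frequency bins with df 34
           and sane bookkeeping", {
  tr <- easy4()
  aln <- simulate_alignment(tr, sym_paper(), 500, seed = 43)
  g <- suppressWarnings(gof_test(aln, "SYM"))
  expect_s3_class(g, "gof_test")
  expect_equal(g$K, 35L)
  expect_equal(g$df, 34)
  expect_equal(sum(g$O), 500)
  expect_equal(sum(g$E), 500, tolerance = 1e-9)
  expect_equal(g$M, 0L)  # exact expectations
  expect_gte(g$X2, 0)
  expect_true(g$p.value >= 0 && g$p.value <= 1)
  expect_equal(g$p.value, pchisq(g$X2, 34, lower.tail = FALSE))
})

test_that("a constructed O = E case gives statistic 0 and p = 1", {
  E <- c(10, 20, 30)
  expect_equal(pearson_statistic(E, E), 0)
  expect_equal(pchisq(0, 2, lower.tail = FALSE), 1)
})

test_that("K-means path: K selection honours the rule of thumb and the
          p-value trace is returned", {
  tr <- study_tree("hard10")
  aln <- simulate_alignment(tr, gtr_paper(), 400, seed = 44)
  fit <- ml_tree_search(compress_patterns(aln), "GTR")
  sel <- select_K(aln, "GTR", K_range = c(3, 5, 8, 12, 40), M = 5e4,
                  seed = 44, fit = fit)
  expect_true(all(c("K", "X2", "p", "rule_ok") %in% names(sel$trace)))
  expect_true(sel$K %in% sel$trace$K)
  ## chosen K is the largest passing one
  passing <- sel$trace$K[sel$trace$rule_ok & !is.na(sel$trace$X2)]
  expect_equal(sel$K, max(passing))
  ## n = 40 cannot support K = 20 (mean E = 2): a smaller K is chosen
  small <- dna_alignment(unclass(aln)[, 1:40])
  sel2 <- suppressWarnings(select_K(small, "GTR",
                                    K_range = c(2, 4, 20), M = 2e4,
                                    seed = 44, fit = fit))
  expect_lt(sel2$K, 20)
  g <- suppressWarnings(gof_test(aln, "GTR", binning = "kmeans",
                                 K = 10, M = 5e4, seed = 44, fit = fit))
  expect_equal(g$K, 10L)
  expect_equal(g$df, 9)
  expect_equal(sum(g$O), 400)
  expect_equal(sum(g$E), 400, tolerance = 1e-9)
})

test_that("multinomial log-likelihood and the Goldman-Cox statistic", {
  sp <- structure(list(counts = c(2L, 2L), n = 4L), class = "site_patterns")
  expect_equal(multinomial_loglik(sp), 4 * log(0.5), tolerance = 1e-12)
  tr <- easy4()
  aln <- simulate_alignment(tr, substitution_model("JC69"), 300, seed = 45)
  gc <- gc_test(aln, "JC69", B = 19, seed = 45)
  expect_gte(gc$statistic, 0)
  expect_true(all(gc$boot >= 0))
  expect_gte(gc$p.value, 1 / 20)
  expect_lte(gc$p.value, 1)
})
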