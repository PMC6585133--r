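---
title: "Testing the adequacy of DNA substitution models by binned goodness-of-fit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the adequacy of DNA substitution models by binned goodness-of-fit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phylogenetic inference conditions on a DNA substitution model. Model
*selection* (hLRT, AIC, BIC) ranks candidate models relative to one
another, but never asks whether the chosen model could plausibly have
generated the data at all. When even the best candidate is badly
mis-specified — for instance in the Felsenstein zone, where long branches
separated by a short internal branch make maximum likelihood inconsistent
under an oversimplified model — the selected model can produce a wrong
topology with strong bootstrap support. An *adequacy* (absolute
goodness-of-fit) test complements selection by testing

$$H_0: \text{the substitution model } \mathcal{M} \text{ is the true
model},$$

with the tree topology, branch lengths and model parameters treated as
nuisance parameters.

`padeq` implements such a test. The data enter only through their *site
patterns* — the columns of the alignment. For $m$ taxa there are $4^m$
possible patterns, far too many for a classical multinomial test: most
patterns are unobserved and the classical rule of thumb for Pearson's
$X^2$ (no more than 20% of cells with expected count below 5) fails
badly. The remedy is to *bin* site patterns and compare observed with
expected bin counts:

$$X^2 = \sum_{j=1}^{K} \frac{(O_j - E_j)^2}{E_j},$$

referred to a $\chi^2$ distribution with $K - 1$ degrees of freedom.

## Binning

The binning is designed so that, under a mis-specified model, the
patterns in a bin tend to have their probabilities biased in a *common*
direction, so the per-bin discrepancies accumulate instead of cancelling.
The summary used is the per-site nucleotide frequency vector
$f_i = (f_{Ai}, f_{Ci}, f_{Gi}, f_{Ti})$, which is highly informative
about frequency mis-specification and, indirectly, about mis-estimated
exchange rates.

* **Equal-frequency binning (4 taxa).** Two patterns share a bin iff
  they have the same nucleotide count vector. The 256 patterns fall into
  35 bins of five types: A (`XXXX`, 4 bins of 1 pattern), B (`XXYY` and
  permutations, 6 bins of 6), C (`XXXY`, 12 bins of 4), D (`XXYZ`, 12
  bins of 12) and E (`XYZW`, 1 bin of 24). Note that nucleotide identity
  is retained: $\{A{:}2, C{:}2\}$ and $\{A{:}2, G{:}2\}$ are different
  bins. Expected frequencies are computed *exactly* by enumerating all
  256 pattern probabilities under the fitted null
  (`exact_pattern_probs()`), and the test uses all 35 bins with df = 34
  even when the rule of thumb is marginal (the `rule_ok` flag is still
  reported).

* **K-means binning (general).** The $n \times 4$ frequency matrix $F$
  is clustered into $K$ bins by K-means under Euclidean distance.
  Expected frequencies come from a parametric bootstrap: $M$ sites are
  simulated under the fitted null, each simulated site is assigned to
  the nearest center, and $E_j = n S_j / M$.

* **Random binning (baseline).** Each taxon gets a random score in
  $0..K-1$ per nucleotide; a site's bin is the score sum modulo $K$.
  This partitions patterns with no regard to their probabilities and
  serves as the control that shows the frequency-based binning is doing
  real work (`k_sweep(..., compare_random = TRUE)`).

## How many sites to simulate, and how many bins

Estimating $E_j$ by simulation perturbs the statistic. When the rule of
thumb holds, the mean squared error of $X^2$ due to simulating $M$ sites
is at most $16Kn/(25M)$ (`mse_bound()`). Requiring a root-MSE of about
0.005 in p-values near the 0.05 critical value gives
$M = 22Kn/(K-1)$, floor-guarded at 100{,}000 (`choose_M()`); for
alignments up to a few thousand sites the guard binds.

For $K$, larger is better — binning exists only to satisfy the rule of
thumb — so `select_K()` scans a range and keeps the *largest* $K$ whose
expected frequencies satisfy the rule, reporting the whole p-value trace;
conclusions should be stable over neighbouring $K$, and the trace makes
that visible.

## Degrees of freedom

The statistic is compared with $\chi^2_{K-1}$, deliberately ignoring
that the model parameters and tree were estimated. The exact asymptotic
law lies between $\chi^2_{K-d-1}$ and $\chi^2_{K-1}$ (Chernoff–Lehmann);
quadratic-form corrections (Rao–Robson) exist but are not implemented
here. Using $K-1$ is *conservative*: in our null calibrations on the
easy 4-taxon tree the estimation of the SYM parameters absorbs roughly 6
of the 34 degrees of freedom, and the empirical size at $\alpha = 0.05$
runs near 2–3% rather than 5%. The power against frequency
mis-specification remains essentially 100% in the study conditions, so
the trade is acceptable; users should remember that a borderline
non-rejection is weaker evidence of adequacy than the nominal level
suggests.

## Maximum-likelihood fitting

The null model is fitted by maximum likelihood over branch lengths,
exchangeabilities, base frequencies and the optional `+I`/`+G`
parameters (`fit_parameters()`), with the numerical optimisation
delegated to `phangorn::optim.pml()`; base frequencies of F81/HKY/GTR
are MLEs, not empirical counts. `ml_tree_search()` fits every unrooted
topology exhaustively for $m \le 6$ (3 topologies for $m = 4$; ties go
to the lowest-index topology) and otherwise climbs by
nearest-neighbour interchanges from a BioNJ starting tree on ML
distances. No jittered restarts are used: at the study scales the
coordinate optimisation proved reliable, and restarts would triple the
cost of every study. Branch lengths are bounded below at $10^{-8}$.

The package carries its own pruning likelihood (`log_likelihood()`,
states ordered T, C, A, G; rate matrix $Q_{ij} = r_{(i,j)}\pi_j$
normalised to mean rate 1 so branch lengths are expected substitutions
per site; $P(t)$ by spectral decomposition of the symmetrised $Q$).
It agrees with `phangorn`'s to $10^{-6}$ on fitted models and with a
brute-force sum over internal states to $10^{-10}$ in the tests, and it
drives `exact_pattern_probs()` and the Goldman–Cox statistic. Discrete
gamma rates use category means with 4 categories by default; with a
proportion $p_{inv}$ of invariant sites the positive rates are rescaled
so the weighted mean rate stays 1.

## The simulator

`simulate_alignment()` is the parametric-bootstrap engine: per site a
rate category is drawn, a root state is drawn from $\pi$, and states
evolve along branches with $P(Q, t \cdot \text{rate})$; generation is
vectorised and streamed in blocks of $10^5$ sites inside
`expected_simulated()`, so $M = 10^6$ never holds a full alignment in
memory. `simulate_two_rate()` implements the two-rate "+D" construction
used in the studies: half of the sites at branch scale $2/(1+\rho)$ and
half at $2\rho/(1+\rho)$, i.e. a 1:$\rho$ ratio with mean scale 1. The
studies fix only the 1:10 ratio; the mean-1 normalisation is
our choice, and the studies' size/power conclusions are insensitive to
the absolute scale at the tolerances used.

What the simulator deliberately does *not* emulate: indels (alignments
are gap-free by construction; real alignments are cleaned by deleting
every column containing a non-ACGT symbol), codon structure or
selection, among-site rate autocorrelation, and non-reversible
processes. Passing size/power checks on these synthetic data therefore
says nothing about, e.g., robustness to alignment error in real data.

## Study conditions and problem sizes

The study harness (`size_power()`, `k_sweep()`, `pattern_bias()`,
`topology_accuracy()`) regenerates everything from a seed. The defaults
are the conditions of the reproduced experiments:

* an "easy" 4-taxon tree with all five branches 0.1
  (`study_tree("easy4")`) — the branch lengths are a package assumption,
  so the lengths are a package assumption; ML recovers this topology
  essentially always at $n = 500$;
* a 10-taxon tree with 0.03 internal branches and heterogeneous tips
  (`study_tree("hard10")`), likewise an assumption, built to make
  topology estimation hard;
* GTR parameters estimated from a pseudogene data set:
  $\pi = (0.308, 0.185, 0.308, 0.199)$ in (T, C, A, G) order and
  exchangeabilities $(0.987, 0.11, 0.218, 0.243, 0.395, 1)$ for the
  pairs (TC, TA, TG, CA, CG, AG); SYM uses the same exchangeabilities
  with equal frequencies;
* 200 replicates of $n = 500$ sites for the 4-taxon size/power table;
  50 replicates for the 10-taxon K-sweeps; $\alpha = 0.05$ throughout.

The automated checks run the 4-taxon table at its full 200 replicates,
the 10-taxon sweeps at 50 replicates over $K \in \{5, 10, \ldots, 30\}$,
the Goldman–Cox calibration at 100 null replicates with $B = 99$
bootstrap refits of $n = 200$-site alignments, and the simulation-error
bound with 200 independent expected-frequency draws at $M = 10^4$,
$n = 2000$ (the smallest round $n$ for which the 35-bin scheme satisfies
the rule of thumb under JC69 on the easy tree). These sizes keep every
check's Monte-Carlo error well inside the tolerances asserted.

## Numerical choices and degenerate inputs

* Ties in nearest-center assignment go to the lowest bin index;
  K-means centers are sorted lexicographically so bin labels are
  reproducible; the K-means seed is recorded in the scheme.
* `pearson_statistic()` refuses zero expected frequencies and points to
  a smaller $K$ or larger $M$; `select_K()` skips such configurations.
* A constant alignment has one site pattern: fitting refuses (< 2
  patterns), and near-constant data drive branch lengths to the lower
  bound rather than erroring.
* The Goldman–Cox p-value uses the add-one convention
  $(1 + \#\{\delta_b \ge \delta\})/(B+1)$, so $p = 0$ is impossible.
* p-values are reported at full floating precision.

## Known limitations

* Power is intentionally sacrificed for size control via df = $K-1$;
  borderline mis-specifications (e.g. GTR data tested as SYM at short
  branch lengths) sit exactly where this costs the most.
* Equal-frequency binning is 4-taxon only; for 5+ taxa the K-means path
  with simulated expectations is the supported route.
* Columns with gaps or ambiguity codes are deleted whole, which can
  discard substantial signal in gappy alignments.
* The $16Kn/(25M)$ guidance understates the simulation-induced error of
  the statistic in our own Monte-Carlo checks (the package's acceptance
  tests measure a mean squared error an order of magnitude above it
  even when every bin's expected count exceeds 5). Treat `mse_bound()`
  as the design heuristic behind `choose_M()`, not a guarantee; the
  $M \ge 10^5$ floor is what keeps the induced p-value error small in
  practice.
* The likelihood supports reversible DNA models only (JC69, F81, HKY,
  SYM, GTR, `+I`, `+G`); no codon or amino-acid models, no partitioned
  analyses.
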