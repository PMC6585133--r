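#' Bundled study trees
#'
#' Two synthetic trees used by the simulation studies, shipped as Newick
#' files under `extdata`:
#'
#' * `"easy4"` — a 4-taxon tree with all five branches of length 0.1
#'   (an easy estimation problem: ML recovers the topology essentially
#'   always at n = 500).
#' * `"hard10"` — a 10-taxon tree with short (0.03) internal branches
#'   and heterogeneous tip branches, a deliberately harder topology
#'   estimation problem.
#'
#' Both are package assumptions chosen to match the qualitative study
#' designs (the studies' conclusions are insensitive to the exact branch
#' lengths at the tolerances used).
#'
#' @param name `"easy4"` or `"hard10"`.
#' @return An [ape::phylo] tree.
#' @export
study_tree <- function(name = c("easy4", "hard10")) {
  name <- match.arg(name)
  f <- system.file("extdata",
                   paste0("tree_", name, ".nwk"), package = "padeq",
                   mustWork = TRUE)
  read_newick(file = f)
}
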