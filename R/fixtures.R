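#' Named micro-crypt configurations for testing and exploration
#'
#' Small deterministic configurations exercising specific regimes:
#'
#' * `"two_lineage_minimal"`: a 3 x 5 grid with 2 founding stem cells and a
#'   high symmetric-division probability, so succession happens within a
#'   few hundred iterations.
#' * `"overflow_guard"`: a strong stem-progeny bias (`B = 0.3`) with a low
#'   stem guard, tripping the unbounded-growth flag quickly.
#' * `"shed_column"`: a single-column crypt of height 6 whose column fills
#'   and sheds within a few hundred iterations, for conservation checks.
#' * `"fast_hit"`: a familial-mutation run with a large second-hit
#'   probability, ending in a stem second hit quickly.
#'
#' @param name Fixture name.
#' @return A list with elements `params`, `mutation` and `seed`, ready for
#'   [simulate_crypt()].
#' @examples
#' fx <- make_fixture("two_lineage_minimal")
#' simulate_crypt(fx$params, fx$mutation, seed = fx$seed)$outcome
#' @export
make_fixture <- function(name = c("two_lineage_minimal", "overflow_guard",
                                  "shed_column", "fast_hit")) {
  name <- match.arg(name)
  switch(name,
    two_lineage_minimal = list(
      params = crypt_params(n_cols = 3, n_rows = 5, n0 = 2, ps = 0.5,
                            max_iterations = 20000),
      mutation = mutation_config("NORMAL"),
      seed = 101L),
    overflow_guard = list(
      params = crypt_params(ps = 0.1, bias = 0.3, max_stem_cells = 60,
                            max_iterations = 20000),
      mutation = mutation_config("NORMAL"),
      seed = 202L),
    shed_column = list(
      params = crypt_params(n_cols = 1, n_rows = 6, n0 = 1, ps = 0,
                            max_iterations = 500),
      mutation = mutation_config("NORMAL"),
      seed = 303L),
    fast_hit = list(
      params = crypt_params(ps = 0.1, max_iterations = 5000),
      mutation = mutation_config("FAP", mutation_prob = 0.05),
      seed = 404L))
}
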