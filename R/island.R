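#' Configure a Wright island model
#'
#' Convenience wrapper around [wf_config()] for the classic n-deme island
#' model. `m` follows Wright's convention: the per-generation probability
#' that a gene comes from the *deme-unspecific* migrant pool, to which all
#' demes contribute equally. The pairwise exchange rate between any two
#' demes is therefore `m / n_demes`, which makes the equilibrium
#' approximation [expected_island_fst()] `1/(4 N m + 1)` apply directly
#' regardless of the number of demes.
#'
#' @param N diploid deme size
#' @param m migrant-pool rate (Wright's m)
#' @param n_demes number of demes (default 2)
#' @param n_sample individuals sampled per deme
#' @param n_generations generations to run (several multiples of
#'   `1/(2m + 1/(2N))` to approach equilibrium)
#' @param seed integer seed
#' @param ... further arguments passed to [wf_config()]
#' @return a `wf_config`
#' @export
island_config <- function(N, m, n_demes = 2L, n_sample = 30L,
                          n_generations = 800L, seed, ...) {
  pops <- lapply(seq_len(n_demes), function(i)
    list(label = paste0("deme", LETTERS[i]), size = N, n_sample = n_sample))
  M <- matrix(m / n_demes, n_demes, n_demes)
  diag(M) <- 0
  wf_config(populations = pops, n_generations = n_generations,
            migration = M, seed = seed, ...)
}
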