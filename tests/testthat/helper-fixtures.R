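# Shared small fixtures, built once per test run.

# 189-haplotype founder panel over 400 loci on the default 5-arm map.
fixture_panel <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- generate_founder_haplotypes(189, 400, seed = 20240)
    p
  }
})

# mean F at a given generation across an ensemble
ensemble_mean_F <- function(ens, gen) {
  mean(vapply(ens, function(tr) tr$F[tr$generation == gen & tr$trait_id == 1],
              numeric(1)))
}

ensemble_F <- function(ens, gen) {
  vapply(ens, function(tr) tr$F[tr$generation == gen & tr$trait_id == 1],
         numeric(1))
}
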