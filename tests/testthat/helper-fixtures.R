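# Shared fixtures, built in code. Expensive ones are memoized for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small deterministic seed alignment (5 members of one simulated family).
seed_fixture_alignment <- function() {
  memo("seed_aln", function() {
    cfg <- sim_config(n_clades = 1, seqs_per_clade = 8, n_decoys = 0,
                      seed = 123)
    sim <- embed_domains(evolve_domain_sequences(simulate_family_tree(cfg),
                                                 cfg), cfg)
    seed_alignments(sim, 5)[[1]]
  })
}

# The full desk-scale profile: the default study conditions (6 x 40
# planted members, 600 decoys) run end to end once and reused by the
# acceptance checks.
desk_pipeline <- function() {
  memo("desk_run", function() {
    suppressMessages(run_pipeline(desk_config()))
  })
}

desk_config <- function() {
  pipeline_config(min_clade_size = 8L, min_retained = 5L, n_bootstrap = 100L)
}
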