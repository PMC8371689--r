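# Shared fixtures: one lexicon for the whole suite, and a cache so the
# heavier simulation sweeps are run once and reused across test blocks.

lex <- build_lexicon()

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# All 63 nominal trials (21 stimulus words x 3 variants), deterministic.
nominal_sweep <- function() cached("nominal", {
  plan <- grid_plan(lex, grid_seed = 1)
  run_grid(lex, plan[plan$condition == "nominal", ])
})

noisy_sweep <- function() cached("noisy", {
  plan <- grid_plan(lex, grid_seed = 1)
  run_grid(lex, plan[plan$condition == "noisy" &
                       plan$variant %in% c("bu_only", "and"), ])
})

hypo_sweep <- function() cached("hypo", {
  plan <- grid_plan(lex, grid_seed = 1)
  run_grid(lex, plan[plan$condition == "hypo", ])
})

onehot <- function(domain, which) {
  p <- stats::setNames(rep(0, length(domain)), domain)
  p[which] <- 1
  p
}
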