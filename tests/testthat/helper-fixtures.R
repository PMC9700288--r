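# Shared fixtures.  The default-condition simulation and its pipeline runs
# are computed once per test session and reused by the end-to-end checks.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

default_sim <- function() memo("sim", simulate_dataset(sim_config(seed = 42L)))

default_ref_index <- function() memo("idx", seq_index(default_sim()$reference))

default_results <- function() memo("results", {
  sim <- default_sim()
  idx <- default_ref_index()
  res <- lapply(setNames(names(sim$reads), names(sim$reads)), function(sid) {
    discover_novel(sim$reads[[sid]], idx, classifier = sim$classifier,
                   tax = sim$taxonomy, sample_id = sid)
  })
  res
})

default_placements <- function() memo("placements", {
  sim <- default_sim()
  idx <- default_ref_index()
  lapply(setNames(names(sim$reads), names(sim$reads)), function(sid) {
    call_novel_placements(sim$reads[[sid]], idx, sample_id = sid)
  })
})

# A tiny taxonomy identical in shape to the built-in one, for hand checks.
tiny_tax <- function(labels = NULL) default_taxonomy(labels = labels)

# Write a character vector to a temp file and return the path.
tmp_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
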