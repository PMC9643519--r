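# Shared (lazily computed, cached) scenario runs: the full case matrix, the
# pressure scenarios and the ON-stiffness variants are expensive, so the
# scenario and acceptance tests reuse one computation.
grid_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = grid_cache))
    assign(name, force(expr), envir = grid_cache)
  get(name, envir = grid_cache)
}

get_case_matrix <- function() cached("matrix", run_matrix(library = ont_lib))

get_pressure_scenarios <- function()
  cached("pressure", run_pressure_scenarios(library = ont_lib))

get_on_variants <- function()
  cached("variants", run_on_stiffness_variants("B", library = ont_lib))

get_convergence <- function()
  cached("convergence", convergence_study("average", library = ont_lib))

stress_at <- function(bundle, loc) bundle_value(bundle, loc, "stress")
strain_at <- function(bundle, loc) bundle_value(bundle, loc, "strain")
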