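# Shared, lazily computed fixtures. The default model's preferred-direction
# map and the per-orientation population-vector tables are the expensive
# pieces; they are computed once per test run and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) {
    assign(key, fn(), envir = .fixture_cache)
  }
  .fixture_cache[[key]]
}

default_model <- function() {
  cached("default_model", function() {
    with_preferred_directions(urchin_model())
  })
}

pv_table <- function(family, phi_stim = NA_real_) {
  key <- paste0("pv_", family, "_", phi_stim)
  cached(key, function() {
    population_vectors(default_model(), make_stimulus(family, phi_stim))
  })
}

# circular sd (degrees) of a sample of angles, via mean resultant length
circ_sd_deg <- function(angles) {
  r <- circular_mean(angles)$length
  sqrt(-2 * log(r)) * 180 / pi
}
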