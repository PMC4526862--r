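# Lazily computed, memoised reconstructions of the standard phantom so that
# several tests can share one run.

.std_cache <- new.env(parent = emptyenv())

std_phantom <- function(blob = TRUE) {
  key <- paste0("phantom_", blob)
  if (is.null(.std_cache[[key]])) {
    .std_cache[[key]] <- generate_phantom(standard_phantom_spec(blob = blob))
  }
  .std_cache[[key]]
}

std_model <- function(n_points = 540, blob = TRUE) {
  key <- paste0("model_", n_points, "_", blob)
  if (is.null(.std_cache[[key]])) {
    ph <- std_phantom(blob)
    .std_cache[[key]] <- suppressWarnings(
      reconstruct_stack(ph$stack, ph$truths[[1]],
                        solver_params(n_points = n_points), start_z = 1))
  }
  .std_cache[[key]]
}
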