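# Shared fixtures, built in code. The model scene (noise-free, one lateral
# column) is cached because several files reuse it.

model_grid <- function() acquisition_grid(512L, 2.5)

model_phantom <- function() {
  layered_phantom(c(0.073, 0.561, 1.050, 2.5), c(1, 2, 4))
}

.scene_cache <- new.env(parent = emptyenv())

model_scene_clean <- function() {
  if (is.null(.scene_cache$clean))
    .scene_cache$clean <- simulate_model_scene(n_lateral = 1)
  .scene_cache$clean
}

# independent oracle for the cumulative attenuation integral: vectorized
# overlap-length formulation, a different derivation than the package's
# per-layer loop
oracle_cum_mu <- function(phantom, z) {
  b <- phantom$boundaries
  lo <- b[-length(b)]
  hi <- b[-1]
  vapply(z, function(q)
    sum(phantom$mu * pmax(0, pmin(q, hi) - lo)), numeric(1))
}

# layer interior pixel indices (strictly inside, one pixel trimmed per side)
layer_interior <- function(phantom, grid, layer) {
  b <- phantom$boundaries
  idx <- which(grid$z >= b[layer] & grid$z < b[layer + 1])
  idx[-c(1, length(idx))]
}
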