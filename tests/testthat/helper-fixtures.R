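# Shared small fixtures, generated once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixtures)) assign(name, build(), .fixtures)
  get(name, .fixtures)
}

# small balanced cohort on a 12^3 grid for fast training tests
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(n_total = 48, n_ad = 24, n_female = 24,
                    grid = volume_grid(c(12, 12, 12)), seed = 101)
  })
}

# strongly separable cohort (large effect, no per-subject or voxel noise)
separable_cohort <- function(n = 40, grid_dim = 12, seed = 103) {
  generate_cohort(n_total = n, n_ad = n / 2, n_female = n / 2,
                  grid = volume_grid(rep(grid_dim, 3)),
                  signal = signal_model(effect = 0.5, subject_sd = 0),
                  noise_sd = 0, seed = seed)
}

small_spec <- function(dim = 12) cnn_spec(rep(dim, 3))

# toy field configuration for hand-arithmetic share tests
toy_secagg <- function(Q = 97, f = 4, B = 1.5) {
  secagg_config(Q = Q, f = f, B = B, min_clients = 2, n_max = 2)
}

# minimal "model" for aggregation arithmetic tests: plain named list of arrays
toy_params <- function(w, b = c(0, 0)) list(w = matrix(w, 2, 2), b = b)

# n subject ids alternating AD/CN (cohort records are grouped by cell)
mixed_ids <- function(co, n, offset = 0) {
  r <- co$records
  ad <- r$subject_id[r$diagnosis == "AD"]
  cn <- r$subject_id[r$diagnosis == "CN"]
  k <- ceiling(n / 2)
  ids <- as.vector(rbind(ad[(offset + 1):(offset + k)],
                         cn[(offset + 1):(offset + k)]))
  ids[seq_len(n)]
}
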