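# Shared fixtures: a small render geometry so imaging tests stay fast, and a
# counting config whose RATS noise floor matches that geometry's noise.

small_render <- function(...) {
  render_config(width = 400L, height = 300L, radius_range = c(8, 12), ...)
}

test_vectors <- stain_vectors()
test_lambda <- estimate_rats_lambda(small_render(), test_vectors, seed = 99L)

small_counting <- function(...) {
  counting_config(vectors = test_vectors, rats_lambda = test_lambda, ...)
}

# all-positive / all-negative nucleus record sets over a given geometry
nuclei_records <- function(geom, mib1 = TRUE, phh3 = FALSE, mitvis = FALSE,
                           dna = 1.5) {
  n <- nrow(geom)
  cbind(geom,
        mib1_pos = rep_len(mib1, n), phh3_pos = rep_len(phh3, n),
        mitotically_visible = rep_len(mitvis, n),
        dna_content = rep_len(dna, n))
}

# binary disc mask helper for watershed/IOD geometry oracles
disc_mask <- function(nrow_, ncol_, centers, radius) {
  m <- matrix(0, nrow_, ncol_)
  for (i in seq_len(nrow_)) for (j in seq_len(ncol_)) {
    for (k in seq_len(nrow(centers))) {
      if ((i - centers[k, 1])^2 + (j - centers[k, 2])^2 <= radius^2) m[i, j] <- 1
    }
  }
  m
}
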