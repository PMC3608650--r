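# Shared fixture builders; everything is generated in code at test time.

# A small, fast simulation configuration used where the exact operating
# point does not matter.
tiny_config <- function(n_voxels = 30, separation = 1, sigma_good = 4,
                        sigma_bad = sqrt(2) * sigma_good, sigma_noise = 6,
                        proto_seed = 99) {
  cfg <- simulation_config(
    n_voxels = n_voxels, separation = separation,
    variance_spec = exemplar_variance_spec(sigma_good, sigma_bad),
    sigma_noise = sigma_noise
  )
  cfg$prototypes <- generate_prototypes(n_voxels, separation, seed = proto_seed)
  cfg
}

# A configuration with (numerically) zero exemplar noise.
noiseless_config <- function(n_voxels = 20, separation = 1, sigma_noise = 0,
                             proto_seed = 7) {
  cfg <- simulation_config(
    n_voxels = n_voxels, separation = separation,
    variance_spec = exemplar_variance_spec(1e-12),
    sigma_noise = sigma_noise
  )
  cfg$prototypes <- generate_prototypes(n_voxels, separation, seed = proto_seed)
  cfg
}

# Hand-built rating table rows for the discount-score worked examples.
rating_row <- function(rater, trial, image, response, rating,
                       is_check = FALSE, refers_to = NA_integer_) {
  data.frame(rater_id = rater, trial = trial, image_id = image,
             response = response, rating = rating, is_check = is_check,
             refers_to = refers_to, stringsAsFactors = FALSE)
}
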