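# Shared fixtures: small synthetic-study configurations built in code.

# Quick two-culture bundle for plumbing tests.
tiny_bundle <- function(seed = 42L, ...) {
  simulate_emotion_study(generator_config(
    n_stimuli = 60L, n_categories = 8L, n_latent = 3L, n_expressible = 2L,
    n_features = 6L, n_raters = c(4L, 3L), seed = seed, ...))
}

# Fully additive (no clipping, no selection threshold) configuration: the
# regime in which the generator's closed-form identities are exact.
linear_config <- function(seed, ...) {
  generator_config(selection_threshold = NULL, clip = NULL,
                   loading_perturbation_sd = 0, seed = seed, ...)
}

# Per-participant stimulus x category matrices from a long rating table.
participant_matrices <- function(ratings) {
  stimuli <- sort(unique(ratings$stimulus))
  cats <- sort(unique(ratings$category))
  lapply(split(seq_len(nrow(ratings)), ratings$participant), function(ix) {
    m <- matrix(NA_real_, length(stimuli), length(cats),
                dimnames = list(stimuli, cats))
    m[cbind(match(ratings$stimulus[ix], stimuli),
            match(ratings$category[ix], cats))] <- ratings$value[ix]
    m
  })
}

# Smallest angle (degrees) between two directions, sign-agnostic.
direction_angle <- function(u, v) {
  acos(pmin(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
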