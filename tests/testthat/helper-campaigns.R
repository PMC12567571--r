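# Shared fixtures: campaigns are generated in code and memoized per
# (campaign, seed, noise) so expensive simulations are built once per run.

zero_noise <- c(bulk_density = 0, weight = 0, force = 0, hardness = 0)

.campaign_cache <- new.env(parent = emptyenv())

cached_campaign <- function(campaign, seed = 3, noise = zero_noise) {
  key <- paste(campaign, seed, paste(noise, collapse = ","), sep = "|")
  if (is.null(.campaign_cache[[key]])) {
    .campaign_cache[[key]] <- simulate_campaign(
      campaign_spec(campaign, noise = noise), seed = seed)
  }
  .campaign_cache[[key]]
}

cached_stage_data <- function(campaign, stage, seed = 3, noise = zero_noise) {
  stage_data(cached_campaign(campaign, seed, noise), stage,
             campaign_norm(campaign))
}

# admissible random parameters for a library variant
random_variant_params <- function(id) {
  v <- rational_variant(id)
  p <- lapply(v$free_params, function(nm) 10^stats::runif(1, -2, 2))
  names(p) <- v$free_params
  p
}
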