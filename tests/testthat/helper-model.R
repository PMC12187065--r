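# Shared fixtures: the synthetic life table and default parameter sets.
lt_default <- synthesize_lifetable()
params70 <- default_parameters(70)
params80 <- default_parameters(80)

# A parameter world without aortic stenosis: no prevalent disease at
# screening and no incident disease, so the paired arms differ only by the
# one-time screening fee.
params_no_as <- local({
  p <- params80
  p$screening$screen_positive_rate <- 0
  modify_parameters(p, list(transitions = list(incidence_gp_to_mild = 0)))
})

# Distribution specs degenerated to point masses at the current defaults.
fixed_specs <- function(params) {
  specs <- default_psa_specs(params)
  defaults <- list(
    "transitions.ava_rate_mean" = params$transitions$ava_rate_mean,
    "screening.severity_split" = params$screening$severity_split,
    "screening.screen_positive_rate" = params$screening$screen_positive_rate
  )
  for (key in names(specs)) {
    val <- defaults[[key]]
    if (is.null(val)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      val <- params[[parts[1]]][[parts[2]]]
    }
    specs[[key]] <- dist_spec("fixed", val)
  }
  specs
}
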