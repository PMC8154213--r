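# Shared plate builders for the imine-reductase scenario: dehydrosalsolidine
# (C12H15NO2, imine substrate) reduced to salsolidine (C12H17NO2, amine
# product), both observed as [M+H]+. Product lies two mass units above the
# substrate, so the substrate M+2 isotopologue leaks into the product channel.

IRED_SUB <- "C12H15NO2"
IRED_PROD <- "C12H17NO2"

ired_species <- function(layout, wells = well_labels(layout),
                         drift_sub = 5, drift_prod = 8) {
  n <- length(wells)
  species_table(rep(wells, each = 2L),
                rep(c("substrate", "product"), n),
                rep(c(IRED_SUB, IRED_PROD), n), "M+H",
                rep(c(drift_sub, drift_prod), n), layout = layout)
}

ired_channels <- function(species, window = 0.2) {
  asg <- assign_channels(species, window)
  list(substrate = get_channel(asg, grep("substrate", asg$channels$label)),
       product = get_channel(asg, grep("product", asg$channels$label)),
       assignment = asg)
}

# simulate a plate with given conversions; returns sim + channels + quants
sim_ired_plate <- function(layout, conversions, seed = 1L,
                           instrument = instrument_params(),
                           responses = response_model(), offset = c(0, 0),
                           total_mM = 0.1) {
  species <- ired_species(layout, wells = names(conversions))
  truth <- ground_truth(layout, species, conversions, total_mM = total_mM,
                        responses = responses, seed = seed)
  sim <- simulate_membrane(layout, species, truth, instrument, seed = seed,
                           offset = offset)
  ch <- ired_channels(species)
  c(sim, ch, list(species = species, layout = layout))
}

quantify_ired <- function(simlist, registration = NULL, margin = 0.1) {
  imgs <- list(extract_ion_image(simlist$dataset, simlist$substrate),
               extract_ion_image(simlist$dataset, simlist$product))
  quantify_wells(imgs, simlist$layout, registration, margin)
}

# noise-free, jitter-free instrument for closed-form checks
quiet_instrument <- function(...) instrument_params(mz_jitter_sd = 0, ...)
quiet_response <- function(...) {
  args <- list(...)
  defaults <- list(noise_scale = 0, baseline = 0)
  do.call(response_model, utils::modifyList(defaults, args))
}
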