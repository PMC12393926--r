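# Shared fixtures for the test suite.

# A minimal hand-specified diet with known arithmetic.
demo_diet <- function(name = "DEMO") {
  diet_spec(
    name,
    ingredients = data.frame(
      ingredient = c("fishmeal", "wheat", "fish oil"),
      inclusion = c(40, 45, 15),
      gwp_factor = c(1500, 700, 2000)),
    dm = 94, ash = 7.8, crude_protein = 50, crude_fat = 18,
    total_p = 1.1, gross_energy = 22, marker = 0.02,
    aa_profile = data.frame(
      amino_acid = c("lysine", "methionine", "glycine"),
      class = c("essential", "essential", "nonessential"),
      mg_per_g_dm = c(30, 10, 25)))
}

demo_tank <- function(tank_id = "T1", diet = "DEMO", period = "growth") {
  tank_record(tank_id, diet, n_initial = 90, n_final = 87,
              biomass_initial = 90 * 14.1, biomass_final = 87 * 47.8,
              feed_distributed = 87 * 36.3, days = 65,
              temperatures = 23.5, period = period)
}

# Faeces designed so every ADC is computable by hand:
# diet marker (DM) = 0.02/0.94; with faecal marker 5x the diet marker,
# ADC_dm = 80 exactly.
demo_faeces <- function(tank_id = "T1") {
  d <- demo_diet()
  dmark <- as_dm_basis(d$marker, d$dm)
  faecal_sample(tank_id,
                protein = 14, lipid = 5, phosphorus = 2.2,
                energy = 16, marker = 5 * dmark)
}
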