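# Fixture knot tables (synthetic stand-ins)

These CSVs (`age_years,value`) are synthetic, representative stand-ins for
the tabulated age trends the analysis interpolates; the original
growth-chart and histology source tables are not redistributed here.

- `weight_male.csv`, `weight_female.csv` — body weight for age (kg),
  shaped like sex-specific growth-chart averages, ages 0-20 y.
- `beta_cell_density.csv` — beta cell density (abstract BCM-units per
  cm^3), declining with age, ages 0-25 y.
- `pancreas_volume.csv` — pancreas volume (cm^3), rising with age,
  ages 0-25 y.

The density table is scaled so that the total-mass-to-weight ratio
BCM(20)/W(20) equals 829 BCM-units/kg: at the default demand parameter
alpha = 499 the predicted excess beta cell mass at age 20 is
1 - 499/829 = 0.398 (~40% tolerable reduction at age 20, ~85% at the
youngest ages).
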