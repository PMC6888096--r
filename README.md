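# micellar

Micellization analysis of surfactant titration data in R.

When an ionic surfactant such as ammonium perfluorooctanoate (APFO, a
widely used and environmentally persistent PFAS) micellizes in water, the
transition leaves fingerprints in four classical bench experiments:

* **conductivity** — a break at the critical micelle concentration (CMC);
  the post/pre-break slope ratio gives the degree of counterion
  dissociation, α = S₂/S₁;
* **surface tension** — a log-linear descent to a plateau; the Gibbs
  adsorption isotherm, Γ_max = −(dγ/dlogC)/(2.303 nRT), converts the
  pre-CMC slope into the surface excess and the minimum headgroup area
  A_min = 1/(N_A Γ_max), which with tail geometry yields the critical
  packing parameter CPP = V₀/(A_min·l_c) and a shape class;
* **pyrene I1/I3 fluorescence** — the micropolarity ratio drops as the
  probe partitions into micelles; the intersection of the plateau and
  descent lines marks the CMC;
* **capillary viscometry** — relative viscosity grows as
  η_r = 1 + νφ + k₁(νφ)², with φ the hydrated micelle volume fraction;
  fitting it yields the hydrated volume per surfactant molecule V_s,hyd
  and, by volume bookkeeping, the number of bound water and cosolvent
  (e.g. urea) molecules.

`micellar` implements all four inference chains as tested, auditable
estimators, plus a seeded forward simulator of all four measurements so
every estimator can be validated by parameter recovery. It is aimed at
colloid/formulation chemists and environmental chemists working with
fluorinated (or ordinary ionic) surfactants in aqueous media with
cosolvents.

## Worked example

Simulate a full four-experiment study at the APFO-in-water conditions
(CMC 26.5 mM, α 0.47, tension slope −29.6 mN/m per decade, ν 2.97,
V_s,hyd 0.710 nm³) with realistic instrument noise, then analyze it:

```r
library(micellar)

params <- truth_params(seed = 2026)
bundle <- gen_bundle(params, seed = 2026)

fit <- fit_two_segments(bundle$conductivity, refine = TRUE)
fit
#> <breakpoint_fit: CMC = 26.86 mM, alpha = 0.456 (S1 49.99, S2 22.79), RSS 594.9>

ads <- analyze_tension(bundle$tension, n_prefactor = 2, surfactant = apfo_spec())
ads
#> <adsorption_result: slope -29.4 mN/m/decade, Gamma_max 2.58e-10 mol/cm^2, Amin 64.3 A^2, CMC 27.19 mM>
#> <packing_result: CPP = 0.465 (displays 0.47), shape cylinder, Amin 64.33 A^2>

visc <- fit_virial(bundle$viscosity, cmc = fit$cmc, nu = 2.97)
visc
#> <viscosity_fit: p1 1.333 L/mol, k1 0.592, nu 2.97 -> Vshyd 0.7453 nm^3 (c1 26.86 mM)>

hydration_budget(visc$v_shyd, apfo_spec(), solvent_spec())
#> <hydration_budget [direct]: Vshyd 0.745 = mol 0.376 + water 0.369 (n=12) + cosolvent 0.000 (n=0.0) nm^3>
```

Reading the output: the conductimetric break lands at 26.9 mM with
α = 0.46 (truth: 26.5, 0.47); the Gibbs chain recovers a 64 Å² headgroup
footprint whose CPP of 0.47 classifies the micelles as cylindrical; the
viscometric fit puts the hydrated molecular volume at 0.745 nm³ (truth
0.710), i.e. about a dozen bound waters per APFO. With a 4 M urea
condition you would additionally pass `urea_solvent(4)` and the
plain-water bound-water volume as `v_water_total_reference` to count
bound urea molecules.

Real data enter through two-column CSVs
(`read_titration(path, response_kind, temperature)`), and
`run_report(config)` chains whatever stages have inputs into one JSON
report (`write_report()` serializes it canonically). A thin command-line
wrapper with subcommands `conduct`, `tension`, `fluor`, `visc`, `pack`,
`simulate` and `report` is installed at `inst/cli/micellar`.

## Documentation

The methods vignette (`vignettes/micellization-analysis.Rmd`) explains
each model and its assumptions, every tunable parameter with units and
defaults, the window-selection and break-detection design decisions,
known estimator biases, and what passing the synthetic-data tests does
and does not certify about real titrations.
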