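# allosim

An evolutionary agent-based simulation of large-theropod foraging ecology:
did selection in sauropod-dominated ecosystems favour hunters or
scavengers?

Giant herbivore carcasses ("sauropod falls", by analogy with whale falls)
were a uniquely rich carrion resource. `allosim` puts a population of
large endothermic theropod agents on a 70 × 70 km toroidal landscape
together with a floor-maintained herd of 2,000 kg prey and up to five
concurrent 10–25 t decaying carcasses, equips every agent with six
heritable traits — three scavenging traits (carcass detection range,
fat-storage capacity, carcass-site dominance) and three hunting traits
(bite force, hearing, binocular vision) — and lets lifetime reproductive
success decide which trait classes propagate. The package is aimed at
evolutionary ecologists and palaeoecology modellers who want a seeded,
configurable reimplementation of this class of model with a statistics
layer for the selection analyses.

## The model in brief

* **Energy.** Body "energy" is mass in kg of meat equivalent. The daily
  requirement follows the all-bird field-metabolic-rate allometry
  anchored at the initialization mass,
  `N(M) = 29 (M/2000)^0.681` kg meat/day, so mass obeys
  `M' = M + intake − N(M)`; starvation strikes below a fixed floor of
  1,840 kg (92% of initialization). Daily intake is capped by the
  fat-storage ("tailfat") ability, 11.4–64.6 kg depending on genotype.
* **Heredity.** Each trait is an ordered expression class
  (`extra_small … extra_big`) with a continuous advantage factor in
  [0.3, 1.7]. Offspring keep the parental class with probability 0.8 and
  otherwise step to an adjacent class; the factor is re-drawn within the
  offspring class. An `extra_small` lineage needs at least four
  generations to reach `extra_big`.
* **Foraging.** Carrion-first perception (nearest carcass within the
  detection radius, else nearest prey within the ten-times-shorter
  binocular radius, else a correlated random walk); dominance-ordered
  feeding contests at carcass sites; committed multi-day pursuits in
  which hearing slows the prey, strikes fire at a 0.1 km capture radius,
  and each strike kills with probability equal to the bite-force ability.
* **Demography.** Asexual reproduction at 0.02 per agent per day, gated
  by a standing cap of 30 and a body-condition floor; killed prey become
  2,000 kg carcasses and the prey herd is replenished to 20; carcasses
  decay, are randomly removed, and vanish at 20% residual mass.

The methods vignette
(`vignettes/foraging-evolution-model.Rmd`) documents every model rule,
the reconstruction decisions behind the defaults, and what the defaults
do and do not reproduce.

## Worked example

```r
library(allosim)

fit <- allosim(allosim_config(), seed = 1)   # full 279-year run
print(fit)
#> Foraging-evolution simulation (allosim)
#>   101835 days (279.0 years), seed 1
#>   agents produced: 16846 (12 founders)
#>   zero-offspring fraction: 0.592
#>   kills: 386 of 4141 strikes (960 pursuits)

summary(fit)
#> allosim run summary
#>   agents produced:            16846
#>   zero-offspring fraction:    0.592
#>   max offspring:              30
#>   tailfat fitness ratio:      1.34  (> 35 kg vs rest, k = 1)
#>   bite-force fitness ratio:   0.98  (> 0.11 vs rest, k = 1)
#>   successful agents: mean mass 2285 kg, mean tailfat 53.1 kg
#>   sauropod carcasses/year:    39.3
```

16,846 agents were produced over 279 simulated years; 59.2% died without
reproducing. Agents whose daily fat-storage capacity exceeds 35 kg were
1.34× as likely to produce exactly one offspring as all others — fat
storage is under positive selection — while high bite force (kill
probability above 0.11) was selectively neutral (ratio 0.98).
Reproductively successful agents operated at a mean body mass of
2,285 kg, i.e. a daily requirement near 33 kg of meat: an emergent,
energetically sustained body-mass plateau.

Analysis functions work on the run object or on written records:

```r
tab <- fitness_table(fit)
zero_offspring_fraction(tab)               # 0.592
fitness_ratio(tab, "tailfat", 35, k = 1)   # 1.34
successful_mass_mean(tab)                  # $mass 2285, $tailfat 53.1
bin_summary(tab)                           # trait means by offspring count
plot(fit, type = "composition", trait = "tailfat")
```

A thin command-line front-end wraps the same functions:

```sh
exec/allosim run --seed 1 --years 279 --out runs/a
exec/allosim analyze --records runs/a/records.csv --out runs/a/summary
```

writing `records.csv`, `events.csv`, `yearly.csv`, `run_meta.json`, and
`summary.json` with the headline statistics.

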