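# DamageClust

Complex DNA damage — two or more vicinal lesions within 10–20 base pairs
(bp) — is the most biologically consequential class of radiation-induced
DNA lesions, and it cannot be resolved directly by experiment at the
nanometre scale. `DamageClust` implements a simplified cluster analysis of
electron track structure for estimating the yields and type fractions of
complex DNA damage: single- and double-strand breaks (SSB, DSB), base
damage (BD), clustered base damage (cBD), and their combinations (DSB/BD,
DSB/BD/BD, 2BD–4BD, DSB+, DSB++). It is aimed at radiation biophysicists
who have per-event track-structure output (3-D coordinates of ionization
and electronic excitation events with deposited energies) from a Monte
Carlo transport code, or who want to explore the counting/classification
machinery with the built-in synthetic track generator.

## The model

From an event cloud with `N_event` inelastic events depositing a total
energy `E_dep` (keV), with `N_link(L_c)` the number of event pairs closer
than the maximum inter-lesion distance `L_c` (10 bp = 3.4 nm by default),
the damage yields in Gy⁻¹Da⁻¹ are

    Y_SSB       = k_SSB · N_event   / E_dep
    Y_DSB       = k_DSB · N_link(10 bp) / E_dep
    Y_BD        = k_BD  · N_event   / E_dep
    Y_cBD(L_c)  = k_cBD · N_link(L_c)  / E_dep

with `k_SSB = 5.66·10⁻¹²` and `k_DSB = 1.61·10⁻¹³` keV·Gy⁻¹·Da⁻¹
calibrated against measured X-ray strand-break yields, and the
base-damage coefficients derived from the induction ratio BD/SSB = 1.3:
`k_BD = 1.3·k_SSB = 7.36·10⁻¹²` and `k_cBD = 1.3²·k_DSB = 2.72·10⁻¹³`.

Damage complexity is then resolved by a cluster analysis: each linkage
(event pair within `L_c`) defines a site, and the number of events per
cluster `N_cl` within `L_c` of the site midpoint classifies the site.
With ~9 events needed per additional base damage, the bins
`2 ≤ N_cl < 11`, `11 ≤ N_cl < 20`, `20 ≤ N_cl < 29` map DSB sites to
DSB, DSB/BD, DSB/BD/BD (and cBD sites to BD/BD … BD/BD/BD/BD); with
~12 events per additional strand break (9 × 1.3), the bins
`2 ≤ N_cl < 14`, `14 ≤ N_cl < 26`, `26 ≤ N_cl < 38` map DSB sites to
DSB, DSB+, DSB++. The per-bin site fractions `f(N_cl)` split the parent
yields into per-type yields.

Two experimental-detection corrections are included for probe-based
(aldehyde reactive probe + atomic force microscopy) base-damage
measurements: a per-base-damage detection efficiency η (so `Y_BD·η`,
`Y_cBD·η²`, and generally `η^k` for a type with k base damages), and the
probe-size detection loss `Y*_cBD = Y_cBD(10 bp) − Y_cBD(5 bp)` for
clustered base damages too close to be resolved by ~10 bp-wide probes.

## Worked example

```r
library(DamageClust)
rep <- runAnalysis(params = trackParams(nEvents = 500, seed = 3),
                   eta = 0.9, arpLoss = TRUE)
rep
#> YieldReport
#>   N_event = 500, E_dep = 10.764 keV
#>   N_link: 10bp = 1202, 5bp = 464
#>   Y_SSB = 2.629e-10  Y_DSB = 1.798e-11  Y_BD = 3.418e-10  Y_cBD = 3.038e-11  (Gy^-1 Da^-1)
#>   Y*_cBD (detection loss) = 1.865e-11
#>   detection: eta = 0.9 (per-lesion mode)
```

A 500-event synthetic track (3 nm mean free path) deposited 10.76 keV;
1202 event pairs lie within 3.4 nm (10 bp) and 464 within 1.7 nm (5 bp).
The strand-break yields follow directly from those counts; the clustered
base damage detectable by a 10 bp-wide probe is what remains after
subtracting the sub-5 bp linkages (1.865·10⁻¹¹ of 3.038·10⁻¹¹ Gy⁻¹Da⁻¹).
The per-type split of the parent yields:

```r
fractionTable(rep)
#>         label n_sites fraction     yield
#> 1         DSB     839    0.698 1.255e-11
#> 2      DSB/BD     363    0.302 5.429e-12
#> 3   DSB/BD/BD       0    0.000 0.000e+00
#> 5       BD/BD     839    0.698 2.121e-11
#> 6    BD/BD/BD     363    0.302 9.176e-12
#> 7 BD/BD/BD/BD       0    0.000 0.000e+00
```

i.e. 69.8% of the sites are simple (N_cl < 11) and 30.2% carry one
additional base damage — a dense track, as expected for a 3 nm mean free
path. `yields(rep)`, `fractions(rep)` and `rep@ratios` expose the raw
numbers (here `bd_ssb = 1.3` by construction, `cdsb_dsb = 30.2%`).

A command-line interface wraps the same functions:

```sh
exec/damageclust simulate --n-events 500 --mfp-nm 3 --seed 3 --out track.tsv
exec/damageclust analyze --input track.tsv --eta 0.9 --arp-loss --out report.json
exec/damageclust report --report report.json
```

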