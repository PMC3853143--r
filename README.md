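# kinmotif

Kinetic motif discovery for synthetic gene circuit design.

## The problem

Picking genetic parts (promoter/RBS/degradation-tag combinations) that make a
designed gene circuit actually produce its specified behaviour still takes
many build–test cycles, because circuit function depends not only on wiring
but on the kinetic efficiencies of the parts. `kinmotif` attacks this
computationally for small transcriptional circuits: it simulates the circuit
over **every** combination of binned kinetic-parameter efficiency levels,
finds the combinations that hit a user-specified steady-state target under
both noise-free and noise-perturbed dynamics, clusters those functional
combinations into recurring patterns ("kinetic motifs"), ranks them into a
handbook, and answers practical design queries against that handbook: *which
parts do I swap to make my broken circuit work, or my working circuit work
better?*

It is aimed at synthetic-biology modellers and tool builders; everything is
driven by a single structured configuration file, from R or the bundled
command-line script.

## The model

Each gene *i* carries a protein concentration x_i(t) (nM) updated per unit
time step by

    dx_i/dt = p_i0 + p_i * r_i(x_j) - d_i * x_i ,    r_i(x) = 1 / (1 + (x/K)^n)

where p_i0 is the basal production rate, p_i the production rate constant,
d_i the degradation rate constant, and r_i the Hill repression function of
gene *i*'s (at most one) repressor *j* (r = 1 for unregulated genes; K =
1000 nM, n = 2 by default). The noise-perturbed counterpart adds a
parametric perturbation scaled by a fresh standard-normal draw n_i per gene
per step, plus extrinsic noise v_i:

    dy_i/dt = f_i(y) + (Δp_i0 + Δp_i * r_i(y_j) - Δd_i * y_i) * n_i + v_i

Each gene contributes a production and a degradation slot; each slot's value
range is split into 5 uniform efficiency levels represented by bin
midpoints, so a 4-gene circuit has 5^8 = 390,625 level combinations. Every
combination is integrated for T = 100 steps from the target state and scored
by the log-summed absolute deviation from the target z:

    DD (or DS) = ln( sum_i sum_t | x_i(t) - z_i | )

A run is *functional* only if no concentration ever exceeds 10^6 nM and every
gene's steady state (mean of the second half of the run) is within 20% of
z_i; ill-behaved runs get the sentinel deviation 15. Sets functional in both
the deterministic (DD) and stochastic (DS) sense are clustered by Hamming
distance on their level sequences; each cluster's consensus logo (wildcard
`*` where no level reaches 90% share) and mean DD + DS score define the
ranked handbook.

The bundled demo is the TetR ⊣ LacI ⊣ CI ⊣ Eyfp repression cascade with
target z = (1000, 30000, 300, 30000) nM.

## Worked example

A reduced 3-level grid (3^8 = 6,561 sets, a few seconds; the full 5-level
demo takes about a minute and behaves the same way):

```r
library(kinmotif)

cfg <- demo_config(n_levels = 3)
sc  <- scan_grid(cfg)
glance(sc)
#>   n_sets both_ok det_only stoch_only both_fail functional_fraction
#> 1   6561     192       51          0      6318              0.0293

hb <- run_handbook(sc, cfg)
head(tidy(hb)[, c("rank", "logo_paired", "size", "mean_DD", "mean_DS", "score")], 5)
#>    rank logo_paired              size mean_DD mean_DS score
#> 1     1 (2,2);(2,2);(*,*);(1,1)     7    8.89    11.0  19.8
#> 2     2 (3,3);(1,1);(*,*);(1,1)     7    9.23    10.7  19.9
#> 3     3 (3,3);(3,3);(*,*);(1,1)     7    8.91    11.1  20.0
#> 4     4 (2,2);(1,1);(*,*);(1,1)     8    9.10    11.1  20.2
#> 5     5 (2,2);(1,1);(*,*);(3,3)     5    9.18    11.1  20.3
```

Only 192 of 6,561 level combinations (2.9%) are functional under both
conditions; another 51 work only without noise. The motif logos show the
hallmark structure: matched production/degradation levels per gene (fast
turnover must be fed by fast production to hold the same steady state) and
wildcards at the CI positions — LacI sits at 30,000 nM, so CI's promoter is
silenced to 1/901 of full activity and its own kinetics barely matter.

Repairing a non-functional design by handbook lookup:

```r
run_advise(hb, "(3,3);(2,1);(2,2);(2,1)", mode = "repair", k = 2)
#> design: 33212221 (3,3);(2,1);(2,2);(2,1)
#> <kin_route> to motif rank 2 3311**11 (distance 2)
#>   gene2 RBS: level 2 -> 1
#>   gene4 RBS: level 2 -> 1
#>   Route preserves production/degradation level symmetry for all genes.
#> <kin_route> to motif rank 8 3311**22 (distance 2)
#>   gene2 RBS: level 2 -> 1
#>   gene4 PDT: level 1 -> 2
#>   Route preserves production/degradation level symmetry for all genes.
```

Each route is a minimal set of part swaps (ribosome binding sites set
production levels, protein degradation tags set degradation levels) that
lands the design exactly on a functional motif.

On the full 5-level demo grid, `scan_grid(demo_config())` classifies 2,499
of 390,625 sets (0.64%) as functional under both conditions, 626 as
functional only deterministically and 46 only stochastically, with the rest
(99.2%) failing both.

The command-line wrapper exposes the same stages:

```sh
Rscript inst/cli/kinmotif.R scan --config inst/extdata/demo_config.yaml --out results/
Rscript inst/cli/kinmotif.R handbook --config inst/extdata/demo_config.yaml \
    --scan results/solution_map.tsv --out results/handbook.tsv
Rscript inst/cli/kinmotif.R advise --handbook results/handbook.tsv \
    --levels "33212221" --mode repair --library inst/extdata/parts_demo.tsv
```

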