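# patchadapt

Theory and simulation machinery for **convergent local adaptation to patchy
landscapes**: when a species meets many patches of similar unusual habitat,
does each patch adapt through its own new mutation (parallel, convergent
adaptation), or does one adapted patch export its allele to the others by
migration?

The package is for population geneticists studying spatially restricted
adaptation — heavy-metal tolerance on mine tailings, cryptic coloration on
lava flows, and similar systems — who want quantitative answers to: how long
until a patch adapts by mutation? by migration from a patch at distance
*R*? which route wins, as a function of *R*? and how long a shared
hitchhiking haplotype does a migrant origin leave behind?

## The model in brief

An allele B has advantage *s<sub>p</sub>* inside patches and disadvantage
*s<sub>m</sub>* between them; dispersal is local with RMS displacement σ,
density is ρ, offspring variance ξ², mutation rate μ. Outside a patch B's
equilibrium frequency decays as

&nbsp;&nbsp;&nbsp;&nbsp;q(x) ≈ C (x√(2s<sub>m</sub>)/σ)^(−(d−1)/2) · exp(−x√(2s<sub>m</sub>)/σ),

so the **characteristic length** σ/√(2s<sub>m</sub>) sets every spatial
scale. Adaptation by mutation occurs at rate λ<sub>mut</sub> =
2s<sub>p</sub>ρAμ/ξ²; adaptation by migration at distance R at rate
λ<sub>mig</sub>(R) ∝ ρA′ s<sub>m</sub> min(s<sub>m</sub>, p<sub>e</sub>)
e^(−R√(2s<sub>m</sub>)/σ). Their competition gives the probability of
parallel adaptation, which rises logistically in R and crosses 1/2 at the
critical gap

&nbsp;&nbsp;&nbsp;&nbsp;R/σ = log(2γs<sub>m</sub>/(wμ)) / √(2s<sub>m</sub>).

Beyond the closed forms, the package provides numerical
establishment-probability profiles on a deme lattice (generating-function
fixed point), steady-state migration–selection cline solvers, a
killed-Brownian transit model for migrant trunk lineages (transit times and
hitchhiking-haplotype lengths), a forward-time counts-level lattice
simulator with backward lineage tracing, and a multi-patch colonization
Markov chain with its Ewens-sampling island-model limit.

## Worked example

How far apart must two dark lava flows be for the rock pocket mouse to
evolve dark coats twice, independently?

```r
library(patchadapt)

# strong selection against the dark allele on light rock:
# cline width sigma/sqrt(s_m) ~ 3 km with sigma ~ 1 km
as.numeric(critical_gap_distance(s_m = 0.05, mu = 1e-5, w = 10))
#> [1] 21.84424

tab <- reproduce_fig7(R_km = c(20, 50, 100, 200))
subset(tab, s_m > 0.1 & mu == 1e-8)
#>  R_km       s_m    mu prob_parallel expected_haplotype_cM
#>    20 0.1111111 1e-08    0.00263045             2.6070226
#>    50 0.1111111 1e-08    0.99972656             0.9828090
#>   100 0.1111111 1e-08    1.00000000             0.4814045
#>   200 0.1111111 1e-08    1.00000000             0.2382023
```

With a one-base-pair mutational target (μ = 10⁻⁸) and the 3-km cline
width, patches 20 km apart almost surely share one origin by migration
(parallel probability 0.003), while patches 50 km apart almost surely adapt
independently. When migration does carry the allele 20 km, the newly
founded patch initially shares a haplotype of about 2.6 cM around the
selected site — a detectable genomic footprint — shrinking to a fraction of
a centimorgan over 100 km.

The same machinery runs from the shell via the thin CLI in
`exec/patchadapt` (subcommands `theory`, `establish`, `cline`, `transit`,
`simulate`, `multipatch`, `fixtures`, `fig7`; every run writes a manifest
with the config hash and seed).

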