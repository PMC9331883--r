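# LiPDARTS

Label-free drug-target deconvolution in R: DARTS protection scoring to
find *which* protein a small molecule binds, and targeted limited
proteolysis (t-LiP-MRM) to find *where* it binds, plus the surrounding
quantitative pharmacology (GI50 fitting, PAMPA permeability, coupled
enzymatic kinetics, docking free-energy to Kd conversion). Everything is
driven by a seeded synthetic-data generator with planted ground truth,
so the full inference chain is testable without instrument data.

## The science in brief

**DARTS.** Ligand binding shields a target protein from limited
proteolysis. With identification scores from an undigested control
(`S_u`), a vehicle digest (`S_v`) and a ligand-dosed digest (`S_d`), the
per-replicate protection percentage is

```
protection = 100 * (S_d - S_v) / (S_u - S_v),   clipped to [0, 100]
```

Candidate targets must be protected in **every** replicate (the Venn
partition of per-replicate protected sets is reported), then ranked by
mean protection across doses and replicates.

**t-LiP-MRM.** After subtilisin limited proteolysis and full tryptic
digestion, fully tryptic peptide areas (by MRM) drop wherever subtilisin
could cut. Peptides whose double-digest area is significantly below the
trypsin-only control are *LiP peptides* (one-sided Welch t-test on log2
areas); a LiP peptide with fold change
`FC = mean(area | ligand) / mean(area | vehicle) >= 1.5` at `p <= 0.05`
is called protected. Protected peptides are merged and intersected with a
structural annotation track (domains, interface helices, the gate loop,
key residues).

**Pharmacology.** `% growth = 100 (T - T0)/(C - T0)`; GI50 is read off a
four-parameter logistic fit where it crosses 50%. PAMPA:
`Pe = -ln(1 - C_A(t)/C_eq) * V_D V_A / ((V_D + V_A) A t)`, reported as
`-log10 Pe`. Docking: `Kd = exp(dG / RT)`.

## Worked example

```r
library(LiPDARTS)

## --- DARTS: find the target --------------------------------------------
sim  <- simulateDartsTables(seed = 11, nProteins = 100, nTargets = 1)
ptab <- protectionTable(sim$tables)
venn <- intersectReplicates(ptab, floor = 20)
rk   <- rankTargets(ptab, venn$intersection)
sim$truth$target_ids   # "prot0034"
head(rk, 2)
#>   protein_id mean_protection n_replicates_protected doses_protected mean_at_1 mean_at_10 mean_at_100
#> 1   prot0034            61.4                      3        1,10,100      24.6       74.7        85.0
#> 2   prot0039            21.8                      3        1,10,100      21.1       20.9        23.5

## --- t-LiP-MRM: find the binding region --------------------------------
prot <- makeProtein(11)                       # 900-residue synthetic protein
tl   <- simulateTlipAreas(seed = 11, protein = prot)
pip  <- tlipPipeline(tl$areas, prot, tl$peptides)
pip$report
#> RegionReport for 'SYNPYGB': 3 protected interval(s)
#>   68-81, 210-227, 282-294
#>   6 annotation overlap(s):
#>     68-81 ~ N_domain (domain, 14 residues)
#>     68-81 ~ helix_2 (helix, 10 residues)
#>     68-81 ~ Tyr75 (residue, 1 residue)
#>     ...

## --- docking energetics -------------------------------------------------
kdFromDg(-7.884) * 1e6
#> [1] 1.652215   # predicted Kd in uM at 298 K
```

The planted target ranks first with ~61% mean protection against a <25%
background, and the recovered protected intervals are exactly the planted
intervals after snapping to quantifiable tryptic peptides — 68–81 covers
helix 2 and Tyr75, 282–294 covers the gate loop.

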