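# stratlink

Stratified whole-genome pedigree linkage analysis for multiplex-family SNP
studies, of the design used to map susceptibility loci for familial Chiari
Type I Malformation: when a disorder is genetically heterogeneous, a scan
over all families shows little linkage, but restricting to a clinically
coherent subset (for example families with connective-tissue-disorder
comorbidity versus without) can concentrate the signal — and the resulting
increase in LOD scores needs an empirical significance test, because the
analyst chose the best-looking stratum.

The package provides, end to end:

* **Data model and I/O** — PLINK/LINKAGE-dialect PED and MAP files,
  validated loop-free pedigrees, pedigree trimming, founder-based allele
  frequency estimation, Haldane/Kosambi map functions.
* **QC cascade** — call rate, cross-batch presence, Mendelian-error family
  fraction, MAF and exact Hardy–Weinberg test in unaffected founders,
  map-position filters, whole-family masking of Mendelian-inconsistent
  markers, method-of-moments inbreeding F screen, multipoint map thinning.
* **Linkage engines** — exact Elston–Stewart two-point LOD over phased
  two-locus genotypes with LOD(θ) = log10 L(θ) − log10 L(0.5); Smith
  admixture HLOD with α̂; Lander–Green inheritance-vector HMM for
  multipoint; Whittemore–Halpern S_all with exact enumerated null moments;
  Kong–Cox linear and exponential allele-sharing LODs; inter-marker LD
  clustering (r² ≥ 0.16) with EM haplotype frequencies; likelihood-ratio
  genotyping-error detection; 1-LOD-down support intervals.
* **Stratified inference** — clinical-condition stratification and the
  conditional half-split permutation test giving chromosome-wide and
  genome-wide empirical p-values for the six model × scope combinations.
* **Power** — SIMLINK-style Monte-Carlo power conditional on observed
  phenotypes, via exact rejection-free sampling of disease genotypes.
* **Variant follow-up** — the three-criterion triage of sequencing
  variants under linkage peaks and per-family segregation / reduced
  penetrance classification.
* **Synthetic cohorts** — a generator with planted QC defects and a truth
  ledger, so the whole pipeline is testable without any private genotypes.

## Worked example

A two-stratum synthetic cohort: 12 "CTD-positive" families unlinked
everywhere, 12 "CTD-negative" families linked at 4 cM on chromosome 1.

```r
library(stratlink)

coh <- generate_heterogeneity_cohort(
  n_a = 12, n_b = 12, locus_a = NULL, locus_b = list(chrom = "1", cm = 4),
  spec = cohort_spec(n_chrom = 2, markers_per_chrom = 5, spacing_cm = 2,
                     maf_mean = 0.5, maf_sd = 0.01),
  seed = 7)

qc  <- snp_filter_cascade(coh$peds, coh$map, qc_thresholds(),
                          batches = coh$batches)
cfg <- scan_config(models = c("par_mp", "npl_lin_mp"), step_cm = 1)
sc  <- linkage_scan(coh$peds, qc$map, cfg, masked = qc$masked)
st  <- stratify(coh$peds, coh$flags)
#> stratify: 12 positive, 12 negative families

obs_all <- aggregate_scan(sc)
obs_neg <- aggregate_scan(sc, names(st$negative))
round(obs_all$chrom_max, 3)
#>                1     2
#> par_mp     2.408 0.217
#> npl_lin_mp 0.547 0.016
round(obs_neg$chrom_max, 3)
#>                1 2
#> par_mp     3.202 0
#> npl_lin_mp 2.052 0
```

Restricting to the linked stratum raises the chromosome-1 multipoint HLOD
from 2.41 to 3.20 (the Kong–Cox linear LOD from 0.55 to 2.05). Is that
rise more than an arbitrary half of the families would show?

```r
pd <- conditional_permutation(sc, obs_neg, reps = 100, seed = 7)
pd
#> <perm_dist> 100 repetitions (200 draws)
#>   par_mp      observed GW max  3.202  p_emp 0.01493
#>   npl_lin_mp  observed GW max  2.052  p_emp 0.00995
```

With 200 half-split draws, fewer than 2% reach the observed stratum
maximum (add-one empirical p ≈ 0.015 and 0.010), so the stratified signal
is not an artifact of picking a favourable subset. The candidate region:

```r
tab  <- obs_neg$tables$par_mp
chr1 <- tab[tab$chrom == "1", ]
si <- support_interval(chr1$pos_cm, chr1$stat,
                       map = qc$map[qc$map$chrom == "1", ])
cat(sprintf("1-LOD support interval: chr1 %.1f-%.1f cM (peak %.1f, HLOD %.2f)\n",
            si$start_cm, si$end_cm, si$peak_cm, si$max_lod))
#> 1-LOD support interval: chr1 0.0-8.0 cM (peak 4.0, HLOD 3.20)
```

Note the peak sits at the planted locus (4 cM). At this desk scale a
dozen small families have essentially no power for LOD > 3 at a single
marker (`estimate_power()` on this stratum reports 0.00 at 100
replicates); high power at this threshold requires a
full-size cohort of 66 real multiplex families.

## Command line

```sh
Rscript -e 'stratlink::pipeline_main()' run-all --seed 1 --out /tmp/run
```

Subcommands `simulate | qc | linkage | stratify | permute | power |
variants | run-all`; flat `key = value` config files with `[section]`
headers via `--config`; every run writes a `manifest.json` with stage
outputs, seeds, and timings.
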