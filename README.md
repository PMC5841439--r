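# spliceDAS

Differential alternative splicing (DAS) analysis for bulk RNA-Seq, with
cross-species conservation calling and splicing-factor discovery by
splicing-signature connectivity mapping.

The package is aimed at transcriptomics analysts who want to go from a
transcript annotation and per-sample read evidence to (i) a catalog of
alternative-splicing events, (ii) per-event tests of differential isoform
usage between two sample groups, (iii) calls of which events are conserved
between two species (e.g. a mouse disease model and human patients), and
(iv) a ranked list of candidate splicing factors whose perturbation
signatures match the disease signature. A seeded synthetic two-species
generator with planted ground truth makes the whole pipeline testable at
desk scale.

## The model

Events of seven types are enumerated from pairwise transcript comparison
within each gene: exon skipping (ES), alternative 5'/3' splice sites
(A5SS/A3SS), mutually exclusive exons (ME), intron retention (IR), and
alternative first/last exons (AFE/ALE). Each event has two isoforms; reads
are assigned by junction-anchored counting, giving per-sample counts
(n_inc, n_exc) supporting the inclusion (longer, or proximal for AFE/ALE)
and exclusion isoforms.

Percent spliced in is the pooled isoform-usage fraction per group,

    Psi_g = sum_s n_inc,s / sum_s (n_inc,s + n_exc,s),    dPsi = Psi_case − Psi_ctrl.

Counts are modeled per event by a beta-binomial — the two-isoform
specialization of the Dirichlet-Multinomial — with inclusion proportion p
and precision theta (= alpha + beta):

    n_inc,s | n_s ~ BetaBin(n_s, p_g(s), theta).

One precision is shared across events, estimated by maximizing the
Cox–Reid adjusted profile likelihood (per-event group proportions profiled
out and penalized by half the log observed information). The group effect
is tested per event by a likelihood-ratio test of `p_case = p_ctrl` against
free group proportions at that precision, with a chi-square (df = 1)
reference; p-values are Benjamini–Hochberg adjusted, and an event is called
DAS when `|dPsi| > 0.05` and `q < 0.05` (both strict).

Conservation calling maps gene symbols across species (HomoloGene-format
input), tests the overlap of DAS gene sets by a one-sided Fisher exact test
over the homologous expressed background, and, for ES events, aligns the
four cross-species isoform sequence pairings (Needleman–Wunsch, affine
gaps; translated protein when the event lies in annotated CDS on both
isoforms). An event pair is PSI-consistent when dPsi has the same non-zero
sign in both species **and** the straight isoform pairing wins
(label `both`, not `cross_matched`).

Splicing-factor screening encodes each dataset as a signature of +/−/0 per
event (direction-aware for knockout/knockdown/overexpression, and oriented
by the factor's own expression change in disease), tabulates the 3×3 table
over common events, collapses it to 2×2 tables for ++ and −− agreement,
and calls a factor a candidate when both one-sided Fisher tests are
significant. Term enrichment uses Fisher's exact test with an
odds-ratio-threshold null (H0: log OR < 1, i.e. OR < e).

## Worked example

```r
library(spliceDAS)

cfg    <- sim_config(seed = 20, events_per_type = 3, theta = 50,
                     depth_mean = 150, planted_frac = 0.2)
sim    <- simulate_annotation(cfg)           # annotation + genome + truth
events <- enumerate_events(sim$annotation)
table(events$event_type)
#> A3SS A5SS  AFE  ALE   ES   IR   ME
#>    3    3    3    3    3    3    3

counts <- simulate_counts(cfg, events)$counts
fit    <- das_test(counts, case = "case", control = "control", events = events)
summary(fit)
#> DAS summary ( case vs control ): 1 of 21 events significant
#>  event_type n_das
#>          ES     0
#>        A5SS     0
#>        A3SS     0
#>          ME     0
#>          IR     1
#>         AFE     0
#>         ALE     0
```

The top event is a retained intron with `dPsi = -0.22`,
`p = 1.5e-09`, `q = 3.1e-08`: the case group includes the intron in 3.8% of
transcripts against 26.3% in controls, a strong exclusion shift. One of
four planted effects survives both thresholds at this tiny depth and event
count; recall rises above 0.95 at the package's default study scale (1000
events, depth 200 — see the methods vignette).

Cross-species consistency on the packaged 24-row conserved-event table:

```r
tab    <- table1_fixture()
called <- call_psi_consistency(tab$dpsi_a, tab$dpsi_b, tab$conservation)
sum(called == "Y")
#> [1] 18
summarize_conserved(transform(tab, psi_consistency = called))$n_large_both
#> [1] 8
overlap_enrichment(venn_counts(89, 578, 518, 12233))$p
#> [1] 3.162996e-18
```

Eighteen of the 24 events are conserved in the same isoform; eight of those
shift by more than 10% PSI in both species. The homolog-overlap Fisher test
on the 89/578/518 Venn over 12,233 background genes gives p ≈ 3.2e-18
(odds ratio ≈ 3.3) — overwhelming enrichment of shared DAS genes.

The full simulated two-species pipeline, writing TSVs and a hashed run
manifest:

```r
run_pipeline("out/", sim_config(seed = 1))
```

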