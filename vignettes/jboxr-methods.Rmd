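---
title: "Methods: knockout time-course regulon inference and the J-Box promoter model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knockout time-course regulon inference and the J-Box promoter model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`jboxr` analyses a knockout time-course transcriptome design: a wild-type
cyanobacterial strain and three sigma-factor deletion strains (`dsigJ`,
`dsigC`, `dsigF`) sampled at 0, 1, 6, 12 and 18 h after hormogonium
induction, with three biological replicates each. This vignette records the
models, the tunable parameters, the numerical choices, and what the
synthetic data do and do not establish.

## Expression model and normalization

Counts are depth-corrected by **upper-quartile scaling**: each sample is
multiplied by a factor that brings the 75th percentile of its nonzero values
to the geometric mean of those percentiles across samples. The operation is
idempotent and scale-equivariant, and every downstream statistic consumes
only ratios, so any monotone per-sample scaling would feed the pipeline the
same shapes. Its known weakness is **composition bias**: when more than half
the transcriptome moves (here, 1134 of 2000 simulated genes), the upper
quartile moves with it, and genes that are truly flat acquire a small
apparent trajectory. See *Limitations*.

The working quantity is the **ratio to baseline**,

    log2( (x + c) / (baseline + c) ),

where `baseline` is the mean of the wild-type 0-h replicates for the gene
and `c` is a pseudocount, default `c = 1` normalized unit (the zero-handling
rule is otherwise undefined; 1 unit is small against typical baselines of
2^4..2^9). Replicate-level ratios feed the tests; displayed and ranked
profiles average the *values* within strain × time before the ratio, so the
wild-type 0-h profile is exactly 0 at `c = 0`.

## Differential expression

The published analysis used a Bayesian time-series tool whose model cannot
be reproduced from its description; `jboxr` substitutes a deterministic
**moderated-F** procedure (limma):

* wild-type course: quadratic-in-time fit versus constant, F on the two
  time coefficients;
* strain differences: strain-specific curve (intercept + both time terms)
  versus a shared curve, F on the three strain-involving coefficients —
  this also catches pure basal shifts, which a strict interaction test
  would miss;
* empirical-Bayes variance shrinkage across genes, BH adjustment per
  family, flags at `q <= fdr` with `fdr = 0.05` by default (the original
  threshold is unstated; 0.05 is the field's default).

Time enters scaled to `[0, 1]` (`t/18`) to keep the design well
conditioned. A quadratic basis cannot follow a sigmoid exactly, but the
test only asks whether the curve is non-constant (or strain-specific), for
which two curvature degrees of freedom are ample at five time points.

## Regulon assignment

A gene differentially expressed in the wild-type course is `shared` when no
deletion strain differs from the wild type; otherwise it joins the regulon
of the sigma factor whose deletion produced the greatest change, measured
by the **L2 norm** of (strain mean profile − wild-type mean profile) over
all five time points. Two deliberate choices:

* **Ranking is restricted to strains whose difference test is
  significant.** The alternative (ranking all three) lets a large but
  insignificant noise norm win. The wording of the original rule is
  ambiguous on this point; the restriction is this package's choice.
* **Exact ties break by the fixed precedence sigJ > sigC > sigF**, flagged
  in the output and warned about. Ties have measure zero on real data but
  the classifier must be a function.

Direction (`up`/`down`) is taken from the wild-type course, not from the
knockout contrast.

## Clustering

Within each category, genes are clustered by **UPGMA** (unweighted average
linkage) on Euclidean distances between concatenated 4-strain × 5-time mean
profiles (20 values; the distance metric of the original GUI tool is
unstated). Merge heights follow the classical convention (half the average
pairwise distance), so cophenetic distances equal average distances.
Cluster numbering automates a manual step: maximal subtrees with cophenetic
diameter ≤ `height` (default 2 log2 units, chosen from planted-separation
tests on synthetic data where distinct amplitude groups sit ≥ 4 units
apart and within-group noise spreads ~1.3) are numbered in leaf order when
they hold ≥ `min_size = 5` genes; smaller groups stay unnumbered.

## Promoters and coordinates

Only **monocistronic genes and operon leaders** keep their upstream region;
other operon members are dropped (genes with no operon annotation are kept,
with a warning, since their status needs manual review). Promoter windows
span −60..+20 around the annotated TSS on the coding strand. Coordinates
are 1-based genomic; relative coordinates have **no position 0** (+1 is the
TSS base, −1 abuts it). One arithmetic wrinkle is inherited from the
source material: a −60..+20 window without a zero contains 80 coordinates,
but the span is defined genomically as `[tss − 60, tss + 20]` = 81 bases;
`jboxr` keeps the 81-base span, whose downstream edge is relative
coordinate +21.

## Motif discovery

`discover_motif()` is a **ZOOPS EM** (zero-or-one occurrence per sequence):

* fixed 0-order background from the pooled input;
* seeds are the w-mers present in the data, ranked recurrent-first and
  capped at `max_seeds = 1000`; each seed PWM (0.5 on the seed base) is
  scored by one likelihood pass, and the top 5 are refined to convergence
  (tolerance 1e-6 relative log-likelihood, ≤ 200 iterations);
* both strands are searched; the fitted model is reported in its majority
  orientation (the both-strand likelihood is exactly symmetric under
  reverse complementation of the PWM, so the representative is a
  convention);
* M-step pseudocount 0.1 per cell; a site is called when a sequence's
  posterior probability of containing the motif is ≥ 0.5;
* a model is reported only when ≥ 50 % of the sequences carry a called
  site in the same orientation (`min_orientation_frac`), mirroring the
  original reporting rule for cluster promoter sets.

No significance machinery (E-values) is attached; model quality is read
from the log-likelihood ratio and the information content. On i.i.d. random
81-mers the fitted PWM carries ≈ 0.87 bits per column — the selection-bias
floor `log2(2·73)/9` from choosing the best of ~146 windows per strand per
sequence — while a genuinely planted 9-mer approaches the 2-bit ceiling.
Interpretation of discovered motifs should therefore rest on the gap above
that floor, not on absolute information content.

## The consensus promoter and the J-Box

Called sites are aligned by **anchoring on the first G of the GGG trio**
inside each site (sites lacking the trio are errors), which makes the
alignment robust to the ±1-column phase ambiguity of EM. Per-column base
frequencies give information content `IC = 2 + Σ p log2 p` (no small-sample
correction). Elements are annotated from the anchor: the GGG trio is the
extended −10 (`EXT`), the six bases after it are the −10 hexad (`aAtacT`
in the consensus), and the +1 column comes from each sequence's known TSS
position. `tss_motif_offset()` measures the distance from +1 to the hexad
center (third base of six, i.e. the midpoint rounded to the 5′ side); in
the consensus SigJ architecture this is **10 bp**.

The **J-Box scanner** implements the rule "three consecutive Gs, then a
conserved A and T at fixed offsets from the first G". The printed consensus
`GGGaAtacT` places that A at +4 and that T at +8 (0-based from the first
G), and those are the defaults; the alternative literal reading (+2, +7) of
the source text contradicts its own printed consensus, so it is available
only via configuration (`jbox_rule(a_offset = 2, t_offset = 7)`). Scans
run over the 100 bases upstream of the translational start on the coding
strand by default (`anchor = "tss"` switches the anchor), case-insensitive,
reporting all overlapping matches; five constrained positions give an
expected `(1/4)^5` hit rate per position on uniform background.

## qPCR

`ddct_fold_change()` averages the two technical replicates first, forms
`dCt = Ct(target) − Ct(reference)` per biological replicate, subtracts the
mean calibrator `dCt`, and reports `2^−ddCt` per biological replicate with
mean and SD (aggregation order is configurable; per-replicate-then-average
is the default because it yields replicate-level fold changes whose spread
is reportable). Primer efficiency is `10^(−1/slope) − 1` from the
`Ct ~ log10(dilution)` regression, with a 0.90 pass gate.

## The synthetic cascade generator

`simulate_timecourse()` emulates the study conditions: 2000 genes (a
desk-scale stand-in for the ~6.7k-gene genome; regulon sizes stay at their
genome-scale values of 389 sigJ / 300 sigC / 37 sigF / 408 shared, split
up/down as reported, so category proportions are realistic), log2
trajectories rising (or falling) by a **logistic** `A/(1 + e^{−k(t−τ)})`
with mean amplitude `A = 3` log2 units, onset `τ = 5 h`, steepness
`k = 0.7 /h`, and 20 % relative jitter on `A` and `τ`; counts are
negative-binomial with dispersion 0.05 around depth-scaled means (depth
factors lognormal, CV 0.1). A smooth monotone rise is the simplest shape
consistent with the published heat maps, which show no functional form.

The knockout structure encodes the hierarchy:

* `dsigJ` abolishes induction of sigJ-, sigC- and sigF-regulon genes
  (everything below SigJ);
* `dsigC` abolishes induction of sigC-regulon genes and **advances the
  onset by 3 h** for a 30 % subset of the sigJ regulon (the temporally
  shifted clusters; the size of the shift is unreported, so Δτ is a free
  parameter with a visible-but-plausible default);
* `dsigF` affects only the sigF regulon;
* deleting a gene's **direct** regulator additionally moves basal
  expression 1 log2 unit *against* the wild-type response
  (`direct_loss_log2`): induced targets lose basal activation, repressed
  targets are derepressed. Without this term, a sigC-regulon gene would be
  equally perturbed in `dsigJ` and `dsigC` (both abolish its induction)
  and max-L2 ranking would be a coin flip; the term expresses the
  biological asymmetry — loss of the direct regulator perturbs the
  promoter itself — that makes the ranking meaningful.

`simulate_genome()` lays genes on a contig, annotates TSSs 25–60 bp
upstream of translational starts, optionally groups same-strand neighbours
into operons (non-leaders get no TSS), and plants J-Boxes so the first G
sits at −15 relative to the TSS — placing the `aAtacT` center at −10, the
consensus architecture. Required bases (G,G,G, +4 A, +8 T) are written
verbatim; variable positions are drawn consensus-biased (fidelity 0.7)
and never G, keeping the anchor run unique. All scanned windows of
non-planted genes are rejection-sampled free of rule matches.
`simulate_qpcr()` builds the 2-technical × 3-biological Ct layout with a
constant-up-to-noise reference gene.

What the synthetic data do **not** emulate: operon-level count correlation,
gene-length and GC effects, rRNA-depletion artefacts, TSS mis-annotation,
and real promoter background composition. Passing tests demonstrate that
the algorithms implement their definitions and recover planted structure
under realistic noise — not that the biological conclusions transfer to any
particular real data set.

## Reproducibility and problem sizes

Every generator takes an explicit seed and is byte-deterministic;
`run_pipeline()` writes a JSON manifest of all parameters, paths and seeds,
and reruns reproduce identical stage outputs. The shipped tests run the
full default simulation (2000 genes) once, the end-to-end pipeline twice at
300 genes, motif discovery on 20-sequence sets, scanner calibration on 10^6
positions, and the qPCR closed form on 1000 single-gene experiments —
sizes chosen so the whole suite completes in a few minutes on one core.

## Known limitations

* **Composition bias.** With 57 % of genes moving, upper-quartile factors
  at late time points absorb part of the induction, so truly flat genes
  show small apparent trajectories and, in the `dsigJ` contrast (where the
  bulk of the response is absent), systematic strain differences. In the
  default simulation this inflates the *sigJ* category with genes whose
  planted truth is `not_de` or `shared`, while >99 % of genuine
  sigJ/sigC/sigF members are still assigned correctly. A
  reference-gene-based or spike-in normalization would remove this; it is
  kept as-is because the module's contract specifies upper-quartile
  scaling.
* **The DE test is a stand-in.** Gene lists will not match a Bayesian
  time-series analysis call-for-call; downstream logic consumes only flags
  and L2 norms.
* **TSSs come from annotation.** TSS prediction from read coverage is out
  of scope, and the promoter geometry is only as good as the annotated +1.
* **EM finds local optima.** Recurrent-first seeding plus top-5 refinement
  is robust on planted data, but weak or mixed motifs may converge to
  shifted variants; the GGG anchor in consensus building absorbs the
  common ±1 phase error.
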