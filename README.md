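# jboxr

Regulon inference and promoter dissection for the sigma-factor cascade that
drives hormogonium development in filamentous cyanobacteria.

When *Nostoc punctiforme* differentiates its vegetative filaments into
motile hormogonia, a hierarchy of sigma factors — SigJ at the top, with SigC
and SigF beneath it — rewires transcription within hours. `jboxr` implements
the computational analysis of that system for a knockout time-course design:
wild type plus *sigJ*, *sigC* and *sigF* deletion strains sampled across an
induction time course with biological replicates. It is aimed at
microbiologists analysing bacterial knockout time-course RNA-seq and at
anyone who wants a tested, reproducible implementation of the J-Box promoter
model.

## What it computes

* **Ratio-to-baseline profiles.** For every gene, strain and time point,
  `log2(normalized expression / wild-type 0-h mean)`, after upper-quartile
  normalization.
* **Time-course differential expression.** Moderated F-tests (quadratic time
  basis, empirical-Bayes variance shrinkage, Benjamini–Hochberg FDR) for the
  wild-type course and for each strain-versus-wild-type contrast.
* **Regulon assignment by L2 ranking.** Each wild-type-DE gene is classified
  `shared` (no strain differs) or assigned to the sigma factor whose deletion
  produced the largest Euclidean (L2) norm
  `||strain profile − wild-type profile||` among the significantly different
  strains.
* **UPGMA expression clustering** within each regulon, with automatic
  numbering of clusters of ≥ 5 genes.
* **Promoter motif work.** Strand-aware extraction of −60..+20 windows around
  annotated TSSs for operon leaders; de novo ZOOPS EM motif discovery with a
  ≥ 50 % same-orientation reporting gate; a GGG-anchored consensus promoter
  with per-column information content `IC = 2 + Σ p·log2 p`; and a
  parameterized scanner for the J-Box — the extended −10 element with
  consensus `GGGaAtacT`, matched as three consecutive Gs with a conserved A
  (+4) and T (+8) from the first G.
* **qPCR quantification** by 2^−ΔΔCT with reference-gene normalization,
  technical-replicate averaging and primer-efficiency checking.
* **A synthetic cascade generator** that plants all of the above — regulon
  sizes, strain-specific nulling, the ΔsigC temporal shift, negative-binomial
  noise, genomes with J-Boxes planted upstream of TSSs — so the whole
  pipeline is testable end to end.

## Worked example

```r
library(jboxr)

# simulate the default study: 2000 genes, 4 strains x 5 times x 3 replicates
sim    <- simulate_timecourse(cascade_config())
ratios <- ratio_profiles(normalize_uq(sim$dataset))
de     <- de_analysis(ratios, fdr = 0.05)
labels <- assign_regulons(de)
regulon_summary(labels)
#> # A tibble: 5 × 4
#>   category  down    up total
#>   <chr>    <int> <int> <int>
#> 1 not_de     405    70   475
#> 2 shared      35     3    38
#> 3 sigJ       727   427  1154
#> 4 sigC       132   167   299
#> 5 sigF        24    10    34
```

Over 99 % of the planted sigJ/sigC/sigF regulon members receive their true
category (the planted sizes are 389/300/37). The `sigJ` count is inflated by
genes that are flat in truth but appear strain-different after upper-quartile
normalization, because the massive wild-type regulon shift drags the upper
quartile with it — a composition bias discussed in the vignette's
limitations section.

The promoter arm, on a genome fixture with the consensus architecture:

```r
fx     <- simulate_genome(n_genes = 30, planted_fraction = 1, seed = 5)
prom   <- extract_promoters(fx$contigs, select_promoter_genes(fx$features))
model  <- discover_motif(setNames(prom$sequence, prom$gene_id), width = 9)
model$consensus
#> [1] "GGGAATACT"
fw   <- model$sites[model$sites$strand == "+", ]
cons <- build_consensus(setNames(prom$sequence, prom$gene_id)[fw$seq_id],
                        fw$start, tss_pos = 61)
tss_motif_offset(cons)
#> [1] 10
```

The 10 is the signature geometry of the consensus SigJ promoter: the TSS
lies exactly 10 bp downstream of the center of the `aAtacT` hexad.

`run_pipeline(out_dir, cascade_config())` chains every stage, writes all
stage outputs as TSV/FASTA/GFF3 plus a JSON run manifest, and is
byte-for-byte reproducible for a given seed.

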