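# hybridADE

Allelic differential expression (ADE) from full-length long-read RNA-seq
in interspecies F1 hybrids of cattle (*Bos taurus*) and yak
(*Bos grunniens*).

An F1 hybrid carries one haploid genome from each parental species, and
the two genomes differ at roughly 1.2% of sites. A full-length cDNA read
therefore covers many interspecies SNPs and can be attributed to its
parental haplotype as a whole molecule — the per-gene tallies of cattle-
vs yak-origin reads are direct measurements of allelic expression.
`hybridADE` implements the complete analysis:

1. **Reference scaffold** — merge homologous blocks from a whole-genome
   alignment (PAF), restrict interspecies SNPs (VCF) to them, N-mask the
   SNP positions in the cattle-coordinate genome (FASTA) so neither
   allele has a mapping advantage, and keep only genes (GFF3) lying
   inside homologous sequence.
2. **Per-read origin** — walk each aligned read's CIGAR (SAM), collect
   the bases it shows at interspecies SNPs, and call the parental origin
   by majority vote (ties are ambiguous and discarded).
3. **Quantification** — per-gene tallies of cattle/yak/SNP-free reads;
   SNP-free reads are redistributed in the gene's informative ratio
   (counts *c*, *y*, with *u* SNP-free reads, become
   *c*(1 + *u*/(*c*+*y*)) and *y*(1 + *u*/(*c*+*y*))); expression is
   reported as CPM; genes need ≥ 3 reads to be testable.
4. **ADE test** — two-sided Fisher's exact test of the gene's allelic
   counts against the rest of the library's allelic counts, significant
   when fold change > 2 **and** p < 0.05.
5. **Classification** — a gene shows *ubiquitous* ADE in a tissue when
   it is significant in every animal of that tissue; ubiquitous genes
   are classed yak-favoring, cattle-favoring, or variable, and by tissue
   pattern (lung-only / liver-only / both).

A truth-annotated simulator generates parental genomes, SNP catalog,
spliced gene models, homology PAF and per-sample SAM files of
error-bearing full-length reads, so the entire pipeline runs and is
validated without any external data.

## Worked example

Simulate a small cohort (3 animals × lung/liver, 40 genes, 25% of them
with true ADE) and run the whole analysis:

```r
library(hybridADE)

cfg <- simulationConfig(nGenes = 40, chromLength = 1.2e5L, nAnimals = 3,
                        adeFraction = 0.25)
sim <- simulateDataset(cfg, "readme_sim", seed = 42)
res <- runPipeline("readme_sim", "readme_out", seed = 42)
cat(res$log, sep = "\n")
```

```
stage=build-ref blocks=4 homologousFraction=0.94 snpsRetained=2777 genesRetained=38 genesExcluded=2
stage=assign sample=F1 parsed=1693 nonPrimary=0 assigned=1658 noGene=35
...
stage=quantify genes=38 samples=6 meanKept=38
stage=test tested=228 significant=39
stage=classify ubiquitous=5
```

94% of the simulated genome is homologous (the rest is a
species-specific tract whose 2 genes are excluded), every read parsed is
accounted for (`parsed = nonPrimary + assigned + noGene`), and 228
(gene, sample) pairs were tested. The summary:

```r
print(res$summary)
#>                metric count
#> 1      ade_any_sample    14
#> 2    ubiquitous_total     5
#> 3     ubiquitous_lung     2
#> 4    ubiquitous_liver     5
#> 5       direction_yak     3
#> 6    direction_cattle     2
#> 7  direction_variable     0
#> 8   pattern_lung_only     0
#> 9  pattern_liver_only     3
#> 10       pattern_both     2
```

14 genes show ADE in at least one sample; 5 are significant in every
animal of at least one tissue, 3 consistently favoring the yak allele
and 2 the cattle allele (3 + 2 + 0 = 5: the direction classes partition
the ubiquitous set). Per-sample results carry the counts entering each
test:

```r
head(as.data.frame(res$results[res$results$significant, ]), 3)
#>   geneId sampleId cattleCount yakCount foldChange       pValue          bhQ significant direction
#> 1  g0006       F1           5       24   4.800000 3.862368e-03 2.446167e-02        TRUE       YAK
#> 2  g0016       F1          40      121   3.025000 1.632708e-07 3.102145e-06        TRUE       YAK
#> 3  g0018       F1           4        0        Inf 3.740682e-02 2.030656e-01        TRUE    CATTLE
```

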