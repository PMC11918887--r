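# tp53cll

Analysis toolkit for the mutational architecture of *TP53* in chronic
lymphocytic leukemia (CLL).

*TP53* status decides treatment in CLL, and CLL mutates *TP53* unlike any
other cancer: patients frequently carry **several distinct TP53 variants**
(often at 1–5% variant allele frequency, below the reach of Sanger
sequencing), the variants sit in **trans** — on different alleles or in
independent subclones — and a few hotspots are essentially CLL-specific: the
dinucleotide deletion `c.626_627del` (p.Arg209LysfsTer6) inside an
inverted-repeat hairpin context, the treatment-associated codon 234
missense `c.700T>C` (p.Tyr234His), and the intron 6 acceptor substitutions
`c.673-2A>G/T/C` that re-route splicing to a cryptic acceptor 49 nt
upstream, producing a p53psi-type truncated isoform.  The package is aimed
at hematology/molecular-diagnostics groups who hold such cohort tables in
HGVS notation and want the full downstream analysis to be reproducible.

It provides, on transcript NM_000546 / protein NP_000537:

* an **HGVS c. engine** — parsing, 3'-normalization, classification
  (missense / nonsense / synonymous / frameshift / inframe / splice),
  six-class mutational events (GC>AT, AT>GC, …) with CpG context;
* **cohort statistics** — class and event spectra, per-patient
  multiclonality (SM/DM/MM3/MM4plus), cumulated VAF, the 1–5% low-VAF
  census, hotspot enrichment (χ² = Σ(O−E)²/E on the 2×2, Fisher fallback),
  frameshift-codon and splice-signal distributions, rank-sum VAF
  comparisons;
* **protein consequences** — frameshift translation with HGVS p. naming
  (`p.XposYfsTerN`), nonsense truncation, and cryptic-acceptor splice
  outcome construction (retained intronic segment, shifted-frame stop);
* **read-backed phasing** — cis/trans decisions from doubly-called reads
  with a binomial error bound, and whole-amplicon allele reconstruction
  from long reads (SAM via Rsamtools, or a simple call table);
* **CN-LOH inference** — SNP-panel genotyping and the dominant-clone
  decision rule (VAF > 50%, no del(17p), all informative SNPs homozygous);
* a **seeded simulator** for cohorts, reads and SNP profiles with the
  clonal structure the analyses assume (per-patient clone fractions sum to
  ≤ 100, so cumulated VAF can never exceed 100%).

## Worked example

```r
library(tp53cll)
model <- tp53_model()          # packaged NM_000546 model, 393-aa protein

classify_variant("NM_000546_c.700T>C", model)
#> <variant_annotation> c.700T>C: missense, codon 234, p.Tyr234His
#>   event: AT>GC

translate_frameshift("c.626_627del", model)
#> <protein_consequence> p.Arg209LysfsTer6 [truncated]
#>   product: 213 aa; novel C-terminus: KHFST

predict_splice_outcome("c.673-2A>G", model)
#> <splice_outcome> intron6_acceptor: cryptic acceptor 49 nt upstream; 49 nt retained
#> <protein_consequence> p.Val225SerfsTer20 [psi_like]
#>   product: 243 aa; novel C-terminus: SFASLCLAVLRSGSGPGWL
```

The frameshift keeps the reference through Arg208, substitutes Lys at 209,
adds five novel residues (`KHFST`) and stops — exactly what
`p.Arg209LysfsTer6` encodes.  The acceptor variant retains 49 intronic
nucleotides, shifting exon 7's frame so translation stops three codons in:
the p53psi architecture.

Cohort-level, on a simulated 683-patient cohort (511 NGS / 172 Sanger):

```r
sim <- simulate_cohort(n_patients = 683, seed = 20230509)
co  <- load_cohort(sim$table, model)
class_spectrum(co)[1:2, ]
#>    var_class   n proportion
#> 1   missense 727  0.7183794
#> 2 frameshift 123  0.1215415
multiclonality(co)$histogram
#>     label   n
#> 1      SM 356
#> 2      DM  68
#> 3     MM3  54
#> 4 MM4plus  33
max(cumulated_vaf(co)$cum_vaf)
#> [1] 99.5
```

About a third of NGS patients are multi-mutated, the modal frameshift is
`c.626_627del`, the intron 6 acceptor dominates the splice variants, and
no patient's VAFs sum past 100%.  The numbered scripts under `analysis/`
(`01_simulate_cohort.R` … `07_consequences.R`) walk the full workflow —
simulation, spectra, hotspots, multiclonality/VAF, phasing, CN-LOH,
consequences — writing their tables under `results/`.

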