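---
title: "TP53 mutation architecture in CLL: models, rules and simulation design"
author: "tp53cll"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TP53 mutation architecture in CLL: models, rules and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tp53cll)
```

# The problem

TP53 disruption is the strongest predictive marker in chronic lymphocytic
leukemia (CLL): mutated or deleted TP53 predicts failure of
chemoimmunotherapy and redirects patients toward targeted agents.  CLL is
also an outlier among cancers in *how* TP53 is mutated: many patients carry
several distinct TP53 variants at once, often at very low variant allele
frequency (VAF), and a handful of hotspot variants are essentially
CLL-specific — a dinucleotide deletion at codon 209, a treatment-associated
missense at codon 234, and substitutions in the intron 6 splice acceptor.
This package implements the cohort analysis that characterises this
architecture: HGVS variant parsing and classification on the major
transcript NM_000546, mutation spectra, hotspot enrichment, per-patient
multiclonality and cumulated VAF, read-backed cis/trans phasing, SNP-based
copy-neutral loss of heterozygosity (CN-LOH) inference, and protein-level
consequence prediction including the cryptic-acceptor (p53psi-type)
isoform.

# Coordinate system and reference model

All coordinates are HGVS cDNA coordinates on NM_000546: position 1 is the A
of the start codon, intronic positions are written `anchor+offset` /
`anchor-offset`, and 5' UTR positions are negative.  Genomic coordinates
are never exposed; the cohort literature reports exclusively in
NM_000546/NP_000537 terms.

The packaged model carries the 1,182-nt coding sequence (393-residue
protein), ten coding-exon spans (gene exons 2–11; exon 1 is non-coding) and
the ten-intron splice catalogue — two signals per intron (donor +1/+2,
acceptor −2/−1), hence exactly twenty signals.  Intron 1 lies in the 5'
UTR; its anchors are placed at c.-29/c.-28, i.e. 28 nt upstream of the
start codon, consistent with a 202-nt 5' UTR of which 174 nt form exon 1.

Intron sequences are optional.  Only intron 6 ships with sequence, because
only the intron 6 acceptor outcome is modelled at nucleotide level.  The
shipped intron 6 is a **synthetic stand-in**
(`inst/extdata/tp53_intron6_synthetic.fa`): a 120-nt sequence built to the
documented architecture — canonical GT/AG termini, a cryptic acceptor AG
dinucleotide exactly 49 nt upstream of the exon 7 junction, no competing AG
and no in-frame stop inside the retained segment.  Everything downstream of
the junction (the shifted-frame stop at the start of exon 7) follows from
the *real* exon 7 sequence, so the p53psi-type product architecture is
faithful even though the intronic filler is not the genomic sequence.
Models loaded from user-supplied FASTA/TSV records can replace it.

# Variant grammar and classification

The HGVS engine parses the subset of the c. grammar that cohort tables
actually use: substitutions (`c.700T>C`, `c.673-2A>G`, `c.-29+1G>A`),
deletions, duplications, insertions and delins.  Inversions, conversions
and protein-level input are rejected explicitly.  Parsing is lossless
(`parse(format(v))` is the identity on canonical strings) and indels are
normalized to their 3'-most equivalent position, the HGVS rule, so that
duplicate entries written at different positions of a repeat unify before
counting.  Disabling normalization is possible (`normalize = FALSE`)
because cohorts differ in whether they pre-normalized.

Classification follows fixed rules: intronic offsets ±1/±2 are `splice`
(and are attached to their catalogue signal), deeper intronic positions are
`intronic_other`; exonic substitutions are `missense`/`nonsense`/
`synonymous` by codon translation; exonic indels are `frameshift` when the
net length change is not a multiple of 3, else `inframe_indel`.
Substitutions collapse onto the strand-symmetric six-class event spectrum
(GC>AT, AT>GC, GC>TA, GC>CG, AT>TA, AT>CG) — the granularity at which the
CLL-specific AT>GC excess is visible — with a CpG flag for C>T/G>A changes
in CG context.  The 96-class signature taxonomy is deliberately out of
scope.  Reference-allele mismatches are hard errors, not warnings: a silent
mismatch would corrupt every downstream count.  Pathogenicity labels
(P/LP/VUS/LB/B) are consumed from the input, never derived; deriving them
requires database curation outside this package's scope.

# Protein consequences

Frameshift translation applies the edit to the CDS, translates the shifted
frame to its first stop, and names the product per HGVS
(`p.Arg209LysfsTer6`: first changed residue Arg209→Lys, stop at the sixth
position counting from it, hence exactly five novel residues).  When the
first novel residue coincides with the reference, the name shifts to the
first differing residue; when no stop is reached the name carries `fsTer?`
and an explicit flag.  Nonsense substitutions truncate the reference
protein before the new stop.  Naming is self-inverse: re-deriving the name
from (reference, product) reproduces it, and a brute-force
mutate-translate-diff oracle checks both the products and the names on
hundreds of random coding sequences in the test suite.

For acceptor-signal substitutions the model is re-routing to a cryptic
acceptor: the intronic 3' segment between the cryptic AG and the exon is
retained in the transcript (including the disrupting mutation itself) and
translation proceeds through it.  The default rule is `fixed_offset = 49`,
the experimentally supported TP53 intron 6 site; a `scan` mode (nearest
surviving upstream AG, ties toward the canonical site) exists for synthetic
genes and returns the canonical acceptor when nothing is disrupted.  A
product is tagged `psi_like` by a structural rule only: the retention
shifts the reading frame and the new stop falls inside the retained
segment or within the first 90 nt of the downstream exon.  For TP53 this
reproduces the p53psi architecture — 49 retained nucleotides (49 mod 3 =
1), sixteen intron-derived codons, and a stop three codons into exon 7's
shifted frame.  Whether the codon 209 frameshift product is *functionally*
psi-like is a biological hypothesis; it is therefore tagged `truncated`,
not `psi_like`.  Donor-site outcomes, NMD and RNA-level validation are out
of scope.

# Cohort statistics and their denominators

The denominators are fixed explicitly because cohort papers mix them:

* class and event spectra are per **variant** (events per substitution);
* multiclonality (SM/DM/MM3/MM4plus) is per **patient**, on the NGS subset
  only, since Sanger cannot resolve low-VAF clones;
* hotspot shares are per **class subset**: c.626_627del among frameshifts,
  c.673-2 among splice variants;
* the low-VAF census reports both patient-level and variant-level counts
  for the band, split by single- versus multi-mutated patients.  The band
  is closed, `[1, 5]` percent by default, with the 1% NGS reporting cutoff
  (configurable) applied at load time.

A patient appearing under both assays is counted once, under NGS.
Duplicate descriptions within a patient are collapsed after normalization
(keeping the highest VAF); rows that fail parsing, reference checks or the
VAF rules are reported in a rejected table, never silently dropped.

Hotspot enrichment is a 2×2 chi-square without continuity correction
(matching how such cohort comparisons are usually reported), with an
automatic Fisher fallback when any expected cell is below 5 and a Haldane
0.5 correction on the odds ratio when a cell is zero.  VAF comparisons
between groups use two-sided Wilcoxon rank-sum tests; with identical
groups the p-value is defined as 1.

# Phasing and allele reconstruction

Short-read phasing is restricted to eligible pairs: both variants exonic,
same exon, at most 50 nt apart (inclusive) so a single read can span both.
Over doubly-called reads the four haplotype classes are counted and each is
declared *present* (count ≥ `min_support` **and** above the
error-consistent bound) or *absent* (count ≤ the bound), where the bound is
the 0.999 quantile of Binomial(n, `error_rate`).  cis requires the
double-alt haplotype present with both single-alt haplotypes absent; trans
the reverse; anything else is ambiguous with a stated reason.  Present and
absent are disjoint by construction, so a pair can never be called cis and
trans simultaneously.  The defaults (`min_support = 20`,
`error_rate = 0.005`) are conservative for amplicon data at several
thousandfold coverage; the source cohorts give no thresholds, so both are
configuration-exposed.

Long-read (single-molecule style) reconstruction groups reads spanning all
variant positions by their full variant-combination signature, reports
counts and frequencies including the wild-type allele, and flags
signatures below a 1% noise floor as possible chimeras.  Under the
diploid model a clone at cell fraction *f* carrying a heterozygous variant
contributes *f/2* of alleles, which is what the simulator's truth uses in
the convergence tests.

Reads come either from a simplified per-read call TSV (desk-scale tests)
or from SAM via Rsamtools, honouring standard flags (unmapped, secondary
and duplicate reads skipped); allele extraction walks the CIGAR and leaves
soft-clipped or deleted positions uncalled, and a base matching neither
allele is conservatively uncalled.  SAM-mode variant matching covers
substitutions; indel-bearing reads are exercised through the TSV path.

# CN-LOH inference

Eleven locus SNPs (a synthetic default panel; any panel may be supplied)
are genotyped from alternate-allele fractions: heterozygous inside
[0.10, 0.90] at depth ≥ 100, homozygous outside, uninformative below
depth.  Both thresholds are stated assumptions — the source analyses give
none — and are configuration-exposed.  The call is `cn_loh` only for the
dominant-clone pattern: variant VAF > 50%, no del(17p), and every
informative SNP homozygous (wild-type locus replaced by the mutant
haplotype).  del(17p) short-circuits to `hemizygous` (a VAF above 50% then
reflects the single remaining allele).  At least one heterozygous SNP
forces `heterozygous`; adding het SNPs can therefore never create a
`cn_loh` call (monotonicity).  All SNPs homozygous with VAF ≤ 50% is
`uninformative` — the panel cannot distinguish germline homozygosity from
LOH there.  Subclonal CN-LOH is deliberately not called: with the 0.10/0.90
band, a LOH clone must exceed roughly 80% cell fraction before het SNPs
leave the band, so the recovery simulations operate in the near-clonal
regime (fractions 90–98%), which is also the regime the decision rule is
designed for.

# The simulator and what passing tests mean

The generator's defaults are the study conditions, fixed once: 683
patients of whom 511 NGS; per-variant class mixture 73/11/2/6/8 percent;
NGS multiclonality weights 351/81/41/38 over SM/DM/MM3/MM4plus with
MM4plus counts decaying over 4..14; hotspot masses of 16% (c.626_627del
among frameshifts), 4% (codon-210 frameshifts), 22% (the three c.673-2
substitutions, equal parts, among splice variants) and the leading nonsense
variants at codons 213 and 196; a substitution-event mixture with ~20%
AT>GC and CpG-enriched GC>AT; and log-uniform VAF draws (2–90% for
single-mutated patients, 1.2–30% per variant for multi-mutated ones,
placing roughly a third of NGS variants in the 1–5% band) hard-capped so no
patient's cumulated VAF exceeds 100%.  About 2.5% of single-mutated NGS
patients are drawn as near-clonal CN-LOH cases with VAF in 52–98%.  Where
the source conditions state a value the default encodes it; where they do
not (the VAF mixture shape, del(17p) prevalence, the MM4plus decay, the
pathogenicity mix 60/22/18) the default is a realistic one-time choice
documented here.  The clone→VAF map (VAF = f/2 diploid, f under
CN-LOH/del(17p)) is made explicit because cohort papers never formalize
it; for table-level statistics the cohort simulator draws VAFs directly
under that map.

All randomness flows from one seed through a preserved-RNG helper, truth
records are mandatory outputs, and the same seed yields byte-identical
tables.  The simulator emulates the *statistical* structure — hotspot
weights, clone fractions, i.i.d. per-site read errors, binomial SNP
sampling.  It does not emulate platform error profiles (homopolymer,
strand bias), alignment artefacts, germline contamination or
sample-quality variation; a pipeline that passes these tests is verified
for its decision rules and estimators under the stated model, not
validated against sequencing noise in the wild.

# Numerical and design choices

* Translation uses the standard nuclear code via a fast codon-table
  lookup; selenocysteine and alternative initiation are ignored.
  Substitutions in the terminal stop codon are named conservatively and
  excluded from the random-property domain.
* The phasing decision quantile (0.999), the reconstruction noise floor
  (1%), the het band, and the minimum depths are all parameters with the
  defaults above; tests pin their consequences, not their values.
* Problem sizes in the suite and acceptance script — a 683-patient cohort,
  grids of 8–10 phasing simulations, 200 CN-LOH profiles, ~1,000
  oracle-checked random variants — were chosen so distributional checks
  have 4-standard-deviation headroom while the whole run stays light.
* Statistical null checks use a multiplicity-adjusted bar (0.05 divided by
  the number of pairwise tests), since even a true null crosses a fixed
  0.05 line in a few percent of draws.
* Single-seed caveat: quantities estimated from ~100 events (e.g. the
  codon-210 share of frameshifts at a 4% mass) fluctuate visibly between
  seeds; the generator parameter, not any one draw, encodes the condition.

# Known limitations

* The cohort input is the table schema described above; the package does
  not ingest VCF cohorts directly (an annotated export is the natural
  extension point).
* Splice outcomes are modelled only for acceptor signals of introns with
  sequence; donor-site disruption, exon skipping and NMD are not modelled.
* The intron 6 fixture is synthetic (see above); nucleotide-level results
  inside the retained segment (e.g. its exact sequence) are placeholders,
  while its length, frame and downstream stop are faithful.
* CN-LOH calling is dominant-clone only, and cannot separate germline
  homozygosity from LOH when no panel SNP is heterozygous.
* GenBank reference records are not parsed; references load from FASTA
  plus exon/intron tables.
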