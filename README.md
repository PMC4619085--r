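# crisprDel

Paired guide RNA design and in-silico genotyping for CRISPR deletion of
genomic elements.

## What problem this solves

Promoters, enhancers and long non-coding RNA genes cannot be knocked out by
the single-guide frameshift strategy that works for protein-coding genes:
they must be **deleted**. That takes two SpCas9 guide RNAs cutting on either
side of the element, with non-homologous end joining re-ligating the flanks.
For anyone running such experiments — from a single locus to a pooled
library — the desk-side work is always the same: find guide candidates near
the two boundaries, pick a compatible pair, encode both 20-nt targeting
sequences on the single 165-nt oligo used for two-step BsmBI/Gibson cloning
into a dual-promoter (U6/H1) vector, and afterwards genotype clones from
diagnostic PCR band patterns (wild type / heterozygous / homozygous /
inversion). `crisprDel` implements that entire chain as a Bioconductor-style
R package, with a seeded synthetic-locus and clone simulator so every step
is verifiable offline.

## The core model

* A guide candidate is a 20-nt protospacer 5' of an `NGG` PAM (either
  strand). The blunt Cas9 cut falls between protospacer nucleotides 17 and
  18 (3 bp from the PAM); cuts at gap coordinates `g1 < g2` delete exactly
  the interval `[g1 + 1, g2]`, of length `g2 - g1`.
* Candidates containing a BsmBI site (`CGTCTC`/`GAGACG`), a `TTTT` Pol III
  terminator, or `N` are filtered; a G-start is required only in the U6
  slot. Specificity is scored by exhaustive mismatch counting:
  `score = 1 / (1 + sum(w(m)))`, `w(0..3) = 10, 3, 1, 0.2`, over all
  NGG-adjacent sites within 3 mismatches, excluding the on-target site.
* Pairs come from 200-bp windows centered on the target boundaries and are
  ranked by `min(score_left, score_right)`, then by closeness of the
  realized deletion length to the requested one.
* Genotyping uses three PCRs — flanking (WT-size vs. KO-size bands, with
  `KO = WT - deletion_len` for clean junctions), internal (wild-type alleles
  only) and inversion (inverted alleles only; inversions are WT-sized in the
  flanking PCR) — reduced to four evidence booleans and classified by a
  fixed truth table, falling back to `AMBIGUOUS` rather than guessing.
* Knockout quantification: `relativeExpression()` implements the
  housekeeping-normalized fold change `2^(-ddCt)`, `stainIndex()` the
  flow-cytometry separation `(mean_pos - mean_bg) / (2 * sd_bg)`.

See `vignettes/paired-guide-deletion-design.Rmd` for the full model account,
parameter rationale and limitations.

## Worked example

```r
library(crisprDel)
library(GenomicRanges)

locus  <- makeSyntheticLocus(seed = 101, length = 5000, target = c(2200, 2800))
target <- GRanges("synthetic_locus", IRanges(2200, 2800))

pair <- designPairs(locus, target)[[1]]
pair
#> GuidePair
#>   U6 : GCCGTTAGACGTGCCACTGT (TGG) cut 2293
#>   H1 : CATGAGGAGGTACTAGGGAC (CGG) cut 2894
#>   deletion:synthetic_locus:2294-2894(601 bp) pair score 1
```

Both guides scored 1 (no off-target within 3 mismatches in this locus); the
realized deletion is 601 bp for the 601-bp requested target, and both cuts
sit within 100 bp of the boundaries they serve.

```r
assembleInsert1(protospacer(u6Guide(pair)), protospacer(h1Guide(pair)))
#> Insert1Oligo of length 165 nt
#>   gibson5          1- 25  ATCTTGTGGAAAGGACGAAACACCG
#>   t_u6            26- 45  GCCGTTAGACGTGCCACTGT
#>   scaffold_frag   46- 65  GTTTTAGAGCTAGAAATAGC
#>   bsmbi_cassette  66-100  CACCTGCAGAGACGACCGACTAGTCGTCTCCAGCA
#>   t_h1           101-120  CATGAGGAGGTACTAGGGAC
#>   h1_frag        121-145  CTGGGAAATCACCATAAACGTGAAA
#>   gibson3        146-165  GGTTCGTGGTCCCGAGTCAC

simulateCloning(pair)
#> ConstructModel (stage: final )
#>   1. U6_promoter      65 nt
#>   ...
#>   physical sequence: 330 nt, 0 BsmBI site(s)
```

The two variable 20-mers are the only non-constant content of the 165-nt
oligo; the simulated two-step cloning confirms the final construct carries
each targeting sequence once and no residual BsmBI site.

```r
primers <- pickPrimers(locus, pair)
plan <- predictAmplicons(locus, pair, primers, name = "demo")
plan
#> GenotypingPlan: demo
#>   expected PCR sizes: WT 862 | KO 261 | internal 440 | inversion 443 bp
#>   band tolerance: 13.05 bp

clone <- cloneSpec(list("WT", "DEL", "DEL"))   # pseudo-triploid heterozygote
bands <- simulateBands(simulateClone(locus, pair, clone, seed = 3), primers)
classifyGenotype(plan, bands)
#> GenotypeCall: HET
#>   evidence: long=TRUE, short=TRUE, internal=TRUE, inversion=FALSE
```

The KO band (261 bp) is exactly `862 - 601`; the simulated triploid clone
retaining one wild-type allele is called heterozygous because the internal
PCR band — authoritative for wild-type-allele presence — is there.

```r
relativeExpression(26.1, 18.0, 20.4, 17.9)   # strong knockout, ~2% of control
#> [1] 0.02061731
stainIndex(300, 100, 50)
#> [1] 2
```

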