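---
title: "Designing paired-guide CRISPR deletions with crisprDel"
author: "crisprDel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing paired-guide CRISPR deletions with crisprDel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Non-coding genomic elements — promoters, enhancers, long non-coding RNA
genes — cannot be silenced by frameshift indels the way protein-coding genes
can. The established strategy is to *delete* the element outright: two
SpCas9 guide RNAs cut on either side of it, and non-homologous end joining
(NHEJ) re-ligates the flanks, removing the intervening fragment on one or
more alleles. Because two guides are needed per target, library-scale work
benefits from encoding both variable 20-nt targeting sequences on a *single*
synthesized oligonucleotide, cloned in two steps into a dual-promoter
(U6/H1) lentiviral vector.

`crisprDel` implements the complete desk-side arm of this workflow:

1. enumerate and filter SpCas9 guide candidates around the target boundaries;
2. select and slot a guide pair under the U6/H1 promoter rules;
3. assemble the single 165-nt cloning oligo and simulate the two-step
   Type IIS (BsmBI) cloning that produces the final dual-gRNA construct;
4. predict the diagnostic PCR bands of wild-type, deleted and inverted
   alleles, and classify clone genotypes from observed band patterns;
5. simulate synthetic loci and clone allele sets so the whole loop is
   testable without any external data.

```{r, eval = FALSE}
library(crisprDel)
library(GenomicRanges)

locus <- makeSyntheticLocus(seed = 101, length = 5000, target = c(2200, 2800))
target <- GRanges("synthetic_locus", IRanges(2200, 2800))
pair <- designPairs(locus, target)[[1]]
oligo <- assembleInsert1(protospacer(u6Guide(pair)), protospacer(h1Guide(pair)))
construct <- simulateCloning(pair)
plan <- predictAmplicons(locus, pair, pickPrimers(locus, pair))
```

# Guide model

A guide candidate is a 20-nt protospacer immediately 5' of an `NGG` PAM, on
either strand. The predicted Cas9 cut is blunt and falls between protospacer
nucleotides 17 and 18 counting from the PAM-distal end — 3 bp from the PAM —
the junction position observed when sequencing repaired deletion alleles.
Internally guides live in a `GuideSet` (a `GRanges` subclass); the `cut`
column is a *gap coordinate*: the break sits between plus-strand bases
`cut` and `cut + 1`, so the deletion produced by cuts `g1 < g2` is exactly
the closed interval `[g1 + 1, g2]` of length `g2 - g1`. All user-facing
coordinates follow the 1-based GRanges convention; BED input and output pass
through `rtracklayer` and therefore stay native 0-based on disk.

Filtering removes protospacers that would break the cloning chemistry or the
expression cassettes:

* `CGTCTC`/`GAGACG` (a BsmBI recognition site) — the site would be cleaved
  during cloning step 2;
* `TTTT` — a run of T acts as a Pol III terminator, and both gRNA genes are
  Pol III transcripts. This goes beyond the minimal published design rules
  and can be disabled (`filterCandidates(polyT = FALSE)`);
* any `N` — synthetic and draft genomes may contain `N`, so genomes admit it
  but protospacers never do.

Starting with `G` is recorded as a *flag*, not a filter: only the U6 slot
requires it (below).

## Specificity score

The original workflow delegated guide scoring to an external web service.
`crisprDel` ships a deterministic, oracle-verifiable stand-in: an exhaustive
both-strand scan for genomic sites matching the protospacer with at most
`maxMismatch` (default 3) mismatches and carrying an `NGG` PAM, scored as

$$ s = \frac{1}{1 + \sum_{\text{off-targets}} w(m)}, \qquad
   w(0)=10,\; w(1)=3,\; w(2)=1,\; w(3)=0.2 . $$

The on-target site is excluded; `s = 1` exactly when no off-target exists
within the mismatch radius. Mismatch counting is ungapped and
protospacer-only (bulges are out of scope). The scorer is intended for
desk-scale genomes (kilobases to a few megabases); users with external
genome-wide scores can attach them to the `score` column directly.

# Pair selection

Candidates for the left and right cut are drawn from windows of width
`windowBp` (default 200 bp) around the two target boundaries. The published
rule states the window width but not its anchoring; since reported construct
positions straddle the boundaries (e.g. "-70/+30" around a TSS), the window
is *centered* on each boundary here, so every selected cut lies within
`windowBp / 2` of the boundary it serves. A consequence worth being explicit
about: the realized deletion may start or end up to `windowBp / 2` inside
the nominal target, so the deletion is guaranteed to contain the target's
central interior, not necessarily its outermost bases. The nominal target
length is treated as a *request*; realized deletion lengths differ because
cuts are constrained to PAM positions, and no attempt is made to force exact
nominal lengths.

Kept pairs must have the left cut strictly before the right cut and
non-overlapping protospacers (overlapping guides compete for the same
site; the published design does not state this rule, so it is our default).
Pairs are ranked by

1. `pairScore = min(score_U6, score_H1)` — a deletion fails if *either* cut
   fails, so the weakest guide dominates (a product would reward one strong
   and one poor guide);
2. smaller `|deletion_len - target_len|`;
3. genomic position (a deterministic tie-break; the whole designer is
   bit-reproducible, with no hidden randomness).

## U6/H1 slotting

U6-driven Pol III transcripts conventionally start with G, while H1 tolerates
any first nucleoside. `assignSlots()` therefore places the G-starting guide
in the U6 slot; when both start with G the left (lower-coordinate) guide
takes U6; when neither does, the pair is rejected unless
`allowPrependG = TRUE`, in which case the U6 *transcript* is modeled with a
prepended G while the oligo still carries the exact 20-nt genomic match.

# The single-oligo format and cloning simulation

The cloning oligo is

```
gibson5 (25) | t_U6 (20) | scaffold_frag (20) | bsmbi_cassette (35) |
t_H1 (20) | h1_frag (25) | gibson3 (20)
```

Five constant segments total 125 nt, so any two targeting sequences give a
165-nt oligo. The cassette carries two BsmBI sites, one per strand, pointing
outward so that digestion excises *both* recognition sites; no other segment
may contain one, and `assembleInsert1()` additionally refuses assemblies
where a site would form *across* a segment junction. The orientation in
which the second targeting sequence is written (`t2Orientation`) is a
template option, defaulting to sense; parsing is orientation-aware, so
round-trip correctness does not depend on the choice.

The template is data, not code: it ships as a `key=sequence` text config
(`inst/extdata/insert1_template_synthetic.txt`) loaded and validated at run
time, so transcription errors are isolated and checkable. The shipped
segment sequences — like the minimal parental backbone and the universal
second insert (scaffold + H1 promoter) modeled in `simulateCloning()` — are
**synthetic stand-ins**: they satisfy every structural constraint of the
format (lengths, BsmBI content, uniqueness of the Gibson overhangs) but are
not the published plasmid sequences, which are not reproduced here. Users
cloning into a real vector should supply their own template file.

`bsmbiDigest()` implements BsmBI as `CGTCTC(1/5)`: top-strand cut one
nucleotide 3' of the recognition site, bottom-strand cut five, leaving 4-nt
5' overhangs; bottom-strand sites cut mirror-symmetrically upstream.
Circular molecules with *n* sites yield *n* fragments, linear ones *n* + 1,
and top-strand fragment lengths always sum to the input length. Cloning is
simulated at the element/sequence level — no ligation thermodynamics, no
transformation efficiency, no Gibson overlap-melting checks. The final
construct is *verified*, not assumed: zero residual BsmBI sites, each
targeting sequence present exactly once, and the U6 guide immediately
downstream of the U6 promoter block. In the physical plasmid the second
cassette's layout depends on the (ambiguous) orientation choice, so the
element list returned by `simulateCloning()` is the *functional* order
(U6, gRNA1, scaffold, H1, gRNA2, scaffold) rather than a claim about linear
plasmid geometry.

# Genotyping model

Clone genotyping uses three PCRs:

1. **Flanking PCR** (external primers): wild-type alleles give a long
   product; deleted alleles a product exactly `deletion_len` bp shorter
   (for indel-free junctions — `predictAmplicons()` enforces this identity).
2. **Internal PCR** (external + internal primer inside the deletion):
   amplifies wild-type alleles only. This exists because short deletion
   templates can out-compete the long wild-type template in PCR 1, so a
   heterozygote could masquerade as homozygous; the internal band is
   therefore *authoritative* for wild-type-allele presence.
3. **Inversion PCR** (external + inverted internal primer): the excised
   fragment is frequently re-ligated in reverse orientation; such alleles
   give a wild-type-*sized* PCR-1 product and are only revealed by a primer
   that matches the inverted segment's orientation.

`classifyGenotype()` reduces observed bands to four booleans (long, short,
internal, inversion) by tolerance matching and applies a fixed truth table:
inversion evidence takes precedence (`INV_HET` with an internal band,
`INV_HOM` with long-or-short but no internal band); otherwise
long + internal without short is `WT`, long + short + internal is `HET`,
short alone is `HOM_KO`; every other combination returns `AMBIGUOUS` with
the evidence attached — never an error, and never a guessed category. In
particular, mixed deletion + inversion patterns on clones with more than two
alleles (aneuploid lines such as pseudo-triploid HeLa carry three copies of
many loci) map to `INV_HET`/`INV_HOM` only when the evidence is coherent;
incoherent patterns stay `AMBIGUOUS` by design.

Band intensities are deliberately ignored: amplification efficiency differs
between products of different lengths, so intensity cannot quantify allele
ratios. The default band-size tolerance is `max(10, 5%)` of the expected
size, mimicking agarose gel resolution; junction indels smaller than the
tolerance therefore do not change a call, which matches how such gels are
read in practice.

Primer design is user-supplied by default (published primer sets exist for
real targets); `pickPrimers()` is an optional naive picker — plain 20-mers,
placed by geometry, required to map uniquely in the locus on both strands —
with no melting-temperature model.

# The synthetic generator as closed-loop oracle

`makeSyntheticLocus()` draws a seeded random sequence at a stated GC
fraction and *guarantees* that each design window contains at least one
filter-passing, G-starting candidate whose cut lies in the window,
engineering a protospacer + `AGG` PAM in place only when the random draw
lacks one. Defaults — 5 kb locus, GC 0.5, a 600-bp target with 200-bp
windows — mirror a realistic promoter-deletion design (published constructs
ranged from 100 to 3000 bp; 0.5–3 kb is the sweet spot for promoter
knockouts).

Allele simulation covers the repair outcomes actually observed when such
clones are sequenced: clean flank-to-flank junctions, junction indels
(observed examples include a single inserted base and cut sites displaced
by up to ~15 bp with short insertions — `junctionIndel` is a signed integer,
|indel| ≤ 20, insertions seeded), and full inversions of the excised
fragment. The default junction-indel distribution is a point mass at zero:
the literature reports specific observed indels but no distribution, so the
conservative default leaves indels as an explicit user choice. Ploidy runs
1–4 (default 2; 3 models pseudo-triploid lines).

The central property this enables: for every clone specification at ploidy
2 or 3, `classifyGenotype(predictAmplicons(...), simulateBands(...))`
recovers the specification's true category, provided junction indels stay
below the band tolerance. The test suite and the acceptance script both run
this loop exhaustively (all 3² + 3³ = 36 allele combinations).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: sequence homology and repeats (real primers can
mis-prime), chromatin effects on cutting efficiency, bulk-population allele
mixtures, PCR stochasticity, and sequencing error. The closed loop validates
the *arithmetic and logic* of the design and genotyping chain, not wet-lab
success rates.

# Quantification formulas

Two scalar measures evaluate knockouts downstream:

* **Relative expression** (qPCR): `relativeExpression()` returns
  $2^{-\Delta\Delta C_t}$ with
  $\Delta\Delta C_t = (C_t^{tgt} - C_t^{hk})_{sample} - (C_t^{tgt} - C_t^{hk})_{calibrator}$.
  The source methods text prints the exponent with a *positive* sign
  ("2^(Ct-Cc)"), under which a sample with *more* cycles (less RNA) would
  report *higher* expression; we default to the standard sign convention and
  expose the literal form behind `asPrinted = TRUE`, since it is ambiguous
  whether the printed form assumed already-normalized values. Both modes are
  tested; they are mutual reciprocals.
* **Stain index** (flow cytometry): `stainIndex()` is
  `(mean_pos - mean_bg) / (2 * sd_bg)`, exactly as printed; zero at equal
  means, sign following the difference, invariant under shifting both means.

# Numerical and degenerate-input choices

* All randomness flows through explicit integer seeds; seeded helpers
  restore the caller's RNG state, so library calls never perturb a user's
  random stream.
* Degenerate pairs (identical cut coordinates) are an error, as are empty
  candidate windows (the error names the offending side) and unslottable
  pairs (the error suggests `allowPrependG`).
* Sequences shorter than 23 nt yield an empty candidate set, not an error.
* BsmBI sites whose cut positions would run off a linear molecule are not
  cut, matching enzyme behavior at fragment ends.
* `in_silico_pcr` uses exact primer matching, reports the inclusive span
  between outermost primer 5' ends, considers both orientation assignments
  of the primer pair, and caps products at `maxLen` (default 10 kb).

# Validation problem sizes

The shipped test suite scans 100 random 1-kb sequences against a naive
sliding-window oracle, round-trips 1000 random oligos, checks the
WT/KO amplicon identity on 100 independent 3-kb loci (50 in the acceptance
script), and closes the genotyping loop over all 36 clone specifications on
a 5-kb fixture locus. These sizes were chosen as the smallest that exercise
every code path with comfortable statistical margins; all are configurable
upward through the exported functions.

# Known limitations

* No on-target efficiency model and no genome-wide off-target search; the
  mismatch-weighted score is a transparent stand-in, not a trained model.
* Deletions are sanity-capped by design intent at < 1 Mb; multi-target
  library optimization is greedy per-target.
* No Sanger-trace or sequencing-read analysis; genotyping consumes band
  sizes only.
* The shipped template, backbone and second-insert sequences are synthetic
  stand-ins (clearly labeled); simulated cloning validates structure, not
  chemistry.
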