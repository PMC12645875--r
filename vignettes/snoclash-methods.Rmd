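---
title: "Calling and classifying snoRNA interactions from CLASH/FLASH chimeras"
author: "snoclash authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and classifying snoRNA interactions from CLASH/FLASH chimeras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoclash)
```

## The problem

Box C/D snoRNAs guide site-specific 2'-O-methylation of ribosomal RNA.
The guide rule is geometric: the snoRNA sequence immediately 5' of its
box D (CUGA) or box D' element base-pairs with the target, and the
target nucleotide opposite the snoRNA position exactly five nucleotides
upstream of the box (the "+5 rule") receives the methyl group.
Crosslinking-and-proximity-ligation protocols (CLASH, FLASH) capture
such duplexes as *chimeric reads*: single sequencing reads whose two
segments map to distinct transcript locations, evidencing an in vivo
RNA-RNA contact.

Not every confident snoRNA contact is a methylation guide. Contacts can
sit next to a guide site (possibly stabilising it), can bury a known
site under a long perfect helix formed by a *different* snoRNA
(potentially blocking methylation), or can reflect chaperone-like
structural roles during pre-rRNA folding. snoclash implements the
full calling pipeline: parsing hyb-format chimera tables, predicting
the intermolecular duplex of each chimera, filtering for thermodynamic
stability and reproducibility, applying the decision tree that
separates these interaction classes, and annotating target fragments
with mRNA features, host-intron relationships and branch-point windows.

## The decision tree

For each reproducible snoRNA-target cluster the classifier evaluates, in
fixed precedence:

1. **Strict methylation guide** — all of: the nucleotide 5 upstream of
   box D or D' pairs *exactly* (Watson-Crick; G-U wobble never counts as
   exact) and the duplex has at least 12 base pairs; at least one exact
   pair among offsets 2-4; the four box nucleotides are *not* all
   exactly paired; and either eight consecutive exact offsets within
   1..14 or eleven consecutive offsets within 1..16 with at most one
   non-exact position.
2. **Weak methylation guide** — strict failed, but offset 5 is paired
   (G-U allowed). Weak calls are terminal: they never fall through to
   the later buckets, so a near-guide interaction is not misreported as
   blocking.
3. **Known-site overlap** — the target fragment overlaps a site this
   snoRNA is known to guide, without satisfying either guide criterion.
4. **Ancillary** — a known site guided by the *same* snoRNA family lies
   within 100 nt of (but not overlapping) the target fragment.
5. **Blocking** — at least 22 perfect Watson-Crick pairs fall within
   17 nt of a known site, and the snoRNA does not itself guide
   methylation at a site closer than 20 nt (a guide acting at a
   neighbouring site is not "blocking" it).
6. **Structural** — any remaining confident snoRNA-rRNA duplex.
   Non-rRNA targets that reach this point are reported `unclassified`.

All thresholds live in `classifier_config()` and serialise to JSON, so a
run is reproducible from its config file alone. Two readings in the
tree were genuinely open and are fixed here as documented choices:
the blocking window is read as *containment* (all 22 pairs within
±17 nt of the site), and the neighbour veto uses strict inequality
(separation < 20 nt vetoes; exactly 20 does not). When both boxes
satisfy strict, box D' is reported only if its predicted site matches a
known same-family site and box D's does not; otherwise box D wins.

## Duplex model

The intermolecular duplex between the two read fragments is predicted
by a dynamic program over antiparallel, non-crossing pairs
(Watson-Crick plus G-U; `N` never pairs). The energy model is a
deliberate simplification of nearest-neighbour thermodynamics:

* a helix initiation penalty (default +3.0 kcal/mol),
* a stacking bonus for each contiguous pair step, `-(s(p)+s(q))` with
  `s(GC)=1.6`, `s(AU)=0.9`, `s(GU)=0.5` kcal/mol,
* a linear bulge/interior-loop penalty `1.0 + 0.5·L` kcal/mol for `L`
  unpaired loop nucleotides, with at most 10 unpaired nucleotides per
  side of a single loop — helices further apart are treated as separate
  interactions rather than one duplex.

All arithmetic is in integer tenths of a kcal/mol, so scores compare
exactly and ties can be broken deterministically (more pairs first,
then 5'-most pairing on fragment 1). The −12 kcal/mol stability
threshold is applied *inclusively* (−12.0 passes): the quantitative
wording of the filter ("−12 or below") wins over the looser prose
variant ("less than −12"), and the choice is a config value
(`energy_threshold`) rather than a constant.

The backend is pluggable (`duplex_params(backend=)`), so an external
thermodynamic engine can replace the internal model without touching
downstream code; every classification rule consumes only the `duplex`
contract (pair list, exactness, dG). `brute_force_duplex()` enumerates
*all* non-crossing pairings (inputs up to 24 nt combined) and scores
them with the same parameter table but shares no search code with the
dynamic program; the suite requires exact score and pair-count
agreement between the two on hundreds of random instances.

Under this model a 12-pair mixed guide helix scores roughly −17 to −25
kcal/mol, so canonical guide interactions clear the −12 threshold, as
they should; a lone A-U pair scores positive and is never reported.

## Filtering

* **Intramolecular stems**: chimeras whose two fragments map to the
  same snoRNA are split off first — they describe snoRNA secondary
  structure, not interactions.
* **Stability**: duplex dG ≤ −12 kcal/mol (inclusive).
* **Reproducibility**: single-linkage clustering; two chimeras join a
  cluster iff their fragments overlap by ≥ 1 nt on *both* sides (the
  weakest faithful reading of "overlap"; the threshold is
  configurable). Clusters need ≥ 2 supporting reads. Support counts
  distinct read ids by default; `distinct_sequences = TRUE` restricts
  to distinct read sequences for PCR-duplicate-conservative analyses.
* **Mismapping**: snoRNA-X chimeras (X neither snoRNA nor rRNA) whose X
  fragment locally aligns to a U3 or rRNA decoy at ≥ 75% identity over
  ≥ 70% of the fragment are removed. The published filter gives no
  numeric thresholds ("albeit poorly"), so these defaults are
  deliberately conservative, logged in every filter report, and
  configurable. Genome-wide single-read realignment is out of scope
  here; the decoy-based check covers the dominant failure mode
  (mismapped U3/rRNA stems) without requiring a genome at test time.

Filters are idempotent and conserve records (`kept + removed = input`),
which the pipeline asserts in its MANIFEST.

## Coordinates

All internal coordinates are 1-based and inclusive, matching both the
hyb dialect and the known-site tables as well as the conventions of
IRanges, on which the interval machinery is built. Duplex and
classification logic operates entirely in transcript space (5'→3');
genomic projection (`tx_to_genome()`/`genome_to_tx()`, BED export)
is used only for feature reporting. The reference database extends
each placed snoRNA by 20 nt into its host intron and masks the extended
span out of the host sequence, so host-intron reads cannot double-map.

## The synthetic-data generator

Real CLASH libraries and their reference databases are far too large to
ship or to rebuild in a test environment, and their true interaction
labels are unknown. The generator therefore *is* the study design for
validation: it emits references (GTF, FASTA, known sites, curated box
annotations), hyb chimera files and single-read tables with known truth
for every record.

Each snoRNA follows a fixed box C/D architecture (terminal boxes
C=RUGAUGA and D=CUGA, a 12-nt guide immediately 5' of box D, and an
accessory region more than 16 nt upstream of box D) embedded mid-intron
in its own host gene. Interaction classes are engineered to make the
intended decision path the *unique* truth: guides pair the guide region
with a planted antisense site (weak guides carry G-U wobbles at offsets
5 and 10, which break every strict clause-1/stretch combination while
keeping offset 5 paired); ancillary/blocking/structural interactions
pair the accessory region, so the guide offsets stay unpaired;
mismap decoys carry a verbatim U3 substring as their "mRNA" fragment.
Fragment pads are jittered a few nucleotides per supporting read, giving
fragment lengths in the 25-40 nt range typical of snoRNA chimera
fragments.

Two design rules keep the tests honest:

* **The generator never calls the classifier.** Every planted
  interaction is verified at generation time against
  `naive_guide_call()`, a literal, loop-by-loop transcription of the
  published criteria that shares no code with `check_strict()`; random
  filler is resampled on the rare occasions the folded duplex violates
  the intended class.
* **Noise never touches criterion-critical positions.** The
  substitution-noise model (default 0; 1% in the degradation test)
  mutates only pad/filler bases, so truth labels remain valid while
  recovery is allowed to degrade.

What the generator does *not* emulate: realistic human sequence
composition, alignment ambiguity from repeated elements, ligation
biases, or PCR-duplicate families. Passing the synthetic suite
therefore demonstrates that the *rules* are implemented exactly and the
pipeline is lossless and deterministic — not that any particular
biological recovery rate would be achieved on real libraries, whose
headline counts depend on the sequencing depth and reference set of the
original experiments.

## Feature annotation

Target fragments on mRNA-like genes are labelled by majority overlap
over CDS / 5'UTR / 3'UTR / intron / non-coding exon (ties broken by
that fixed precedence — the choice of rule was open and is documented
here). Host relations distinguish a snoRNA contacting its *own* host
intron (cis), another region of the host gene (trans), or an unrelated
gene. The branch-point window is 20-50 nt upstream of the intron's 3'
end, following the figure-legend definition; the 25-50 nt variant that
appears in prose is available as the `window` argument. Intron
metaprofiles cover the last 1000 intron positions (introns shorter than
that contribute their covered suffix), and single-read comparisons
report Pearson correlations on log10(x+1) counts alongside Spearman.

## Problem sizes

The shipped validation uses, per run: an enumerated grid of ~6,000
guide geometries for the classifier/oracle equivalence; 500 random
sequence pairs (≤ 24 nt combined) for duplex/oracle equality; and a
synthetic bundle of 700 interactions (100 per class, 2-4 supporting
reads each) for end-to-end recovery, clean and at 1% substitution
noise. These sizes exercise every rule boundary while keeping a full
run in the minutes range on a single core.

## Known limitations

* The internal energy model is a simplification; absolute dG values are
  on the model's scale, not Turner-parameter predictions. The −12
  threshold behaves sensibly under it (canonical guides pass, weak
  partial helices near 7 pairs sit at the boundary), but quantitative
  energies should not be compared against ViennaRNA outputs unless that
  backend is plugged in.
* Box D'/C' detection for unannotated snoRNAs is a heuristic fallback
  (internal CUGA-like/RUGAUGA-like scan); curated box annotations
  override it and are what the pipeline uses when provided.
* `unclassified` is an honest bucket: non-rRNA targets that fail every
  criterion, and clusters whose snoRNA lacks a usable box D, are
  reported with a reason rather than forced into a class.
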