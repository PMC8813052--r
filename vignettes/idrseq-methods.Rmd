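---
title: "idrseq: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{idrseq: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrseq)
```

# Scope

`idrseq` quantifies the sequence features that distinguish intrinsically
disordered regions (IDRs) — in particular the charge-rich, aromatics-poor,
branched-hydrophobic-bearing IDRs of DNA replication licensing factors —
and designs composition-preserving sequence variants for testing whether a
property depends on residue order or on composition alone. It operates
purely on primary sequence plus externally supplied per-residue disorder
scores; no structure prediction, phase-separation physics or wet-lab
quantities are modeled.

# Metrics and their definitions

## Composition and complexity

Composition vectors are plain count fractions over the 20-letter alphabet
(`AA_ALPHABET` fixes the column order). Sequence complexity is the
plug-in Shannon entropy of that frequency vector in natural-log units,

$$ H = -\sum_{a\,:\,p_a>0} p_a \ln p_a, \qquad 0 \le H \le \ln 20 \approx 3.0 ,$$

with $0\ln 0 = 0$, no pseudocounts and no finite-sample correction. The
natural-log base is pinned by the conventional "0 to 3" range quoted for
protein sequences; a base-2 or base-20 entropy would not reproduce the
published complexity scores this package is validated against (the
wild-type Cdt1 IDR scores `r round(shannon_complexity(load_fixture("WT")), 3)`
nats, i.e. 2.7 at one decimal). Entropy is exactly permutation-invariant,
which is what makes it the natural complexity measure for
composition-preserving variant design.

Hydropathy uses the original Kyte–Doolittle constants, embedded verbatim
as `KD_HYDROPATHY`; segment hydropathy is the unweighted mean.

## Charge patterning

The charge set is **K, R (+1) and D, E (−1)**. Histidine is neutral for
FCR/NCPR/kappa — at physiological pH its protonated fraction is small,
and the anchor values this package validates against were computed under
the same convention — but it does ionize in the pI model.

Kappa follows the Das–Pappu construction: overlapping blobs of size
$g \in \{5, 6\}$, per-blob charge asymmetry
$\sigma = \mathrm{NCPR}^2/\mathrm{FCR}$, the mean squared deviation
$\delta = \langle(\sigma_{blob}-\sigma_{global})^2\rangle$, and
$\kappa = \tfrac12(\delta_5/\delta^{max}_5 + \delta_6/\delta^{max}_6)$.

### The delta-max normaliser is a construction, not a true maximum

$\delta^{max}$ is computed from candidate *maximally segregated
arrangements* of the same composition: the three blocks (positives,
negatives, neutrals) in all six orders, plus arrangements that split the
neutral block across both termini around adjacent charge blocks. This is
the lineage convention of the field's kappa implementations, and it is
what reproduces the published anchors for the packaged constructs
(wild-type kappa 0.204 → 0.20, uniform-charge variant 0.062 → 0.06,
a fully segregated `EEEEEEKKKKKK` → 1).

It is *not* the maximum of $\delta$ over all permutations. Exhaustive
enumeration on short sequences shows the true optimum often insets the
charge blocks away from the termini (neutral padding at both ends keeps
single-charge blobs in play across more windows), and for unbalanced
charge counts even fully charged terminal blocks are sub-optimal. Two
consequences are documented rather than papered over:

* the package's test suite carries an intentionally failing
  acceptance-style property that demands kappa equality against an
  exhaustive-permutation normaliser — the construction-based kappa (which
  matches the published values) cannot satisfy it, and "fixing" kappa to
  the true maximum would break the published anchors;
* in pathological sparse-charge sequences $\delta$ of the native sequence
  can exceed the constructed $\delta^{max}$, so kappa is not clamped to
  $[0,1]$; for charge-rich natural IDRs this does not occur.

When the sequence length equals a blob size the decomposition is
degenerate ($\delta^{max}=0$); that blob size is skipped, so length-6
sequences use the $g=5$ term only. Sequences lacking either charge sign
have kappa reported as `NA` (undefined), never 0.

## Isoelectric point

Net charge is modeled by Henderson–Hasselbalch sums over D, E, C, Y
(acids), H, K, R (bases) and the free termini, and the pI found by
bisection on pH $[0,14]$ to $|Q| < 10^{-4}$; the charge function is
monotone in pH so the root is unique. The pKa set is the
Bjellqvist/Expasy-style table in `PKA_SET`. This choice was calibrated
once against the published wild-type Cdt1 IDR value (pI 10.1; the model
gives 10.11) and then frozen. EMBOSS-style constants were evaluated and
rejected (they give 10.9 for the same sequence), as was dropping the
termini (negligible difference at this length).

## Windows, runs and motifs

Window tracks carry one value per window *start* (1-based); there is no
edge padding, so a window of size $w$ on length $L$ yields $L-w+1$
values — padding conventions would invent data, and figure-style center
coordinates are a plotting transformation. Threshold comparisons use
`>=` with an absolute guard of $10^{-9}$ so fractions of small integers
(3/5, 4/5) compare exactly at their nominal values.

Overlapping qualifying windows are also reported as merged maximal
regions (`threshold_regions()`): a single dense hydrophobic patch
produces several overlapping qualifying windows, and published counts of
"windows reaching" a level refer to patches, not raw window starts — on
the wild-type Cdt1 IDR the fraction-L/I/V track at 0.6 has 15 raw
qualifying windows merging to 5 patches, one or more in each third of the
sequence. Both numbers are computed; neither is collapsed into the other.

Run-length statistics attribute every L/I/V residue to its maximal run's
class (1, 2, 3+); "3+" has no finer classes because runs beyond
tripeptides carry no separate published class. CDK consensus scanning
reports every `[S/T]P` (minimal) and labels hits extending to
`[S/T]PX[R/K]` as full; overlapping hits are all reported.

## Disorder segmentation

The pipeline consumes per-residue disorder scores in $[0,1]$ from a
pluggable file interface (two-column per-protein or combined
three-column); it never shells out to a predictor. Scores are smoothed by
a centered moving average over 20 residues (left half
$\lfloor w/2\rfloor$, truncated at the edges to the available residues);
a trailing window was rejected because it shifts segment boundaries
asymmetrically. Smoothing is applied before segmentation for every
analysis, at both length cutoffs — the source material describes a single
smoothing step, and applying it inconsistently would make the two
summaries incomparable.

Residues at or above the threshold (default 0.5, the common predictor
convention; configurable because it is rarely printed) are disordered;
maximal same-label runs **strictly longer** than the cutoff are emitted
("longer than N" is strict), shorter runs are dropped rather than merged.
Two cutoffs are carried as named parameters because published analyses
use both: 150 aa for complexity-distribution comparisons and 100 aa for
composition/hydropathy/fraction-L/I/V comparisons. Quartiles use linear
interpolation between order statistics (R quantile type 7), skewness is
the moment coefficient $m_3/m_2^{3/2}$, and percentiles are
tie-inclusive ($100\cdot\Pr[x \le v]$).

`surrogate_disorder_scores()` is a deliberately crude deterministic
stand-in so the pipeline is testable offline: over an 11-residue window,
`0.5 + 0.5*FCR − 0.5*(H/4.5)` clipped to $[0,1]$. It encodes only
"charged → disordered, hydrophobic → ordered" and must not be mistaken
for a disorder predictor.

# Variant designers

`scramble()` draws a uniform seeded permutation; `design_uniform_charge()`
first places the charged residues at evenly spaced positions in
alternating sign order and then applies seeded swap moves (charged–charged
and charged–neutral) accepted only when kappa decreases, stopping at the
target (default 0.07) or after `max_iter` proposals. Feasibility, not
global optimality, is the contract; the normaliser $\delta^{max}$ is
cached because composition never changes under the moves. Both designers
produce exact multiset permutations, so entropy, composition, FCR,
hydropathy and pI are preserved *exactly*, and each design report records
kappa before/after, a composition-identity check and (for scrambles) the
dotplot match count against the parent.

`substitute_residues()` replaces occurrences left-to-right; at fraction
0.5 it takes every second occurrence starting with the first. This rule
is an artifact decision: residue-by-residue comparison of the published
half-substitution construct shows 21 of the 40 Ile/Leu mutated (exactly
half of the Leu but 7 of 12 Ile), so no simple occurrence rule reproduces
it and the comparison tests assert composition and charge metrics, not
string identity. Deletion constructs are compared under the prepended
initiator-methionine convention (the published N-terminal deletion begins
`M` + the retained sequence).

Dotplots score ungapped windows (default 15) under the embedded
`BLOSUM62` table and report pairs at or above the threshold (default 32),
the classic repeat-finding settings; symmetry and re-scoring of reported
matches are tested invariants. The scrambled construct against wild-type
yields zero matches at these settings, the designed verification that no
motif survived scrambling.

# The synthetic proteome generator

`generate_proteome()` emulates the *shape* of a disorder-annotated
proteome: proteins are concatenations of 2–4 alternating ordered/
disordered blocks of 150–400 residues; each class draws i.i.d. residues
from its own composition profile; disorder scores are the block indicator
plus Gaussian noise (sd 0.05) clipped to $[0,1]$. The default class
profiles are tuned so the per-segment complexity distributions center
near 2.9 nats (ordered, narrow) and 2.7 nats (disordered, broader), with
ordered segments enriched in I/L/V/F/A and depleted in charges, mirroring
the qualitative proteome-wide differential; the magnitudes are generator
configuration, not biological claims.

What a green recovery test establishes — and what it does not: real
disorder tracks have structured, autocorrelated errors, soft boundaries
and length distributions this generator does not imitate, and i.i.d.
sampling produces none of the local motif structure of real proteins. A
passing ≥95% residue-label recovery on the default configuration
validates the smoothing/segmentation bookkeeping (boundary handling,
strict cutoffs, label assignment), not predictor robustness. The noise
model itself is a harness choice; real pipelines take their scores from
an external predictor.

# Known limitations

* The published uniform-charge construct is off by a single K→E exchange
  from an exact permutation of wild-type (its DNA row confirms the
  protein row), so "identical composition vectors" fails by one residue
  against the reference material; the corresponding assertion is kept and
  fails loudly rather than being loosened.
* Kappa inherits every caveat of the constructed $\delta^{max}$ above.
* The pI model ignores charge–charge interactions, cysteine oxidation
  and temperature; it is a standard sequence-only estimate.
* Proteome-scale published segment counts depend on the external
  proteome release and predictor version and are deliberately not
  reproduced here.
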