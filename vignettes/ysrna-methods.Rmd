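---
title: "Methods: split-half YsRNA quantification and terminal-chemistry inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-half YsRNA quantification and terminal-chemistry inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ysrna)
```

## The measurement model

`ysrna` profiles YRNA-derived small RNAs (YsRNAs) in small-RNA sequencing
libraries and infers the terminal chemistry of fragment classes from
differential representation across chemically and enzymatically treated
aliquots of the same RNA. Three modelling commitments define the package;
everything else follows from them.

**1. Split-half references.** Full-length YRNA folds its 5' and 3' ends
into a double-stranded stem, so a fragment from one end is complementary
to sequence at the other end. To keep a 5'-end fragment from also
registering against the 3' region, each homolog of length $L$ is split at
$s = \lceil L/2 \rceil$ into a 5' half $[0, s)$ and a 3' half $[s, L)$
(0-based, half-open). The convention makes the 5' half never shorter than
the 3' half, the two halves tile the source exactly, and the split is
deterministic — the exact per-homolog coordinates are a declared
convention of this package, not a reconstruction of any particular
pipeline's cut points.

**2. Exact full-read containment.** A hit requires the entire (trimmed)
read to occur verbatim, forward strand only, inside a half. This is
deliberately stricter than a local alignment at 100% identity: it ties
the hit length to the read length, which is what makes per-length
profiles meaningful. Two consequences are documented properties rather
than bugs: a read carrying a single mismatch contributes nothing, and a
read spanning the split boundary is invisible even though it is a true
substring of the full-length source (the test suite asserts this
"junction blindness" on a constructed read). Multi-target reads increment
every cell they match; there is no tie-breaking.

The matcher enumerates every substring of every half between `min_len`
(default 20 nt, guarding against spurious short matches) and the half
length, and keys them in a hash, so matching a library is one lookup per
read. With four ~100-nt references this is a few thousand keys; the
engine is checked exactly — hit count, positions, multiplicity, ordering —
against a brute-force scan of every start position on 1,000 random reads.

**3. RPM of alignable reads.** Counts are reported as
$\mathrm{RPM} = 10^6 \cdot \mathrm{raw} / D$ where the denominator $D$ is
the library's alignable-read count. $D$ is an *input*: for real data it
comes from an external genome alignment, which is out of scope here; for
simulations it is the number of generated reads, so that treatments that
destroy library mass show up as RPM loss rather than being renormalised
away.

## The treatment algebra

Terminal states are 5' ∈ {OH, P, PPP} and 3' ∈ {OH, P, cP, OMe}, where
OMe is a 2'-O-methylated ribose with free 3'-OH. The treatment operators
act on states (and once on sequence):

* **Oxidation/β-elimination** attacks the free 2',3'-diol: 3'-OH reads
  lose exactly one 3' nucleotide and gain a 3' monophosphate; OMe, P and
  cP ends have no vicinal diol and are untouched.
* **RppH** removes pyrophosphate: 5' PPP → P.
* **PNK** heals 3' phosphates (P, cP → OH), phosphorylates 5'-OH
  (OH → P), and removes canonical 5' monophosphates with probability
  `p_pnk_5p_dephos`.
* **PNK+RppH** is PNK followed by RppH.

**Ligation eligibility** gates what is sequenced: a read is retained iff
its 5' end is P, its 3' end is OH or OMe, and it passes the 50-nt size
selection. This is standard two-adapter small-RNA chemistry and is what
couples terminal states to library representation.

Two notes on this algebra:

* PNK's competing 5' kinase and phosphatase/exchange activities are
  collapsed into a single per-read net dephosphorylation probability,
  default 0.8. The default is a free parameter — the underlying
  observation is a pronounced net *loss* after PNK, without a measured
  rate — and it is exposed precisely so users can explore sensitivity.
  A side effect of modelling both activities is that the PNK operator is
  *not* idempotent for `p_pnk_5p_dephos > 0` (OH and P cycle);
  oxidation, RppH, and PNK's 3' rules are idempotent, and the tests
  assert idempotence exactly where it holds.
* The oxidation operator is a no-op on its own output because the
  eliminated read terminates in a 3' phosphate, which carries no diol.

## Inference rules and thresholds

Calls are made per fragment class (parent × half) from aggregate-RPM
ratios against the untreated aliquot:

* 3' call: oxidation ratio ≥ `protected` (default 0.5) → `protected_2OMe`;
  below → `unprotected`.
* 5' call: RppH ratio ≥ `gain` (default 2.0) → `triP`; otherwise PNK
  ratio ≤ `loss` (default 0.5) → `monoP`; otherwise `insufficient_data`.
  `triP` takes precedence when both rules fire because a genuine 5'-PPP
  population is invisible untreated, making the RppH gain the stronger
  signal.
* A ratio is only computed when its denominator reaches `floor` (default
  1 RPM). The RppH rule uses an asymmetric variant: when the untreated
  RPM is below the floor but the RppH RPM is not, the gain is `Inf` — an
  appearance from nothing, the defining signature of a pure 5'-PPP class.
  Ratios that cannot be computed propagate as `NA` and surface as
  `insufficient_data`.

None of the thresholds is a measured constant; they are working points
chosen to separate the qualitative patterns the assay produces — ratios
near 1 for protected classes versus near 0 for unprotected ones, PNK
losses near the dephosphorylation probability, RppH gains that are
multiples or infinite — with wide margins on both sides. Every call
records the thresholds it used, and the calls are invariant under common
rescaling of a panel's RPMs (only ratios enter the rules). Because both
3' rules and the `monoP` rule condition on the *untreated* library, a
class whose 3' end is phosphorylated (never ligatable in any aliquot)
correctly yields `insufficient_data` rather than a false call; the
parameter-recovery suite covers all eight ligatable-5' × 3' state
combinations and requires the derived call in ≥ 99/100 seeded replicates.

No significance machinery is attached to the calls: the inference is
ratio-based and categorical. The profile module exports tidy long-format
tables so any statistics package can be applied downstream, and
`compare_profiles()` provides scale-free cosine and Spearman summaries
for cross-sample contrasts.

## What the simulator emulates — and what it does not

`generate_library()` draws reads by class abundance, then start offset
(defaults concentrate on the first and second base of the source), length
(25–35 nt, unimodal via `peaked_length_prob()`), and terminal state; the
sequence is copied verbatim from the parent. Background reads are random
sequences rejection-checked against every indexed substring of the
halves, so truth labels are clean. Synthetic references reproduce the
10-nt terminal stem (the last bases are the reverse complement of the
first), which is what makes the split-half design exercisable in
simulation.

The shipped default configurations encode the qualitative biology the
package is designed to detect. The sperm-head configuration: Ys1
(fraction 0.35, mode 30 nt, mostly first-base starts, 5'P/3'OMe), Ys3
(0.20, mode 31 nt, mostly second-base starts, 5'P/3'OMe), Ys4 (0.15, a
0.4/0.6 mixture of 5'P/3'OMe and 5'PPP/3'OH — the mixture weight is
chosen so the class shows both clear 3' protection and an RppH gain
comfortably above the 2.0 threshold rather than sitting on it), Ys5
(0.10, pure 5'PPP/3'OH, visible only after RppH), plus 20% background.
The oocyte configuration is unprotected throughout (3'-OH), Ys3-dominant
with Ys1 nearly absent, modal lengths 31–32 nt; the modal lengths are
stated in the source literature without homolog attribution, so their
assignment to classes here is a convention, not a claim.

Deliberately **not** modelled: sequencing errors, quality scores (the
FASTQ carries a constant maximum symbol), PCR duplication, partial
chemistry efficiencies other than PNK's, and adapter emission (off by
default; a fixed 3' adapter suffix can be appended to exercise trimming,
which truncates at the first full-adapter occurrence or a ≥ 6-nt adapter
prefix flush with the 3' end). Passing tests therefore demonstrate that
the *pipeline logic* — matching, normalisation, treatment algebra,
call rules — is correct under clean reads; they do not certify behaviour
under sequencing noise, nor that real tissues match the default
abundances.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; "first base" is offset 0.
* Sequences are stored in the DNA alphabet; U → T and case folding happen
  at load. Duplicate ids, non-nucleotide characters and empty FASTA are
  rejected with named errors.
* Distribution vectors must sum to 1 within 1e-8.
* Empty libraries are legal at every stage: empty FASTQ in → all-zero
  count table; zero-read simulation → valid empty outputs.
* `homolog_ratio()` returns `NA` on a zero denominator;
  `compare_profiles()` refuses all-zero rows.
* Determinism: every stochastic step takes a seed; treatment draws use
  sub-seeds derived from the master seed (kept below $2^{31}$), and one
  config + seed reproduces byte-identical FASTQ and TSV outputs.

## Problem sizes used by the test suite

Simulated checks run at 100,000 reads per library for profile-shape and
recovery properties (the parameter-recovery suite is 8 chemistries × 100
replicates × 4 aliquots), 20,000–30,000 reads for module-level behaviour,
and 1,000 random queries for the matcher-vs-oracle equivalence. These
sizes put binomial sampling noise far below every decision threshold
(e.g. a PNK ratio of 0.2 estimated from tens of thousands of reads has a
standard error well under 0.01 against a 0.5 threshold).

## Known limitations

* Junction blindness: fragments spanning the half boundary are not
  counted. For 5'-anchored YsRNA starting at offsets 0–1 with lengths
  ≤ 35 nt this costs nothing, but the tool is not a general
  fragment-discovery engine.
* Exact matching means any SNV, editing event or sequencing error drops a
  read entirely; on real data the RPM values are therefore lower bounds.
* The alignable-read denominator is taken on trust; the package does not
  align to a genome.
* Calls are categorical. The methylated *fraction* of a partially
  protected class is not estimated, and mixtures (like the default Ys4)
  surface through their dominant signals.
* The packaged reference is a synthetic stand-in with the correct homolog
  lengths and stem structure; analyses of real libraries must supply the
  real homolog sequences.
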