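---
title: "Auditing arrayed RNAi feeding libraries in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing arrayed RNAi feeding libraries in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneaudit)
```

## The problem

Genome-wide RNAi feeding libraries — the Ahringer *C. elegans* library being
the canonical example, with 16,256 bacterial strains arrayed on 384-well
plates — were built by PCR-amplifying a genomic fragment of each target gene
and cloning it into a feeding vector. Years of genome re-annotation and the
realities of high-throughput bench work leave four kinds of defect in such a
library: (1) clones annotated to *retired* gene names that must be remapped
to whatever gene their insert actually silences; (2) primer pairs that
amplify nonspecific products; (3) cross-RNAi, where the expressed dsRNA also
silences close homologs; and (4) handling errors such as a strain loaded a
fixed number of rows or columns away from its intended well, or an empty
vector. `cloneaudit` implements, as a reusable and fully testable pipeline,
the desk-scale reliability audit of such a library: every clone receives an
integer score from 0 to 100, a green/yellow/red category, a set of flags,
and a list of the genes its predicted amplicon would actually silence.

## The evaluation procedure

For each clone the pipeline runs the following stages.

**Intrinsic primer checks.** Primer melting temperatures come from the
unified nearest-neighbor model (dH/dS stack sums with terminal initiation
terms, the entropy salt correction $\Delta S + 0.368\,(n-1)\ln[\mathrm{Na}^+]$,
and $T_m = 1000\,\Delta H / (\Delta S + R\ln(C_T/4)) - 273.15$ at 50 mM
monovalent salt and 250 nM primer). An efficient pair has both $T_m$ above
50 °C and a forward/reverse difference below 3 °C; violations are flagged
(`TM_LOW_FWD`, `TM_LOW_REV`, `TM_IMBALANCE`) but carry no score penalty, as
the scoring rules assign none.

**3'-end stability rule.** The free energy of the last five residues of
each primer — the sum of the four 3'-terminal stack energies — is checked
against −9 kcal/mol. A more stable (more negative) 3' pentamer primes
promiscuously, so such a pair is discarded and the clone scored 0 outright.
By default the pentamer rule uses the Breslauer stack table: under the
unified table's $\Delta G_{37}$ values even the most stable pentamer
(alternating G·C stacks) sums to −8.96 kcal/mol, which would make a −9
threshold unreachable and the rule vacuous. The table is switchable via
`thermo_params()`.

**In-silico PCR.** Binding sites are found on both strands of every
chromosome by requiring an exact match of the primer's 3'-terminal word
(4 nt — the polymerase extends nothing with a mismatched 3' terminus) and
computing a mismatch-aware duplex $T_m$, in which mismatched positions
contribute no stack terms; sites below 50 °C are discarded, consistent with
the 58 °C annealing protocol used to build such libraries. Amplicons are
all pairings of a plus-strand forward site with a downstream minus-strand
reverse site on the same chromosome, capped at 10 kb (products beyond that
do not amplify under library conditions), no shorter than the two primers,
and filtered by pair coverage
$\mathrm{ppc} = \tfrac12\,(m_f/\ell_f + m_r/\ell_r) \ge 0.3$, the mean
fraction of matched primer bases. A clone with no surviving amplicon scores
0 (`NO_AMPLICON`).

**Virtual gel.** Whether two predicted products are distinguishable on the
validation gel is decided by an empirical 1% agarose mobility law
$$r(L) = a + b \log_{10}(L + c), \qquad a = 4.61,\; b = -0.72,\; c = 474.65,$$
scaled through a calibration band:
$\mathrm{mobility}(L) = M_0 \, r(L)/r(2000)$, with $M_0 = 50$ mm the
migration of the 2000 bp marker band of a DL2000-style ladder. The exact
algebraic form behind the published constants is not recoverable, so the
package adopts this semi-log form — positive and strictly decreasing over
50–10,000 bp with those constants, matching standard gel behavior — and
isolates it in `gel_config()` so an alternative law can be swapped without
touching callers. Only mobility *differences* feed decisions: two bands
closer than $M_{\min} = 2$ mm (the smallest distance the naked eye
resolves) co-migrate, and co-migration groups are the connected components
of that relation.

**Similarity penalties.** For each co-migrating group of two or more
amplicons, the group's sequences are scored for similarity on a 0–100 scale
(100 × mean pairwise identity over global Needleman–Wunsch alignments,
match +1 / mismatch −1 / gap −2; identity = matches over alignment length),
standing in for a T-COFFEE-style alignment score with the same
100-for-identical calibration. The penalty is $100 - \mathrm{similarity}$,
so near-identical homologs (similarity > 95) cost at most a few points —
the clone stays green but silences the whole family — while co-migrating
*unrelated* products drag the clone into yellow or red. The same formula is
applied below similarity 95: the published rule only discusses the homolog
case, but the formula degrades smoothly and reproduces the intended
category semantics.

**Scoring and classification.** Each clone starts at 100 and accumulates
penalties on an auditable ledger (`score_clone()`, `replay_ledger()`).
Scores are integers; similarity is rounded half-up before subtraction.
Categories: score ≥ 95 reliable (green), score ≤ 10 unreliable (red),
otherwise marginal (yellow).

**Target mapping and flags.** Each amplicon is searched against the
unspliced gene sequences (both strands) with an 11-mer seeded, ungapped
extension; hits require identity strictly above 80% over at least 200 nt,
one best hit per gene. Qualification is decided exactly in integer
arithmetic (a window qualifies iff $5m > 4\ell$ at the 0.80 threshold), and
the reported window maximizes that margin. If the annotated gene is absent
from the hit list but other genes are hit, the clone is flagged `REMAPPED`
("R" on the plate map); if nothing is hit, `NO_TARGET`; two or more genes,
`MULTI_TARGET` (no penalty — silencing a redundant pair is often useful). A
clone whose amplicons hit no gene cannot silence its annotated target, so a
nominally green score is displayed and counted as yellow, matching the
yellow "R" marking convention; this is the one place category is not a pure
function of score.

**Loading-shift forensics.** When sequencing reveals a clone's actual gene,
`detect_loading_shift()` looks up the library clone annotated to that gene:
same plate and same column means a vertical ROW shift, same row a
horizontal COLUMN shift, with signed offset (actual − expected) in wells
and ties broken by smallest absolute offset. Only same-plate row/column
shifts are reported; anything else is indistinguishable from coincidental
homology at desk scale.

**Rescue.** For marginal/unreliable clones, `design_alternatives()` slides
candidate windows over the gene, keeps pairs with both $T_m$ in 55–65 °C,
$|\Delta T_m| < 3$ °C and 3' pentamer ≥ −9 kcal/mol, verifies each with the
package's own engine (exactly one genome-wide amplicon, mapping to exactly
this gene), ranks by $T_m$ balance then product size closest to 1 kb, and
returns up to five pairs. The ranking criteria are this package's own; the
guarantee that matters — every candidate re-scores to 100 — is enforced by
construction and asserted in the tests.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `monovalent_mM`, `primer_conc_nM` | 50, 250 | mM, nM | typical PCR buffer and primer load for the $T_m$ model |
| `min_duplex_tm` | 50 | °C | sites colder than this cannot prime at a 58 °C annealing step |
| `word_size` | 4 | nt | exact 3'-terminal seed; extension chemistry tolerates no 3' mismatch |
| `max_amplicon_bp` | 10000 | bp | products beyond ~10 kb do not amplify under library conditions |
| `ppc_cutoff` | 0.3 | — | weak, partially-annealed products are not credible bands |
| `a`, `b`, `c` | 4.61, −0.72, 474.65 | — | empirical 1% agarose mobility constants |
| `marker_migration_mm` | 50 | mm | typical minigel run of the 2000 bp calibration band; only differences matter, so it scales $M_{\min}$ sensitivity |
| `m_min_mm` | 2 | mm | smallest eye-resolvable band separation |
| `min_identity`, `min_len` | 0.80, 200 | —, nt | a dsRNA needs this much shared sequence to silence a gene |
| score thresholds | 95 / 10 | — | green/yellow/red boundaries |
| 3'-end threshold | −9 | kcal/mol | discard line for over-stable primer 3' ends |

## The synthetic data generator

No public accession reproduces the audit at desk scale, so
`generate_genome()` / `generate_library()` emulate the study system:
AT-biased (56% AT) random chromosomes named I–V and X carrying
non-overlapping genes with intergenic spans and two 3 kb gene deserts per
chromosome; paralog pairs embedded on *different* chromosomes at a
requested identity (exact substitution counts, shared primer windows copied
verbatim so one pair amplifies both members); retired gene names with
successors at other loci. The library generator designs primers with the
package's own thermodynamic model — including rejection of over-stable 3'
ends, as any design tool would — so clean clones are not trivially
separable from defective ones by the intrinsic flags. Injected defect
classes with per-clone ground truth: nonspecific pairs (an equal-size decoy
with exact footprints and random interior planted in a desert on another
chromosome, so the two products co-migrate but share no similarity),
intergenic amplicons, retired-and-remapped clones, loading shifts (the
three observed patterns ROW +2, ROW +4, COLUMN −2 by default), empty
vectors, and homolog co-migration via the paralog pairs. Defaults are 10%
of each hard defect plus 5% homolog clones on a 200-clone library — the
stress mix the recovery checks run under.

What the generator does **not** emulate: intron/exon structure (genes are
unspliced blocks, which is also what the target search operates on),
repeat families beyond the planted paralogs, sequencing chromatogram noise
(misreads are class-level flips at a configurable rate), indels between
paralogs, and multi-plate swaps. Passing recovery tests therefore
demonstrates that the pipeline's machinery discriminates the modeled defect
classes, not that it would score a real library identically — real genomes
have repeat structure that makes nonspecific priming both more common and
messier.

## Numerical choices

* Coordinates are 0-based half-open everywhere internally; 1-based
  inclusive only at GFF3/TSV boundaries. Overlap means non-empty interval
  intersection under the half-open convention.
* Percentages in the reporting tables are round-half-up to 2 decimals
  (`floor(100x + 0.5)/100`), which reproduces every published table value;
  R's banker's rounding does not.
* Similarity scores are rounded half-up to integers before penalties, so
  scores are integers as published.
* Threshold comparisons follow the printed wording exactly: 3'-end rule
  fires strictly below −9; identity strictly above 80%; co-migration
  strictly below $M_{\min}$; $T_m$ flags at ≤ 50 °C and ≥ 3 °C.
* Target-window qualification uses exact integer arithmetic
  ($1000\,m > 800\,\ell$), so no float rounding can flip a hit at the
  threshold.
* Degenerate inputs: empty FASTA records, duplicate ids, out-of-geometry
  wells, start > end, unknown strands and unknown chromosomes raise format
  errors naming the offending record; an empty amplicon list yields an
  empty partition; an empty evaluation set yields header-only outputs.
* The generators restore the caller's RNG state and salt the user seed per
  generator function. The salt matters: with a shared seed, two generators
  consuming the same stream can replay overlapping draws, and during
  development this materialized as "random" decoy interiors reproducing
  paralog primer footprints verbatim.
* Single-linkage co-migration groups are order-invariant; group ids are
  assigned by first appearance only for display.

## Scale of the shipped checks

The test suite and the acceptance script size their problems to what the
method needs, not more: oracle equivalence of the binding-site search runs
200 random primer/genome draws on 0.6–1.5 kb genomes against an exhaustive
per-offset scan; the recovery study uses a ~265 kb six-chromosome genome
with 252 genes and a 200-clone library; the published-table arithmetic is
exact and instantaneous. A full `devtools::test()` takes a few minutes on
one CPU.

## Known limitations

* The exact MFEprimer 1.5 internals (its PPC formula, the semantics of its
  `-e` parameter) are not published in a reproducible form; this package's
  pair-coverage score and the 10 kb cap are documented stand-ins honoring
  the printed cutoffs.
* Intermediate published scores such as 49 or 36 for individual clones
  arise from penalty arithmetic that is not derivable from the printed
  rules; the package reproduces the rules and the category boundaries, not
  those specific values.
* Hairpin/dimer screening, degenerate-base primers, partition-function
  binding models, gapped-alignment search statistics (E-values) and band
  intensity simulation are out of scope.
* The seed-and-extend target search can in principle miss a qualifying
  alignment with no exact 11-mer (e.g. a mismatch every 6th base); with
  random divergence this is vanishingly rare, and the tests compare against
  an exhaustive oracle on exactly the kind of diverged fixtures the
  generator produces.
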