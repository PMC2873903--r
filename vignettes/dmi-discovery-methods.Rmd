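---
title: "Methods: structure-based discovery of domain-motif interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based discovery of domain-motif interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmiminer)
```

# The problem and the model

A domain-motif interaction (DMI) is a transient protein interaction in
which a globular domain binds a short peptide stretch — a linear motif
— of another protein (or of a distant part of the same chain). Bound
motifs adopt a well-defined conformation that is unusually *stretched*
and *flat* for their length, whether they bind as extended strands,
polyproline-II helices or short amphipathic helices. `dmiminer` turns
that geometric signature into a discovery pipeline over 3D structures:

1. enumerate all peptide windows of 4-20 residues outside
   sequence-defined (Pfam-like) domain annotations;
2. describe each window by elongation (end-to-end C-alpha distance),
   linearity (maximum C-alpha deviation from the end-to-end line),
   modal 8-class secondary structure, mean solvent accessibility and
   length, and classify it with a linear SVM;
3. keep windows that form a genuine interface with a neighbouring
   domain (contact, area, stoichiometry, chain-context filters);
4. cluster surviving candidates per domain family by interface
   topology and by combined domain+peptide sequence identity;
5. derive consensus patterns per topology cluster from non-redundant
   peptides and assess their significance against a background
   amino-acid model;
6. optionally cross-validate patterns by over-representation among
   interaction partners in an interactome.

The core modelling assumption is that motif-likeness is visible in the
bound geometry even when the sequence does not match any known
pattern. The converse assumption — that windows inside globular
domains are not motifs — is what justifies the domain-exclusion mask;
it is also the pipeline's main known blind spot (see Limitations).

# Tunable parameters

All thresholds live in one place, `dmi_config()`:

| parameter | default | unit | why |
|---|---|---|---|
| `lmin`, `lmax` | 4, 20 | residues | range of catalogued motif lengths |
| `contact_cutoff` | 5.0 | A | heavy-atom contact distance; common interface convention |
| `contact_min_frac` | 0.60 | — | a motif forms one connected interface with its domain |
| `contact_max_gap` | 4 | residues | longest tolerated non-contacting run |
| `min_interface_area` | 150 | A^2 | floor on the buried domain-peptide interface |
| `min_total_ratio` | 0.5 | — | peptide must carry half the inter-protein interface; 0.5/N per domain for N domains |
| `min_seq_dist` | 10 | residues | intrachain peptides flanking their own binding domain are usually assignment artefacts |
| `homomer_identity` | 0.98 | — | chain identity at/above which a pair is called homomeric |
| `topo_cut` | 1.0 | — | complete-linkage cut: distance 1 means no shared contacts |
| `seq_cut` | 0.1 | — | combined-identity cut, i.e. 90% identity diameter |
| `min_upcs` | 3 | clusters | minimum non-redundant support for motif derivation |
| `motif_p` | 0.05 | — | corrected significance threshold for reported patterns |
| `enrichment_p` | 0.025 | — | one-sided Fisher threshold in cross-validation |

The interface-area convention is *half* the total SASA buried on
complex formation (`(SASA_a + SASA_b - SASA_ab)/2`); per-monomer
conventions differ by a factor of about two, which is why the area
floor is configurable rather than hard-wired.

# Numerical choices

**Solvent accessibility.** Shrake-Rupley with 960 Fibonacci-lattice
sphere points and probe radius 1.4 A. Each atom's point lattice is
oriented by a smooth inverse-distance-weighted neighbour frame, so the
sampled points move rigidly with the structure: computed areas are
exactly invariant under rotation and translation, and insensitive to
the exact distance ties that regular test lattices produce. Doubling
the point count changes per-residue areas by under 2%.

**Secondary structure.** When no DSSP file is supplied, an internal
C-alpha-geometry assigner fills H/E/-: a residue is helical if covered
by an i..i+3 window whose C-alpha span lies in 4.2-6.0 A (ideal
alpha-helix: 5.1 A), extended if covered by a 5-residue window whose
trace deviates < 1 A from a straight line. This is a deliberate
simplification of DSSP (no hydrogen-bond assignment, no G/I/B/T/S
classes); it agrees with DSSP on the ideal geometries used in tests,
and a classic DSSP output file is used verbatim when provided. Each
chain is assigned in isolation, mirroring per-protein DSSP practice.

**SVM.** Linear kernel, error/margin trade-off C = 0.1, positive
errors weighted 10x (class-weighted C reproduces the cost-factor
semantics of SVM-light). Features are z-scored with training-set
statistics stored in the model; the one-hot secondary-structure block
is left unscaled. The solver tolerance is tightened to 1e-6 so the
decision function is stable (to ~1e-6) under training-row
permutation. The decision threshold is strictly positive: a decision
value of exactly zero is rejected.

**Modal class tie-break.** The modal DSSP class of a window breaks
ties by the fixed priority H > E > G > I > B > T > S > -, preferring
the strong regular classes.

**Linearity degenerate case.** If a window's terminal C-alphas
coincide the axis is undefined; this is reported as an error rather
than linearity 0, to avoid calling a closed hairpin "linear".

**Stoichiometry iteration.** With N bound domains, domains with
interface ratio below 0.5/N are dropped and N updated until no drop
occurs; the iteration strictly decreases N, so it terminates in at
most N rounds. A single remaining domain below ratio 0.5 is likewise
dropped, leaving an empty set — the candidate is rejected either way.

**Clustering cuts.** The topology cut at 1.0 is exclusive (fully
disjoint interfaces, distance exactly 1, stay separate), while the
sequence cut at 0.1 is inclusive (clusters have combined-identity
diameter <= 0.1, i.e. 90% identity). The hand-rolled agglomerator
makes both semantics explicit and breaks distance ties by the
lexicographically smallest pair, so cluster output is invariant under
input permutation; `stats::hclust` is used as an independent
cross-check in the test suite, not as the implementation.

**Motif significance.** The external motif finder used historically
for this task is replaced by an internal enumerator: all patterns with
2-5 fixed positions and total span <= 8 occurring in the sequences are
counted, with support counted at most once per UPC, and ambiguity
classes (brackets of 2-3 residues) formed from single-position
variants. Each pattern's raw p-value is the binomial tail
P(X >= support) with per-UPC match probability derived from the
background amino-acid frequencies and sequence lengths. Because tens
of millions of patterns are implicitly searched, raw p-values are
Sidak-corrected for the size of the enumerable space; bracket patterns
are charged for the (much larger) one-ambiguous-position space, which
keeps a more specific fixed pattern ranked above its own bracketed
extensions. This binomial-plus-correction model is this package's own
significance stand-in: it controls the null (no significant pattern on
background-only sequence sets at the expected rate) but its p-values
are not comparable to any external tool's. Terminal anchors are never
inferred, because structure fragments are routinely truncated. In
helical clusters (strict majority of helical modal classes), defined
positions are restricted to helix-face offsets {0, 3, 4, 7}; residues
modified in a strict majority of a cluster's peptides are required as
fixed positions in reported patterns.

**Enrichment.** The factor is `(i_m/i)/(m/p)` and the test the
hypergeometric upper tail P(X >= i_m) with margins (i, m, p). Matches
straddling a domain boundary count as inside (strict
outside-of-domains rule). Each pattern is tested at p <= 0.025 with no
additional multiple-testing correction, matching the printed
procedure this pipeline reproduces; users testing many patterns
should bear that in mind.

# What the synthetic generators emulate — and what they do not

The package is fully testable offline through four generators, whose
defaults are the study conditions used by the test and acceptance
suites:

* `ideal_peptide_coords()` — the geometric classes of bound peptides:
  helix (rise 1.5 A/residue, radius 2.3 A, 100 deg/residue), extended
  strand (3.8 A steps in an alternating +/-5 deg pleat with small
  seeded jitter, keeping linearity < 0.5 A at n = 7) and self-avoiding
  coil. A wider +/-10 deg independent jitter makes cumulative
  excursions that violate the flatness the strand class is supposed to
  embody, so the pleated form is used.
* `toy_complex()` — a compact lattice "domain" with a peptide laid
  along a face so that every peptide residue is in heavy-atom contact
  and the buried interface clears 150 A^2 by construction; variants
  place the peptide 60 A away (contact-filter fixture) or add a
  second, domain-masked chain segment that buries more area than the
  peptide (interface-ratio rejection fixture).
* `synth_motif_set()` — one background sequence per UPC (flanks of 12
  residues either side) with one planted pattern instance, or pure
  background for null experiments.
* `synth_interactome()` — 1000-ish protein networks (mean degree 4,
  10% domain carriers, 60-residue sequences) with motif insertion at
  0.05 background rate and 0.15 among interactors for power runs, or
  equal rates for null runs. The 3x planted enrichment and these
  problem sizes (500-protein nulls, 1000-protein power runs) are the
  simulation conditions reported by the acceptance script.

These fixtures are geometric and statistical idealisations: lattice
domains are not folds, pseudo-backbones carry no side chains beyond
C-beta, sequences are i.i.d., and networks are Erdos-Renyi-like.
Passing tests therefore demonstrate the *contracts* of each stage —
counts, filters, invariances, recovery and error rates under the
stated models — not performance on real crystallographic data, with
its disorder, missing residues, crystal contacts and non-uniform
sequence composition.

# Benchmark protocol

`run_loo_benchmark()` scores discovery in a leave-one-domain-out
fashion: for each family, the SVM is retrained without that family's
peptides, discovery is rerun on the family's structures, and a test
case counts as recovered iff an accepted peptide overlaps a known
test peptide in at least 3 positions *and* a significant consensus
pattern is derived for its cluster. Families with fewer than 3
non-redundant sequences are reported as ignored rather than as false
negatives. On the synthetic three-family benchmark (three bound-strand
complexes per family, family-specific planted tetrapeptide motifs)
the held-out families are recovered completely and no helical/coil
negative is accepted — a separability statement about the constructed
design, not a field sensitivity estimate.

# Design choices on genuinely open points

* The topology distance is the Dice-style form
  `1 - 2|A n B|/(n_A + n_B)`: it is the only such form that satisfies
  both stated anchors (distance 1 iff no shared contacts; interfaces
  whose sizes differ by more than 2x are distinct outright). The
  combined sequence distance is the arithmetic mean of domain and
  peptide identities turned into a distance — the simplest combination
  consistent with "90% combined identity".
* Peptide-region alignment scoring: match +1, mismatch 0, gap open
  -1, gap extend -0.5 (configurable); identity is identical positions
  over alignment length.
* Homomers are detected by global-alignment chain identity >= 98%
  over the shorter chain.
* Peptide regions merge only on shared residues; mere sequence
  adjacency does not merge two windows.
* Background amino-acid frequencies default to the input structure
  set rather than an external corpus, keeping runs self-contained; any
  frequency table can be supplied.

# Known limitations

* Motifs inside annotated sequence domains are invisible by
  construction — historically the largest source of missed true
  motifs for this class of pipeline.
* The internal secondary-structure assigner distinguishes only H/E/-;
  supply DSSP files for full 8-class fidelity.
* The significance model is a documented stand-in; p-values are
  comparable within a run, not across tools.
* Binding energetics are never evaluated; the interface-area ratio is
  the only proxy for the peptide's contribution.
* Intrachain-only clusters cannot be validated by the interactome
  route and are gated by the interchain-membership eligibility rule.

# Problem sizes used by the shipped suites

The test and acceptance suites run at desk scale: toy complexes of 48
domain + 8 peptide residues, three-family benchmarks, 100-replicate
motif-recovery batteries, 400-1000-replicate network simulations at
500-1000 proteins. These sizes give stable rates for the properties
being asserted while keeping a full run in the minutes range on one
CPU.
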