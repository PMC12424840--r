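---
title: "Methods: association mining and druggability triage in phytomine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association mining and druggability triage in phytomine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytomine)
```

## The problem

Traditional-medicine pharmacopeias record multi-ingredient *formulas*: each
links plant species, the phytochemicals those species contain, and free-text
therapeutic *indications*. phytomine mines such tables for four
neuro-related disorder categories — Anxiety/Mood, Movement/Seizure, Pain and
Sleep — to ask which compounds are repeatedly associated with those uses
across medical systems, and which of them are tractable starting points for
formulation. The motivating use case is the genus *Piper*: kava
(*Piper methysticum*) has clinically supported anxiolytic use attributed to
its kavalactones, and the question is whether other, more widely distributed
*Piper* species carry non-kavalactone chemistry associated with the same
indications.

## Data model and ingestion

The canonical unit is the **formula**: an identifier, its medical system,
region, a non-empty set of member species, a list of free-text indications,
and — through its species — a set of compounds. A compound is attributed to
a formula when **any** member species of that formula is linked to the
compound. Source tables rarely state how species-specific compound lists
were flattened into formulas, so this any-member-species rule is the
package's documented choice; it is the most inclusive lifting and is applied
uniformly.

Compound identity is reconciled with the precedence **InChIKey > CID >
normalized name**: the InChIKey is the most structure-specific identifier,
the CID the next, and a case-folded, punctuation-collapsed name the
fallback. Two records merge when they share an InChIKey; records without
one merge on a shared CID; records with neither merge on equal normalized
names. The merge is a single-pass partition — it is deliberately *not* a
transitive closure across identifier systems, because chaining weak links
(name equals name, which shares a CID, which shares a key…) propagates
curation errors across otherwise distinct compounds. Identifier conflicts
inside a group (one InChIKey, two CIDs) keep the smallest value and are
logged, never fatal. An optional lookup table (name to InChIKey) emulates
database enrichment and lets name-only records join key-bearing ones.

Species names are reduced to clean binomials (authority strings and
infraspecific ranks dropped, genus capitalized, epithet lower-cased), with
an optional synonym table applied afterwards. Regions pass through an
optional ISO 3166 lookup and are otherwise carried verbatim with a warning.

## The indication dictionary

The four categories are defined by a term dictionary of literal words and
truncation patterns (18 Anxiety/Mood, 15 Movement/Seizure, 13 Pain and 9
Sleep patterns in the packaged default). A trailing asterisk
(`depress*`) matches tokens that start with the stem; a leading asterisk
(`*ache`) matches tokens that end with it; a bare term matches whole
tokens only. Matching is case-insensitive on tokens split at
non-alphanumeric characters, so `"sleep-disorder"` tokenizes to
`sleep`, `disorder`.

Whole-token semantics is a deliberate design decision: the truncated forms
are explicitly marked, which implies the unmarked forms are exact, and
substring matching over-fires badly (`"benefits"` would match `fits`,
`"calmness"` would match `calm`). The substring alternative remains
available (`mode = "substring"`) for sensitivity analysis. A formula's
category set is the union over its indication strings; a formula treating
k categories counts once in each of the k categories in every downstream
statistic — there is no fractional weighting.

## Association statistics

Two percentage definitions coexist and are never interchangeable:

* the **association percentage** of compound *x* for category *c* has as
  denominator the formulas *containing x*, and as numerator those of them
  whose category set includes *c*. The four percentages sum to at most
  400; the **candidate filter** keeps compounds whose sum strictly
  exceeds 300 ("exceeding" reads as a strict inequality), sorted by sum,
  then formula count, then key, so outputs are byte-stable;
* the **containment percentage** has as denominator the formulas
  *treating c*; the **compound index** is the arithmetic mean of the four
  containment percentages. A category treated by no formula is excluded
  from the mean with a warning (or raises an error in strict mode).

Species-level statistics follow the pairing rule: a formula with *s*
qualifying species treating *c* categories contributes *s x c*
species-category linkages, each counted individually — so one formula
with two focal-genus species and all four categories yields eight. The
enrichment ratio compares a species' share of category-linked
formula-species memberships with its share of all memberships; values
above 1 flag over-representation. Formulas (not formula-region pairs)
are the counting unit throughout; region is a grouping column only.

## Meta-metabolome assembly

Per-source compound lists (literature compilations, databases, extraction
studies) merge through the same reconciliation into one composite
"meta-metabolome" with a compound-by-source presence matrix. Chemical
classes use eight bins (alkaloid, benzenoid, terpene, cinnamic acid,
flavonoid, kavalactone, chalcone, miscellaneous) assigned by a two-layer
rule: identifier-level overrides first, then case-insensitive keyword
rules on the source-supplied classification string, with miscellaneous as
the total fallback. Both layers ship as an editable CSV because source
classifications are driven by naming conventions and users will want to
pin individual compounds. Within-source duplicates count once — the unit
is the compound, not the report. The packaged fixture
(`synthetic_pm_sources()`) is a synthetic stand-in whose eight class
sizes (29/31/39/28/10/35/17/79, total 268) mirror a published kava
survey; the compound identities are generated, and the fixture exists to
exercise the assembly contract, not to transcribe the survey.

## Networks

The species-compound bipartite network has one edge per distinct
(species, compound) link; compound nodes carry their class bin. The
species projection quantifies "sharedness" with both the raw shared-
compound count and the Jaccard index — the normalized view matters
because chemically over-studied species (e.g. black pepper) dominate raw
counts. Exports are a TSV edge list and GraphML with node attributes;
rendering and layout are left to external viewers, and no filtering is
applied at export.

## Druggability triage

Scalar descriptors (molecular weight, ALogP, topological polar surface
area, H-bond donors/acceptors, rotatable bonds) come from OpenBabel;
"polar surface area" is computed topologically (TPSA), the standard
reading in this descriptor family. Acceptor counting defaults to the
refined pharmacophore-style definition with a plain N+O mode available
(`hba_mode = "n_plus_o"`), since sources differ on the convention. The
2048-bit circular fingerprint (radius 2, ECFP4-class) is computed by the
package on the molecular graph: initial atom invariants (atomic number,
heavy degree, bond-order sum), two neighbourhood-hashing rounds, all
identifiers folded into 2048 bits. It is deterministic and
hydrogen-free; it is used as a machine-learning feature block, and no
downstream result depends on bit-compatibility with any other toolkit.

Rule-of-five violations count strict breaches of MW > 500, ALogP > 5,
HBD > 5, HBA > 10. Weighted QED is the exponentially weighted geometric
mean of eight asymmetric-double-sigmoid desirabilities with the canonical
published parameterization, shipped as a data file; the structural-alert
property uses a curated alert list (also an editable data file). The
desirable bands used in set comparisons are 0.4-0.7 for weighted QED and
0.5-2.5 for NP-likeness.

NP-likeness scores (scale -5 to +5) are an input column where observed;
missing scores are imputed by a random-forest regression on the
fingerprint plus the six scalar descriptors, with 150 trees, maximum
depth 80 and an unstratified 85/15 train/validation split. The forest
follows the reference regressor's behaviour of considering **all**
features at each split and splitting nodes down to pairs
(`imputer_config(mtry = NULL, min_node_size = 2)`); this matters on a
feature block of 2054 columns where only a handful drive the signal, and
is configurable. One seed governs split, bootstrap and feature
subsampling. Observed values are never overwritten, and records whose
structures cannot be featurized are skipped with a log entry rather than
silently imputed.

## Synthetic data: what it emulates, and what it does not

The generators define the package's reference study conditions:

* `simulate_formula_dataset()` — default 200 formulas over 30 species
  (40% focal genus) and 40 compounds; per-category prevalences 0.35 /
  0.25 / 0.40 / 0.30 (pain most common, movement least, mirroring the
  relative frequencies seen in pharmacopeia mining); 1-3 uniformly drawn
  species per formula; species-compound density 0.15; baseline
  compound-carrier inclusion 0.08. Indication strings come from a phrase
  bank that fires exactly the drawn categories; decoys ("benefits",
  "calmness") pin the whole-token matching semantics. Associations are
  planted through carrier species, so every statistic remains exactly
  enumerable from the emitted tables; an optional planted compound rides
  a dedicated species inserted only into formulas covering the target
  categories, which drives its percentage sum to 400 by construction.
* `simulate_compound_records()` / `simulate_source_tables()` — blank
  identifiers per compound-level regime (key-bearing / CID-only /
  name-only) so the single-pass precedence merge can provably recover
  the true partition; fully random blanking would make the target
  partition unrecoverable by *any* non-transitive merge.
* `simulate_molecule_panel()` — enumerates 14 scaffold templates
  (benzenoids, cinnamates, kavalactone-like lactones, piperamide-like
  amides, indoles, chalcones, flavones, a menthane terpene, a glycoside)
  with two substituent positions over 16 fragments; every combination is
  a valid structure. Labels are a fixed linear function of five scalar
  descriptors (intercept 1.2; -0.004 per Da above 300; -0.35 per ALogP
  unit; +0.012 per A^2 TPSA; +0.25 per donor; -0.15 per rotatable bond)
  plus seeded Gaussian noise, clipped to [-5, 5]. The coefficients were
  chosen once to give a natural-product-like gradient (polar, rigid,
  donor-rich molecules score higher) with most mass inside the scale.

What passing tests on these data do **not** show: real pharmacopeias have
correlated categories, vernacular and misspelled indication text,
non-uniform species usage, and compound panels far outside the template
library's chemical space. The generators validate the *statistical
machinery* (denominators, counting rules, reconciliation, model
plumbing), not the field behaviour of the dictionary or the imputer.

A note on imputer validation: with noise-free labels that are exactly
linear in descriptors, a random forest cannot extrapolate the linear
surface, only interpolate it, so validation R-squared saturates near —
but slightly below — 0.99 (about 0.989 at n = 2000 under the reference
conditions): the residual comes from held-out molecules without a close
descriptor twin in training. With label noise at sigma = 0.25 the
validation R-squared is about 0.89, and with shuffled labels it is
indistinguishable from zero, which together bracket the imputer's
behaviour.

## Numerical and reproducibility choices

* All generator randomness flows through one fully specified RNG
  (Mersenne-Twister, inversion normals, rejection sampling), so a seed
  fixes every byte of every output file on every platform.
* Sorted, deterministic orderings everywhere a file is written: profiles
  by descending percentage sum with documented tie-breaks, networks by
  node name, interchange CSVs by key. Re-running any stage with the same
  seed and inputs is byte-identical.
* Degenerate inputs have defined behaviour: a compound in no formula has
  undefined (NA) percentages rather than zeros; an empty category is
  excluded from the compound index with a warning (error in strict
  mode); unparseable structures raise an error carrying the input in
  strict contexts and are dropped with a message in batch contexts;
  empty compound sets produce n = 0 rows with NA statistics.
* Problem sizes used by the shipped checks (100 datasets of up to 50
  formulas for oracle equivalence; 2000 molecules for imputer recovery)
  were chosen as the smallest scales at which the binomial and forest
  behaviours stabilize.

## Known limitations

* The dictionary is English-only, with no stemming or fuzzy matching;
  recall on real free text will be lower than on the phrase bank.
* Descriptor values follow OpenBabel's definitions; other toolkits
  differ slightly on acceptor counts and rotatable bonds, which shifts
  absolute (not relative) druggability scores.
* The structural-alert list is a pragmatic curation (~20 patterns);
  alert counts are smaller than those of exhaustive published
  collections, which nudges weighted QED upward for alert-rich
  molecules.
* Ertl-style NP-likeness is not computed from structures; the package
  imputes from observed scores and says so per record (`np_source`).
* Reconciliation cannot merge records that share no identifier system;
  with heavily blanked real data, compound counts are upper bounds.
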