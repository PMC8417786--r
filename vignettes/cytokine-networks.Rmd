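---
title: "Mining and modeling cytokine signaling in lysosomal storage diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and modeling cytokine signaling in lysosomal storage diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytolit)
```

## The problem

Chronic inflammation is a recurring clinical feature of lysosomal storage
diseases, in particular the three sphingolipidoses covered here: Gaucher
disease (GD, glucosylceramide accumulation), acid sphingomyelinase
deficiency (ASMD, historically Niemann-Pick disease types A and B,
sphingomyelin accumulation), and Fabry disease (FD, globotriaosylceramide
accumulation). Knowledge about which cytokines are involved is scattered
across decades of publications. `cytolit` implements an integrative
workflow that (i) extracts disease-cytokine relations from literature text
with a dictionary-based, sentence-level relation miner, (ii) asks in which
blood immune cell types the mined cytokines are preferentially expressed,
(iii) reconstructs transcription-factor (TF) to cytokine regulatory
networks restricted to a cell type of interest, and (iv) scores directed
cell-cell communication from ligand-receptor pair counts.

Every stage consumes plain-text inputs (JSONL corpus, TSV tables, GMT gene
sets), and the package ships generators that emulate all of them with
planted ground truth, so the full workflow is testable without any
download.

## Dictionaries and variant expansion

Concepts are organized in five categories: disease synonyms, accumulated
metabolites (including deacylated lyso-species such as lyso-GL1),
mutated-enzyme names, cytokines, and TFs. Each synonym is expanded into
the closure of three alternations before indexing:

* hyphen / space / fused: `interleukin-6`, `interleukin 6`, `interleukin6`;
* Greek letter vs spelled-out name: `IFN-γ` vs `IFN-gamma`;
* case-insensitive canonical form (lowercase, collapsed whitespace,
  trailing punctuation stripped).

The expansion is deterministic and idempotent, so the surface-form index
is a fixed point: looking up any variant of any synonym resolves to its
entry. Common mistypings (`neimann-pick`) are included as ordinary
synonyms. A cytokine name that the registry attaches to zero or more than
one gene symbol (e.g. `MIP-1`, which denotes both CCL3 and CCL4) is
flagged *ambiguous at build time* and excluded from all gene-level
analyses; ambiguity is a property of the name, decided once, not at query
time.

## Relation mining

Documents are segmented into sentences with an abbreviation-safe,
rule-based splitter (offsets are 0-based half-open and every sentence
equals its source slice, which the tests fuzz corpus-wide). Entity
tagging is greedy longest-match, left-to-right, at word boundaries on the
normalized text. A relation triple (effector, trigger verb, affected) is
emitted for every co-occurring cytokine / disease-concept mention pair in
a sentence that contains a trigger verb.

The directionality rule is deliberately simple: when a trigger verb lies
strictly between the two mentions, the mention preceding the trigger is
the effector; when triggers are present in the sentence but not between
the pair, the earlier mention is taken as effector and the trigger nearest
the pair is recorded. This adjacency heuristic replaces a full syntactic
parser while preserving the effector/verb/affected output contract; the
trigger-verb list is a plain config file
(`system.file("extdata", "trigger_verbs.txt", package = "cytolit")`), so
the precision/recall trade-off is auditable and adjustable. Paragraph-level
co-mention is deliberately not implemented: sentence scope keeps precision
high at a known cost in recall.

Filtering then removes (a) relations from clinical-trial records,
(b) relations in methods-like sections (the section-name set is
configurable; protocol text rarely reports findings), (c) relations whose
cytokine cannot be mapped to a unique gene symbol, and (d) for ASMD,
relations whose sentence names a Niemann-Pick subtype other than A or B —
types C-F are genetically distinct diseases. A Niemann-Pick mention
without an adjoining subtype pattern (`type X`, `NPD X`, `NP-X`) counts as
generic and is retained.

Associations aggregate the retained triples per (disease, cytokine):
distinct-sentence counts (deduplication key: document, section, offsets),
distinct-article counts, and a flag for evidence in a title or abstract.

## Cell-type specificity

The expression atlas models a consensus blood atlas over eight immune cell
types (eosinophils, basophils, neutrophils, T cells, B cells, monocytes,
NK cells, dendritic cells). A gene is *expressed* in a cell when its
normalized expression (NX) is strictly greater than 1; genes absent from
the atlas or classed `not_detected` are removed from networks with a
warning rather than treated as unexpressed — the CCL18 situation, where the
most-cited GD cytokine cannot be evaluated at all. A gene is
*cell-specific* when its atlas class is cell-type enriched (one cell) or
group enriched (a small group); a group-enriched gene belongs to the set of
every cell in its group.

Overrepresentation of a mined cytokine list in a cell-specific set is
tested with the one-sided Fisher (hypergeometric upper-tail) probability
P(X ≥ overlap). The universe is the *dictionary*: all cytokines with an
unambiguous human gene symbol, whether or not the atlas detects them —
membership in the universe is a property of the search, not of the
measurement. Sets overlapping the query in fewer than five genes are not
tested at all (reported with `tested = FALSE` and no p-value). When only
one set passes this rule no multiplicity correction is needed; when
several sets are testable the package reports BH-adjusted values alongside
the raw ones so either convention can be audited.

## Regulatory networks and co-expression

The TF-cytokine network applies three filters to a curated interaction
table, in order: human interactions only; cytokines identified by mining;
both endpoints expressed (NX > threshold) in the target cell. The filters
commute (asserted on random fixtures), and raising the threshold can only
shrink the network. Duplicate evidence rows collapse to one directed
edge; a symbol appearing on both sides gets role `both` so degree
accounting stays well defined.

Co-expression uses the atlas design of six donor samples, each measured in
three monocyte subtypes; the sample-level value is the subtype mean.
Each edge is tested with the Pearson product-moment correlation,
two-sided, p from t = r·sqrt(n−2)/sqrt(1−r²) on n−2 degrees of freedom.
Significance is raw p < 0.05 (the convention matched by "significant
correlation" in this literature); BH-adjusted values are reported next to
the raw ones. With n = 6 the test is badly underpowered — the suite
verifies that a true correlation of 0.5 is rejected in well under half of
simulated runs — so significant edges are leads, not conclusions.

## Cell-cell communication

Cytokine-receptor (CR) pairs are read off a ligand-receptor database;
cytokines absent from the database are listed in a dropped-report, not
silently ignored. Pathway overrepresentation of the cytokines and their
receptors uses the hypergeometric test against a custom background (the
dictionary cytokines present in the database plus their receptors), with
pathways restricted to the background, a minimum restricted set size of 5,
and BH correction.

The communication network is built over all ordered (sender, receiver)
cell pairs, self-pairs included: the edge weight is the number of CR pairs
whose ligand is expressed in the sender and whose receptor is expressed in
the receiver. Retention keeps edges whose weight strictly exceeds the
75th percentile of the weight distribution over all 64 ordered pairs.
"75th percentile" is ambiguous across at least nine quantile conventions;
this package fixes linear interpolation between order statistics (R's
default type 7), under which counts (1, 2, 3, 4) give a threshold of
3.25. The strict reading of "above" means an all-equal count distribution
retains nothing; `strict = FALSE` switches to ≥ for sensitivity analysis.
Both the percentile base (ordered pairs including zeros) and the
inequality are configurable and logged.

## The synthetic study and what it shows

The generator defaults define the study conditions:

* **Corpus**: 20-24 documents, planted per-disease cytokine lists that
  share exactly six cytokines across GD, FD and ASMD (CCL5, CXCL8, IL1B,
  IL4, IL6, TNF), each association realized by 1-6 templated sentences
  whose trigger verb lies between the entities; 50% decoy sentences
  covering every filter branch (cytokine-only, methods-section placement,
  clinical-trial records, the ambiguous `MIP-1`, a Niemann-Pick type C
  relation). The first sentence of each association is planted in an
  abstract.
* **Atlas**: log-normal background NX with median 1 (sdlog 0.6 by
  default, 0.5 in the bundled study), so the NX > 1 rule bisects the gene
  pool and both filter branches are exercised; a monocyte-specific block
  of six cytokines (CCL1, CCL2, CXCL10, CXCL12, IL1RN, EPO); CCL18 marked
  not detected; GD cytokines and the TF pool elevated in monocytes,
  receptors elevated in T cells.
* **Sample-level expression**: 6 samples × 3 subtypes, subtype noise
  sdlog 0.1 — within-donor subtype profiles are highly concordant, so
  subtype-level noise is small relative to across-donor variance; the
  averaged series then attenuates a planted correlation by less than 1%.
* **Problem sizes** elsewhere: 200 randomized instances (universe ≤ 60)
  for the hypergeometric oracle, 100 random p-vectors for the BH oracle,
  500 replicates for correlation coverage and power. These sizes give
  stable Monte-Carlo estimates while keeping a full test run under a
  minute.

Recovering the planted truth with precision and recall 1.0 shows that the
mining contract (tagging, directionality, filters, counting) is
self-consistent; it does **not** show that the heuristic parses real prose
well. Real literature has coreference, negation, hedging, and relations
spanning sentences — all out of scope here (the sentence-scope and
trigger-adjacency choices trade recall for precision by design). The
generated text is deliberately simple; harder templates can be added to
the template config file to probe the heuristic's limits. Likewise the
atlas emulates specificity classes and expression magnitudes but not
compositional effects, batch structure, or the correlation between
specificity class and expression level found in real consensus datasets.

## Numerical and degenerate-input choices

* Hypergeometric and BH computations delegate to `phyper` / `p.adjust`
  and are checked against independent enumeration and step-up oracles to
  1e-12.
* Strict inequalities everywhere a threshold is stated (NX > 1,
  count > percentile); boundary cases (NX = 1, all counts equal) are
  fixed by tests.
* Empty results are valid: an empty mined list, an all-filtered
  interaction table, or an empty ligand set produce empty networks with
  warnings, never errors.
* Zero-variance genes are excluded from correlation with a warning (r is
  undefined); samples missing a gene in every subtype yield NA and a
  warning.
* All randomness flows from a single seed per generator; the pipeline
  seed derives per-stage seeds by fixed offsets, so one integer
  reproduces a full run byte-identically.

## Known limitations

* The trigger-adjacency heuristic assigns directionality by position, not
  syntax; passive constructions can swap effector and affected.
* Disease-cytokine sentence and article totals depend entirely on the
  corpus supplied; the package makes no claim about absolute counts in
  the real literature.
* The enrichment universe comes from whatever registry table is supplied;
  its size changes p-values and is not a constant of the method.
* With six samples, co-expression significance has low power and the
  reported significant pairs should be treated as hypotheses.
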