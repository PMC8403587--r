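---
title: "Methods: genome mining for biosynthetic gene cluster families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome mining for biosynthetic gene cluster families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Filamentous fungi encode most of their secondary metabolism in biosynthetic
gene clusters (BGCs): co-localised genes comprising a core synthase —
a polyketide synthase (PKS), nonribosomal peptide synthetase (NRPS), terpene
cyclase, citrate synthase, prenyltransferase, or a ribosomally synthesised
precursor peptide (RiPP) — together with tailoring, regulatory, transport
and resistance genes. Given annotated genomes, `bgcfam` answers four
questions in sequence:

1. **Which genes are biosynthetic cores?** Smith–Waterman search of every
   gene product against a template library of known core enzymes.
2. **Where does each cluster start and end?** A border rule over
   homology-based function calls on the neighbouring genes.
3. **What kind of pathway is it?** A precedence-ordered class taxonomy over
   the domain architecture and gene content of each locus.
4. **Which clusters across species are the same pathway family?** A
   similarity network over domain inventories whose connected subnetworks
   are gene cluster families (GCFs).

Because real fungal genome cohorts, curated protein databases and reference
BGC collections cannot be redistributed with the package, every stage is
validated against synthetic cohorts with *planted* clusters whose borders,
classes and family structure are known exactly.

## Alignment model

All similarity decisions run through one primitive: local alignment under
BLOSUM62 with affine gap cost "11 1", i.e. a gap of length $L$ costs
$11 + L$. The unknown residue `X` scores 0 against everything. Significance
uses the Karlin–Altschul form

$$E = K \, m \, n \, e^{-\lambda S}$$

with the published gapped-BLOSUM62 constants $\lambda = 0.267$,
$K = 0.041$, query length $m$, and $n$ the *total* residue count of the
searched database (the whole proteome for genome scans). The database-length
convention matters: at the permissive core-search threshold $E \le 10^{-1}$
a search is expected to produce about 0.1 chance hits *per proteome*, not
per gene. The implementation is verified against an independent brute-force
affine-gap dynamic program in the test suite.

Tunables (defaults): core search `max_evalue = 1e-1` (the published search
protocol); neighbour function calls `max_evalue = 1e-5` — stricter because a
single spurious neighbour call can extend a border by up to three genes;
domain matcher acceptance at 0.3 of a reference's self-score.

## Core detection and domain strings

The bundled template library mirrors a 17-entry manifest of characterised
core enzymes (type I and type III PKS, an NRPS adenylation domain, eight
terpene/triterpene cyclases including a fernane-type synthase, citrate
synthase, tryptophan dimethylallyltransferase, three RiPP precursors). Every
gene keeps at most one core hit: the best-scoring template at
$E \le 10^{-1}$, ties broken by E-value then accession, which makes
detection invariant to template order.

Domain strings are parsed with a deliberately simple, auditable matcher:
one reference segment per label in the controlled vocabulary
(`domain_vocab()`), greedy non-overlapping selection by score with re-fitting
of displaced candidates to the remaining intervals. A pre-computed domain
annotation table, when supplied, takes precedence per gene, so an external
profile-HMM annotator can be plugged in without touching downstream code.
Two consequential minimal definitions are made explicit here:

* a gene is a **PKS** iff its domain string contains KS and (AT or ACP);
* an **NRPS module** is an ordered C–A–T triple; one complete module
  suffices for the NRPS class (module counts are reported alongside).

## Border calling

Walking outward from a core gene in each direction independently, the locus
ends as soon as **three consecutive genes** are unrelated — no homolog in
the labelled function database at $E \le 10^{-5}$, or a best hit that is a
housekeeping protein. "Consecutive" counts genes only, regardless of strand
or intergenic distance. The locus is trimmed back to the outermost related
gene; a contig end terminates a walk early; a core whose neighbours are all
unrelated forms a single-gene locus (single-gene loci are still reported as
BGCs). Loci sharing genes are merged, and merged loci with two or more
type I PKS cores carry a `collaborative_candidate` flag — the flag records,
rather than resolves, the known ambiguity that adjacent independent
pathways can intertwine.

## Class taxonomy

`classify_locus()` applies the first matching rule in a fixed precedence
order: exclusions first (the A-T-R-R glycine-betaine-reductase architecture
and the single-gene primary lanosterol synthase copy are primary
metabolism), then RiPP, then the most gene-content-specific composites
(alkyl citrate: citrate synthase plus a dedicated FAS pair or an hrPKS;
meroterpenoid: PKS plus prenyltransferase and/or terpene cyclase), then
single-protein PKS/NRPS hybrids (PKS-NRPS when the KS/AT half is
N-terminal), collaborative PKS, disintegrated PKS, the PKS reduction
subtypes, type III PKS (recognised by template similarity, not domains),
NRPS and the two NRPS-like architectures (A-T-TE vs A-T-R), the diterpene
split (bifunctional labdane-type cyclase — TC and GGPPS domains on one
protein — before GGPPS-coupled two-gene systems), triterpene (clustered
LSS or any squalene-hopene-type cyclase), DMAT alkaloid, and finally
mono/sesquiterpene. A fallback on the core template's target class makes
the assignment total.

PKS subtypes are formalised as: hrPKS requires the full reducing loop
(KS, AT, DH, ER, KR); a string missing KS, AT or ACP is truncated; no
reductive domain at all is non-reducing; any partial reductive set short of
the full loop is partially reducing. The truncated check must precede the
non-reducing check — a bare KS-AT fragment has no reductive domains yet is
a defective gene, not an nrPKS. A disintegrated PKS is two *partial* genes
within 10 kb whose domain sets are complementary and together complete
(e.g. KS-AT-DH-CMeT-ER plus KR-ACP, the split observed about 8 kb apart in
real assemblies).

Unclustered single-gene A-T-R NRPS-like loci are assembled and classified
but flagged `counted = FALSE` — whether they belong to secondary metabolism
is unresolved, so they are excluded from class counts and networks, as are
the primary-metabolism exclusions.

## The GCF distance

For two loci with domain inventories $A$ and $B$:

* **JI** — Jaccard of the domain *type* sets;
* **DSI** — copies of each shared type are paired greedily by descending
  pairwise local-alignment identity; each paired copy contributes its pair
  identity, unpaired copies contribute 0, and the DSI is the weighted mean
  over all copies in both loci, with anchor types (citrate synthase,
  terpene cyclase, UbiA-type prenyltransferase, tryptophan DMAT) weighted
  ×2;
* **AI** — Jaccard of the sets of adjacent ordered domain pairs along each
  locus's linear domain sequence (genes left to right, domains N→C,
  minus-strand genes reversed gene-wise).

$$d = 1 - (0.2\,\mathrm{JI} + 0.75\,\mathrm{DSI} + 0.05\,\mathrm{AI})$$

clamped to $[0,1]$; 0 is complete similarity. An edge is kept iff
$d < \text{cutoff}$ (strictly below), networks are built at cutoffs 0.3,
0.4, 0.5 and 0.6, all classes mixed in one network, and the connected
subnetworks *are* the GCFs — no secondary clustering step, because fungal
BGC networks are sparse enough that subnetworks correspond to pathway
families. Singletons are kept; subnetworks consisting only of characterised
reference BGCs are pruned.

Numerical conventions, chosen where the indices are degenerate:

* empty-vs-empty inventories give JI = DSI = AI = 0, hence $d = 1$ —
  domainless loci (RiPP precursors, type III PKS) never glue families
  together;
* when *both* loci have fewer than two domains there are no adjacencies,
  and AI degrades to the Jaccard of the type sets; this keeps the axiom
  $d(X, X) = 0$ for every locus with at least one domain, which the
  weighted formula would otherwise violate by exactly the AI weight. A
  single-domain locus against a multi-domain locus still has AI 0.
* greedy (not optimal-assignment) copy pairing in the DSI: deterministic,
  fast, and inventories are small; the alternative normalisation per type
  rather than over all copies jointly was considered and rejected because
  copy-number differences should dilute similarity.

Raising the cutoff can only merge components, never split them, so GCF
partitions are nested across the cutoff grid — asserted as a property test.

## Synteny links and co-localised search

`compare_bgcs()` reports, for each gene of one locus, the single best link
into the other, ranked by similarity percentage (positives) — ties broken
by raw score then gene order — with two floors: 30 % identity and 50 %
coverage of the better-covered protein. The coverage floor exists because
optimal local alignments of *any* two proteins contain short high-identity
islands; a link is only meaningful when it relates genes more or less end
to end. `homology_groups()` single-links these links across many loci.
`find_colocalized()` scans genomes for windows where at least
`min_queries` distinct query proteins have homologs with at most
`max_gap_genes` intervening non-hit genes, reporting maximal windows only.

## What the synthetic cohorts emulate

`make_cohort()` builds multi-species cohorts top-down from the bundled
references, so recovery is a genuine end-to-end exercise of the alignment
stack, not a bookkeeping identity:

* **core genes** are concatenations of per-domain segments, each derived
  from the reference panel through a family *archetype* at 55 % identity
  (50 % for the two diterpene singletons, whose domain-type sets coincide
  and whose distinctness therefore rests on sequence divergence and
  opposite gene order);
* **members** of a family are mutated independently from the archetype at
  $\sqrt{t}$ so that the *pairwise* member identity matches the family's
  stated target $t$ — mutating at $t$ directly would give pairwise
  identity $\approx t^2$ and families at the low end of the 0.70–0.90
  design range would not stay connected;
* **mutations** are BLOSUM-biased point substitutions with an exact
  conserved-position count and no indels, so identity targets are exact
  and DSI expectations analytic;
* **accessory genes** (tailoring, regulatory, transport) derive from
  labelled function-database entries, so the border caller recovers the
  planted roles; standalone core-adjacent enzymes (prenyltransferase,
  GGPPS, FAS subunits) share sequences with the domain panel and carry the
  `core` label in the function database;
* **filler** is housekeeping-derived and rejection-sampled against the
  template library under a deliberately small database length (1 kaa), so
  a chance core hit in filler is impossible by construction rather than
  merely improbable — at $E \le 10^{-1}$, unfiltered random proteins
  *would* produce the expected ~0.1 chance hits per search;
* planted loci are separated and flanked by at least four filler genes —
  one more than the three-gene border run — so planted borders are the
  only borders the rule can find.

The default design is the package's study condition: eight species, six
multi-species families (hrPKS, nrPKS, NRPS, meroterpenoid, collaborative
PKS, A-T-TE NRPS-like; identities 0.70–0.90; one member rearranged, one
truncated — ACP dropped, one disintegrated — split after the ER domain),
ten species-private singletons covering the remaining classes, and
primary-metabolism decoys (an A-T-R-R gene and one unclustered lanosterol
synthase per genome) that the classifier must refuse to count. Two families
span all eight species, fixing the designed conserved-GCF count at 2. Genes
are back-translated with a fixed codon per amino acid and written as both
GenBank and GFF3+FASTA, exercising both readers. Everything is derived from
a single seed; identical seeds give byte-identical cohorts and pipeline
outputs.

What the cohorts do **not** emulate: realistic intergenic sequence,
introns, genome-scale gene counts (tens of genes per species suffice),
composition bias, low-complexity regions, indel divergence (optional in
the mutator but off by default), and distally located tailoring genes.
Passing the planted-recovery tests therefore demonstrates the correctness
of the algorithms under their stated assumptions, not detection
performance on real assemblies — where gene prediction errors and the
absence of SEG-style masking in the alignment stage are the dominant
unknowns.

## Problem sizes and costs

The test suite and the acceptance script run the default cohort (eight
species, ~460 genes, 58 planted loci) end to end; a full run is a few
minutes on one CPU, dominated by the all-vs-all domain-copy alignments of
the DSI. The alignment oracle check uses 200 random peptide pairs of
length ≤ 30; network property checks use up to 50-node random graphs, where
brute-force transitive closure is still exact and fast.

## Known limitations

* The domain matcher is similarity-based, not profile-based; on real
  proteins a profile-HMM annotator should be supplied via the domain
  annotation table.
* Heuristic seeding is absent by design (all-vs-all dynamic programming is
  adequate at package scale); do not point the pipeline at hundreds of
  full genomes.
* Distally located tailoring genes are out of scope — the border rule
  cannot see them, a limitation shared with the manual protocol the rule
  formalises.
* The original manual protocol's alignment stage may have applied
  low-complexity masking; this package deliberately does not, which can
  change neighbour calls on real data.
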