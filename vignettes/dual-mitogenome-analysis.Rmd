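---
title: "Detecting and characterizing two co-existing divergent mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing two co-existing divergent mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Most animals carry a single mitochondrial genome sequence, with
polymorphism limited to low-level heteroplasmy. The Tuatara
(*Sphenodon punctatus*) is the one known vertebrate exception: a single
individual carries two complete mitochondrial molecules, M1 and M2,
about 10% divergent at the nucleotide level, with the minor molecule at
roughly one seventh the concentration of the major one. Detecting such a
second molecule from whole-genome sequencing data, convincing yourself
it is genuinely mitochondrial (and not a nuclear insertion or a
contaminant), dating the split, and characterizing its unusual genomic
organization together form a reusable analysis, and that analysis is
what `mitotwin` implements.

The pipeline has five stages, each usable on its own:

1. **Read/contig partitioning** (`assign_reads()`, `screen_contigs()`):
   every read is aligned to both candidate references and assigned by a
   divergence cutoff.
2. **Mitochondrial validation** (`genome_qc()`): strand composition,
   translation under the vertebrate mitochondrial code, tRNA cloverleaf
   folding, replication-origin stem-loops.
3. **Divergence and dating** (`pairwise_p_distance()`, `clock_date()`).
4. **Parsimony hypothesis testing** (`branch_and_bound_search()`,
   `bootstrap_support()`, `decay_index()`, `templeton_test()`,
   `test_monophyly()`).
5. **Gene-order comparison** (`extract_order()`, `compare_orders()`).

Because the real data are a 9.5 Gb sequencing archive, the package ships
a synthetic-data generator (`sim_config()`, `simulate_truth_set()`)
whose defaults reproduce the study conditions at desk scale, with known
truth labels for every read and every substitution.

# The synthetic study conditions

`sim_config()` defaults are the conditions reported for the real data:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 18,078 bp | size of the M1 assembly |
| `target_divergence` | 0.104 | M1-M2 nucleotide divergence |
| `minor_fraction` | 0.145 | minor-molecule share of assignable reads |
| `nc_block_count`, `nc_within_identity` | 3, 0.99 | triplicated Control-Region-like blocks, nearly identical within a genome |
| `short_read_length`, `insert_mean` | 100 bp, 180 bp | the paired-end library geometry |
| `long_length_mean/sd/min/max` | 2504.5 / 2409.2 / 514 / 16,978 bp | the observed long-read length summary |
| `depth_major` | 17 | long-read coverage of the major molecule |

The ancestor carries all 37 genes of the standard vertebrate
mitochondrial order. CDS are valid open reading frames under NCBI
translation table 2 (ATG start, terminal stop, no internal stops
counting AGA/AGG as termination and TGA as tryptophan); tRNAs are
instantiated from a 71-nt cloverleaf template with perfect Watson-Crick
stems and the standard anticodons; an O_L-like hairpin with the `GGC`
elongation motif sits between tRNA-Asn and tRNA-Cys; and the non-coding
blocks are exact copies of one master in the ancestor. Base composition
is drawn with the mitochondrial anti-guanine bias (G at 14% on the heavy
strand), so the composition test has something to detect.

**Divergence process.** Each lineage receives half the target divergence
under a Kimura two-parameter substitution scheme (transition/transversion
ratio `kappa = 4`, configurable; mitochondrial sequence is
transition-rich and no substitution model is prescribed by the source
analysis, which works with uncorrected distances throughout).
Substitution counts are fixed, with disjoint site sets per lineage, so
the realized pairwise divergence lands within ±0.005 of target by
construction rather than by luck. CDS substitutions are rejection-sampled
so no internal stop codon ever arises; tRNA stems, anticodons, start/stop
codons and the O_L spacer are excluded from the mutable site pool so that
*every* simulated genome passes the full QC battery — a closure property
the tests rely on. The cost of that choice is that simulated tRNA loops
carry slightly more than their share of divergence; nothing downstream
measures per-gene rates, so this is harmless at desk scale.

**Concerted evolution.** Within each genome one NC master evolves like
ordinary sequence, is copied to all blocks, and each copy then receives
a fixed number of private substitutions, `floor((1 -
nc_within_identity)/2 * B)` for a block of length `B`. Two copies then
differ at no more than `(1 - nc_within_identity) * B` sites, so the
within-genome identity floor (99% by default) holds deterministically,
while orthologous blocks between genomes differ at the full molecule
divergence. This is exactly the signature concerted evolution leaves and
the one the parsimony stage must recover: blocks cluster by genome, not
by block class. (The generator takes the per-copy noise rate as *half*
of `1 - nc_within_identity` because two independently noised copies
differ at about twice the per-copy rate.)

**Reads.** Short paired-end fragments are placed uniformly on the
circle (insert ~ Normal(180, 18)), both 100-bp ends reported with
substitution errors at 0.1%. Long-read lengths follow a lognormal
moment-matched to the observed mean/sd and clipped to the observed
min/max; errors are indel-rich (3% substitution, 2.5% insertion, 2.5%
deletion — conventional single-molecule error rates, since none are
reported for the original chemistry; all configurable). With probability
0.01 a long read is a *full-molecule two-strand read*: the rotated
genome concatenated with its own reverse complement, emulating the
end-connected native strands of a nicked circular molecule read in one
pass. `mix_reads()` draws a mixture whose per-read origin is Bernoulli
with the minor fraction, so realized minor counts are binomial — as they
would be in a sequencer.

What the generator does *not* emulate: base-quality profiles, chimeric
reads, nuclear mitochondrial insertions (NUMTs), library and GC biases,
and length differences between the molecules (both simulated genomes are
18,078 bp; the real M2 is 237 bp longer). Passing tests therefore show
the analysis machinery is correct under clean two-molecule mixtures, not
that it is robust to every artifact of real libraries.

# Read partitioning: operationalizing the 5% cutoff

The source analysis assigned long reads by separate searches against
both molecule references with "a cut-off of 5% difference", without
stating the comparison arithmetic. `assign_reads()` makes the rule
explicit: each read (either orientation, against the doubled reference
so origin-spanning reads align contiguously) receives a gap-compressed
identity to each reference — matches / (matches + mismatches +
gap-openings), a run of gaps counting once, which keeps the long
unread stretches of single-molecule reads from dominating the score. A
read is called for the higher-identity molecule when the identity
difference reaches `delta_rel`, which defaults to *half* the cutoff
(2.5 points at the 5% setting): a read truly from one molecule is
expected to lose the full inter-molecule divergence against the wrong
reference while noise is symmetric, so half the cutoff separates the two
populations with maximal margin. Exact ties are always `unassigned`,
never broken arbitrarily; reads under 500 bp are set aside as
`too_short` (the study's length filter); and the raw identities are
always emitted so any alternative rule can be applied after the fact.
Reads matching only one molecule (e.g. in the non-homologous tail of the
third non-coding block) are called from the single finite identity.

Batch alignment is delegated to `minimap2` (the standard mapper for
long-read data; presets `map-ont` / `sr` by platform), with
`Biostrings::pairwiseAlignment()` as the exact affine-gap engine for
single reads — the two agree to within 2 identity points on simulated
reads, and the tests cross-check them. Coverage is computed from the
assigned spans via `IRanges`, folding the doubled-reference coordinates
back onto the circle; consensus building maps the assigned reads back
with `minimap2 -a` and takes a per-position majority vote from the
`Rsamtools` pileup (ties resolve to the reference base when it is among
the tied bases, else alphabetically — deterministic either way).

At the default study conditions the whole battery behaves like the real
one: the major molecule sits at ~17x with 100% breadth, the minor at
~3.7x with breadth in the 90s, assignment accuracy among called reads is
at or near 100%, and the estimated minor fraction's 95% Wilson interval
covers the true 14.5% at the nominal rate. The mixture-recovery
validation draws 100 seeded mixtures of 250 reads each; 250 was chosen
by computing the exact Wilson coverage at p = 0.145 over candidate sizes
*before* running the pipeline (coverage of a discrete interval
oscillates with n; 250 sits at ≈95.2%), and because per-read alignment
is deterministic the pooled reads are aligned once and each seeded
mixture is tallied from the stored calls — numerically identical to
re-aligning every mixture.

# QC: what counts as "looks mitochondrial"

Four lines of evidence, mirroring the validation applied to the real
molecules:

- **Composition** (`base_composition()`): exact counts; the heavy strand
  is *defined* as the strand given in the FASTA (bias statistics flip
  with strand, so this convention is documented rather than guessed);
  `N` is excluded from denominators.
- **Translation** (`translate_cds()`): vertebrate mitochondrial code,
  hard-coded as NCBI table 2. Incomplete terminal stops (`T`/`TA` at the
  gene end, completed by polyadenylation in vivo) pass with a flag —
  failing them would reject essentially every real vertebrate
  mitogenome. Internal stops anywhere fail the genome.
- **tRNA folding** (`fold_trna()`): a constrained combinatorial search
  over cloverleaf architectures (acceptor 6-8 bp anchored at the ends, D
  stem 3-4 bp *or* a D-arm replacement loop, anticodon stem 5 bp with a
  7-nt loop, T stem 4-5 bp, variable arm 3-9 nt), each stem tolerating
  one G-U wobble or mismatch. This is constraint satisfaction, not
  free-energy minimization: the claim being tested is structural
  plausibility with a recognizable anticodon, which a deterministic
  search answers directly, with no energy parameters to tune. Random
  70-mers fold in well under 5% of cases, so a successful fold is
  informative. The D-arm replacement loop matters because the real
  tRNA-Cys lacks a D stem — a fold search without that allowance would
  wrongly fail a genuine gene.
- **Stem-loops** (`scan_ol_stemloop()`): every hairpin (stem ≥ 5, loop
  3-20, G-U allowed) in the tRNA-Asn..tRNA-Cys window, reported with its
  overlap into the flanking tRNAs and the presence of the `GGC`
  heavy-strand elongation motif. The scan reports candidates rather than
  adjudicating them: the real molecule's O_L-like structure is unusual
  (14-base overlap into tRNA-Asn), so a filter tight enough to reject
  noise would reject the finding itself.

`site_class_fraction()` summarizes an *externally supplied* table of
protein sites classified as transmembrane/loop/other with a flag column;
the selection analyses that produce such tables (codon-model and
fixed-effects site tests, structure prediction) are deliberately outside
this package's scope.

# Divergence and the clock

`pairwise_p_distance()` is the uncorrected proportion of differing
sites, pairwise-deleting gaps, `N`, and any masked interval (the real
analysis excluded the unalignable tail of the third non-coding block;
`exclusion_mask()` expresses exactly such rules). No multiple-hit
correction is applied anywhere — deliberately: the 1.3%-per-million-year
rate used for dating is an *empirical pairwise* rate for the well-dated
ND1-COI section in amphibians and reptiles, calibrated on raw percent
divergence, so correcting distances would double-count multiple hits.
`clock_date()` is then `time = 100 d / rate`, reported at one decimal as
such estimates conventionally are. At 1.3%/MY, 10.1% divergence gives
7.8 MY and 1.6% gives 1.2 MY; the published abstract-level figure of
10.4% corresponds to 8.0 MY — the 10.1% vs 10.4% difference between the
source's sections presumably reflects different alignment masks and is
reported as-is, not resolved.

`align_small_set()` exists for the small alignment jobs in this
pipeline (non-coding blocks, per-gene sets): progressive profile-profile
Needleman-Wunsch with affine gaps (match 1, mismatch −1, open −4,
extend −1; a gap of length k costs open + k·extend) on a UPGMA guide
tree from k-mer distances, deterministic, with optional anchor intervals
held gapless as a stand-in for structure-guided manual adjustment of
tRNA alignments. It makes no attempt to reproduce a production
multiple-aligner; externally produced alignments load via
`read_alignment()`.

# Parsimony machinery

The phylogenetic questions in this analysis are parsimony questions
(the original work used exact branch-and-bound searches), so the package
implements that machinery exactly rather than heuristically:

- `fitch_length()`: unordered unit-cost Fitch optimization, gaps and
  ambiguity as missing data (they never contribute steps) — the default
  treatment in the standard software. Verified against unit-cost Sankoff
  from an independent implementation in the tests.
- `branch_and_bound_search()`: exact enumeration with pruning, addition
  order by decreasing distance to the first taxon, initial bound from a
  greedy stepwise-addition tree. All minimum-length trees are returned.
  Guarded at 16 taxa — beyond that an exact search is the wrong tool and
  the error says so. Verified against exhaustive enumeration on hundreds
  of random alignments.
- **Constraints**: the same search can require or forbid the monophyly
  of a group. Decay (Bremer) indices are computed by the
  reverse-constraint route — shortest tree *lacking* the clade minus
  global shortest — which is the same quantity the
  retain-suboptimal-trees sweep produces, by a cleaner exact algorithm;
  in pathological tie cases the two procedures could in principle differ,
  which is noted rather than hidden.
- `bootstrap_support()`: site resampling; each replicate is summarized
  by the strict consensus of its shortest trees before voting, so
  equal-length ties collapse instead of voting for an arbitrary
  first-found topology. Deterministic given the seed.
- `templeton_test()`: the paired-sites Wilcoxon signed-ranks comparison
  of per-site step counts between two trees, with midranks and the
  tie-corrected normal variance. With ≤ 20 differing sites the two-tailed
  p comes from the exact sign-assignment distribution (computed by
  dynamic programming; identical to brute-force enumeration, which the
  tests check at n ≤ 12); beyond that the normal approximation is used.
  `p = P(|T⁺ − μ| ≥ |observed − μ|)` under uniform random signs — the
  symmetric two-tailed convention that a sign permutation reproduces
  naturally.
- `build_concatenation()` applies the fixed editing rules used when
  concatenating protein-coding genes across genomes: terminal overlaps
  of the bicistronic pairs excluded (last 96 nt of ATP8, last 7 nt of
  ND4L), length-difference gaps inserted into designated rows at stated
  offsets (the Cytb allele 7 codons longer than the rest), optional gene
  exclusions, with a per-column gene provenance map retained.

On synthetic concerted-evolution data the expected result reproduces
robustly: every shortest tree clusters NC blocks by genome, and
constraining any block class (all NC1, all NC2, all NC3) to be
monophyletic costs on the order of 90 extra steps with vanishing
Templeton p — the qualitative "monophyly rejected" result, at effect
sizes like the published ones (107 steps over 737 sites with 80
informative there; ~114 steps over ~860 sites with ~90 informative
here, by construction of the block lengths).

# Gene orders as signed circular permutations

`gene_order` objects are canonicalized by rotation (anchor tRNA-Phe,
configurable — both published maps begin near it) and reflection
(anchor on the heavy strand), so all reports are rotation- and
reflection-invariant. `compare_orders()` reports four things: signed
breakpoints on the shared single-copy gene set (duplicates and NC blocks
removed first — the standard convention for breakpoint distance, since
the distance is defined on signed permutations); moved genes, defined as
any gene whose signed (predecessor, successor) neighborhood changed —
note this deliberately includes genes *flanking* a rearranged segment
(e.g. ND4 and tRNA-Phe, which kept their positions while their
neighbors left), because adjacency disruption is what breakpoint
analysis measures; duplicated elements present in only one order, with
the pseudogenized duplicate tRNA-Lys flagged `pseudo` and excluded from
breakpoint computation (treating a pseudogene as a gene would
manufacture adjacencies no functional map contains); and the difference
in non-coding block counts. The two reference orders — standard
vertebrate and the rearranged Tuatara arrangement — ship as plain-text
tables in `inst/extdata/`.

# Numerical and degenerate-input conventions

- Internal coordinates are 0-based half-open everywhere; external text
  formats are 1-based inclusive (the GFF convention). Circular features
  are stored unwrapped (`end` may exceed the genome length) and
  round-trip through the annotation format by re-wrapping. Positions
  quoted by the source in prose are assumed 1-based inclusive (the
  GenBank convention), which is flagged here rather than silently
  assumed.
- `N` is a mismatch for identity purposes and excluded from composition
  denominators and p-distance comparisons.
- Wilson 95% intervals for mixture fractions (never the Wald interval,
  which misbehaves at small minor counts).
- All ties anywhere (read assignment, consensus bases, fold
  architectures, alignment traceback) resolve by a stated deterministic
  rule, never by RNG.
- Every stochastic operation takes its stream from the configured seed
  plus a fixed per-operation offset, so stages are reproducible
  independently of call order, and reruns are bit-identical.
- Degenerate inputs error early with the reason: empty read sets produce
  empty tables, zero assignable reads refuse a mixture estimate,
  coverage with no assigned reads reports breadth 0 with `NULL` depth
  statistics (not fabricated zeros), and a consensus without the
  required breadth refuses to vote.

# Problem sizes

The shipped analysis and test suite run at desk scale by design: 18 kb
genomes, read sets of a few hundred long reads (tens of thousands of
short reads where depth matters, e.g. k-mer repeat detection, which
needs k-mer coverage of a few dozen before a 1.6x threshold separates
repeats from Poisson noise), six-to-eight-taxon exact parsimony with
hundreds of oracle comparisons, 100-1000 bootstrap replicates, and 100
seeded mixture draws for the interval-coverage study. These sizes were
chosen so each validation exercises the same code paths as a full-scale
run while completing in seconds to a couple of minutes.

# Known limitations

- The exact parsimony search is for small taxon sets only; there is no
  heuristic mode.
- The progressive aligner is for small sequence sets; genome-scale
  alignments should come from a dedicated aligner and be loaded.
- The accession-dependent results (the published tree lengths,
  informative-site counts, decay totals and guanine percentages of the
  deposited sequences) require the deposited data; this package
  reproduces the machinery and validates it on synthetic truth, plus
  every analytic quantity recomputable from printed inputs.
- `batch` alignment requires `minimap2` on the PATH; without it, the
  exact pairwise engine still serves single-read and small-set uses.
- The simulator's fidelity limits are listed above; in particular no
  NUMT decoys are simulated, so the pipeline's behavior in the presence
  of nuclear copies is untested here.
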