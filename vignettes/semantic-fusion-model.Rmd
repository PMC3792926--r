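---
title: "The DNA semantic-fusion model: encoding, simulation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DNA semantic-fusion model: encoding, simulation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnafuse)
library(dplyr)
```

## The problem and the model

When several owners of the same data object — the motivating case is a
remote sensing image held in replica databases — annotate it with different
subsets of a shared property list, each record is incomplete: properties an
owner did not annotate carry the value *null*. Semantic fusion merges these
partial records into complete, null-free ones. dnafuse implements an
in-silico model of doing this with DNA chemistry instead of ontology
reasoning: annotations become oligonucleotides, a ligation reaction
assembles candidate merged records as DNA strands in parallel, and a short
sequence of physical screening steps discards everything but the complete
records.

The model has three parts.

**Degenerate bit encoding.** Text is converted to bits via 8-bit ASCII
(MSB first) and each bit becomes one base: 0 is a purine (`a` or `g`), 1 a
pyrimidine (`T` or `C`), the choice within the pair uniform random. Any
sequence therefore decodes unambiguously (purine = 0, pyrimidine = 1) while
the encoder retains freedom that real synthesis would use for GC balance.
Because many sequences encode the same bits, payload equality is defined at
the bit level (`degenerate_equal()`). Case is purely presentational —
purines lowercase, pyrimidines uppercase, verbatim code regions uppercase —
and every comparison in the package is case-insensitive.

**Vertex and edge oligos.** One annotated property is the vertex
`(name, value, type, unit)`, realised as `V = N·T·U·A`: the bit-encoded
name (8 nt per character), a verbatim 4-nt data-type code, a verbatim 4-nt
unit code, and the bit-encoded value. At the default field widths (3-char
names, 2-char values) a vertex is 48 nt. Names are left-padded with spaces;
integer values are left-padded with zeros and all other values with spaces —
the padding rule is per data type and configurable. An unannotated property
encodes pad characters under `undefined` type and unit, so its centre is the
8-mer `TGCATGCA`, the null marker. `Start`/`End` terminals are the padded
labels bit-encoded across the whole oligo, with no code segments. An edge
from vertex *i* to vertex *j* is the *position-wise* Watson–Crick complement
of the second half of `V_i` followed by the first half of `V_j`: during
ligation it hybridises across the junction and splints the two vertex oligos
together. The position-wise (non-reversed) definition is a deliberate
modelling choice: it makes the complement an involution that aligns base *k*
of the edge with base *k* of the junction, which is what the screening
simulation needs; the chemically conventional antiparallel 5'→3' read would
additionally reverse the string, and `reverse_complement()` is provided for
that reading but unused by the pipeline.

**The property network.** All sources' chains are merged into a layered DAG
— one layer per property, vertices unique by `(property, value, type,
unit)`, `Start` and `End` terminals — and, crucially, the edge set is
*recombined*: every vertex in layer *k* connects to every vertex in layer
*k+1*. Recombination is what allows a fused record to combine values
contributed by different sources; in the two-source worked example the
surviving path uses an edge present in neither source chain, so chain edges
alone cannot produce it (`recombination = FALSE` exists for exactly that
demonstration). Start→End paths then enumerate every candidate value
assignment, one vertex per layer.

## The simulated protocol

`ligate()` mixes the vertex and edge oligos and produces a multiset *tube*
of strands, each the concatenation of the vertex oligos along a walk in the
network. The screening pipeline is then applied in the order of the
abstract tube model:

1. `pre_separate` on the Start oligo — drop strands not beginning at Start;
2. `post_separate` on the End oligo — drop strands not ending at End;
3. `length_separate` at `8·(name_width + value_width + 1)·(K+2)` nt — for
   K properties at default widths this is `48·(K+2)`, i.e. 240 nt for K = 3,
   enforcing exactly K+2 vertex segments;
4. `sub_separate` on the null marker, keeping the *not-containing* fraction;
5. `detect` and read out the survivors.

The abstract model's sub-separate *selects* strands containing a probe,
while the screening algorithm must *reject* strands containing the null
marker; the two presentations are internally inconsistent if read literally.
`sub_separate()` therefore returns both fractions (`containing` /
`not_containing`) and the pipeline takes the latter, which preserves both
readings rather than guessing one away.

Separation matches literal sequence content (case-insensitively), not
degenerate bit equivalence: a probe hybridises to one specific sequence.
This is also why each vertex's oligo is generated once per run and reused
everywhere — one synthesised species per vertex — otherwise the Start probe
would miss strands built from a different random realisation of the same
bits.

Survivors decode into `FusedRecord`s: per-layer `(property, value, type,
unit)` entries plus the fixed-width flat property string (for the worked
example, `" startctyGZ qa E cc00   end"`, 27 characters).

## Ligation modes and the oracle

A wet ligation only says that large quantities of oligos are mixed; the
sampling policy that stands in for it is this package's construct and is
documented here. In **sampled** mode each of `n_molecules` products starts at a
uniformly chosen vertex and extends independently in both directions, each
step continuing with probability `p_extend = 0.75` along a uniformly chosen
incident edge. This produces the realistic soup of partial products the
screening steps exist to remove; from a middle vertex of a 3-layer network
a full Start→End product occurs with probability about `0.75^4 ≈ 0.32`, so
10,000 molecules leave thousands of full-length candidates. In
**exhaustive** mode every directed walk appears exactly once — a
deterministic tube on which the screening pipeline must agree *exactly*
with `fuse_oracle()`, the independent graph-search implementation
(enumerate Start→End paths, drop paths through null vertices, decode). The
test suite asserts that equality on 100 random fixtures and asserts
sampled-mode equality at 10,000 molecules on smaller ones.

```{r fusion}
fus <- semantic_fuse(example_annotations(), n_molecules = 10000,
                     seed = 1, mode = "sampled")
tidy(fus)[, c("flat_text", "n_vertices", "length_nt", "count")]
glance(fus)
```

One caveat the simulation shares with the chemistry: the null marker is
screened as a *sequence*, and a bit-bearing region could in principle
realise `TGCATGCA` by chance (probability `2^-16` per 8-mer window: the
window must carry the right bits *and* the right random base choices),
falsely rejecting a good strand. At the problem sizes simulated here this
has no practical effect, but it is a property of the encoding, not of the
implementation.

## The synthetic fixture generator

`generate_fixture()` emulates the study's setting: `n_sources` owners
annotate one object over `k_layers` shared properties; values are drawn
from per-layer alphabets and each entry is independently null with
probability `null_rate` (default 0.3, roughly the sparsity of the worked
example, where a third of entries are null); `guarantee_complete = TRUE`
forces at least one non-null value per layer so a complete record exists.
It does *not* emulate: disagreeing property orders between sources,
typing conflicts for the same value, synthesis or separation errors, or
strand breakage — so green tests say the model and its screening logic are
correct, not that the wet protocol would be robust. Error chemistry is
explicitly out of scope.

## The archival codec

Independently of fusion, arbitrary byte streams can be stored as an
address-tagged oligo pool: bits are split into 128-bit blocks (the last
zero-padded; no length header is stored, so decoding returns padded bytes
and the CLI records the true length in a sidecar manifest), each block gets
a 32-bit big-endian address counting from 0, and the 160 bits are
degenerately encoded and framed by two fixed 20-nt handles into a 200-nt
oligo. The 40 handle nucleotides are the package's own allocation of the
200-nt layout — amplification/sequencing primers in the style of bulk DNA
storage — chosen so that the published per-oligo accounting (128 data bits
per 200-nt oligo) holds exactly. Decoding is order-free: handles are
verified and stripped, blocks sorted by address, gaps and inconsistent
duplicates are errors. Each block's random choices derive from
`(master seed, address)`, so any chunked partition of the conversion emits
the identical pool — the contract that makes the conversion embarrassingly
parallel.

```{r archive}
pool <- encode_stream(charToRaw(" startctyGZ qa E cc00   end"), seed = 1)
pool
rawToChar(decode_pool(pool)[1:27])
```

## Storage density

With 128 payload bits per 200-bp duplex (400 nucleotides counting both
strands), a mean nucleotide weight of 330 g/mol and DNA's density
approximated by water's:

```{r density}
signif(bits_per_gram(), 3)    # bits per gram of duplex DNA
signif(storage_volume(petabytes_to_bits(3)), 3)  # mm^3 for 3 PiB
```

The petabyte here is binary (2^50 bytes); that convention is the one under
which the two figures above are mutually consistent, and it is exposed as
the `binary` argument of `petabytes_to_bits()`. Single-stranded accounting
(`nt_per_duplex = 200`) doubles the density and is available as an option.

## Numerical and design choices

* **Field widths** default to (3, 2) characters, forced by the 24/16-nt
  segments of the 48-nt vertex; both widths are arguments everywhere and
  scale segments by 8 nt per character, since realistic values (`"1.85"`)
  exceed two characters.
* **Padding** for value fields of types other than integer defaults to
  spaces; only the integer rule (zeros) is fixed by the worked example.
* **Vertex identity** includes type and unit: if two sources type the same
  `(property, value)` differently, both vertices are kept and surface as
  distinct records rather than being silently collapsed.
* **Seeds**: every randomised function takes a `seed` argument and uses a
  local RNG, leaving the session RNG untouched; derived seeds (library vs
  ligation, per-block archival seeds) are mixed with fixed linear maps kept
  below 2^31.
* **Problem sizes**: the shipped tests run the worked example at 10,000
  sampled molecules, oracle-equality sweeps over 100 random fixtures of up
  to 4 layers × 4 sources, and a 1 MiB (65,536-oligo) shuffled archival
  round trip — sizes at which the whole suite completes in under a minute
  on one core while exercising every contract.

## Known limitations

* No thermodynamics: hybridisation is exact string matching; mispairing,
  GC content, melting temperature and strand breakage are not modelled.
* Only layered, single-value-per-property records are fused; general RDF
  graph fusion and ontology (RDFS/OWL) reasoning are out of scope — the
  model's point is fusion *without* the ontology in the loop.
* The RDF/XML reader is a minimal striped-syntax extractor for annotation
  instances and node/edge counting, not a conforming RDF parser; its
  counting convention (nodes = distinct subjects and objects, edges =
  triples, literals included by default) is configurable because published
  graph-drawing counts rarely state theirs.
* Unit codes beyond `%` and `undefined` are not predefined; the registry is
  extensible at run time (`register_code()`).
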