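---
title: "Threading with a partial-decoy pair potential: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threading with a partial-decoy pair potential: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `pdthread`, the meaning and
default values of its parameters, what the synthetic data generators do and
do not emulate, and the numerical choices that shape the implementation. It
is a source document; the code chunks are illustrative and not evaluated.

## 1. The model

A threading instance is a template structure with `m` residues and a query
sequence with `n` residues. An alignment is a non-decreasing mapping

\[
A : \{1, \dots, m\} \to \{0, \dots, n\}, \qquad A(s) \ge A(s-1),
\]

where `A(s) = 0` means "template position `s` precedes all aligned query
positions" and a repeated value means the position is deleted against the
query. The *match states* of `A` are the pairs `(s, A(s))` where `A(s) > 0`
appears for the first time; their number is the match size `k(A)`. This
mapping family is exactly the set of global alignments: there are
`choose(m + n, m)` of them, a fact the test suite uses to enumerate small
instances exhaustively.

The alignment score being minimized is

\[
\mathrm{score}(A) = \omega_L \, L(A) + G(A).
\]

### The local item L

`L(A)` is the sum over match states of four per-position terms, plus affine
gap penalties, normalized by `k(A)`:

* **mutation** — minus the query profile log-odds of the template residue at
  the matched query position (a PSSM when available, a BLOSUM62 column
  fallback otherwise);
* **ss** — disagreement between the template's DSSP-style 3-state secondary
  structure and the query's predicted string;
* **sa** — disagreement between a burial 2-state string derived from contact
  counts and the query's predicted burial;
* **cle** — a conformation-letter term over a coarse structural alphabet
  derived from backbone dihedral bins, scored with an identity substitution
  fallback.

Gaps enter as `w_go * GO + w_ge * GE`, where `GO` counts maximal gap runs
over both rows of the gapped form and `GE` counts gapped columns. Query
insertions at the two ends are free by default (`free_query_ends = TRUE`):
threading aligns a full template against a possibly longer query, and
penalizing the overhang would bias toward spurious terminal matches.

The empty alignment (no match states) has normalized score `+Inf` — a
deliberate sentinel: normalization by `k(A) = 0` is undefined and an empty
threading is never an acceptable answer.

### The global item G

`G(A)` is a distance-dependent pairwise statistical potential evaluated on
the **partial decoy** of `A`: the matched residues only, with coordinates
copied verbatim from the template and residue types taken from the query.
This is the structural hypothesis the alignment asserts — "the query's
residues sit where the template's matched residues sit" — so scoring it with
a potential trained on real structures asks whether that hypothesis makes
physical sense.

The potential is DFIRE-style. For type pair `(a, b)` and distance bin `k`,

\[
E(a,b,k) = -\eta \,\ln \frac{N(a,b,k) + pc}{f_k \,\big(N(a,b,K) + pc\big)},
\qquad f_k = (r_k / r_K)^{\alpha},
\]

with `N` the symmetrized observed pair counts, `K` the outermost bin (the
reference state), `pc = 0.5` a pseudocount, and `f_k` the finite-ideal-gas
volume correction with exponent `alpha = 1.61`. Pairs closer than
`min_separation = 2` in sequence are excluded (bonded neighbors carry no
non-local signal). Two type schemes are supported: `"res_atom"` (20 residues
x 5 backbone atoms = 100 types) and `"cb"` (20 residue types on C-beta
positions, C-alpha for glycine). `G(A)` is the decoy's summed energy
normalized by `k(A)`, with the same `+Inf` sentinel at `k(A) = 0`.

## 2. Optimization

`L` alone decomposes per column, so a three-state (match / delete / insert)
affine-gap dynamic program finds its exact minimizer; the test suite checks
this against exhaustive enumeration on hundreds of random instances. `G`
couples arbitrarily distant columns, which is what makes the combined
problem hard; the package follows the intended two-stage strategy in
`thread()`:

1. **Gate.** If the DP optimum's normalized local score is below `theta`,
   the pair is declared easy and the DP alignment is returned unchanged
   (provenance `"easy"`). The default `theta = -87` is meaningful only at
   its calibrated score scale — see section 4.
2. **Search.** Otherwise, candidate alignments are sampled by a stochastic
   traceback of a Boltzmann-weighted version of the same DP (log-sum-exp
   partition recursion; the deterministic optimum is always candidate one;
   duplicates are removed). Each candidate seeds a local search over the
   **k-neighborhood**: `B` is a neighbor of `A` when the positions where
   they differ take at most `k` distinct new values in `B`. The
   neighborhoods nest in `k`, reach the full alignment space at
   `k = n + 1`, and for `k = 1` have size bounded by a polynomial
   `(n+1) m (m+1)/2 + 1`, enumerated directly by intervals rather than by
   filtering.

The search accepts the best neighbor only when

\[
(1 + \alpha)\,\widetilde{\mathrm{score}}(B) < \widetilde{\mathrm{score}}(A),
\]

where the tilde denotes the **positivity shift**: scores are translated by
`-(shift) + 1` with `shift` a lower bound on the attainable score, so that
all compared values are positive and the multiplicative criterion is
well-defined regardless of sign. This is the one place the implementation
adds machinery the model statement leaves implicit: a multiplicative
acceptance test on possibly negative scores is meaningless, and the shift
makes the logarithmic termination bound
`iterations <= log(shift_0 / shift_final) / log(1 + alpha)` valid verbatim.
`thread()` computes a per-instance lower bound from the minimum entries of
the score matrix and the potential table; the bound only needs to be a
lower bound, not tight. Note that `alpha` and `k` never change *which*
neighbor is chosen — only whether the move is accepted — so a stricter
`alpha` walks a prefix of the looser trajectory.

Ties everywhere (DP traceback states, equal-scoring search results) are
broken deterministically: match over delete over insert in the DP, and
lexicographically smallest mapping in the search, so every seeded run is
bit-reproducible.

## 3. Parameters and defaults

| parameter | default | role |
|---|---|---|
| `w_m, w_ss, w_cle, w_sa` | 1, 0.5, 0.5, 0.2 | weights of the four local terms |
| `w_go, w_ge` | 3, 0.5 | affine gap open / extend |
| `free_query_ends` | `TRUE` | terminal query insertions cost nothing |
| `omega_L` | 0.0047 | weight of `L` against `G` |
| `theta` | -87 | easiness gate on the normalized DP optimum |
| `alpha` | 0.01 | multiplicative acceptance margin |
| `k` | 1 | neighborhood order |
| `candidates` | 100 | DP candidates seeding the search |
| `r_cut`, bins | 15 A, 30 x 0.5 A | potential range and resolution |
| `alpha` (exponent) | 1.61 | reference-state volume exponent |
| `eta` | 0.01 | energy scale of the potential |
| `pc` | 0.5 | estimation pseudocount |
| `min_separation` | 2 | sequence-separation cutoff for pairs |

`omega_L` is trained by slope maximization: each (positive, negative)
alignment pair contributes an inequality `omega * (L_n - L_p) > G_p - G_n`,
i.e. a half-plane in `(x, y) = (L_p - L_n, G_n - G_p)` coordinates, and
`train_omega()` picks the slope through the origin satisfying the most
inequalities (`H`), scanning the finitely many candidate slopes defined by
the points — which a dense-grid brute force confirms exactly in the tests.
`theta` is selected by `select_theta()`: order threading records by their
normalized local score, accumulate the mean quality gap between the best
achievable and the DP alignment, and return the largest score whose running
mean gap stays below `gap_limit`.

## 4. Score scales, and what the defaults mean

The printed defaults `theta = -87` and `omega_L = 0.0047` come from a
scoring calibration (profile magnitudes, term weights) that this package
does not reproduce: with the default weights and BLOSUM62-scale profiles,
normalized local scores land around -3 to -7, never near -87, so the
default gate classifies essentially every instance as hard and routes it
through the search — a conservative behavior. The defaults are kept because
they are the model's published operating point, but they are only
meaningful relative to a weight scale; this is why the command-line
interface refuses a custom `--weights` file unless `--theta` and
`--omega-l` are re-specified explicitly, and why `select_theta()` /
`train_omega()` exist: recalibrate both whenever the local scale changes.

## 5. Synthetic data: what it is and is not

All fixtures are generated in code (`make_ideal_structure`,
`make_threading_pair`, `make_decoy_set`, `make_rescue_pair`):

* Backbones are built by natural-extension (NeRF) placement with ideal bond
  lengths/angles and canonical helix (-57, -47) and strand (-120, +120)
  dihedrals; C-beta is the standard virtual construction with L-amino-acid
  chirality. Geometry is exact by construction, which is what makes the
  feature-derivation tests (dihedrals against `bio3d::torsion.pdb`,
  secondary-structure strings, CA-CA spacing) sharp.
* Threading pairs delete a contiguous template block, perturb the remaining
  coordinates with Gaussian noise, and mutate a fraction of residues, so the
  reference alignment is known exactly. Profiles are point masses on the
  query residue — an idealization of a sharp PSSM.
* The rescue fixture plants exactly one long-range residue contact that
  only the reference alignment realizes, with a potential rewarding it, so
  "the global item rescues a locally wrong alignment" is a constructed
  certainty rather than a statistical tendency.

None of this emulates real structural statistics: no side chains, no
packing, no realistic decoy ensembles (fragment-assembly or otherwise), no
database-scale pair-count distributions, no real PSSM noise. Consequently
the package demonstrates the *mechanics* of the method — exact DP,
neighborhood search with its guarantees, estimator consistency on data
simulated from a planted table, discrimination on separable toy ensembles —
not its published benchmark accuracy, which requires external structure
sets and sequence profiles.

## 6. Numerical choices

* **Minimization convention.** All scores are costs; published
  similarity-style quantities enter negated (e.g. the mutation term is minus
  the profile log-odds).
* **Gap counting.** `GO`/`GE` are counted on the two-row gapped form, with
  template-deletion columns emitted before query-insertion columns between
  consecutive match states; terminal query insertions are exempt under
  `free_query_ends`.
* **"Best 100 alignments".** Exact suboptimal enumeration (k-best
  traceback) is replaced by seeded stochastic traceback from the Boltzmann
  partition DP with de-duplication and oversampling; the exact optimum is
  always included, so the candidate set is a superset of what the gate
  needs and a reasonable spread for seeding the search.
* **Log-sum-exp.** The partition DP works in log space with the usual
  max-factoring to avoid overflow.
* **Positivity shift.** See section 2; the shift is the implementation's
  explicit answer to the sign-ambiguity of a multiplicative acceptance rule.
* **Conformation letters.** A coarse dihedral-bin alphabet with identity
  substitution stands in for a trained structural-alphabet substitution
  matrix.
* **Problem sizes.** Exhaustive oracles are run at `m, n <= 6`
  (`choose(12, 6) = 924` alignments); the search is practical to a few
  hundred residues since a `k = 1` sweep costs about `(n+1) m^2 / 2`
  memoized score evaluations.

## 7. Limitations

* The potential ships empty (all-zero energies) and must be estimated from
  structures; estimates from the toy generators are illustrative, not
  transferable.
* Default `theta`/`omega_L` are at a foreign score scale (section 4); they
  must be retrained for any serious use.
* The candidate sampler is stochastic, not an exact k-best enumeration; with
  few candidates on adversarial instances the search can miss basins that a
  true k-best list would seed.
* Quality assessment (`tm_quality`) uses an iterative-superposition
  TM-score-style kernel, adequate for comparing alignments of the same pair
  but not a replacement for a full structural aligner.
* Runtime grows quickly with the neighborhood order `k`; `k = 1` is the
  practical setting, with larger `k` available mainly to certify global
  optimality on tiny instances.
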