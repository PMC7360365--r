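---
title: "Modeling controlled glycan synthesis across Golgi compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling controlled glycan synthesis across Golgi compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycompart)
```

## The model

Glycans are branched sugar oligomers assembled on proteins and lipids by
glycosyltransferase (GTase) enzymes distributed across the ordered
compartments of the Golgi apparatus. `glycompart` implements an abstract,
combinatorial model of this assembly line:

* **Oligomers** are rooted trees of typed monomers. Each bond occupies one
  numbered acceptor carbon on the parent and one donor carbon on the child;
  a carbon, once linked, is occupied. Growth is by single-monomer additions
  and is irreversible — O-glycan-style chemistry with no pruning. The
  protein or lipid anchor is not modeled; it adds nothing to the
  combinatorics.
* **Enzymes** (`enzyme_rule()`) catalyze one specific linkage — a donor
  monomer type attached through a fixed carbon pair to an acceptor monomer
  type — and differ in how much *context* they read around the acceptor.
  Three idealized promiscuity classes are modeled: context-free (no
  context; maximally promiscuous), ideal branch-sensitive (required and/or
  forbidden branch subtrees on the acceptor, read to arbitrary depth), and
  ideal root-sensitive (a fully specified chain from the acceptor down to
  the root, which pins the acceptor to a unique position in the tree).
  Enzymes reading roots or branches to partial depth are real but outside
  the scope of the class-level results, and are not modeled.
* **Compartments** (`compartment()`) hold an enzyme set and an average
  residence time `T`. Residence is exponentially distributed under the
  `transport` picture of Golgi traffic and sharply peaked (modeled as
  fixed) under `maturation`; all qualitative results depend only on whether
  `T` is small or large relative to the monomer-addition time scale.

While an oligomer is inside a compartment, the order in which it meets
enzymes is random: assembly is a continuous-time Markov chain in which
every matching (enzyme, site) pair fires independently at a propensity
equal to the enzyme's concentration (donor sugars are assumed unlimited).
The *reaction network* (`build_reaction_network()`) enumerates every
reachable oligomer state; the exit distribution over states is computed
exactly (`exact_output_distribution()`) from the generator matrix `Q`:
the resolvent `r p0ᵀ (rI − Q)⁻¹` with `r = 1/T` for transport exit, the
matrix exponential `p0ᵀ exp(QT)` for maturation, and absorption
probabilities for `T = ∞`. A Gillespie simulator
(`simulate_compartment()`) provides the stochastic counterpart and is used
automatically where the state space is unbounded. Variability of the
output profile is quantified as the Shannon entropy of the exit
distribution in bits (`shannon_entropy()`): roughly the log2 of the number
of distinct high-abundance products.

## The three causes of variability

For any assembly line built from irreversible single-monomer additions,
output variability can arise in exactly three ways, and
`classify_variability()` diagnoses all three:

1. **Truncated reactions** — the residence time is comparable to the
   monomer-addition time, so intermediate oligomers exit alongside
   terminal ones. Diagnosed dynamically: a finite-`T` stage whose exit
   distribution places mass on extendable states.
2. **Runaway reactions** — some growth step can iterate forever, producing
   tandem repeats. Diagnosed structurally on the *linkage network*
   (`build_linkage_network()`): the directed multigraph over monomer types
   with one edge per enzyme from acceptor type to donor type. A
   compartment supports runaway growth iff this graph, restricted to
   active edges of non-root-sensitive enzymes, has a directed loop
   (`detect_runaway()`). Root-sensitive enzymes cannot loop — their
   acceptor sits at a fixed depth. Branch-sensitive enzymes can break
   loops through *triggers*: if an enzyme's required-branch motif cannot
   be synthesized inside the compartment from a single monomer
   (`is_trigger_disabled()`), its edge is inactive.
3. **Divergent reactions** — a fork in the reaction network that never
   reconverges (`detect_divergence()`), so identical inputs reach mutually
   exclusive fates. Forks onto different carbons reconverge; forks that do
   not imply an *acceptor block* (`detect_acceptor_blocks()`): either two
   enzymes compete for the same acceptor carbon (bidirectional, any
   class), or one enzyme's action destroys another's branch motif
   (unidirectional, branch-sensitive only). Blocks are necessary but not
   sufficient for divergence, and the test suite checks exactly that
   asymmetry on randomized compartments.

Removing an enzyme from every loop and all but one enzyme from every block
yields an *algorithmic compartment* (`make_algorithmic()`,
`is_algorithmic_compartment()`): at long residence time it maps each input
to a unique output.

## Planning multi-compartment synthesis

`min_compartments()` answers the central design question: can a target
oligomer be synthesized from an input with no byproducts, and with how few
compartments? Two structural facts organize the search. First, specific
synthesis is possible at all iff it is possible through a chain of
single-enzyme compartments (`single_enzyme_step()`), which makes
feasibility cheap to decide. Second, the minimum number of compartments
equals the minimum number of *algorithmic growth stretches*
(`is_algorithmic_stretch()`) into which some growth order can be
decomposed; the planner computes it as a shortest path on the sub-oligomer
lattice (`enumerate_sub_oligomers()`), with one edge wherever some enzyme
set maps the lower oligomer to the higher one as a unique terminal.

We operationalize "algorithmic stretch" dynamically — a stretch is
algorithmic iff a witness enzyme set, run to completion from the stretch
start, has the stretch end as its unique terminal, verified by expanding
the reaction network — rather than through static per-class growth-order
characterizations. The dynamic definition is precisely the property the
compartment-count argument uses, and it is checked against an exhaustive
ordered-sequence search (`brute_force_min_compartments()`) on every
instance small enough to brute-force.

Class-based planning constructs candidate enzymes with
`make_ideal_enzyme()`. For the root-sensitive class one compartment always
suffices (every addition is pinned to its unique position); the planner
still verifies the single-compartment witness by expansion rather than
asserting it. For the context-free class the candidate per addition is
unique. For the branch-sensitive class the candidate space is finite but
genuinely combinatorial: in an algorithmic compartment every intermediate
is a sub-oligomer of the target, so any useful required pattern is a
root-subtree of a final branch and any useful forbidden constraint is a
wildcard or such a subtree; `bs_candidate_enzymes()` (internal) enumerates
exactly this space. Witness sets are searched exhaustively over subsets up
to a size limit (12 by default), with a greedy specific-first fallback
beyond it; the fallback can in principle overestimate N for the
branch-sensitive class, never for context-free or root-sensitive, and
bare branch-sensitive candidates subsume the context-free solutions so
the promiscuity ordering N(rs) ≤ N(bs) ≤ N(cf) is preserved. Ties among
equal-length plans are broken deterministically by the breadth-first
processing order of canonical strings.

The package ships a constructed branch-sensitive target —
`[C(2-1)][B(3-1)]B(3-1)A` over a three-letter alphabet — for which no
single branch-sensitive compartment is algorithmic but two compartments
suffice; the claim is verified in the tests by the exhaustive oracle over
the complete candidate space described above.

## Worked example: the blood-group B antigen

```{r b-antigen}
fx <- builtin_fixtures("b_antigen")
fx$input
fx$target

# one shared compartment: the fucosyltransferase synthesizes GTB's trigger,
# reactivating a Gal->Gal linkage loop
joint <- compartment(fx$library, residence_time = Inf)
length(detect_runaway(joint, fx$input))

# two compartments restore specific synthesis
pl <- min_compartments(fx$input, fx$target, fx$library)
pl
d <- run_series(plan_to_series(pl), fx$input)
tidy(d)
shannon_entropy(d)
```

## What the synthetic scenarios emulate

`builtin_fixtures()` ships four named scenarios. All enzyme sets are
synthetic reconstructions chosen to exhibit a qualitative behavior —
they are not fitted to glycomics measurements, and nothing in the
package's tests should be read as validation against real profiles:

* `b_antigen` — the two-enzyme specific-synthesis story above.
* `mucin_like` — a two-stage divergent upstream producing three inputs in
  a 1:1:2 ratio (entropy 1.5 bits) feeding a convergent chain-extension
  compartment probed at short residence time: intermediates exit, the
  truncated pattern.
* `human_cg_like` — the same upstream with the final stage run long: the
  intermediates converge onto few terminals, entropy falls from its peak.
* `horse_cg_like` — a unique input entering a compartment whose two
  enzymes form a GlcNAc–Gal linkage loop: poly-LacNAc-style tandem
  repeats; entropy keeps rising with residence time.

```{r entropy-curve, fig.width = 5.5, fig.height = 3.5}
mucin <- builtin_fixtures("mucin_like")
Tg <- exp(seq(log(0.05), log(50), length.out = 9))
ec <- entropy_curve(mucin$series, mucin$input, Tg)
autoplot(ec)
```

The curve starts at the 1.5-bit input entropy, rises as intermediates exit
at short `T`, and falls back toward the terminal-set entropy at long `T`.
For the runaway scenario the curve keeps climbing instead (computed by
Monte Carlo, since the state space is unbounded).

The generator of random fixtures (`generate_random_oligomer()`,
`generate_random_enzyme_library()`) emulates only the combinatorial
skeleton of glycogenesis: uniform random tree growth under carbon
constraints and uniformly drawn enzyme rules with small branch motifs. It
does not emulate real monosaccharide chemistry (anomericity, sugar-specific
carbon availability), enzyme kinetics beyond a single propensity,
donor-nucleotide limitation, or partial-depth recognition — so passing
tests demonstrate the internal consistency of the combinatorial theory,
not agreement with measured glycan profiles.

## Numerical and algorithmic choices

* **Carbon model.** The default alphabet gives every type acceptor carbons
  {2, 3, 4, 6} and donor carbon 1 — a generic hexose-like choice; carbon
  sets are fully user-configurable and nothing downstream depends on the
  specific labels. The bacterial-style small alphabets used in randomized
  tests use two carbons {2, 3} to keep exhaustive oracles cheap.
* **Canonical form.** Children are serialized in ascending acceptor-carbon
  order, branches bracketed, the root's lowest-carbon child written
  unbracketed (chain style). The parser additionally accepts unbracketed
  chain segments anywhere; the emitted form is unique per tree, so string
  equality is structural equality.
* **Exact vs Monte Carlo.** The exact method enumerates at most 500 states
  by default and errors beyond; `run_series(method = "auto")` falls back
  to Gillespie sampling whenever the exact result would be capped
  (runaway) or too large. Exact transport exit solves one dense linear
  system; maturation uses `Matrix::expm`. Probabilities below 1e-15 are
  dropped and the distribution renormalized.
* **Trigger search bound.** Whether a branch-sensitive motif is
  synthesizable from a single monomer is decided by breadth-first growth
  capped at the motif's size — sufficient because growth can stop at any
  point, so any reachable motif is reachable without overshoot. Contexts
  assembled only deep inside a larger tree by root-sensitive helpers are
  beyond this bound; with the ideal classes used here that situation does
  not arise in the shipped batteries.
* **Input-aware loop reachability.** A linkage loop is reported for an
  input only if every loop edge can sustain itself on freshly added
  monomers and at least one loop enzyme can actually fire, where
  fireability is computed by a bounded reaction probe (input size + 8,
  at most 3000 states) plus fresh-monomer propagation. Pure type-level
  reachability is too coarse — an input whose only eligible carbon is
  already occupied must not count as loop-reachable.
* **Divergence on truncated networks** is reported on the clipped graph
  and flagged approximate; with unbounded growth "never reconverges" is
  undecidable by enumeration.
* **Degenerate inputs.** Enzyme-free compartments are allowed and act as
  the identity; zero-concentration enzymes are present but inert
  everywhere (networks, loops, simulation); `make_algorithmic()` may
  empty a compartment whose last enzyme self-loops.
* **Problem sizes.** The randomized batteries use alphabets of 3 types ×
  2 carbons, compartments of 2–4 context-free/branch-sensitive enzymes,
  inputs of at most 3 monomers and targets of at most 8 (6 where an
  exhaustive oracle runs); these sizes make every brute-force oracle
  exact while exercising all code paths.

## Known limitations

* Ideal classes only: no partial-depth root or branch reading, no
  glycosidases, no kinetic regulation of specificity (concentration
  tuning as a control mechanism is deliberately out of scope).
* The branch-sensitive planner's completeness rests on the
  sub-oligomer-pattern argument above; for witness sets larger than the
  exhaustive-search limit the greedy fallback may (rarely) miss a witness
  and overestimate N for that class.
* Exact distributions on runaway compartments at finite T are computed on
  a capped state space only when explicitly requested; the automatic path
  switches to simulation instead.
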