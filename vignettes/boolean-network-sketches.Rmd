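---
title: "Inferring Boolean networks from sketches: models, properties and data"
author: "bnsketch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring Boolean networks from sketches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnsketch)
```

## The inference problem

A Boolean network (BN) over variables $v_1, \dots, v_n$ assigns each
variable an update function $F_i : \mathbb{B}^n \to \mathbb{B}$.  Under the
asynchronous update scheme a transition changes exactly one variable to its
update value, $(s, t) \in T \iff s \ne t \wedge \exists i.\; t = s[i \mapsto
F_i(s)]$, and a state carries a self-loop when no variable can change, which
makes the transition relation total.  The long-run behaviour is captured by
the attractors: the bottom (terminal) strongly connected components of this
state-transition graph, classified as fixed-point (singleton), cyclic
(a single cycle) or complex.

In practice the update functions are rarely known.  What a modeller has is
partial: a signed influence diagram from the literature, qualitative
knowledge such as "this regulator is inhibiting", expectations about the
attractor landscape, and binarized measurements.  A **sketch** packages all
of this as a four-tuple

$$\mathcal{S} = (I, \mathcal{E}, \Pi, \Omega)$$

* $I$ — an **influence graph**: the admissible regulator → target pairs.  A
  concrete network is consistent with $I$ when every *essential* input of
  every $F_i$ (every $v_j$ with $F_i(x[j \mapsto 0]) \ne F_i(x[j \mapsto 1])$
  for some $x$) is an admitted regulator.  Nothing forces an admitted
  regulator to be used.
* $\mathcal{E}$ — a **partially specified BN**: one update expression per
  variable over the grammar $0 \mid 1 \mid v \mid \neg E \mid E \wedge E
  \mid f^{(a)}(E, \dots, E)$, where $f^{(a)}$ is an *uninterpreted* function
  symbol of arity $a$ (fixed but unknown).  An interpretation $\iota$ assigns
  every symbol a concrete truth table; specializing $\mathcal{E}$ under
  $\iota$ yields an ordinary BN.
* $\Pi$ — **update-function properties**: first-order predicates over the
  function computed by an expression.  The atoms are essentiality,
  non-strict positive/negative monotonicity in a named network variable,
  canalization ($v = a$ forces output $b$) and veto (canalization to output
  0), closed under Boolean connectives.  $\Pi$ is interpreted as the
  *intersection* of the individual property evaluations.
* $\Omega$ — **dynamic properties**: closed formulae of hybrid CTL (HCTL),
  CTL extended with state variables, a binder $\downarrow x$ naming the
  current state, a jump $@x$ re-evaluating at a named state, and existential
  state quantification $\exists x$.  The key example is attractor
  membership, $\varphi_{\text{att}} = {\downarrow} x.\, \mathrm{AG}\,
  \mathrm{EF}\, x$: a state is in an attractor exactly when everything
  reachable from it can reach it back.

The inference problem: compute **all** BNs consistent with every component.

## The pipeline

`infer()` runs the following stages, rejecting with a classed error as soon
as a stage empties the candidate space:

1. **Syntactic influence check.**  Every variable occurring in an update
   expression (including inside symbol arguments) must be an admitted
   regulator.  This is deliberately syntactic — it can be done before any
   semantic work, and the generators only produce expressions over admitted
   regulators.
2. **Symbol elimination.**  Each application $f^{(a)}(e_1, \dots, e_a)$ with
   $a > 0$ is replaced by its row-selection expansion over $2^a$ fresh
   zero-arity constants that spell out $f$'s truth table: the disjunction
   over argument rows $b$ of $c_{f,b} \wedge \bigwedge_i (e_i
   \leftrightarrow b_i)$.  Zero-arity symbols already are constants and pass
   through.  A valuation of all constants — a **colour** — corresponds
   one-to-one to an interpretation, and `interpretation_from_constants()`
   inverts the encoding.
3. **Property evaluation.**  Each property is compiled against the
   eliminated expression of its target.  The state quantifiers inside the
   atoms ($\exists x$ for essentiality, $\forall x$ for monotonicity and
   canalization) are eliminated bit-parallel across all colours at once, and
   the per-item colour sets are intersected.
4. **Coloured transition graph.**  One truth matrix per variable (states ×
   surviving colours) defines, for every colour simultaneously, which
   variable may flip where.  The per-variable transition structure is kept
   separate — standard practice for asynchronous semantics — plus a
   self-loop predicate at states where nothing can flip.
5. **Coloured model checking.**  Each formula of $\Omega$ is checked
   bottom-up over (state, bound-state-variable, colour) sets: `EX` is the
   predecessor image, `E[p U q]` and `A[p U q]` are least fixpoints (the
   universal one via "all successors lie in the set", well-defined because
   the relation is total), the binder equates its variable with the current
   state and discharges it, the jump re-reads the result at the named state,
   and $\exists$ projects the variable away.  Colours whose graphs fail the
   formula are dropped; the surviving set is returned with full decoding
   tables.

The result supports exact counting (`count_interpretations()`,
`count_distinct_networks()`), deterministic enumeration in lexicographic
colour order, membership tests for concrete networks, and attractor
analysis of all candidates at once via $\varphi_{\text{att}}$.

### Why two counts

Two interpretations can specialize to the same network (e.g. `f | 1` is
constantly true whatever `f` is), so the package always reports both the
number of satisfying colour valuations and the number of semantically
distinct networks; the distinct-network count is the headline number.
Influence-graph-only counts are a closed form, $\prod_i 2^{2^{k_i}}$ with
$k_i$ the in-degree — always a power of two — and are produced at arbitrary
precision by repeated doubling of a decimal digit vector, so that even
counts far beyond double precision are exact.

## The symbolic representation

The candidate space is manipulated as *sets*, never candidate by candidate.
The package realizes these sets as dense bit-parallel logical arrays over
(state × one dimension per quantified HCTL state variable × colour), with
one fixed bit-order convention everywhere: tuples are read as unsigned
binary numbers with the *first* component most significant — truth-table
rows (argument 1 first), network states ($v_1$ first) and colours (first
constant first).  All engine operations (images, fixpoints, quantifier
elimination) are whole-array operations, so the cost per symbolic step is
independent of how many candidates the step touches.  A dense array is the
right trade-off at the scale this package targets — up to roughly a dozen
state variables plus 16 parameter constants on one core — and keeps the
engine free of external decision-diagram dependencies; it does not reach
the hundreds-of-variables regime that compressed decision-diagram
representations enable.

Two independent code paths guard correctness.  The `explicit_*`/`oracle_*`
functions enumerate states and interpretations one by one, use recursive
HCTL evaluation with explicit environments, and compute attractors through
igraph's strongly-connected-components machinery; they share no evaluation
code with the symbolic path and serve as the reference in the test suite.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `arity_cap` | `eliminate_symbols()`, `infer()` | 8 | refuse symbols above this arity; the expansion needs $2^a$ constants, and realistic regulatory in-degrees are small (2–3) |
| `max_colour_bits` | `infer()`, `oracle_infer()` | 16 | cap on total parameter constants (= $\log_2$ colours) |
| `mode` | `infer()`, `colours_satisfying()` | `all_states` | a colour satisfies a closed formula when it holds in **all** states; `some_state` requires one |
| `limit` | `enumerate_candidates()` | 10 | decoded candidates, lexicographic colour order |

The `all_states` default deserves a note: every formula the data encoders
produce is existentially anchored (`3{x}: @{x}: ...`), hence
state-independent, so the convention cannot change their meaning — but
universal requirements such as "no attractor beyond these phenotypes"
(`prohibit_other_attractors()`) only make sense universally.  Both modes are
exposed because a closed formula *can* still be state-dependent (e.g. plain
`EF v1`), and reasonable tools differ on the convention.

Veto is defined here as sign-parameterized forcing of the output to 0
($x_i = \text{sign} \Rightarrow f(x) = 0$), i.e. `prop_veto(v, s)` is
`prop_canalizing(v, s, 0)`; the atom is a thin wrapper so an alternative
convention is a one-line change.  Properties combine only by intersection —
arbitrary Boolean structure *within* one item is supported
(`prop_or`, `prop_imp`, ...), which covers conditional constraints without
complicating the sketch container.

## What the synthetic generator emulates

`random_sketch()` produces ground-truth bundles for validation: it samples
a network with in-degrees drawn from `1..max_in_degree` (default 2, the
typical regime for regulatory networks), hides a fraction of the update
functions (default 0.5) behind fresh symbols over their true regulators,
emits a monotonicity + essentiality property for each hidden input whose
true function is monotone and essential in it (emulating a signed,
observable edge in an influence diagram), and samples steady-state
observations (default 2) from the true attractor states, encoded as
attractor-membership formulae.  By construction the truth satisfies every
component, so `contains_network(infer(sketch), truth)` must always hold —
the package's end-to-end self-check.

What the generator does **not** emulate: measurement noise (observations
are exact attractor states, never corrupted), partial observability (all
variables are observed; the encoders support `NA` cells, the generator does
not produce them), dependencies between experiments, and the skewed
topology of real regulatory graphs (hubs, long tails).  Passing tests on
these bundles therefore demonstrate correctness of the machinery — that
every consistent network and no inconsistent one is returned — not
robustness of inference under real experimental error.

## Numerical and procedural choices

* **Determinism.**  There is no randomness anywhere in the inference path;
  enumeration order is lexicographic in the colour encoding.  The generator
  derives everything from its `seed` argument via an isolated RNG scope.
* **Fixpoints.**  `EU`/`AU` iterations are monotone non-decreasing and
  terminate after at most $2^n$ rounds per colour; `AU` is computed directly
  from its own fixpoint rather than by duality, avoiding edge cases of `EG`
  under a total relation.
* **Degenerate inputs.**  Empty property sets mean "no constraint" (the
  full colour space); an empty candidate set is a *result* for counting
  functions but a classed rejection inside `infer()`; fully unobserved
  observation rows are an error rather than a vacuous constraint.
* **Alpha-renaming.**  Binders are renamed apart at parse time, so the
  checker can allocate one array dimension per quantifier name without
  capture; printing restores the original spellings.
* **Problem sizes in the test-suite.**  Cross-validation against the
  explicit oracle runs on hundreds of networks with $n \le 4$ and colour
  spaces up to $2^8$; ground-truth recovery on 100+ bundles with
  $n \le 5$.  These sizes keep the whole suite around a minute while every
  comparison is exact (no tolerances anywhere — all quantities are integer
  counts or Boolean).

## The bundled example

The three-variable sketch returned by `running_example_sketch()` exercises
every component; each stage below is computed, not quoted:

```{r example}
cs <- infer(running_example_sketch())
stage_counts(cs)[c("ig", "ig_psbn", "ig_psbn_ufp", "ig_psbn_ufp_dp")]
enumerate_candidates(cs, 1)[[1]]$interpretation
```

1024 networks fit the influence graph, 256 the partial specification, 16
the update-function properties (the inhibition property pins `f` to
negation; essentiality of both inputs with one activation leaves four
options each for `g`'s essentiality-free slot and for `h`), 4 survive the
shared-basin requirement, and the two steady-state observations identify a
single network with `g = v1` and `h = v1 & !v2`.  Of the 16
property-consistent candidates, exactly 12 have a single attractor —
which is why the shared-basin property is so informative here.

## Known limitations

* Only asynchronous semantics; synchronous or most-permissive schemes would
  need a different transition builder (the rest of the pipeline is
  agnostic).
* The dense engine's memory grows as $2^{n + m}$ (states × colours) times
  one extra factor $2^n$ per simultaneously live quantifier; it is meant
  for desk-scale models, not genome-scale ones.
* No counterexample or witness *paths* are produced for failed dynamic
  properties, only the surviving colour sets.
* Observation binarization is out of scope: tables must already be 0/1/NA.
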