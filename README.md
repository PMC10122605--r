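# bnsketch

Exhaustive inference of asynchronous Boolean networks from partial
knowledge, for systems biologists who have an influence diagram, fragments
of update logic, qualitative expectations about the dynamics, and binarized
measurements — but not the network itself.

## The idea

A Boolean network over variables `v1..vn` assigns each variable an update
function `F_i : B^n -> B`; under asynchronous semantics one variable updates
per transition and the attractors (bottom strongly connected components of
the state-transition graph) model the phenotypes.  A **sketch** collects
everything known about an unknown network:

    S = (I, E, Π, Ω)

* `I` — influence graph: admissible regulator → target pairs; consistency
  means `dep(F_i) ⊆` admitted regulators (essential inputs only).
* `E` — partially specified network: update expressions over the grammar
  `0 | 1 | v | !E | E & E | f(E, ..., E)` where `f` is an *uninterpreted*
  function symbol; an interpretation assigns every symbol a truth table.
* `Π` — first-order update-function properties (essentiality, monotonicity,
  canalization, veto) applied to the expressions; `prop[E]` is the set of
  interpretations making the property true, and `Π` is their intersection.
* `Ω` — closed dynamic properties in hybrid CTL (HCTL): CTL plus state
  variables with binder (`!{x}:`), jump (`@{x}:`) and quantification
  (`3{x}:`, `V{x}:`).  Attractor membership is `!{x}: AG EF {x}`;
  steady-state and time-series data are encoded automatically as such
  formulae.

Inference computes **all** networks consistent with every component at
once: positive-arity symbols are eliminated into truth-table constants, a
valuation of the constants (a *colour*) is one candidate, and a
bit-parallel coloured model checker evaluates `Ω` over every colour's
state-transition graph simultaneously.  The result is a compact candidate
set supporting exact counting, enumeration, membership tests and
whole-ensemble attractor analysis, with an explicit-state brute-force
oracle as an independent cross-check.

## Worked example

The bundled three-variable sketch has influence graph
`v1 -> v1, v3 -> v1, v1 -> v2, v1 -> v3, v2 -> v3`, update expressions
`v1 <- v1 & f(v3)`, `v2 <- g(v1)`, `v3 <- h(v1, v2)` with unknown `f/1`,
`g/1`, `h/2`, properties making `v3` essential and inhibiting in `E1` and
both inputs of `h` essential with `v1` activating, a shared-basin dynamic
property (some state can reach two different attractors), and two
steady-state observations `(0,0,0)` and `(1,1,0)`.

```r
library(bnsketch)
cs <- infer(running_example_sketch())
cs
#> Candidate set: 1 interpretation(s), 1 distinct network(s)
#>   cascade: IG 1024 | +PSBN 256 | +UFP 16 | +DP 1
```

1024 networks are consistent with the influence graph alone, 256 with the
partial expressions, 16 with the update-function properties, 4 with the
shared-basin property, and exactly one with the data.  Decoding it:

```r
str(enumerate_candidates(cs, 1)[[1]]$interpretation)
#> List of 3
#>  $ f: logi [1:2] TRUE FALSE
#>  $ g: logi [1:2] FALSE TRUE
#>  $ h: logi [1:4] FALSE FALSE TRUE FALSE
```

Truth tables are read row-wise with argument 1 most significant: `f` is
negation, `g` the identity (`g = v1`) and `h = v1 & !v2` — the inferred
network is `v1 <- v1 & !v3`, `v2 <- v1`, `v3 <- v1 & !v2`.  Attractor
analysis of the whole 16-candidate ensemble in one call:

```r
count_attractors(infer(running_example_sketch(dynamics = character(0))))
#>  [1] 2 1 1 1 1 2 1 1 2 1 1 1 1 2 1 1
```

twelve candidates have a single attractor, four are bistable — which is
exactly why the shared-basin property cuts 16 down to 4.

Sketches are plain JSON (`read_sketch()`/`write_sketch()`; see
`inst/extdata/running_example.json`), networks interchange with the BoolNet
`targets, factors` format (`read_bnet()`/`write_bnet()`), observations are
CSV/TSV with 0/1/NA cells, and a minimal `.aeon`-style dialect is read.  A
command-line wrapper lives at `inst/cli/bnsketch.R`:

```sh
Rscript inst/cli/bnsketch.R infer inst/extdata/running_example.json
```

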