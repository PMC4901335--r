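---
title: "Simulating spiking neural P systems with self-organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating spiking neural P systems with self-organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpso)
```

## The model

A spiking neural P system (SN P system) is a directed graph of neurons that
exchange indistinguishable spikes under a global synchronous clock. Each
neuron holds a spike count and a list of rules guarded by regular
expressions over the one-letter alphabet `{a}`: a rule is applicable when
the neuron's current count, read as the unary word `a^k`, belongs to the
guard's language *and* covers the rule's consumption. The *self-organizing*
variant starts with **no synapses at all**: alongside the classical spiking
rule `E/a^c -> a^p; d` (consume `c`, emit `p` along all current outgoing
synapses after delay `d`; `p = 0` is forgetting) it has synapse *creation*
rules `E/a^c -> +(a^p, {targets})`, which wire the neuron to each target and
deliver `p` spikes to each, and synapse *deletion* rules
`E/a^c -> -(lambda, {targets})`. The topology is therefore part of the
computation's state, rebuilt and torn down on the fly.

Because unary regular languages are semilinear, every guard is stored as a
finite union of arithmetic progressions of counts; membership is O(1) for
the single-period guards the constructions use, with a small
coin-representation dynamic program as the general fallback. A neuron that
fires with delay `d >= 1` is *closed* for `d` steps: it applies no rule and
any spike sent to it is lost — the engine tallies such losses explicitly so
that spike accounting can be audited from traces.

### Timing model

The synchronous step is the one place where the model's prose narratives
leave genuine freedom, and the engine fixes it as follows:

* rule selection uses start-of-step counts; every open neuron with at least
  one enabled rule applies exactly one;
* spiking emissions travel along the synapses existing at the *start* of
  the step; creation rules deliver only to their own targets, within the
  step (usable from the next step); deletions take effect at end of step;
* a scheduled input spike is credited at end of step (a spike read at step
  `t` is usable at `t + 1`);
* creating an already-existing synapse is idempotent, but the emission
  still delivers; deleting an absent synapse is a no-op.

These choices reproduce every timed narrative of the register-machine
modules below (receipt at `t`, firing at `t + 1` throughout). Whether
spiking uses the pre- or post-creation synapse set when *another* neuron
creates an edge in the same step is not distinguished by any narrative; the
start-of-step set is used.

Nondeterminism (several enabled rules in one neuron) is resolved by a
pluggable policy: `"first"` (deterministic), `"random"` (seeded), a user
function, or exhaustively by `snp_explore()`, which branches over the
Cartesian product of all per-neuron choice sets and deduplicates
configurations on a full digest. In the compiled systems only one neuron —
the branching ADD auxiliary — ever has more than one enabled rule, which
`snp_explore()` reports via its branching statistic.

## Register machines as the yardstick

Computational power is measured against register machines: labelled
`ADD(r)`/`SUB(r)`/`HALT` programs over unbounded counters, which
characterize the Turing computable sets of naturals. The package contains a
direct interpreter (`rm_run()`, `rm_generate_set()`) that serves as the
*semantic oracle*: every compiled spiking system is tested for bounded
equivalence against it, rather than against hand-computed expectations.

The compilers realize the constructions under three conventions:

* register `r` holding `n` ⇔ `5n` spikes in neuron `r<r>`;
* an instruction-label neuron becomes active exactly when it holds 6
  spikes;
* after a module finishes, its own wiring is deleted again, so the synapse
  set over the module's neurons is empty between simulations.

An ADD module is a label neuron plus two auxiliaries: the label wires and
feeds 5 spikes to each auxiliary and to the register (one ADD = +5 spikes),
the first auxiliary feeds 3 spikes to both successor labels, and the second
nondeterministically picks one — so exactly one successor reaches 6. A SUB
module's register neuron distinguishes `5n + 4` (consume 8: decrement,
leaving `5(n-1) + 1`) from exactly `4` (zero test, leaving 1), then cleans
up via a deletion rule guarded by `a(a^5)^*`; merging the two cleanup cases
into that one guard keeps register neurons at three rules. When several SUB
instructions share a register, the register broadcasts to *all* their
auxiliaries; foreign auxiliaries absorb the 6- or 3-spike broadcast with
forgetting rules (`a^6 -> lambda`, `a^3 -> lambda`), and each module's own
off-branch auxiliary absorbs its 7- or 10-spike residue — those two
absorbers are needed even for a solitary SUB. The FIN module primes the
output register with 2 extra spikes; the register then creates a synapse to
the environment and emits one spike per encoded unit (`a(a^5)^+/a^5 -> a`)
until one spike remains and the final deletion rule severs the
environment edge.

In acceptor mode the machine must be deterministic, the halt-label neuron
is rule-less (acceptance = halting, rejection = divergence), and an INPUT
module of three neurons reads `n` as the spike train `1 0^(n-1) 1`: two
auxiliaries exchange five spikes per clock tick between the two input
spikes, metering `5n` spikes into register 1. Function mode reads
`1 0^(g-1) 1 0^(y-1) 1` through a five-neuron INPUT module loading
registers 1 and 2, and attaches FIN to the designated output register.

### Design notes on the INPUT modules

Two reconstruction decisions deserve a record. First, the acceptor
module's second auxiliary tops register 1 up with its final five spikes via
`a^7/a^5 -> +(a^5,{r1})` — consuming five, not seven: the two remaining
spikes drive the subsequent `a^2 -> -(lambda,{r1})` cleanup, and the
module's handoff postconditions (register 1 at `5n`, start label at 6) pin
this form down uniquely. Second, in the function-mode module the pair
loading register 2 starts one clock tick later, relative to its triggering
input spike, than the pair loading register 1; a lambda-emitting activation
would therefore deliver one five-spike instalment too few. Its exchange
instead runs on the idempotent creation rule `a^6/a^5 -> +(a^5, .)` — each
neuron cycles 6 → 1 → 6 — delivering five spikes already at activation,
which restores register 2 to exactly `5y` after the closing `+3`/`+2`
top-ups. The supported argument range is `g >= 1`, `y >= 2`: with `y = 1`
the third input spike arrives before the second loader starts, the input
neuron deadlocks on an unmatched 9-spike count, and the system halts
without simulating any instruction (the boundary is tested).

The loaders finish while the first instruction may already be running; all
intermediate register counts stay off the SUB guards (multiples of five, or
residues 2 and 3 mod 5), so no interference is possible — the test suite's
handoff audit checks exactly this.

## The universal system

The function-computing compiler applied to the classical 8-register,
23-instruction universal register machine — after the standard halt
replacement that drains result register 0 into a fresh, never-decremented
register 8 (`l_h: (SUB(0), l22, l_h')`, `l22: (ADD(8), l_h)`, `l_h':
HALT`) — yields a system of

```{r census}
cs <- compile_function(rm_modify_universal(rm_universal()), 8)
neuron_census(cs)
```

neurons: 9 register + 25 label + 20 ADD-auxiliary + 28 SUB-auxiliary + 5
INPUT neurons = 87, with at most five rules per neuron
(`system_stats(cs)`). The machine's instruction list is shipped as a
plain-text fixture (`inst/extdata/m_u.rm`) transcribed from the standard
published listing, with its census (8 registers, 23 instructions; after
modification 9 / 24 / 25) asserted in the tests as a transcription guard.

A caveat on end-to-end runs: the universal machine interprets register 1 as
the Gödel code of a function, and almost all small numbers are not codes of
defined functions — the machine (and hence the compiled system) genuinely
diverges on them. The equivalence tests therefore check value equality on
small halting codes (`g` in 1, 5, 7, whose runs still walk hundreds of
machine steps across the whole instruction set) and halting *parity* —
divergence matching divergence within the step bound — on a small grid of
non-halting preloads. The Gödel numbering itself is out of scope;
universality is exercised at the register level only.

## Numerical and scale choices

* `max_steps` defaults to 10 000 with an explicit non-halt verdict, since
  acceptor rejection is divergence; tests use bounds of a few hundred to a
  few thousand steps, sized to the machines at hand.
* Exploration deduplicates on the full configuration digest and prunes on
  step and per-neuron spike bounds, reporting pruning counts — never
  silently.
* Oracle-equivalence suites run generators to result sets within `[1, 8]`,
  acceptors for `n <= 8`, and function machines for arguments up to 5
  (`y >= 2`), with the universal system probed at preloads up to 7; these
  sizes exercise every module and branch while keeping the whole suite
  around half a minute.
* Determinism: identical seed and inputs give byte-identical traces; the
  seed is recorded in every trace header.

## What the fixtures do and do not show

The curated machines (`sample_machines()`) cover every instruction form,
both SUB branches, cross-module interference on a shared register, and
both nondeterministic and deterministic ADD. Bounded equivalence on them —
plus the universal system's census and behaviour — is strong evidence that
the compilation is faithful, but it is not a universality proof: the claim
that these constructions simulate *every* register machine is checked here
only on finite instances within finite step bounds. Spike trains are idealized (exact unary gaps, no jitter), and the
engine's delays/refractory machinery, while implemented per the
definition, is unused by the constructions, which operate entirely at
delay 0.
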