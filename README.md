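# snpso — spiking neural P systems with self-organization

Spiking neural P (SN P) systems are membrane-computing models: directed
graphs of neurons exchanging indistinguishable spikes under a global
synchronous clock, with rules guarded by regular expressions over the unary
alphabet `{a}`. The *self-organizing* variant starts with **no synapses**:
besides spiking rules `E/a^c -> a^p; d` it has synapse-creation rules
`E/a^c -> +(a^p, {targets})` and synapse-deletion rules
`E/a^c -> -(lambda, {targets})`, so the topology is rebuilt at run time as
part of the computation. This package is for researchers in natural
computing who want to *execute* and *verify* such systems rather than only
reason about them on paper.

It provides:

* an exact synchronous-step simulator (`snp_run`, `snp_step`) with unary
  regular-expression guards, delays/refractory periods, loss accounting and
  per-step traces;
* a register machine interpreter (`rm_run`, `rm_generate_set`) used as the
  semantic oracle, plus the classical 8-register universal machine
  (`rm_universal`) and its halt-replacement modification
  (`rm_modify_universal`);
* compilers from register machines to self-organizing SN P systems in three
  modes — number **generator** (result = total spikes emitted at halt),
  number **acceptor** (input spike train `1 0^(n-1) 1`, acceptance =
  halting) and **function** computing (arguments read from the train
  `1 0^(g-1) 1 0^(y-1) 1`), realizing the ADD / SUB / FIN / INPUT module
  constructions, including the 87-neuron universal system
  (`compile_generator`, `compile_acceptor`, `compile_function`);
* exhaustive exploration of nondeterministic computations (`snp_explore`),
  system/machine file formats, TSV traces, DOT topology export, and a
  command-line wrapper (`inst/cli/snpso.R`).

Registers encode `n` as `5n` spikes; an instruction-label neuron activates
at exactly 6 spikes; modules wire themselves with creation rules and tear
the wiring down before handing control over.

## Worked example

Compile a nondeterministic generator of even numbers and verify it against
the register-machine oracle:

```r
library(snpso)

m <- rm_machine(list(
  l0 = list(op = "ADD", reg = 1, next1 = "l1", next2 = "l1"),
  l1 = list(op = "ADD", reg = 1, next1 = "l0", next2 = "lh"),
  lh = list(op = "HALT")))

cs <- compile_generator(m)
cs
#> Compiled SN P system (generator mode): 8 neurons, max 3 synapses created / 3 deleted per rule, max 3 rules per neuron

snp_run(cs$system, policy = "random", seed = 11)
#> SN P run: halted after 9 steps; 2 spike(s) emitted

snp_explore(cs$system, max_steps = 60)$results
#> 2 4 6 8 10 ...            # every even number reachable within the bound
rm_generate_set(m, max_steps = 40, max_value = 8)
#> 2 4 6 8                   # the oracle agrees
```

The run emitted 2 spikes: the machine added twice to register 1 before the
nondeterministic branch chose the halt label, and the FIN module emitted
one spike per encoded unit. The compiled universal function-computing
system reproduces the published neuron budget exactly:

```r
cu <- compile_function(rm_modify_universal(rm_universal()), 8)
neuron_census(cu)
#> registers    labels   add_aux   sub_aux     input     total
#>         9        25        20        28         5        87
```

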