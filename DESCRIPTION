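Package: snpso
Title: Spiking Neural P Systems with Self-Organization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and verification toolkit for spiking neural P systems
    with self-organization: membrane-computing models that start with no
    synapses and rebuild their topology at run time through synapse creation
    and deletion rules. Provides exact synchronous-clock semantics with
    unary regular-expression rule guards, delays and refractory periods; a
    register machine interpreter used as a semantic oracle; compilers
    realizing the register-machine constructions in generator, acceptor and
    function-computing modes (including the 87-neuron universal system);
    exhaustive exploration of nondeterministic computations; and trace/DOT
    export of the evolving synapse graph.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
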