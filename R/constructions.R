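#' Compiling register machines into self-organizing spiking systems
#'
#' @description
#' The compilers translate a register machine into an SN P system with
#' self-organization under the standard encodings:
#' \itemize{
#'   \item register \code{r} holding \code{n} is represented by \code{5n}
#'     spikes in neuron \code{r<r>};
#'   \item an instruction-label neuron becomes active exactly when it holds 6
#'     spikes;
#'   \item the synapse set is empty at every instruction handoff — modules
#'     wire themselves up with creation rules and tear the wiring down with
#'     deletion rules before passing control.
#' }
#' \code{compile_generator} produces a number generator (result = total
#' spikes emitted at halt, via the FIN output module on register 1);
#' \code{compile_acceptor} compiles a deterministic machine plus an INPUT
#' module reading the spike train \code{1 0^(n-1) 1} (acceptance = halting;
#' the halt-label neuron is rule-less); \code{compile_function} compiles a
#' deterministic machine with arguments read from the train
#' \code{1 0^(g-1) 1 0^(y-1) 1} into registers 1 and 2 and the FIN module
#' attached to \code{out_register}.
#'
#' @param m a \code{\link{rm_machine}}.
#' @return a \code{compiled_snp}: list with \code{system}
#'   (\code{\link{snp_system}}), \code{register_map}, \code{label_map},
#'   \code{aux_map}, \code{input_neurons}, \code{mode} and \code{machine}.
#' @name compilers
NULL

reg_id <- function(r) paste0("r", r)
aux_id <- function(lab, k) paste0(lab, "#", k)

# --- module builders (rule lists) -----------------------------------------

# Nondeterministic ADD: label neuron wires {aux1, aux2, sigma_r}, feeds 5
# spikes to each; aux1 deterministically feeds both successor labels 3 spikes,
# aux2 nondeterministically picks one, so exactly one successor reaches 6.
build_add_module <- function(lab, ins) {
  a1 <- aux_id(lab, 1); a2 <- aux_id(lab, 2)
  r <- reg_id(ins$reg); lj <- ins$next1; lk <- ins$next2
  both <- paste0("{", paste(unique(c(lj, lk)), collapse = ","), "}")
  # with equal branch labels the two alternative creation rules coincide;
  # keep a single copy so the module is genuinely deterministic in that case
  alts <- unique(c(sprintf("a^5/a^4 -> +(a^3,{%s})", lj),
                   sprintf("a^5/a^4 -> +(a^3,{%s})", lk)))
  list(
    label = c(
      sprintf("a^6/a^5 -> +(a^5,{%s,%s,%s})", a1, a2, r),
      sprintf("a -> -(lambda,{%s,%s,%s})", a1, a2, r),
      "a^3 -> lambda"),
    aux = stats::setNames(list(
      c(sprintf("a^5/a^4 -> +(a^3,%s)", both),
        sprintf("a -> -(lambda,%s)", both)),
      c(alts, sprintf("a -> -(lambda,%s)", both))), c(a1, a2)))
}

# Deterministic ADD (acceptor / function modes): both auxiliaries feed the
# single successor 3 spikes each.
build_add_det_module <- function(lab, ins) {
  a1 <- aux_id(lab, 1); a2 <- aux_id(lab, 2)
  r <- reg_id(ins$reg); lj <- ins$next1
  aux_rules <- c(sprintf("a^5/a^4 -> +(a^3,{%s})", lj),
                 sprintf("a -> -(lambda,{%s})", lj))
  list(
    label = c(
      sprintf("a^6/a^5 -> +(a^5,{%s,%s,%s})", a1, a2, r),
      sprintf("a -> -(lambda,{%s,%s,%s})", a1, a2, r),
      "a^3 -> lambda"),
    aux = stats::setNames(list(aux_rules, aux_rules), c(a1, a2)))
}

# SUB: the label neuron feeds 4 spikes to its two auxiliaries and sigma_r;
# sigma_r distinguishes 5n+4 (n>0: consume 8, feed 6 to every SUB auxiliary
# on r) from exactly 4 (zero test: consume 3, feed 3), then cleans up at
# counts ~ 1 (mod 5). Auxiliaries of the active module turn 10 / 7 spikes
# into the successor activation; the other modules' auxiliaries absorb the
# broadcast (a^6 / a^3) and the off-branch residue (a^7 / a^10).
build_sub_module <- function(lab, ins) {
  aj <- aux_id(lab, 1); ak <- aux_id(lab, 2)
  r <- reg_id(ins$reg); lj <- ins$next1; lk <- ins$next2
  list(
    label = c(
      sprintf("a^6/a^5 -> +(a^4,{%s,%s,%s})", aj, ak, r),
      sprintf("a -> -(lambda,{%s,%s,%s})", aj, ak, r),
      "a^3 -> lambda"),
    aux = stats::setNames(list(
      c(sprintf("a^10/a^9 -> +(a^6,{%s})", lj),
        sprintf("a -> -(lambda,{%s})", lj),
        "a^7 -> lambda"),
      c(sprintf("a^7/a^6 -> +(a^6,{%s})", lk),
        sprintf("a -> -(lambda,{%s})", lk),
        "a^10 -> lambda")), c(aj, ak)))
}

# register-neuron rules for a register with >= 1 SUB instruction; aux_all is
# the set of ALL SUB auxiliaries on this register (2 per SUB instruction)
build_register_rules <- function(aux_all) {
  tset <- paste0("{", paste(aux_all, collapse = ","), "}")
  c(sprintf("a^4(a^5)^+/a^8 -> +(a^6,%s)", tset),
    sprintf("a^4/a^3 -> +(a^3,%s)", tset),
    sprintf("a(a^5)^*/a -> -(lambda,%s)", tset))
}

# interference absorbers, added to auxiliaries of register r when s_r > 1
interference_rules <- c("a^6 -> lambda", "a^3 -> lambda")

# FIN / OUTPUT: the halt label primes the output register with 2 spikes; the
# output register then emits one spike per encoded unit into the environment.
build_fin_module <- function(out_reg) {
  out <- reg_id(out_reg)
  list(
    halt = c(
      sprintf("a^6/a^5 -> +(a^2,{%s})", out),
      sprintf("a -> -(lambda,{%s})", out),
      "a^3 -> lambda"),
    output = c(
      "a^2(a^5)^+/a -> +(lambda,{0})",
      "a(a^5)^+/a^5 -> a",
      "a -> -(lambda,{0})"))
}

# Acceptor INPUT (3 neurons): sigma_in (8 initial spikes), I1, I2.  I2 holds
# the edge to register 1 and tops it up; I1 hands 6 spikes to l0.
build_input_acceptor <- function(l0) {
  list(
    "in" = list(spikes = 8L, rules = c(
      "a^9/a^6 -> +(a^6,{I1,I2})",
      "a^4/a^3 -> a^3")),
    I1 = list(spikes = 0L, rules = c(
      "a^6/a -> +(lambda,{I2})",
      "a^5 -> a^5",
      sprintf("a^8/a^6 -> +(a^6,{%s})", l0))),
    I2 = list(spikes = 0L, rules = c(
      "a^6/a -> +(lambda,{I1,r1})",
      "a^5 -> a^5",
      "a^8/a -> -(lambda,{I1})",
      "a^7/a^5 -> +(a^5,{r1})",
      "a^2 -> -(lambda,{r1})")))
}

# Function-mode INPUT (5 neurons): sigma_in (15 initial spikes), I1/I2 load
# register 1 with 5*g spikes, I3/I4 load register 2 with 5*y and hand off to
# l0.  The I3/I4 pair activates one step later relative to its triggering
# input spike than I1/I2 does, so it must already deliver 5 spikes at
# activation: its exchange runs on the self-sustaining idempotent creation
# rule a^6/a^5 -> +(a^5,.) (each neuron cycles 6 -> 1 -> 6), which gives
# register 2 the required y-1 five-spike instalments before the +3/+2
# top-up.  Supported argument range: g >= 1, y >= 2.
build_input_function <- function(l0) {
  list(
    "in" = list(spikes = 15L, rules = c(
      "a^16/a^6 -> +(a^6,{I1,I2})",
      "a^11/a^3 -> a^3",
      "a^8/a^6 -> +(a^6,{I3,I4})",
      "a^3/a^2 -> a^2")),
    I1 = list(spikes = 0L, rules = c(
      "a^6/a -> +(lambda,{I2,r1})",
      "a^5 -> a^5",
      "a^8/a -> -(lambda,{I2})",
      "a^7/a^5 -> a^5",
      "a^2 -> -(lambda,{r1})")),
    I2 = list(spikes = 0L, rules = c(
      "a^6/a -> +(lambda,{I1})",
      "a^5 -> a^5",
      "a^8/a -> -(lambda,{I1})",
      "a^7/a^5 -> a^5",
      "a^2 -> lambda")),
    I3 = list(spikes = 0L, rules = c(
      "a^6/a^5 -> +(a^5,{I4,r2})",
      "a^8/a^5 -> a^3",
      "a^3/a -> -(lambda,{I4})",
      "a^2 -> a^2")),
    I4 = list(spikes = 0L, rules = c(
      "a^6/a^5 -> +(a^5,{I3})",
      sprintf("a^8/a^6 -> +(a^6,{%s})", l0))))
}

# --- compilers -------------------------------------------------------------

compile_core <- function(m, deterministic_add, fin_register = NULL,
                         halt_rules = TRUE, extra_registers = integer(0)) {
  ops <- vapply(m$instructions, `[[`, character(1), "op")
  labs <- names(m$instructions)
  registers <- sort(unique(c(m$registers, extra_registers)))

  # SUB bookkeeping: all auxiliaries acting on each register
  sub_labs <- labs[ops == "SUB"]
  sub_regs <- vapply(m$instructions[sub_labs], `[[`, numeric(1), "reg")
  aux_on_reg <- lapply(stats::setNames(nm = registers), function(r) {
    on <- sub_labs[sub_regs == r]
    as.vector(rbind(vapply(on, aux_id, character(1), 1),
                    vapply(on, aux_id, character(1), 2)))
  })

  neurons <- list()
  aux_map <- list()
  push <- function(id, spikes, rules)
    neurons[[length(neurons) + 1L]] <<- snp_neuron(id, spikes, rules)

  for (r in registers) {
    rules <- character(0)
    if (length(aux_on_reg[[as.character(r)]]))
      rules <- build_register_rules(aux_on_reg[[as.character(r)]])
    if (!is.null(fin_register) && r == fin_register) {
      if (length(rules))
        stop("output register ", r, " must never be a SUB target")
      rules <- build_fin_module(fin_register)$output
    }
    push(reg_id(r), 0L, rules)
  }

  for (lab in labs) {
    ins <- m$instructions[[lab]]
    if (ins$op == "HALT") {
      rules <- if (halt_rules) build_fin_module(fin_register)$halt else character(0)
      push(lab, 0L, rules)
      next
    }
    mod <- if (ins$op == "ADD") {
      if (deterministic_add) {
        if (!identical(ins$next1, ins$next2))
          stop("nondeterministic ADD at ", lab, " not allowed in this mode")
        build_add_det_module(lab, ins)
      } else build_add_module(lab, ins)
    } else build_sub_module(lab, ins)
    push(lab, 0L, mod$label)
    extra <- if (ins$op == "SUB" && sum(sub_regs == ins$reg) > 1L)
      interference_rules else character(0)
    for (aid in names(mod$aux)) push(aid, 0L, c(mod$aux[[aid]], extra))
    aux_map[[lab]] <- names(mod$aux)
  }
  list(neurons = neurons, aux_map = aux_map, registers = registers)
}

finish_compiled <- function(core, m, mode, input = NULL, output = NULL,
                            input_neurons = character(0), start_spikes = NULL) {
  neurons <- core$neurons
  ids <- vapply(neurons, `[[`, character(1), "id")
  if (!is.null(start_spikes))
    neurons[[which(ids == start_spikes)]]$spikes <- 6L
  system <- snp_system(neurons, input = input, output = output)
  out <- list(system = system,
              register_map = stats::setNames(vapply(core$registers, reg_id,
                                                    character(1)),
                                             as.character(core$registers)),
              label_map = stats::setNames(nm = names(m$instructions)),
              aux_map = core$aux_map,
              input_neurons = input_neurons,
              mode = mode, machine = m)
  class(out) <- "compiled_snp"
  out$stats <- system_stats(out)
  out
}

#' @rdname compilers
#' @export
compile_generator <- function(m) {
  ops <- vapply(m$instructions, `[[`, character(1), "op")
  sub_on_1 <- any(ops == "SUB" &
    vapply(m$instructions, function(i) identical(i$reg, 1L) ||
             identical(i$reg, 1), logical(1)))
  if (sub_on_1)
    stop("generator mode: register 1 is the output register and must never be decremented")
  core <- compile_core(m, deterministic_add = FALSE, fin_register = 1L,
                       extra_registers = 1L)
  finish_compiled(core, m, "generator", output = reg_id(1L),
                  start_spikes = m$start)
}

#' @rdname compilers
#' @export
compile_acceptor <- function(m) {
  if (!rm_is_deterministic(m))
    stop("acceptor mode requires a deterministic register machine")
  core <- compile_core(m, deterministic_add = TRUE, fin_register = NULL,
                       halt_rules = FALSE, extra_registers = 1L)
  inp <- build_input_acceptor(m$start)
  for (id in names(inp))
    core$neurons[[length(core$neurons) + 1L]] <-
      snp_neuron(id, inp[[id]]$spikes, inp[[id]]$rules)
  finish_compiled(core, m, "acceptor", input = "in",
                  input_neurons = names(inp))
}

#' @rdname compilers
#' @param out_register the machine's output register (never decremented);
#'   the FIN module attaches to it.
#' @export
compile_function <- function(m, out_register) {
  if (!rm_is_deterministic(m))
    stop("function mode requires a deterministic register machine")
  sub_on_out <- any(vapply(m$instructions, function(i)
    identical(i$op, "SUB") && i$reg == out_register, logical(1)))
  if (sub_on_out)
    stop("function mode: the output register must never be decremented")
  core <- compile_core(m, deterministic_add = TRUE,
                       fin_register = as.integer(out_register),
                       extra_registers = as.integer(c(1L, 2L, out_register)))
  inp <- build_input_function(m$start)
  for (id in names(inp))
    core$neurons[[length(core$neurons) + 1L]] <-
      snp_neuron(id, inp[[id]]$spikes, inp[[id]]$rules)
  finish_compiled(core, m, "function", input = "in",
                  output = reg_id(out_register), input_neurons = names(inp))
}

#' @export
print.compiled_snp <- function(x, ...) {
  s <- x$stats
  cat("Compiled SN P system (", x$mode, " mode): ", s[["neurons"]],
      " neurons, max ", s[["h"]], " synapses created / ", s[["g"]],
      " deleted per rule, max ", s[["r"]], " rules per neuron\n", sep = "")
  invisible(x)
}

#' System statistics
#'
#' The size parameters used to classify self-organizing systems: neuron
#' count, the maximal number of synapses created by one creation rule
#' (\code{h}), deleted by one deletion rule (\code{g}), and the maximal
#' number of rules in any neuron (\code{r}).
#'
#' @param cs a \code{compiled_snp} or \code{snp_system}.
#' @return named integer vector \code{c(neurons, h, g, r)}.
#' @export
system_stats <- function(cs) {
  system <- if (inherits(cs, "compiled_snp")) cs$system else cs
  h <- 0L; g <- 0L; r <- 0L
  for (nr in system$neurons) {
    r <- max(r, length(nr$rules))
    for (rl in nr$rules) {
      if (rl$kind == "creation") h <- max(h, length(rl$targets))
      if (rl$kind == "deletion") g <- max(g, length(rl$targets))
    }
  }
  c(neurons = length(system$neurons), h = h, g = g, r = r)
}

#' Neuron census of a compiled system
#'
#' Decomposes the neuron count into register, label, ADD-auxiliary,
#' SUB-auxiliary and INPUT-module neurons (the constructive counting
#' \code{registers + labels + 2*ADD + 2*SUB [+ input neurons]}).
#'
#' @param cs a \code{compiled_snp}.
#' @return named integer vector.
#' @export
neuron_census <- function(cs) {
  stopifnot(inherits(cs, "compiled_snp"))
  ops <- vapply(cs$machine$instructions, `[[`, character(1), "op")
  aux_by_op <- function(op) sum(lengths(cs$aux_map[names(ops)[ops == op]]))
  c(registers = length(cs$register_map),
    labels = length(cs$label_map),
    add_aux = aux_by_op("ADD"),
    sub_aux = aux_by_op("SUB"),
    input = length(cs$input_neurons),
    total = length(cs$system$neurons))
}
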