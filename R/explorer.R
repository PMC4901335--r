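#' Exhaustive exploration of nondeterministic computations
#'
#' Enumerates every computation of a system by branching over the joint
#' nondeterministic choices of one step (the Cartesian product of the
#' enabled-rule alternatives of every neuron; in the register-machine
#' constructions at most one neuron — the branching ADD auxiliary — ever has
#' more than one enabled rule). States are deduplicated on the full
#' configuration digest (spike counts, countdowns, pending emissions,
#' synapse set, remaining input schedule and environment tally), so the
#' result set is independent of exploration order.
#'
#' @param system an \code{\link{snp_system}}.
#' @param mode as in \code{\link{snp_run}}.
#' @param input_train input spike schedule (acceptor / function modes).
#' @param max_steps per-computation step bound; deeper branches are pruned
#'   and counted in \code{pruned_steps}.
#' @param max_spikes per-neuron spike bound; configurations exceeding it are
#'   pruned and counted in \code{pruned_spikes}.
#' @return list with \code{results} (sorted environment tallies of halting
#'   computations; for acceptor mode \code{accepted} instead), \code{halts},
#'   \code{pruned_steps}, \code{pruned_spikes}, \code{states} (expansions)
#'   and \code{max_branching} (largest per-neuron choice set seen).
#' @examples
#' cs <- compile_generator(sample_machines()$loop_add)
#' snp_explore(cs$system, max_steps = 40)$results
#' @export
snp_explore <- function(system, mode = c("generator", "acceptor", "function"),
                        input_train = integer(0),
                        max_steps = 10000L, max_spikes = 10000L) {
  mode <- match.arg(mode)
  init <- snp_init(system, input_train)
  sim <- init$sim
  seen <- new.env(parent = emptyenv())
  results <- integer(0)
  halts <- 0L; pruned_steps <- 0L; pruned_spikes <- 0L
  states <- 0L; max_branching <- 1L

  digest <- function(cf) paste(
    paste(cf$counts, collapse = ","), paste(cf$closed, collapse = ","),
    paste(cf$pend_amt, collapse = ","), paste(cf$pend_due, collapse = ","),
    paste(which(cf$syn), collapse = ","),
    paste(cf$schedule, collapse = ","), cf$env, sep = "|")

  stack <- list(init)
  while (length(stack)) {
    cf <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- digest(cf)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    states <- states + 1L
    if (snp_quiescent(cf)) {
      halts <- halts + 1L
      results <- c(results, cf$env)
      next
    }
    if (cf$step >= max_steps) { pruned_steps <- pruned_steps + 1L; next }
    if (any(cf$counts > max_spikes)) { pruned_spikes <- pruned_spikes + 1L; next }

    # per-neuron enabled alternatives on this configuration
    choice_sets <- list()
    for (i in seq_len(sim$m)) {
      if (cf$closed[i] > 0L) next
      if (!is.na(cf$pend_due[i]) && cf$pend_due[i] == cf$step + 1L) next
      en <- enabled_rule_idx(sim$rules[[i]], cf$counts[i])
      if (length(en) > 1L) {
        choice_sets[[sim$ids[i]]] <- en
        max_branching <- max(max_branching, length(en))
      }
    }
    # mixed-radix walk over the Cartesian product of the choice sets
    sizes <- lengths(choice_sets)
    n_combos <- if (length(sizes)) prod(sizes) else 1L
    for (ci in seq_len(n_combos) - 1L) {
      pick <- integer(0)
      rest <- ci
      for (j in seq_along(choice_sets)) {
        pick[names(choice_sets)[j]] <- choice_sets[[j]][rest %% sizes[j] + 1L]
        rest <- rest %/% sizes[j]
      }
      policy <- function(id, en) {
        if (id %in% names(pick)) pick[[id]] else en[1L]
      }
      stack[[length(stack) + 1L]] <- snp_step(cf, policy = policy)
    }
  }
  out <- list(halts = halts, pruned_steps = pruned_steps,
              pruned_spikes = pruned_spikes, states = states,
              max_branching = max_branching)
  if (mode == "acceptor") out$accepted <- halts > 0L
  out$results <- sort(unique(results))
  out
}
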