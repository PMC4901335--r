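# Exact synchronous-clock semantics.
#
# One global step, computed from start-of-step state:
#   1. every open neuron whose count enables at least one rule applies exactly
#      one (chosen by the policy); guards and the k >= c check use the
#      start-of-step count;
#   2. spiking rules with delay 0 deliver along the synapses existing at the
#      START of the step; a delay d >= 1 closes the neuron for d steps and
#      schedules the emission; creation rules add their synapses and deliver
#      to their own targets within the step; deletion rules take effect at end
#      of step;
#   3. deliveries to the environment are tallied, deliveries to closed
#      neurons are lost, all others are usable from the next step;
#   4. a scheduled input spike due this step is credited at end of step.

# Compile a system into indexed form for fast stepping.
snp_sim <- function(system) {
  stopifnot(inherits(system, "snp_system"))
  ids <- names(system$neurons)
  m <- length(ids)
  idx <- stats::setNames(seq_len(m), ids)
  rules <- lapply(system$neurons, function(nr) {
    lapply(nr$rules, function(rl) {
      tg <- if (length(rl$targets))
        unname(vapply(rl$targets, function(t) if (t == "0") 0L else idx[[t]],
                      integer(1)))
      else integer(0)
      list(kind = rl$kind, guard = rl$guard, consume = rl$consume,
           emit = rl$emit, delay = rl$delay, targets = tg, src = rl)
    })
  })
  list(ids = ids, m = m, idx = idx, rules = rules,
       n_rules = vapply(rules, length, integer(1)),
       init = vapply(system$neurons, `[[`, integer(1), "spikes"),
       input = if (is.null(system$input)) NA_integer_ else idx[[system$input]],
       output = if (is.null(system$output)) NA_integer_ else idx[[system$output]])
}

#' Initial configuration
#'
#' @param system an \code{\link{snp_system}}.
#' @param input_train integer vector of step indices (1-based clock) at which
#'   the input neuron receives one spike from the environment.
#' @return a \code{snp_config}: spike counts, closed-status countdowns,
#'   pending delayed emissions, the current synapse set (empty at start), the
#'   step index, the environment tally and the loss tally.
#' @export
snp_init <- function(system, input_train = integer(0)) {
  sim <- snp_sim(system)
  if (length(input_train) && is.na(sim$input))
    stop("input train given but the system has no input neuron")
  structure(list(
    counts = sim$init,
    closed = integer(sim$m),
    pend_amt = integer(sim$m), pend_due = rep(NA_integer_, sim$m),
    syn = matrix(FALSE, sim$m, sim$m + 1L),   # column t+1 = target t; t = 0 is env
    step = 0L,
    env = 0L, lost = 0L,
    schedule = sort(as.integer(input_train)),
    sim = sim), class = "snp_config")
}

# rules enabled on count k (indices into the neuron's rule list, order kept)
enabled_rule_idx <- function(rules, k) {
  if (k <= 0L || !length(rules)) return(integer(0))
  which(vapply(rules, function(rl)
    k >= rl$consume && guard_matches(rl$guard, k), logical(1)))
}

#' Enabled rules of a neuron at a given spike count
#'
#' @param neuron an \code{snp_neuron}.
#' @param k spike count.
#' @return the sub-list of \code{neuron$rules} whose guard matches \code{k}
#'   and whose consumption does not exceed \code{k}, in listed order.
#' @export
snp_enabled_rules <- function(neuron, k) {
  stopifnot(inherits(neuron, "snp_neuron"))
  keep <- vapply(neuron$rules, function(rl)
    k >= rl$consume && guard_matches(rl$guard, k), logical(1))
  neuron$rules[keep]
}

#' Advance a configuration by one synchronous step
#'
#' @param config an \code{snp_config} from \code{\link{snp_init}} or a
#'   previous \code{snp_step}.
#' @param policy how to resolve nondeterminism when several rules are enabled
#'   in one neuron: \code{"first"} (first listed), \code{"random"} (uniform,
#'   uses the R RNG), or a \code{function(neuron_id, enabled_idx)} returning
#'   one element of \code{enabled_idx}.
#' @param record when TRUE, attach a one-step trace (applied rules, spike
#'   movements, synapse deltas) as attribute \code{"trace"}.
#' @return the next \code{snp_config}.
#' @export
snp_step <- function(config, policy = "first", record = FALSE) {
  sim <- config$sim
  m <- sim$m
  counts0 <- config$counts
  syn0 <- config$syn
  now <- config$step + 1L          # the step being computed, 1-based

  new_counts <- counts0
  closed <- config$closed
  pend_amt <- config$pend_amt; pend_due <- config$pend_due
  syn <- syn0
  deliver <- integer(m + 1L)       # index t+1, t = 0 env
  deletions <- list()
  applied <- 0L
  tr <- if (record) list() else NULL

  # pending delayed emissions due now fire first (neuron reopens)
  due <- which(!is.na(pend_due) & pend_due == now)
  for (i in due) {
    out <- which(syn0[i, ])
    if (length(out)) deliver[out] <- deliver[out] + pend_amt[i]
    if (record) tr[[length(tr) + 1L]] <- list(
      neuron = sim$ids[i], rule = "<delayed emission>", consumed = 0L,
      emitted = pend_amt[i], targets = out - 1L)
    pend_amt[i] <- 0L; pend_due[i] <- NA_integer_
    closed[i] <- 0L
    applied <- applied + 1L        # activity: the step is not quiescent
  }
  still_closed <- closed > 0L
  closed[still_closed] <- closed[still_closed] - 1L

  for (i in seq_len(m)) {
    if (still_closed[i] || i %in% due) next
    k <- counts0[i]
    en <- enabled_rule_idx(sim$rules[[i]], k)
    if (!length(en)) next
    pick <- if (length(en) == 1L) en
      else if (identical(policy, "first")) en[1L]
      else if (identical(policy, "random")) en[sample.int(length(en), 1L)]
      else {
        ch <- policy(sim$ids[i], en)
        if (!ch %in% en) stop("choice policy returned a rule (", ch,
                              ") not enabled in neuron ", sim$ids[i])
        ch
      }
    rl <- sim$rules[[i]][[pick]]
    new_counts[i] <- new_counts[i] - rl$consume
    tg <- integer(0)
    if (rl$kind == "spiking") {
      if (rl$delay == 0L) {
        tg <- which(syn0[i, ]) - 1L
        if (rl$emit > 0L && length(tg))
          deliver[tg + 1L] <- deliver[tg + 1L] + rl$emit
      } else {
        pend_amt[i] <- rl$emit
        pend_due[i] <- now + rl$delay
        closed[i] <- rl$delay
      }
    } else if (rl$kind == "creation") {
      syn[cbind(i, rl$targets + 1L)] <- TRUE
      tg <- rl$targets
      if (rl$emit > 0L) deliver[tg + 1L] <- deliver[tg + 1L] + rl$emit
    } else { # deletion at end of step
      deletions[[length(deletions) + 1L]] <- list(i = i, targets = rl$targets)
      tg <- rl$targets
    }
    applied <- applied + 1L
    if (record) tr[[length(tr) + 1L]] <- list(
      neuron = sim$ids[i], rule = format(rl$src), consumed = rl$consume,
      emitted = rl$emit, targets = tg)
  }

  # resolve deliveries against end-of-step open/closed status
  env_gain <- deliver[1L]
  lost_gain <- 0L
  inflow <- deliver[-1L]
  if (any(inflow > 0L)) {
    blocked <- closed > 0L & inflow > 0L
    lost_gain <- sum(inflow[blocked])
    inflow[blocked] <- 0L
    new_counts <- new_counts + inflow
  }

  # scheduled input spike lands at end of step
  schedule <- config$schedule
  if (length(schedule) && schedule[1L] == now) {
    schedule <- schedule[-1L]
    if (closed[sim$input] > 0L) lost_gain <- lost_gain + 1L
    else new_counts[sim$input] <- new_counts[sim$input] + 1L
    applied <- applied + 1L
  }

  for (d in deletions) syn[cbind(d$i, d$targets + 1L)] <- FALSE

  out <- config
  out$counts <- new_counts
  out$closed <- closed
  out$pend_amt <- pend_amt; out$pend_due <- pend_due
  out$syn <- syn
  out$step <- now
  out$env <- config$env + env_gain
  out$lost <- config$lost + lost_gain
  out$schedule <- schedule
  attr(out, "activity") <- applied
  if (record) attr(out, "trace") <- tr
  out
}

#' Halting test for a configuration
#'
#' TRUE when no rule is enabled in any open neuron, no neuron is closed or
#' holds a pending delayed emission, and no input spike remains scheduled:
#' the halting configuration of the synchronous semantics.
#'
#' @param config an \code{snp_config}.
#' @return logical.
#' @export
snp_quiescent <- function(config) {
  if (any(config$closed > 0L) || any(!is.na(config$pend_due)) ||
      length(config$schedule)) return(FALSE)
  sim <- config$sim
  for (i in seq_len(sim$m)) {
    if (config$counts[i] > 0L &&
        length(enabled_rule_idx(sim$rules[[i]], config$counts[i])))
      return(FALSE)
  }
  TRUE
}

#' Run a system to halting
#'
#' Runs the synchronous semantics until the halting configuration (no rule
#' enabled in any neuron, no pending delayed emission, no remaining input
#' spike) or until \code{max_steps}.
#'
#' @param system an \code{\link{snp_system}}.
#' @param mode \code{"generator"} (no input; result = environment tally),
#'   \code{"acceptor"} (input train required; result = halting) or
#'   \code{"function"} (input train required; result = environment tally).
#' @param input_train steps at which the input neuron receives a spike; see
#'   \code{\link{spike_train}}.
#' @param policy,record passed to \code{\link{snp_step}}.
#' @param seed optional seed applied before a \code{"random"} policy run.
#' @param max_steps divergence bound (acceptor rejection is divergence).
#' @return list with \code{halted}, \code{steps}, \code{emitted} (environment
#'   tally), \code{accepted} (acceptor mode), \code{counts} (final per-neuron
#'   spikes, named), \code{lost}, and \code{trace} (data frame when
#'   \code{record = TRUE}).
#' @examples
#' m <- sample_machines()$two_add
#' gen <- compile_generator(m)
#' snp_run(gen$system)$emitted   # 2, matching rm_run(m, "generate")
#' @export
snp_run <- function(system, mode = c("generator", "acceptor", "function"),
                    input_train = integer(0), policy = "first",
                    seed = NULL, max_steps = 10000L, record = FALSE) {
  mode <- match.arg(mode)
  if (mode != "generator" && !length(input_train))
    stop(mode, " mode requires an input spike train")
  if (mode != "acceptor" && is.null(system$output))
    stop(mode, " mode requires an output neuron")
  if (!is.null(seed)) set.seed(seed)
  config <- snp_init(system, input_train)
  traces <- list()
  halted <- FALSE
  while (config$step < max_steps) {
    if (snp_quiescent(config)) { halted <- TRUE; break }
    config <- snp_step(config, policy = policy, record = record)
    if (record) traces[[length(traces) + 1L]] <-
        steptrace_rows(attr(config, "trace"), config$step)
  }
  res <- list(halted = halted, steps = config$step,
              emitted = config$env,
              accepted = if (mode == "acceptor") halted else NA,
              counts = stats::setNames(config$counts, config$sim$ids),
              lost = config$lost,
              config = config)
  if (record) res$trace <- do.call(rbind, c(traces,
                                            list(make.row.names = FALSE)))
  class(res) <- "snp_run"
  res
}

#' @export
print.snp_run <- function(x, ...) {
  cat("SN P run:", if (x$halted) "halted" else "step bound reached",
      "after", x$steps, "steps;", x$emitted, "spike(s) emitted\n")
  invisible(x)
}

steptrace_rows <- function(tr, step) {
  if (!length(tr)) return(NULL)
  do.call(rbind, lapply(tr, function(e) data.frame(
    step = step, neuron = e$neuron, rule = e$rule,
    consumed = e$consumed, emitted = e$emitted,
    targets = paste(e$targets, collapse = ","),
    stringsAsFactors = FALSE)))
}

#' Observe a run step by step
#'
#' Convenience wrapper that advances the system while calling \code{observe}
#' on every configuration (including the initial one); used to audit the
#' module timelines (spike counts and synapse sets at each step).
#'
#' @inheritParams snp_run
#' @param observe \code{function(config)} called on each configuration.
#' @param steps exact number of steps to take (no halting check).
#' @return the final \code{snp_config}, invisibly.
#' @export
snp_replay <- function(system, steps, input_train = integer(0),
                       policy = "first", observe = NULL) {
  config <- snp_init(system, input_train)
  if (!is.null(observe)) observe(config)
  for (s in seq_len(steps)) {
    config <- snp_step(config, policy = policy)
    if (!is.null(observe)) observe(config)
  }
  invisible(config)
}

#' Current synapse set of a configuration
#'
#' @param config an \code{snp_config}.
#' @return two-column character matrix (\code{from}, \code{to}); the
#'   environment appears as \code{"0"}.
#' @export
snp_synapses <- function(config) {
  sim <- config$sim
  w <- which(config$syn, arr.ind = TRUE)
  cbind(from = sim$ids[w[, 1L]],
        to = ifelse(w[, 2L] == 1L, "0", sim$ids[w[, 2L] - 1L]))
}
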