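# Micro-dynamics of the compiled modules, replayed step by step against the
# instruction-level conventions: registers encode n as 5n spikes, labels
# activate at exactly 6 spikes, and modules tear their wiring down.

test_that("one ADD simulation adds 5 to the register and activates one successor", {
  m <- make_machine(l0 = ADD(2, "l1", "lh"), l1 = ADD(3, "lh"), lh = HALT)
  cs <- compile_generator(m)
  # policy picks aux2's first rule -> successor l1; second rule -> lh
  for (branch in 1:2) {
    pol <- function(id, en) if (id == "l0#2") en[branch] else en[1]
    cf <- snp_init(cs$system)
    r2 <- cf$sim$idx[["r2"]]
    hand <- NULL
    for (s in 1:20) {
      cf <- snp_step(cf, policy = pol)
      succ <- if (branch == 1) "l1" else "lh"
      if (is.null(hand) && cf$counts[[cf$sim$idx[[succ]]]] == 6L) hand <- cf
    }
    expect_false(is.null(hand))
    expect_identical(hand$counts[[r2]], 5L)       # +5 on the register
    other <- if (branch == 1) "lh" else "l1"
    expect_lt(hand$counts[[hand$sim$idx[[other]]]], 6L)
  }
})

test_that("exhaustive exploration of a nondeterministic ADD reaches both branches", {
  # l0's branches are distinguishable by which register gets incremented next
  m <- make_machine(l0 = ADD(2, "l1", "lh"), l1 = ADD(3, "lh"), lh = HALT)
  ex <- snp_explore(compile_generator(m)$system, max_steps = 60)
  expect_identical(ex$halts, 2L)                  # two terminal computations
  expect_identical(ex$max_branching, 2L)
  expect_identical(ex$results, 0L)                # register 1 untouched
})

test_that("ADD modules end synapse-free and hand exactly 6 spikes over", {
  cs <- compile_generator(make_machine(l0 = ADD(1, "l1"), l1 = ADD(1, "lh"),
                                       lh = HALT))
  hits <- counts_when_fires(cs$system, "l1")
  expect_true(length(hits) >= 1L)
  expect_identical(unname(hits[[1]][["l1"]]), 6L)
  r <- snp_run(cs$system)
  expect_true(r$halted)
  expect_identical(nrow(snp_synapses(r$config)), 0L)
})

test_that("SUB decrement branch: register net -5, successor gets 6 spikes", {
  # input n = 1 plus two ADDs load register 1 with 15 spikes before the SUB
  cs <- compile_acceptor(make_machine(
    a0 = ADD(1, "a1"), a1 = ADD(1, "a2"),
    a2 = SUB(1, "a3", "a4"), a3 = ADD(2, "ah"),
    a4 = ADD(3, "ah"), ah = HALT))
  # acceptor input n = 1 preloads r1 with 5; the two ADDs raise it to 15
  cf <- snp_init(cs$system, spike_train("acceptor", 1))
  sim <- cf$sim
  r1 <- sim$idx[["r1"]]
  before_sub <- NA_integer_; hand <- NULL
  for (s in 1:80) {
    start <- cf$counts
    cf <- snp_step(cf, record = TRUE)
    fired <- vapply(attr(cf, "trace"), `[[`, character(1), "neuron")
    if ("a2" %in% fired && is.na(before_sub)) before_sub <- start[[r1]]
    if (is.null(hand) && cf$counts[[sim$idx[["a3"]]]] == 6L) hand <- cf
  }
  expect_identical(before_sub, 15L)               # 5n with n = 3
  expect_false(is.null(hand))
  expect_identical(hand$counts[[r1]], 10L)        # 5(n-1): net change -5
  expect_identical(hand$counts[[sim$idx[["a4"]]]], 0L)
})

test_that("SUB zero branch: register returns to 0 and l_k gets 6 spikes", {
  cs <- compile_acceptor(make_machine(
    a0 = SUB(2, "a1", "a2"), a1 = ADD(3, "ah"), a2 = ADD(4, "ah"), ah = HALT))
  cf <- snp_init(cs$system, spike_train("acceptor", 1))
  sim <- cf$sim
  hand <- NULL
  for (s in 1:60) {
    cf <- snp_step(cf)
    if (is.null(hand) && cf$counts[[sim$idx[["a2"]]]] == 6L) hand <- cf
  }
  expect_false(is.null(hand))
  expect_identical(hand$counts[[sim$idx[["r2"]]]], 0L)
  expect_identical(hand$counts[[sim$idx[["a1"]]]], 0L)
  r <- snp_run(cs$system, "acceptor", input_train = spike_train("acceptor", 1),
               max_steps = 200)
  expect_true(r$accepted)
})

test_that("interference between two SUB modules on one register is absorbed", {
  fx <- sample_machines()$double_sub
  cs <- compile_acceptor(fx)
  # auxiliaries of SUB modules on register 1 carry the absorber rules: 5 each
  expect_identical(system_stats(cs)[["r"]], 5L)
  for (n in 2:4) {
    r <- snp_run(cs$system, "acceptor", input_train = spike_train("acceptor", n),
                 max_steps = 600)
    expect_identical(r$accepted, n %% 2 == 0)
    if (r$halted) {
      # foreign auxiliaries hold no residue at the end
      aux <- unlist(cs$aux_map[c("l0", "l1")])
      expect_true(all(r$counts[aux] == 0L))
    }
  }
})

test_that("FIN emits exactly the encoded register value, then quiesces clean", {
  for (n in c(1L, 4L)) {
    # n ADDs on register 1, then halt: FIN must emit n
    labs <- paste0("l", seq_len(n) - 1L)
    ins <- stats::setNames(lapply(seq_len(n), function(i)
      ADD(1, if (i < n) paste0("l", i) else "lh")), labs)
    ins$lh <- HALT
    cs <- compile_generator(rm_machine(ins))
    r <- snp_run(cs$system, record = TRUE)
    expect_true(r$halted)
    expect_identical(r$emitted, n)
    expect_identical(nrow(snp_synapses(r$config)), 0L)
    # final deletion severs the environment edge exactly once
    expect_identical(sum(grepl("-\\(lambda,\\{0\\}", r$trace$rule)), 1L)
  }
})

test_that("acceptor INPUT loads 5n spikes into register 1 and activates l0", {
  # the probe machine never touches register 1, so the final count of r1 is
  # exactly what the INPUT module deposited
  probe <- make_machine(l0 = ADD(2, "lh"), lh = HALT)
  cs <- compile_acceptor(probe)
  for (n in c(1L, 4L)) {
    hits <- counts_when_fires(cs$system, "l0", max_steps = 60,
                              input_train = spike_train("acceptor", n))
    expect_true(length(hits) >= 1L)
    expect_identical(unname(hits[[1]][["l0"]]), 6L)
    r <- snp_run(cs$system, "acceptor",
                 input_train = spike_train("acceptor", n), max_steps = 100)
    expect_true(r$halted)
    expect_identical(unname(r$counts[["r1"]]), 5L * n)
  }
})

test_that("function INPUT loads 5g and 5y and hands 6 spikes to l0", {
  m <- sample_machines()$add_fun
  cs <- compile_function(m, 3)
  for (gy in list(c(3L, 2L), c(2L, 3L), c(1L, 2L))) {
    hits <- counts_when_fires(cs$system, "l0", max_steps = 60,
                              input_train = spike_train("function", gy))
    expect_true(length(hits) >= 1L)
    h <- hits[[1]]
    expect_identical(unname(h[["l0"]]), 6L)
    expect_identical(unname(h[["r1"]]), 5L * gy[1])  # settled before handoff
    r <- snp_run(cs$system, "function", input_train = spike_train("function", gy),
                 max_steps = 400)
    expect_true(r$halted)
    expect_identical(r$emitted, gy[1] + gy[2])
  }
  # proj_fun never reads register 2: its final count is the pure INPUT load
  pf <- compile_function(sample_machines()$proj_fun, 3)
  for (gy in list(c(2L, 2L), c(3L, 4L))) {
    r <- snp_run(pf$system, "function",
                 input_train = spike_train("function", gy), max_steps = 400)
    expect_true(r$halted)
    expect_identical(unname(r$counts[["r2"]]), 5L * gy[2])
    expect_identical(r$emitted, gy[1])
  }
  # y = 1 is outside the INPUT module's supported range: the third spike
  # lands before the second-argument loader starts, the input neuron
  # deadlocks at an unmatched 9-spike count and no instruction ever runs
  expect_length(counts_when_fires(cs$system, "l0", max_steps = 60,
                                  input_train = spike_train("function", c(2L, 1L))),
                0L)
})

test_that("handoff instants see registers at multiples of five", {
  m <- sample_machines()$even_acc
  cs <- compile_acceptor(m)
  cf <- snp_init(cs$system, spike_train("acceptor", 4))
  sim <- cf$sim
  regs <- unname(cs$register_map)
  labels <- names(cs$label_map)
  while (!snp_quiescent(cf) && cf$step < 300) {
    start <- stats::setNames(cf$counts, sim$ids)
    cf <- snp_step(cf, record = TRUE)
    fired <- vapply(attr(cf, "trace"), `[[`, character(1), "neuron")
    for (lab in intersect(fired, labels)) {
      if (start[[lab]] == 6L)   # the label is simulating its instruction
        expect_true(all(start[regs] %% 5L == 0L),
                    label = sprintf("registers at handoff of %s", lab))
    }
  }
  expect_true(snp_quiescent(cf))
})

test_that("neuron census follows the constructive counting formula", {
  fx <- sample_machines()
  for (nm in names(fx)) {
    m <- fx[[nm]]
    ops <- vapply(m$instructions, `[[`, character(1), "op")
    base <- length(m$instructions) + 2L * sum(ops != "HALT")
    if (nm %in% c("two_add", "loop_add", "even_gen")) {
      cs <- compile_generator(m)
      nregs <- length(unique(c(1L, m$registers)))
      expect_identical(length(cs$system$neurons), base + nregs,
                       label = paste("generator census", nm))
    }
    if (nm %in% c("even_acc", "double_sub")) {
      cs <- compile_acceptor(m)
      nregs <- length(unique(c(1L, m$registers)))
      expect_identical(length(cs$system$neurons), base + nregs + 3L,
                       label = paste("acceptor census", nm))
    }
  }
  cf <- compile_function(fx$add_fun, 3)
  expect_identical(length(cf$system$neurons),
                   3L + 5L + 2L * 4L + 5L)  # registers + labels + aux + input
})

test_that("rule-count bounds: 3 in plain generators, 5 with shared SUB registers", {
  expect_identical(system_stats(compile_generator(sample_machines()$even_gen))[["r"]], 3L)
  expect_identical(system_stats(compile_generator(make_machine(
    l0 = ADD(2, "l1"), l1 = SUB(2, "l2", "lh"), l2 = ADD(1, "l0"),
    lh = HALT)))[["r"]], 3L)
  expect_identical(system_stats(compile_acceptor(sample_machines()$double_sub))[["r"]], 5L)
})

test_that("generator mode rejects machines that decrement the output register", {
  expect_error(compile_generator(make_machine(
    l0 = SUB(1, "l0", "lh"), lh = HALT)), "never be decremented")
  expect_error(compile_function(make_machine(
    l0 = SUB(3, "l0", "lh"), lh = HALT), 3), "never be decremented")
  expect_error(compile_acceptor(sample_machines()$loop_add), "deterministic")
})
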