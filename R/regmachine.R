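#' Register machines
#'
#' A register machine is a labelled program over unbounded non-negative
#' counters with three instruction forms:
#' \itemize{
#'   \item \code{l_i: (ADD(r), l_j, l_k)} — increment register \code{r}, then
#'     jump nondeterministically to \code{l_j} or \code{l_k} (deterministic
#'     when \code{l_j == l_k});
#'   \item \code{l_i: (SUB(r), l_j, l_k)} — if register \code{r} is positive,
#'     decrement it and jump to \code{l_j}, otherwise jump to \code{l_k};
#'   \item \code{l_h: HALT}.
#' }
#' Register machines characterise the Turing computable sets of naturals and
#' serve here as the semantic oracle against which compiled spiking systems
#' are verified.
#'
#' @param instructions named list; each element is a list with fields
#'   \code{op} ("ADD", "SUB" or "HALT"), \code{reg} (register index, absent
#'   for HALT) and \code{next1}/\code{next2} (continuation labels).
#' @param start start label (default first instruction).
#' @return an object of class \code{reg_machine}.
#' @examples
#' m <- rm_machine(list(
#'   l0 = list(op = "ADD", reg = 1, next1 = "l1", next2 = "l1"),
#'   l1 = list(op = "ADD", reg = 1, next1 = "lh", next2 = "lh"),
#'   lh = list(op = "HALT")))
#' rm_run(m, mode = "generate")$registers[["1"]]
#' @export
rm_machine <- function(instructions, start = names(instructions)[1]) {
  stopifnot(is.list(instructions), length(instructions) >= 1,
            !is.null(names(instructions)), all(nzchar(names(instructions))))
  labs <- names(instructions)
  if (anyDuplicated(labs)) stop("duplicate instruction labels")
  halt <- labs[vapply(instructions, function(i) identical(i$op, "HALT"), logical(1))]
  if (length(halt) != 1L) stop("a register machine needs exactly one HALT instruction")
  for (lab in labs) {
    ins <- instructions[[lab]]
    if (!ins$op %in% c("ADD", "SUB", "HALT"))
      stop("unknown op '", ins$op, "' at label ", lab)
    if (ins$op != "HALT") {
      if (is.null(ins$reg) || ins$reg < 0) stop("bad register at label ", lab)
      instructions[[lab]]$reg <- as.integer(ins$reg)
      for (nx in c(ins$next1, ins$next2))
        if (!nx %in% labs) stop("label ", lab, " jumps to unknown label ", nx)
    }
  }
  if (!start %in% labs) stop("unknown start label ", start)
  regs <- sort(unique(vapply(instructions[labs != halt], `[[`, integer(1), "reg")))
  structure(list(instructions = instructions, start = start, halt = halt,
                 registers = regs), class = "reg_machine")
}

#' @export
print.reg_machine <- function(x, ...) {
  cat("Register machine:", length(x$instructions), "instructions,",
      length(x$registers), "registers, start", x$start, "\n")
  invisible(x)
}

#' @describeIn rm_machine TRUE when every ADD instruction has a single
#'   continuation (the machine's run is then a function of its preload).
#' @param m a \code{reg_machine}.
#' @export
rm_is_deterministic <- function(m) {
  all(vapply(m$instructions, function(i)
    i$op != "ADD" || identical(i$next1, i$next2), logical(1)))
}

#' Count ADD / SUB instructions
#' @param m a \code{reg_machine}.
#' @return named integer vector with components \code{ADD}, \code{SUB},
#'   \code{HALT}, \code{labels}, \code{registers}.
#' @export
rm_census <- function(m) {
  ops <- vapply(m$instructions, `[[`, character(1), "op")
  c(ADD = sum(ops == "ADD"), SUB = sum(ops == "SUB"), HALT = sum(ops == "HALT"),
    labels = length(ops), registers = length(m$registers))
}

#' Run a register machine
#'
#' Direct interpreter. In \code{generate} mode all registers start at zero and
#' ADD branches are resolved by \code{choose} (a function of the two labels;
#' defaults to the first — use \code{\link{rm_generate_set}} for the full
#' nondeterministic result set). In \code{accept} mode register 1 is preloaded
#' with \code{input} and acceptance is halting. In \code{function} mode the
#' elements of \code{input} preload registers 1, 2, ... and the value is read
#' from \code{out_register} at halt.
#'
#' @param m a \code{reg_machine}.
#' @param mode one of \code{"generate"}, \code{"accept"}, \code{"function"}.
#' @param input integer vector of arguments (accept: length 1).
#' @param out_register register read at halt (generate: 1).
#' @param max_steps divergence bound.
#' @param choose callback \code{function(l_j, l_k)} picking an ADD branch.
#' @return list with \code{halted}, \code{steps}, \code{registers} (named by
#'   register index), and \code{value} (the mode's result; \code{NA} when the
#'   bound is hit).
#' @export
rm_run <- function(m, mode = c("generate", "accept", "function"),
                   input = integer(0), out_register = 1L,
                   max_steps = 100000L, choose = NULL) {
  mode <- match.arg(mode)
  regs <- stats::setNames(integer(length(m$registers)), as.character(m$registers))
  if (mode == "accept") {
    stopifnot(length(input) == 1L, input >= 0)
    regs[["1"]] <- as.integer(input)
  } else if (mode == "function") {
    stopifnot(length(input) >= 1L, all(input >= 0))
    for (i in seq_along(input)) regs[[as.character(i)]] <- as.integer(input[i])
  }
  if (mode == "generate") out_register <- 1L
  lab <- m$start
  steps <- 0L
  while (lab != m$halt) {
    if (steps >= max_steps)
      return(list(halted = FALSE, steps = steps, registers = regs, value = NA_integer_))
    ins <- m$instructions[[lab]]
    r <- as.character(ins$reg)
    if (ins$op == "ADD") {
      regs[[r]] <- regs[[r]] + 1L
      lab <- if (identical(ins$next1, ins$next2) || is.null(choose)) ins$next1
             else choose(ins$next1, ins$next2)
    } else { # SUB
      if (regs[[r]] > 0L) {
        regs[[r]] <- regs[[r]] - 1L
        lab <- ins$next1
      } else lab <- ins$next2
    }
    steps <- steps + 1L
  }
  value <- switch(mode,
    generate = if ("1" %in% names(regs)) regs[["1"]] else 0L,
    accept   = 1L,
    `function` = regs[[as.character(out_register)]])
  list(halted = TRUE, steps = steps, registers = regs, value = as.integer(value))
}

#' Enumerate the generated number set N(M)
#'
#' Breadth-first exploration over all ADD branch choices, memoised on
#' (label, register contents). Returns every register-1 value of a halting
#' run reached within \code{max_steps} machine steps.
#'
#' @param m a \code{reg_machine} in generator form.
#' @param max_steps exploration depth bound.
#' @param max_value optional cap; values above it are dropped (exploration
#'   of a state whose register 1 already exceeds it is pruned).
#' @return sorted integer vector.
#' @export
rm_generate_set <- function(m, max_steps = 200L, max_value = Inf) {
  results <- integer(0)
  seen <- new.env(parent = emptyenv())
  # frontier entries: list(lab, regs)
  frontier <- list(list(lab = m$start,
                        regs = stats::setNames(integer(length(m$registers)),
                                               as.character(m$registers))))
  for (depth in seq_len(max_steps + 1L)) {
    if (!length(frontier)) break
    nxt <- list()
    for (st in frontier) {
      key <- paste(st$lab, paste(st$regs, collapse = ","), sep = "|")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      if (st$lab == m$halt) {
        v <- if ("1" %in% names(st$regs)) st$regs[["1"]] else 0L
        if (v <= max_value) results <- c(results, v)
        next
      }
      ins <- m$instructions[[st$lab]]
      r <- as.character(ins$reg)
      if (ins$op == "ADD") {
        regs2 <- st$regs
        regs2[[r]] <- regs2[[r]] + 1L
        v1 <- if ("1" %in% names(regs2)) regs2[["1"]] else 0L
        if (v1 <= max_value)
          for (nx in unique(c(ins$next1, ins$next2)))
            nxt[[length(nxt) + 1L]] <- list(lab = nx, regs = regs2)
      } else {
        regs2 <- st$regs
        if (regs2[[r]] > 0L) {
          regs2[[r]] <- regs2[[r]] - 1L
          nxt[[length(nxt) + 1L]] <- list(lab = ins$next1, regs = regs2)
        } else nxt[[length(nxt) + 1L]] <- list(lab = ins$next2, regs = regs2)
      }
    }
    frontier <- nxt
  }
  sort(unique(results))
}

#' The universal register machine
#'
#' The 8-register, 23-instruction universal register machine (registers
#' numbered 0 to 7; the "code" g(x) of the function to compute enters in
#' register 1, the argument y in register 2, the result is read from
#' register 0 at halt).
#'
#' @return a \code{reg_machine}.
#' @seealso \code{\link{rm_modify_universal}}
#' @export
rm_universal <- function() {
  read_register_machine(system.file("extdata", "m_u.rm", package = "snpso",
                                    mustWork = TRUE))
}

#' Halt-replacement modification of the universal machine
#'
#' Function-computing spiking compilations forbid SUB instructions on the
#' output register, but register 0 of the universal machine is decremented.
#' The standard fix adds a fresh register 8 and replaces \code{l_h: HALT} by a
#' drain loop moving register 0 into register 8:
#' \preformatted{ l_h : (SUB(0), l22, l_h')
#'  l22 : (ADD(8), l_h)
#'  l_h': HALT }
#' yielding 9 registers, 24 ADD/SUB instructions and 25 labels, with the
#' result in the never-decremented register 8.
#'
#' @param m the machine returned by \code{\link{rm_universal}} (any machine
#'   with a halt instruction is accepted).
#' @param drain register to drain (default 0).
#' @param out fresh output register (default 8).
#' @return a \code{reg_machine}.
#' @export
rm_modify_universal <- function(m, drain = 0L, out = 8L) {
  loop_lab <- "l22"
  stopifnot(!loop_lab %in% names(m$instructions))
  halt2 <- paste0(m$halt, "p")
  ins <- m$instructions
  ins[[m$halt]] <- list(op = "SUB", reg = drain, next1 = loop_lab, next2 = halt2)
  ins[[loop_lab]] <- list(op = "ADD", reg = out, next1 = m$halt, next2 = m$halt)
  ins[[halt2]] <- list(op = "HALT")
  rm_machine(ins, start = m$start)
}

#' Read / write register machine files
#'
#' One instruction per line: \code{"l0: ADD 1 l1 l2"}, \code{"l1: SUB 2 l2 l3"},
#' \code{"lh: HALT"}; a deterministic ADD may omit the second label.
#' \code{#} starts a comment. The first instruction is the start label.
#'
#' @param path file path.
#' @return \code{read_register_machine}: a \code{reg_machine}.
#' @export
read_register_machine <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  ins <- list()
  for (ln in lines) {
    mlab <- regmatches(ln, regexec("^([A-Za-z0-9_']+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(mlab) != 3) stop("malformed instruction line: ", ln)
    lab <- mlab[2]; body <- mlab[3]
    toks <- strsplit(body, "\\s+")[[1]]
    op <- toupper(toks[1])
    if (op == "HALT") {
      ins[[lab]] <- list(op = "HALT")
    } else if (op %in% c("ADD", "SUB")) {
      if (length(toks) < 3) stop("missing operands: ", ln)
      n2 <- if (length(toks) >= 4) toks[4] else toks[3]
      ins[[lab]] <- list(op = op, reg = as.integer(toks[2]),
                         next1 = toks[3], next2 = n2)
    } else stop("unknown op in line: ", ln)
  }
  rm_machine(ins)
}

#' @rdname read_register_machine
#' @param m a \code{reg_machine}.
#' @return \code{write_register_machine}: \code{path}, invisibly.
#' @export
write_register_machine <- function(m, path) {
  fmt <- vapply(names(m$instructions), function(lab) {
    i <- m$instructions[[lab]]
    if (i$op == "HALT") paste0(lab, ": HALT")
    else paste0(lab, ": ", i$op, " ", i$reg, " ", i$next1,
                if (!identical(i$next1, i$next2)) paste0(" ", i$next2) else "")
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}
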