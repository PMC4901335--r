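# Independent brute-force oracle for unary regular languages: evaluates the
# set of word lengths <= N by set operations (concatenation = truncated
# sumset, '+' = iterated closure), sharing no code with the package's
# arithmetic-progression matcher.
oracle_lengths <- function(text, N) {
  src <- gsub("\\s+", "", text)
  alts <- strsplit(src, "|", fixed = TRUE)[[1]]
  term_lengths <- function(s) {
    i <- 1L; n <- nchar(s)
    sets <- list()
    read_run <- function() {
      i <<- i + 1L
      k <- 1L
      if (i <= n && substr(s, i, i) == "^") {
        m <- regmatches(substr(s, i + 1L, n), regexpr("^[0-9]+", substr(s, i + 1L, n)))
        k <- as.integer(m)
        i <<- i + 1L + nchar(m)
      }
      k
    }
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch == "a") {
        sets[[length(sets) + 1L]] <- read_run()
      } else if (ch == "(") {
        i <- i + 1L
        inner <- 0L
        while (i <= n && substr(s, i, i) == "a") inner <- inner + read_run()
        stopifnot(substr(s, i, i) == ")")
        i <- i + 1L
        if (i <= n && substr(s, i, i) == "^") i <- i + 1L
        suf <- if (i <= n) substr(s, i, i) else ""
        base <- inner
        if (suf == "+" || suf == "*") {
          i <- i + 1L
          cl <- integer(0)
          v <- base
          while (v <= N) { cl <- c(cl, v); v <- v + base }
          if (suf == "*") cl <- c(0L, cl)
          sets[[length(sets) + 1L]] <- cl
        } else {
          sets[[length(sets) + 1L]] <- base
        }
      } else stop("oracle cannot parse: ", text)
    }
    # truncated sumset of all factors
    acc <- 0L
    for (st in sets) {
      acc <- unique(as.vector(outer(acc, st, `+`)))
      acc <- acc[acc <= N]
      if (!length(acc)) return(integer(0))
    }
    acc
  }
  sort(unique(unlist(lapply(alts, term_lengths))))
}

# every distinct guard string appearing in a system's rules
system_guards <- function(system) {
  unique(unlist(lapply(system$neurons, function(nr)
    vapply(nr$rules, function(rl) format(rl$guard), character(1)))))
}

# tiny machines reused across tests
make_machine <- function(...) rm_machine(list(...))
ADD <- function(r, j, k = j) list(op = "ADD", reg = r, next1 = j, next2 = k)
SUB <- function(r, j, k) list(op = "SUB", reg = r, next1 = j, next2 = k)
HALT <- list(op = "HALT")

# run a compiled system while recording the start-of-step counts at every
# step where `neuron` applies a rule; returns list of those count vectors
counts_when_fires <- function(system, neuron, max_steps = 500L,
                              input_train = integer(0)) {
  config <- snp_init(system, input_train)
  hits <- list()
  while (config$step < max_steps && !snp_quiescent(config)) {
    before <- config$counts
    config <- snp_step(config, record = TRUE)
    tr <- attr(config, "trace")
    if (any(vapply(tr, function(e) e$neuron == neuron, logical(1))))
      hits[[length(hits) + 1L]] <- stats::setNames(before, config$sim$ids)
  }
  hits
}

# first configuration (start-of-step counts) at which `neuron` has an
# enabled rule; NULL when it never does within the bound
counts_when_enabled <- function(system, neuron, max_steps = 500L,
                                input_train = integer(0)) {
  config <- snp_init(system, input_train)
  nr <- system$neurons[[neuron]]
  repeat {
    if (length(snp_enabled_rules(nr, config$counts[[config$sim$idx[[neuron]]]])))
      return(stats::setNames(config$counts, config$sim$ids))
    if (config$step >= max_steps || snp_quiescent(config)) return(NULL)
    config <- snp_step(config)
  }
}
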