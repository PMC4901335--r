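#' Unary regular-expression guards
#'
#' Rule applicability in a spiking neural P system is controlled by a regular
#' expression over the one-letter alphabet \code{{a}}. A unary regular
#' language is semilinear: a finite union of arithmetic progressions of spike
#' counts, and the parser stores guards in that canonical form. The grammar
#' accepted covers runs \code{a^k}, the iterated groups \code{(a^k)^+} and
#' \code{(a^k)^*}, concatenations thereof, and unions written with \code{|}:
#' e.g. \code{a^6}, \code{a^2(a^5)^+}, \code{a(a^5)^*}.
#'
#' @param text guard in surface syntax. \code{^} may be omitted after a
#'   parenthesis suffix (\code{(a^5)+} equals \code{(a^5)^+}).
#' @return an object of class \code{snp_guard}.
#' @examples
#' g <- snp_guard("a^2(a^5)^+")
#' guard_matches(g, 7)   # TRUE
#' guard_matches(g, 2)   # FALSE
#' @export
snp_guard <- function(text) {
  if (inherits(text, "snp_guard")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  src <- gsub("\\s+", "", text)
  if (!nzchar(src)) stop("empty guard expression")
  alts <- strsplit(src, "|", fixed = TRUE)[[1]]
  if (!length(alts) || any(!nzchar(alts)))
    stop("malformed guard (empty union branch): ", text)
  terms <- lapply(alts, parse_guard_term, full = text)
  structure(list(terms = terms, text = text), class = "snp_guard")
}

# One union-free term: sequence of a^k runs and (a^k)^+/(a^k)^* groups.
# Returned as list(const, periodic = list of c(step, tmin)).
parse_guard_term <- function(s, full = s) {
  i <- 1L; n <- nchar(s)
  const <- 0L
  periodic <- list()
  peek <- function() if (i <= n) substr(s, i, i) else ""
  read_run <- function() {
    # at 'a'; returns run length
    i <<- i + 1L
    k <- 1L
    if (peek() == "^") {
      i <<- i + 1L
      m <- regmatches(substr(s, i, n), regexpr("^[0-9]+", substr(s, i, n)))
      if (!length(m)) stop("expected exponent after '^' in guard: ", full)
      k <- as.integer(m)
      i <<- i + nchar(m)
    }
    k
  }
  while (i <= n) {
    ch <- peek()
    if (ch == "a") {
      const <- const + read_run()
    } else if (ch == "(") {
      i <- i + 1L
      inner <- 0L
      while (peek() == "a") inner <- inner + read_run()
      if (peek() != ")" || inner == 0L)
        stop("malformed group in guard near position ", i, ": ", full)
      i <- i + 1L
      if (peek() == "^") i <- i + 1L
      suf <- peek()
      if (suf == "+") {
        periodic[[length(periodic) + 1L]] <- c(step = inner, tmin = 1L)
        i <- i + 1L
      } else if (suf == "*") {
        periodic[[length(periodic) + 1L]] <- c(step = inner, tmin = 0L)
        i <- i + 1L
      } else {
        const <- const + inner   # plain grouping
      }
    } else {
      stop("unexpected token '", ch, "' in guard: ", full)
    }
  }
  list(const = const, periodic = periodic)
}

#' Test membership of a spike count in a guard language
#'
#' @param guard an \code{snp_guard} (or its surface string).
#' @param k non-negative spike count (vectorised).
#' @return logical: is the unary string of length \code{k} in the guard's
#'   language? Membership is exact: guard \code{a^c} matches only \code{k == c}.
#' @export
guard_matches <- function(guard, k) {
  guard <- snp_guard(guard)
  vapply(as.integer(k), function(kk) {
    if (kk < 0L) return(FALSE)
    for (term in guard$terms) {
      r <- kk - term$const
      if (r < 0L) next
      np <- length(term$periodic)
      if (np == 0L) {
        if (r == 0L) return(TRUE)
      } else if (np == 1L) {
        p <- term$periodic[[1L]]
        r2 <- r - p[["step"]] * p[["tmin"]]
        if (r2 >= 0L && r2 %% p[["step"]] == 0L) return(TRUE)
      } else {
        # general case: subtract mandatory repetitions, then ask whether the
        # remainder is a non-negative integer combination of the step sizes
        steps <- vapply(term$periodic, `[[`, integer(1), "step")
        r2 <- r - sum(steps * vapply(term$periodic, `[[`, integer(1), "tmin"))
        if (r2 < 0L) next
        reach <- logical(r2 + 1L); reach[1L] <- TRUE
        for (v in seq_len(r2)) {
          for (st in steps) {
            if (st <= v && reach[v + 1L - st]) { reach[v + 1L] <- TRUE; break }
          }
        }
        if (reach[r2 + 1L]) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

#' @export
format.snp_guard <- function(x, ...) {
  paste(vapply(x$terms, function(term) {
    run <- function(k) if (k == 1L) "a" else paste0("a^", k)
    out <- if (term$const > 0L) run(term$const) else ""
    for (p in term$periodic)
      out <- paste0(out, "(", run(p[["step"]]), ")^",
                    if (p[["tmin"]] == 1L) "+" else "*")
    if (!nzchar(out)) "a^0" else out
  }, character(1)), collapse = "|")
}

#' @export
print.snp_guard <- function(x, ...) {
  cat("<guard>", format(x), "\n")
  invisible(x)
}
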