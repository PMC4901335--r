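#' Neuron rules
#'
#' Three rule forms drive a spiking neural P system with self-organization,
#' written here in the field's surface syntax:
#' \itemize{
#'   \item spiking \code{"E/a^c -> a^p; d"} — when the spike count is in
#'     \code{L(E)} and at least \code{c}, consume \code{c} spikes and emit
#'     \code{p} along every *currently existing* outgoing synapse after
#'     \code{d} steps (\code{p = 0}, written \code{lambda}, is a forgetting
#'     rule; during a delay the neuron is closed and incoming spikes are
#'     lost);
#'   \item synapse creation \code{"E/a^c -> +(a^p,{t1,t2,...})"} — create a
#'     synapse from the owner to each listed target and deliver \code{p}
#'     spikes to each (target \code{0} is the environment);
#'   \item synapse deletion \code{"E/a^c -> -(lambda,{t1,...})"} — remove the
#'     owner's synapses to the listed targets (absent edges are skipped).
#' }
#' When \code{E} is omitted it defaults to \code{a^c} (exact-count guard);
#' \code{a} abbreviates \code{a^1} and \code{λ}/\code{lambda} both denote the
#' empty emission.
#'
#' @param text rule in surface syntax.
#' @return an object of class \code{snp_rule} with fields \code{kind}
#'   (\code{"spiking"}, \code{"creation"}, \code{"deletion"}), \code{guard},
#'   \code{consume}, \code{emit}, \code{delay}, \code{targets}.
#' @examples
#' snp_rule("a^5/a^4 -> +(a^3,{lj,lk})")
#' snp_rule("a^3 -> lambda")
#' snp_rule("a -> -(lambda,{0})")
#' @export
snp_rule <- function(text) {
  if (inherits(text, "snp_rule")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  src <- gsub("λ", "lambda", text)
  src <- gsub("−", "-", src)          # unicode minus
  src <- gsub("→", "->", src)         # unicode arrow
  src <- gsub("\\s+", "", src)
  m <- regmatches(src, regexec("^(.*?)->(.*)$", src))[[1]]
  if (length(m) != 3L) stop("rule lacks '->': ", text)
  lhs <- m[2]; rhs <- m[3]

  # left side: "E/a^c" or bare "a^c" (then E = a^c)
  lm <- regmatches(lhs, regexec("^(?:(.*)/)?a(?:\\^([0-9]+))?$", lhs))[[1]]
  if (length(lm) != 3L) stop("malformed rule left side: ", text)
  consume <- if (nzchar(lm[3])) as.integer(lm[3]) else 1L
  guard_txt <- if (nzchar(lm[2])) lm[2] else paste0("a^", consume)
  guard <- snp_guard(guard_txt)

  amount <- function(s) {   # "a^p", "a", or "lambda"
    if (s == "lambda") return(0L)
    am <- regmatches(s, regexec("^a(?:\\^([0-9]+))?$", s))[[1]]
    if (length(am) != 2L) stop("malformed spike amount '", s, "' in rule: ", text)
    if (nzchar(am[2])) as.integer(am[2]) else 1L
  }
  target_set <- function(s) {
    tm <- regmatches(s, regexec("^\\{(.*)\\}$", s))[[1]]
    if (length(tm) != 2L || !nzchar(tm[2]))
      stop("malformed target set in rule: ", text)
    strsplit(tm[2], ",", fixed = TRUE)[[1]]
  }

  if (startsWith(rhs, "+(")) {
    body <- sub("^\\+\\((.*)\\)$", "\\1", rhs)
    if (identical(body, rhs)) stop("malformed creation rule: ", text)
    parts <- regmatches(body, regexec("^([^,]*),(\\{.*\\})$", body))[[1]]
    if (length(parts) != 3L) stop("malformed creation rule: ", text)
    kind <- "creation"; emit <- amount(parts[2]); delay <- 0L
    targets <- target_set(parts[3])
  } else if (startsWith(rhs, "-(")) {
    body <- sub("^-\\((.*)\\)$", "\\1", rhs)
    if (identical(body, rhs)) stop("malformed deletion rule: ", text)
    parts <- regmatches(body, regexec("^([^,]*),(\\{.*\\})$", body))[[1]]
    if (length(parts) != 3L) stop("malformed deletion rule: ", text)
    if (amount(parts[2]) != 0L)
      stop("deletion rules emit nothing (use lambda): ", text)
    kind <- "deletion"; emit <- 0L; delay <- 0L
    targets <- target_set(parts[3])
  } else {
    # spiking: "a^p", "lambda", optionally ";d"
    sm <- regmatches(rhs, regexec("^([^;]*)(?:;([0-9]+))?$", rhs))[[1]]
    if (length(sm) != 3L) stop("malformed spiking rule: ", text)
    kind <- "spiking"; emit <- amount(sm[2])
    delay <- if (nzchar(sm[3])) as.integer(sm[3]) else 0L
    targets <- character(0)
  }
  if (consume < 1L) stop("rules must consume at least one spike: ", text)
  if (emit > consume)
    stop("a rule cannot emit more spikes than it consumes: ", text)
  structure(list(kind = kind, guard = guard, consume = consume, emit = emit,
                 delay = delay, targets = targets),
            class = "snp_rule")
}

#' @export
format.snp_rule <- function(x, ...) {
  lhs <- {
    gtxt <- format(x$guard)
    ctxt <- if (x$consume == 1L) "a" else paste0("a^", x$consume)
    if (identical(gtxt, ctxt)) ctxt else paste0(gtxt, "/", ctxt)
  }
  amt <- function(p) if (p == 0L) "lambda" else if (p == 1L) "a" else paste0("a^", p)
  rhs <- switch(x$kind,
    spiking  = paste0(amt(x$emit), if (x$delay > 0L) paste0(";", x$delay) else ""),
    creation = paste0("+(", amt(x$emit), ",{", paste(x$targets, collapse = ","), "})"),
    deletion = paste0("-(lambda,{", paste(x$targets, collapse = ","), "})"))
  paste(lhs, "->", rhs)
}

#' @export
print.snp_rule <- function(x, ...) {
  cat("<", x$kind, "rule>", format(x), "\n")
  invisible(x)
}
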