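#' Curated test machines
#'
#' A suite of small register machines exercising every instruction form:
#' \describe{
#'   \item{two_add}{deterministic, generates 2 (two increments then halt).}
#'   \item{loop_add}{\code{l0:(ADD(1), l0, lh)} — nondeterministic loop
#'     generating every positive integer.}
#'   \item{even_gen}{nondeterministic generator of the even numbers.}
#'   \item{even_acc}{deterministic acceptor of the even numbers (odd inputs
#'     diverge).}
#'   \item{add_fun}{function machine computing \code{x + y} (drains
#'     registers 1 and 2 into output register 3).}
#'   \item{proj_fun}{function machine computing \code{f(x, y) = x}.}
#'   \item{double_sub}{acceptor with two SUB instructions on register 1
#'     (exercises the cross-module interference absorbers).}
#' }
#'
#' @return named list of \code{\link{rm_machine}}s, each with attribute
#'   \code{"out_register"} where relevant.
#' @export
sample_machines <- function() {
  M <- function(...) rm_machine(list(...))
  add <- function(r, j, k = j) list(op = "ADD", reg = r, next1 = j, next2 = k)
  sub <- function(r, j, k) list(op = "SUB", reg = r, next1 = j, next2 = k)
  halt <- list(op = "HALT")

  out <- list(
    two_add = M(l0 = add(1, "l1"), l1 = add(1, "lh"), lh = halt),
    loop_add = M(l0 = add(1, "l0", "lh"), lh = halt),
    even_gen = M(l0 = add(1, "l1"), l1 = add(1, "l0", "lh"), lh = halt),
    even_acc = M(l0 = sub(1, "l1", "lh"), l1 = sub(1, "l0", "l2"),
                 l2 = add(2, "l2"), lh = halt),
    add_fun = M(l0 = sub(1, "l1", "l2"), l1 = add(3, "l0"),
                l2 = sub(2, "l3", "lh"), l3 = add(3, "l2"), lh = halt),
    proj_fun = M(l0 = sub(1, "l1", "lh"), l1 = add(3, "l0"), lh = halt),
    double_sub = M(l0 = sub(1, "l1", "lh"), l1 = sub(1, "l0", "l2"),
                   l2 = add(2, "l2"), lh = halt))
  attr(out$add_fun, "out_register") <- 3L
  attr(out$proj_fun, "out_register") <- 3L
  out
}

#' Input spike trains
#'
#' Encodes numbers as the binary spike trains read by the INPUT modules:
#' acceptor mode reads \code{n} as \code{1 0^(n-1) 1} (two spikes \code{n}
#' steps apart); function mode reads \code{k} arguments as
#' \code{1 0^(n1-1) 1 0^(n2-1) 1 ...} (\code{k + 1} spikes, consecutive gaps
#' equal to the arguments).
#'
#' @param mode \code{"acceptor"} or \code{"function"}.
#' @param numbers the encoded number(s); all must be >= 1.
#' @param offset clock step of the first spike (default 1, so trace step
#'   \code{t} matches the narrated timelines).
#' @return sorted integer vector of spike steps.
#' @examples
#' spike_train("acceptor", 4)        # c(1, 5)
#' spike_train("function", c(2, 3))  # c(1, 3, 6)
#' @export
spike_train <- function(mode = c("acceptor", "function"), numbers,
                        offset = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(numbers) >= 1L, all(numbers >= 1L))
  if (mode == "acceptor" && length(numbers) != 1L)
    stop("acceptor mode encodes a single number")
  as.integer(offset + cumsum(c(0L, as.integer(numbers))))
}
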