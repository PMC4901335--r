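#' Neurons and systems
#'
#' @description
#' \code{snp_neuron} bundles a neuron id, its initial spike load and its
#' (possibly empty, order-preserving) rule list. \code{snp_system} assembles
#' neurons into a spiking neural P system with self-organization: the synapse
#' set starts empty and is rebuilt at run time by the neurons' creation and
#' deletion rules. The environment is the reserved target label \code{"0"}.
#'
#' @param id unique neuron label (must not be \code{"0"}).
#' @param spikes initial spike count.
#' @param rules character vector of rule strings or list of \code{snp_rule}s.
#' @return \code{snp_neuron}: an object of class \code{snp_neuron}.
#' @export
snp_neuron <- function(id, spikes = 0L, rules = character(0)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id), spikes >= 0)
  if (id == "0") stop("neuron id '0' is reserved for the environment")
  rules <- lapply(rules, snp_rule)
  structure(list(id = id, spikes = as.integer(spikes), rules = rules),
            class = "snp_neuron")
}

#' @rdname snp_neuron
#' @param neurons list of \code{snp_neuron}s.
#' @param input,output optional ids of the input / output neuron.
#' @return \code{snp_system}: an object of class \code{snp_system}.
#' @examples
#' sys <- snp_system(list(
#'   snp_neuron("n1", 6, c("a^6/a^5 -> +(a^2,{n2})", "a -> -(lambda,{n2})")),
#'   snp_neuron("n2", 0, "a^2 -> lambda")))
#' snp_run(sys)$halted
#' @export
snp_system <- function(neurons, input = NULL, output = NULL) {
  stopifnot(is.list(neurons), length(neurons) >= 1L,
            all(vapply(neurons, inherits, logical(1), "snp_neuron")))
  ids <- vapply(neurons, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate neuron ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(neurons) <- ids
  for (nr in neurons) {
    for (rl in nr$rules) {
      if (rl$kind %in% c("creation", "deletion")) {
        if (!length(rl$targets)) stop("empty target set in neuron ", nr$id)
        if (nr$id %in% rl$targets)
          stop("neuron ", nr$id, " targets itself in a ", rl$kind, " rule")
        bad <- setdiff(rl$targets, c(ids, "0"))
        if (length(bad))
          stop("neuron ", nr$id, " targets unknown neuron(s): ",
               paste(bad, collapse = ", "))
      }
    }
  }
  if (!is.null(input) && !input %in% ids) stop("unknown input neuron: ", input)
  if (!is.null(output) && !output %in% ids) stop("unknown output neuron: ", output)
  structure(list(neurons = neurons, input = input, output = output),
            class = "snp_system")
}

#' @export
print.snp_system <- function(x, ...) {
  nrules <- sum(vapply(x$neurons, function(n) length(n$rules), integer(1)))
  cat("SN P system with self-organization:", length(x$neurons), "neurons,",
      nrules, "rules\n")
  if (!is.null(x$input))  cat("  input neuron: ", x$input, "\n")
  if (!is.null(x$output)) cat("  output neuron:", x$output, "\n")
  invisible(x)
}

#' Read / write a system description file
#'
#' JSON with fields \code{neurons} (objects with \code{id}, \code{spikes},
#' \code{rules} as surface-syntax strings), and optional \code{input} /
#' \code{output}. Parsing then re-serializing is the identity on the
#' canonical rule form.
#'
#' @param path file path.
#' @return \code{read_snp_system}: an \code{snp_system}.
#' @export
read_snp_system <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$neurons)) stop("system file lacks a 'neurons' field: ", path)
  neurons <- lapply(doc$neurons, function(nd) {
    snp_neuron(nd$id,
               if (is.null(nd$spikes)) 0L else nd$spikes,
               vapply(nd$rules %||% list(), as.character, character(1)))
  })
  as_id <- function(x) if (is.null(x)) NULL else as.character(x)
  snp_system(neurons, input = as_id(doc$input), output = as_id(doc$output))
}

#' @rdname read_snp_system
#' @param system an \code{snp_system}.
#' @return \code{write_snp_system}: \code{path}, invisibly.
#' @export
write_snp_system <- function(system, path) {
  doc <- list(
    neurons = lapply(unname(system$neurons), function(nr) list(
      id = nr$id, spikes = nr$spikes,
      rules = vapply(nr$rules, format, character(1)))),
    input = system$input, output = system$output)
  doc <- Filter(Negate(is.null), doc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
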