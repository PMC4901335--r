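#' Trace and topology export
#'
#' \code{write_trace_tsv} writes the per-step audit log of a recorded run
#' (one row per applied rule: step, neuron, rule, spikes consumed / emitted,
#' targets). \code{trace_dot} renders the synapse set of a configuration as
#' a DOT digraph (the environment appears as node \code{"0"}), suitable for
#' animating the self-organizing topology step by step.
#'
#' @param run an \code{\link{snp_run}} result with \code{record = TRUE}.
#' @param path output file.
#' @param seed seed recorded in the trace header (NA when none was used).
#' @return the path, invisibly.
#' @export
write_trace_tsv <- function(run, path, seed = NA) {
  stopifnot(inherits(run, "snp_run"))
  if (is.null(run$trace)) stop("run was not recorded; use snp_run(record = TRUE)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# snpso trace; seed=", seed), con)
  utils::write.table(run$trace, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @param config an \code{snp_config} (e.g. \code{run$config}, or any
#'   configuration produced by \code{\link{snp_step}}).
#' @param name graph name.
#' @return \code{trace_dot}: character vector of DOT lines.
#' @export
trace_dot <- function(config, name = "syn_t") {
  edges <- snp_synapses(config)
  sim <- config$sim
  lines <- c(sprintf("digraph %s {", name),
             "  node [shape=circle];",
             sprintf('  "%s" [label="%s\\n%d"];', sim$ids, sim$ids,
                     config$counts),
             if (nrow(edges))
               sprintf('  "%s" -> "%s";', edges[, "from"], edges[, "to"]),
             "}")
  lines
}
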