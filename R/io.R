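#' Read and write trace tables as TSV
#'
#' Traces are stored long-format with columns `molecule_id`, `frame`,
#' `time_s`, `I_D`, `I_A` — the same schema whether traces come from the
#' simulator or from movie extraction. A comment header records the
#' package version and, when supplied, the seed and a configuration hash,
#' so any output can be traced back to the run that produced it.
#'
#' @param traces Trace tibble.
#' @param path File path.
#' @param seed,config Optional provenance recorded in the header.
#' @return `write_traces()` returns `path` invisibly; `read_traces()` a
#'   tibble.
#' @export
write_traces <- function(traces, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  write.table(traces, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  as_tibble(read.delim(path, comment.char = "#"))
}

#' Write ground truth, events or other per-molecule tables as TSV
#'
#' @param x Tibble (list columns such as `state_path` are dropped).
#' @param path File path.
#' @param seed,config Optional provenance recorded in the header.
#' @export
write_table_tsv <- function(x, path, seed = NULL, config = NULL) {
  x <- x[, !vapply(x, is.list, TRUE), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a mixture fit (or dwell fit) as JSON
#'
#' @param fit A `fret_mixture` or `dwell_fit`.
#' @param path File path.
#' @param seed,config Optional provenance fields.
#' @export
write_fit_json <- function(fit, path, seed = NULL, config = NULL) {
  payload <- if (inherits(fit, "fret_mixture")) {
    list(k = fit$k, means = fit$means, sds = fit$sds, weights = fit$weights,
         loglik = fit$loglik, bic = as.list(fit$bic), n = fit$n)
  } else if (inherits(fit, "dwell_fit")) {
    list(model = fit$model, rates = fit$rates, rate_se = fit$rate_se,
         amplitudes = fit$amplitudes, aic = as.list(fit$aic),
         mle_rate = fit$mle_rate, n = fit$n)
  } else {
    abort("unsupported fit object")
  }
  payload$provenance <- list(
    package_version = as.character(utils::packageVersion("smfret")),
    seed = seed, config_hash = config_hash(config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

provenance_header <- function(seed = NULL, config = NULL) {
  c(paste0("# smfret ", utils::packageVersion("smfret")),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(config)) paste0("# config_hash: ", config_hash(config)))
}

config_hash <- function(config) {
  if (is.null(config)) return(NULL)
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; avoids a digest dependency
  h <- 7
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
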