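#' Read / write headerless numeric matrices as TSV
#'
#' Matrices (SC, covariate maps, BOLD) travel as tab-separated text with no
#' header, one region per row. Malformed rows surface as parse errors with
#' the offending line number; round trips are value-exact to about 1e-15
#' (17 significant digits are written).
#'
#' @param path File path.
#' @return `load_matrix()`: a numeric matrix.
#' @export
load_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lens <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    abort(sprintf("parse error in %s: line %d has %d fields, expected %d",
                  path, bad, lens[bad], lens[1]))
  }
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' @rdname load_matrix
#' @param m Numeric matrix to write.
#' @export
save_matrix <- function(m, path) {
  utils::write.table(format(m, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write BOLD series (TSV + YAML sidecar)
#'
#' The regions x time matrix goes to `<path>` and the acquisition metadata
#' (TR, frame count, config hash) to `<path>.meta.yaml`.
#'
#' @param path File path for the TSV matrix.
#' @param config_hash Optional config hash recorded in the sidecar.
#' @return `load_bold()`: a `"bold_series"`.
#' @export
load_bold <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  m <- load_matrix(path)
  if (ncol(m) != meta$n_frames) {
    abort(sprintf("BOLD matrix has %d frames but sidecar says %d",
                  ncol(m), meta$n_frames))
  }
  structure(list(bold = m, tr_s = meta$tr_s, n_frames = meta$n_frames),
            class = "bold_series")
}

#' @rdname load_bold
#' @param bold A `"bold_series"`.
#' @export
save_bold <- function(bold, path, config_hash = NULL) {
  save_matrix(bold$bold, path)
  yaml::write_yaml(list(tr_s = bold$tr_s, n_frames = bold$n_frames,
                        config_hash = config_hash),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read / write run configurations as YAML
#'
#' `load_config()` revalidates through [run_config()], so unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return `load_config()`: a `"run_config"`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @rdname load_config
#' @param config A [run_config()].
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Append a record to a JSONL ledger file
#'
#' One JSON object per line; numbers are written unboxed.
#'
#' @param path Ledger file path (created if absent).
#' @param record Named list.
#' @return The path, invisibly.
#' @export
ledger_append <- function(path, record) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}
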