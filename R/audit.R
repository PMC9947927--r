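# Leakage audit instrumentation.
#
# Cross-validation with per-fold feature selection is only honest if no
# held-out row ever reaches selection, scaler fitting or model training for
# its fold. Any fitting stage calls `audit_record(stage, ids)`; when an audit
# collector is installed (tests, instrumented runs) the sample ids the stage
# actually saw are logged under the current audit context, so a test can
# assert the logged ids are disjoint from the held-out rows.

#' Enable the leakage audit collector
#'
#' Installs a fresh collector environment; subsequent fitting operations
#' record the sample ids they see, tagged with the current context set via
#' [audit_context()].
#'
#' @return the collector environment, invisibly.
#' @export
audit_enable <- function() {
  env <- new.env(parent = emptyenv())
  env$log <- list()
  env$context <- "global"
  options(subloc2l.audit = env)
  invisible(env)
}

#' Disable the leakage audit collector
#' @export
audit_disable <- function() {
  options(subloc2l.audit = NULL)
  invisible(NULL)
}

#' Set the audit context label (e.g. "fold_3")
#' @param label character context tag under which subsequent fitting stages
#'   are logged.
#' @export
audit_context <- function(label) {
  env <- getOption("subloc2l.audit")
  if (!is.null(env)) env$context <- label
  invisible(label)
}

audit_record <- function(stage, ids) {
  env <- getOption("subloc2l.audit")
  if (is.null(env)) return(invisible(NULL))
  key <- env$context
  entry <- list(stage = stage, ids = as.character(ids))
  env$log[[key]] <- c(env$log[[key]], list(entry))
  invisible(NULL)
}

#' Retrieve the audit log
#'
#' @return named list: per context, a list of (stage, ids) records.
#' @export
audit_log <- function() {
  env <- getOption("subloc2l.audit")
  if (is.null(env)) stop("audit collector is not enabled")
  env$log
}
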