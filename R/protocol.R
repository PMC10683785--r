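#' Platform-translation trial protocols
#'
#' A protocol is an ordered table of platform-translation trials, one row per
#' trial, with the translation direction and the label under which the trial
#' enters analysis. The default protocol is the 34-trial sequence used for
#' perturbation-evoked potential (PEP) studies: a long habituation run of
#' posterior translations with anterior "catch" trials interspersed at fixed
#' positions. Trial 1 (the very first, unannounced translation) and the five
#' anterior catch trials are analyzed as *unpredictable*; trials 2-5 are
#' excluded from analysis as habituation trials; the remaining posterior
#' translations are *predictable*.
#'
#' @name protocol
NULL

PEP_DIRECTIONS <- c("posterior", "anterior")
PEP_LABELS <- c("unpredictable", "predictable", "excluded")

#' Construct a trial protocol
#'
#' @param index Integer trial numbers (1-based, unique).
#' @param direction Character vector, `"posterior"` or `"anterior"`.
#' @param analysis_label Character vector, one of `"unpredictable"`,
#'   `"predictable"`, `"excluded"`.
#' @param name Short identifier for the protocol.
#'
#' @return A tibble of class `pep_protocol` with columns `index`, `direction`,
#'   `analysis_label` and attribute `name`.
#' @export
pep_protocol <- function(index, direction, analysis_label, name = "custom") {
  index <- as.integer(index)
  if (length(index) == 0L) stop("protocol must contain at least one trial")
  if (anyDuplicated(index)) stop("trial indices must be unique")
  direction <- match.arg(direction, PEP_DIRECTIONS, several.ok = TRUE)
  analysis_label <- match.arg(analysis_label, PEP_LABELS, several.ok = TRUE)
  if (length(direction) != length(index) || length(analysis_label) != length(index)) {
    stop("index, direction and analysis_label must have equal length")
  }
  if (any(analysis_label == "excluded" & direction != "posterior")) {
    stop("only posterior trials may carry the 'excluded' label")
  }
  out <- tibble::tibble(index = index, direction = direction,
                        analysis_label = analysis_label)
  out <- out[order(out$index), ]
  attr(out, "name") <- name
  class(out) <- c("pep_protocol", class(out))
  out
}

#' The default 34-trial perturbation protocol
#'
#' Returns the fixed sequence: anterior translations at trials
#' 16, 22, 28, 29 and 34, posterior everywhere else; analysis labels
#' `unpredictable` for trials 1, 16, 22, 28, 29, 34, `excluded` for trials
#' 2-5, and `predictable` for the remaining posterior trials. The sequence
#' contains 29 posterior and 5 anterior translations, and 6 unpredictable,
#' 24 predictable and 4 excluded trials.
#'
#' @return A [pep_protocol] with 34 trials.
#' @examples
#' prot <- build_default_protocol()
#' condition_counts(prot)
#' @export
build_default_protocol <- function() {
  idx <- 1:34
  anterior <- c(16L, 22L, 28L, 29L, 34L)
  direction <- ifelse(idx %in% anterior, "anterior", "posterior")
  label <- rep("predictable", 34L)
  label[c(1L, anterior)] <- "unpredictable"
  label[2:5] <- "excluded"
  pep_protocol(idx, direction, label, name = "default-34")
}

#' Tally trials by analysis label
#'
#' @param protocol A [pep_protocol].
#' @return Named integer vector with counts for `unpredictable`,
#'   `predictable` and `excluded`; the counts sum to the number of trials.
#' @export
condition_counts <- function(protocol) {
  stopifnot(inherits(protocol, "pep_protocol"))
  if (nrow(protocol) == 0L) stop("protocol is empty")
  counts <- vapply(PEP_LABELS, function(l) sum(protocol$analysis_label == l),
                   integer(1))
  counts
}

#' Trial indices retained for analysis (label != excluded)
#' @param protocol A [pep_protocol].
#' @return Integer vector of trial indices.
#' @export
analyzable_trials <- function(protocol) {
  protocol$index[protocol$analysis_label != "excluded"]
}

#' Read / write a protocol as a plain-text table
#'
#' The on-disk form is a tab-separated table with columns
#' `index`, `direction`, `analysis_label`.
#'
#' @param path File path.
#' @param protocol A [pep_protocol].
#' @param name Protocol name to attach on read.
#' @return `read_protocol` returns a [pep_protocol]; `write_protocol`
#'   invisibly returns `path`.
#' @export
read_protocol <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pep_protocol(tab$index, tab$direction, tab$analysis_label, name = name)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "pep_protocol"))
  utils::write.table(as.data.frame(protocol), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pep_protocol <- function(x, ...) {
  cat(sprintf("<pep_protocol '%s'> %d trials (%d posterior, %d anterior)\n",
              attr(x, "name") %||% "?", nrow(x),
              sum(x$direction == "posterior"), sum(x$direction == "anterior")))
  cc <- condition_counts(x)
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", names(cc), cc), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
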