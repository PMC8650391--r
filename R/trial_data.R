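# Data model for composite-endpoint trial datasets.
#
# Columns in an input CSV are bound strictly by position: subject ID,
# treatment arm (0/1), the continuous outcome(s), the binary outcome (if
# present), then one baseline column per continuous outcome.  Variables are
# identified by column order, never by name.

#' Describe the structure of a composite responder endpoint
#'
#' A composite responder endpoint has one or two continuous components, each
#' with a responder threshold, and optionally one binary component.  A
#' subject responds overall when every continuous reading is below its
#' threshold and the binary component (when present) equals 1.  Response is
#' always "below threshold": endpoints where improvement is an increase
#' should be sign-flipped before analysis.
#'
#' @param n_cont Number of continuous components, 1 or 2.
#' @param has_binary Whether a binary component is present.
#' @param thresholds Numeric vector of length `n_cont`: responder threshold
#'   per continuous component, in the units of the clinical scale (e.g. a
#'   SLEDAI change threshold of -4, a PGA change threshold of 0.3).
#' @param inclusive Logical vector of length `n_cont` (recycled from length
#'   1): whether a reading exactly at the threshold counts as a response in
#'   the observed classification.  Model-based probabilities are unaffected
#'   (the boundary has probability zero under a continuous model).
#' @return An object of class `endpoint_spec`.
#' @examples
#' endpoint_spec(2, TRUE, thresholds = c(-4, 0.3), inclusive = c(TRUE, FALSE))
#' @export
endpoint_spec <- function(n_cont, has_binary, thresholds,
                          inclusive = FALSE) {
  if (!n_cont %in% c(1L, 2L))
    stop("n_cont must be 1 or 2")
  n_cont <- as.integer(n_cont)
  stopifnot(is.logical(has_binary), length(has_binary) == 1L)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != n_cont)
    stop("need exactly ", n_cont, " threshold(s), got ", length(thresholds))
  if (any(!is.finite(thresholds)))
    stop("thresholds must be finite")
  inclusive <- rep_len(as.logical(inclusive), n_cont)
  structure(list(n_cont = n_cont, has_binary = has_binary,
                 thresholds = thresholds, inclusive = inclusive),
            class = "endpoint_spec")
}

#' @export
print.endpoint_spec <- function(x, ...) {
  cat(sprintf("Composite responder endpoint: %d continuous + %d binary component(s)\n",
              x$n_cont, as.integer(x$has_binary)))
  for (j in seq_len(x$n_cont))
    cat(sprintf("  continuous %d: response if value %s %g\n", j,
                if (x$inclusive[j]) "<=" else "<", x$thresholds[j]))
  if (x$has_binary) cat("  binary: response if value == 1\n")
  invisible(x)
}

n_latent <- function(spec) spec$n_cont + as.integer(spec$has_binary)

#' Construct a validated trial dataset
#'
#' @param subject_id Vector of subject identifiers (opaque).
#' @param arm Treatment indicator, 0 = control, 1 = treatment.
#' @param y_cont Numeric matrix (or vector when `n_cont = 1`) of continuous
#'   outcomes, one column per component.
#' @param y_bin Binary outcome in \{0, 1\}, or `NULL` when the endpoint has
#'   no binary component.
#' @param baselines Numeric matrix (or vector) of baseline values, same
#'   shape as `y_cont`.
#' @param spec An [endpoint_spec()].
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(subject_id, arm, y_cont, y_bin, baselines, spec) {
  stopifnot(inherits(spec, "endpoint_spec"))
  y_cont <- as.matrix(y_cont)
  baselines <- as.matrix(baselines)
  n <- length(subject_id)
  if (length(arm) != n || nrow(y_cont) != n || nrow(baselines) != n)
    stop("subject_id, arm, y_cont and baselines must have the same number of rows")
  if (ncol(y_cont) != spec$n_cont)
    stop("y_cont has ", ncol(y_cont), " column(s); endpoint declares ", spec$n_cont)
  if (ncol(baselines) != spec$n_cont)
    stop("baselines must have one column per continuous component")
  if (spec$has_binary) {
    if (is.null(y_bin) || length(y_bin) != n)
      stop("y_bin must be supplied with one value per subject")
  } else if (!is.null(y_bin)) {
    stop("endpoint has no binary component but y_bin was supplied")
  }
  miss <- !stats::complete.cases(arm, y_cont, baselines,
                                 if (spec$has_binary) y_bin else rep(0, n))
  if (any(miss))
    stop("missing values in rows: ", paste(which(miss), collapse = ", "),
         ". Rows with missing data must be resolved before analysis.")
  if (!all(arm %in% c(0, 1)))
    stop("arm must be coded 0/1; offending rows: ",
         paste(which(!arm %in% c(0, 1)), collapse = ", "))
  if (spec$has_binary && !all(y_bin %in% c(0, 1)))
    stop("binary outcome must be coded 0/1; offending rows: ",
         paste(which(!y_bin %in% c(0, 1)), collapse = ", "))
  structure(list(subject_id = subject_id,
                 arm = as.integer(arm),
                 y_cont = unname(y_cont),
                 y_bin = if (spec$has_binary) as.integer(y_bin) else NULL,
                 baselines = unname(baselines),
                 spec = spec),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("Trial dataset: %d subjects (%d control, %d treatment), %d continuous + %d binary component(s)\n",
              length(x$arm), sum(x$arm == 0), sum(x$arm == 1),
              x$spec$n_cont, as.integer(x$spec$has_binary)))
  invisible(x)
}

#' Read a composite-endpoint trial dataset from CSV
#'
#' Columns are identified strictly by position: subject ID, arm, the
#' `n_cont` continuous outcome(s), the binary outcome when the endpoint has
#' one, then `n_cont` baseline columns (one per continuous outcome).  A
#' file with the wrong number of columns is rejected with a message naming
#' the expected layout.
#'
#' @param path Path to a comma-delimited file, decimal point notation.
#' @param spec An [endpoint_spec()].
#' @param has_header Whether the first row is a header (discarded; names are
#'   never used).
#' @return A validated [trial_dataset()].
#' @export
read_dataset <- function(path, spec, has_header = TRUE) {
  stopifnot(inherits(spec, "endpoint_spec"))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE, strip.white = TRUE)
  expected <- 2L + 2L * spec$n_cont + as.integer(spec$has_binary)
  layout <- paste(c("id", "arm",
                    paste0("y", seq_len(spec$n_cont)),
                    if (spec$has_binary) "ybin",
                    paste0("base", seq_len(spec$n_cont))), collapse = ", ")
  if (ncol(df) != expected)
    stop("expected ", expected, " columns (", layout, "), found ", ncol(df))
  num <- df[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (any(is.na(v2) & !is.na(v) & nzchar(trimws(v))))
        stop("non-numeric values in column ", j + 1L,
             " (is the header flag set correctly?)")
      num[[j]] <- v2
    }
  }
  cont_idx <- seq_len(spec$n_cont)
  bin_idx <- if (spec$has_binary) spec$n_cont + 2L else NULL  # within num (offset by arm)
  base_idx <- spec$n_cont + 1L + as.integer(spec$has_binary) + cont_idx
  trial_dataset(subject_id = df[[1L]],
                arm = num[[1L]],
                y_cont = as.matrix(num[, 1L + cont_idx, drop = FALSE]),
                y_bin = if (spec$has_binary) num[[bin_idx]] else NULL,
                baselines = as.matrix(num[, base_idx, drop = FALSE]),
                spec = spec)
}

#' Write a validated dataset back to delimited text (audit echo)
#'
#' @param data A [trial_dataset()].
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, sep = "\t") {
  stopifnot(inherits(data, "trial_dataset"))
  spec <- data$spec
  out <- data.frame(id = data$subject_id, arm = data$arm)
  for (j in seq_len(spec$n_cont)) out[[paste0("y", j)]] <- data$y_cont[, j]
  if (spec$has_binary) out$ybin <- data$y_bin
  for (j in seq_len(spec$n_cont)) out[[paste0("base", j)]] <- data$baselines[, j]
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse a composite endpoint to the observed responder indicator
#'
#' A subject is a responder when every continuous component is below its
#' threshold (at it, when the component is flagged inclusive) and the binary
#' component, when present, equals 1.
#'
#' @param data A [trial_dataset()].
#' @param spec An [endpoint_spec()]; defaults to the one carried by `data`.
#' @return Integer vector of 0/1 responder indicators, one per subject.
#' @export
classify_responders <- function(data, spec = data$spec) {
  stopifnot(inherits(data, "trial_dataset"), inherits(spec, "endpoint_spec"))
  resp <- rep(TRUE, length(data$arm))
  for (j in seq_len(spec$n_cont)) {
    yj <- data$y_cont[, j]
    resp <- resp & if (spec$inclusive[j]) yj <= spec$thresholds[j]
                   else yj < spec$thresholds[j]
  }
  if (spec$has_binary) resp <- resp & data$y_bin == 1L
  as.integer(resp)
}

# Per-component responder indicators (used for summaries and calibration).
component_responders <- function(data, spec = data$spec) {
  cols <- list()
  for (j in seq_len(spec$n_cont)) {
    yj <- data$y_cont[, j]
    cols[[paste0("cont", j)]] <- as.integer(
      if (spec$inclusive[j]) yj <= spec$thresholds[j] else yj < spec$thresholds[j])
  }
  if (spec$has_binary) cols$binary <- data$y_bin
  cols$overall <- classify_responders(data, spec)
  as.data.frame(cols)
}
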