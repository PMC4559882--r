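#' Structured error helpers
#'
#' All user-facing failures are signalled as classed conditions so that
#' callers (and the command-line driver) can map them to exit codes:
#' validation problems are `qpcr_validation_error`, degenerate statistics
#' are `qpcr_degenerate_error`.
#' @noRd
stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("qpcr_validation_error", "qpcr_error")))
}

#' @noRd
stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("qpcr_degenerate_error", "qpcr_error")))
}

#' Build a cohort of qRT-PCR triplicates
#'
#' A cohort is a long-format table with one row per (sample, assay)
#' triplicate. Replicate cycle-threshold (Ct) values are summarised by
#' their sample mean `x` and sample standard deviation `s` (n-1
#' denominator), the two quantities every downstream stage works with.
#'
#' @param records data.frame with columns `sample_id`, `class_label`
#'   (one of `"target"`, `"versus"`, `"unknown"`), `session` (character,
#'   may be `NA`), `assay`, and replicate columns `rep1`, `rep2`, `rep3`
#'   (`rep3` may be `NA`; at least two finite replicates are required
#'   per row, since a sample SD is undefined otherwise).
#' @param priors named numeric of length 2, `c(target = , versus = )`,
#'   strictly positive prior presentation probabilities summing to 1.
#' @return An object of class `qpcr_cohort`: the records with derived
#'   columns `x` (triplicate mean), `s` (triplicate SD) and `n_rep`,
#'   plus attributes `assays` (ordered assay names) and `priors`.
#' @export
qpcr_cohort <- function(records,
                        priors = c(target = 0.5, versus = 0.5)) {
  required <- c("sample_id", "class_label", "session", "assay",
                "rep1", "rep2", "rep3")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop_validation("cohort records lack column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  if (!all(records$class_label %in% c("target", "versus", "unknown"))) {
    stop_validation("class_label must be one of 'target', 'versus', 'unknown'")
  }
  key <- paste(records$sample_id, records$assay, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE]
    stop_validation("duplicate (sample_id, assay) pair(s): %s",
                    paste(unique(paste0(dup$sample_id, "/", dup$assay)),
                          collapse = ", "))
  }
  if (length(priors) != 2 || any(!is.finite(priors)) || any(priors <= 0)) {
    stop_validation("priors must be two strictly positive probabilities")
  }
  priors <- priors / sum(priors)
  names(priors) <- c("target", "versus")

  reps <- as.matrix(records[, c("rep1", "rep2", "rep3")])
  storage.mode(reps) <- "double"
  if (any(is.infinite(reps), na.rm = TRUE)) {
    stop_validation("replicate values must be finite")
  }
  n_rep <- rowSums(is.finite(reps))
  if (any(n_rep < 2)) {
    bad <- records$sample_id[n_rep < 2]
    stop_validation("rows with fewer than 2 usable replicates: %s",
                    paste(unique(bad), collapse = ", "))
  }
  records$n_rep <- as.integer(n_rep)
  records$x <- rowMeans(reps, na.rm = TRUE)
  records$s <- apply(reps, 1L, stats::sd, na.rm = TRUE)

  structure(as.data.frame(records, stringsAsFactors = FALSE),
            assays = unique(records$assay),
            priors = priors,
            class = c("qpcr_cohort", "data.frame"))
}

#' @export
print.qpcr_cohort <- function(x, ...) {
  cat(sprintf("qpcr_cohort: %d triplicates, %d samples, assays: %s\n",
              nrow(x), length(unique(x$sample_id)),
              paste(attr(x, "assays"), collapse = ", ")))
  tab <- table(x$class_label[!duplicated(x$sample_id)])
  cat("  samples per class:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read a triplicate cohort from a TSV file
#'
#' The native schema is long format (tab-separated, header mandatory):
#' `sample_id, class, session, assay, rep1, rep2, rep3`, with `"NA"` as
#' the only missing-value token and plain decimal points. Class labels
#' in files are free strings mapped onto the internal
#' `{target, versus}` dichotomy through `class_map` (for the lung-tumor
#' study this is `c(ADC = "target", SQC = "versus")`); unmapped labels
#' become `"unknown"`. A documented alternate wide layout (one row per
#' sample, replicate columns named `<assay>_1 .. <assay>_3`) is
#' accepted with `format = "wide"`.
#'
#' Rows whose replicate cells leave fewer than two usable values are
#' rejected, not silently dropped: they are reported in the `rejected`
#' attribute of the returned cohort.
#'
#' @param path path to the TSV file.
#' @param class_map named character vector mapping file labels to
#'   `"target"`/`"versus"`.
#' @param priors prior class probabilities, see [qpcr_cohort()].
#' @param format `"long"` (default) or `"wide"`.
#' @param assays for `format = "wide"`, the assay names whose replicate
#'   columns to read; default: inferred from `_1` column suffixes.
#' @return A [qpcr_cohort()] with attribute `rejected` (data.frame of
#'   rejected rows and reasons; zero rows when none).
#' @export
read_cohort <- function(path,
                        class_map = c(ADC = "target", SQC = "versus"),
                        priors = c(target = 0.5, versus = 0.5),
                        format = c("long", "wide"),
                        assays = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           na.strings = "NA", quote = "",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (format == "wide") {
    raw <- wide_to_long(raw, assays)
  }
  required <- c("sample_id", "class", "session", "assay",
                "rep1", "rep2", "rep3")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_validation("%s: header lacks column(s): %s", path,
                    paste(missing_cols, collapse = ", "))
  }

  for (col in c("rep1", "rep2", "rep3")) {
    cell <- raw[[col]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad) > 0) {
      stop_validation("%s: malformed numeric cell at row %d, column %s: '%s'",
                      path, bad[1], col, cell[bad[1]])
    }
    raw[[col]] <- num
  }

  mapped <- unname(class_map[raw$class])
  mapped[is.na(mapped)] <- "unknown"
  records <- data.frame(sample_id = raw$sample_id,
                        class_label = mapped,
                        session = raw$session,
                        assay = raw$assay,
                        rep1 = raw$rep1, rep2 = raw$rep2, rep3 = raw$rep3,
                        stringsAsFactors = FALSE)

  usable <- rowSums(is.finite(as.matrix(records[, c("rep1", "rep2", "rep3")])))
  rejected <- records[usable < 2, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- "fewer than 2 usable replicates"
  } else {
    rejected$reason <- character(0)
  }
  cohort <- qpcr_cohort(records[usable >= 2, , drop = FALSE], priors = priors)
  attr(cohort, "rejected") <- rejected
  cohort
}

# Wide layout: sample_id, class, session, then <assay>_1..<assay>_3.
#' @noRd
wide_to_long <- function(raw, assays = NULL) {
  if (is.null(assays)) {
    suffixed <- grep("_1$", names(raw), value = TRUE)
    assays <- sub("_1$", "", suffixed)
  }
  if (length(assays) == 0) {
    stop_validation("wide layout: no '<assay>_1' replicate columns found")
  }
  if (!"session" %in% names(raw)) raw$session <- NA_character_
  blocks <- lapply(assays, function(a) {
    cols <- paste0(a, "_", 1:3)
    present <- cols %in% names(raw)
    if (!any(present[1:2])) {
      stop_validation("wide layout: assay '%s' lacks replicate columns", a)
    }
    get <- function(i) if (present[i]) raw[[cols[i]]] else NA_character_
    data.frame(sample_id = raw$sample_id, class = raw$class,
               session = raw$session, assay = a,
               rep1 = get(1), rep2 = get(2), rep3 = get(3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, blocks)
}

#' Write a cohort back to the long-format TSV schema
#'
#' @param cohort a [qpcr_cohort()].
#' @param path output file path.
#' @param class_map named character vector mapping the internal labels
#'   back to file labels (inverse of the `read_cohort()` mapping).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path,
                         class_map = c(target = "ADC", versus = "SQC")) {
  out <- data.frame(sample_id = cohort$sample_id,
                    class = ifelse(cohort$class_label %in% names(class_map),
                                   unname(class_map[cohort$class_label]),
                                   cohort$class_label),
                    session = cohort$session,
                    assay = cohort$assay,
                    rep1 = cohort$rep1, rep2 = cohort$rep2, rep3 = cohort$rep3,
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_validation("cannot write: %s", path)
  invisible(path)
}

#' Write a machine-readable analysis report
#'
#' Serialises any report object (fitted models, QC summaries, confusion
#' matrices, or plain nested lists of scalars) to a JSON key-value
#' document that round-trips exactly: `read_report(write_report(x))`
#' recovers `x`'s values. Objects with an `as_report()` method are
#' converted first.
#'
#' @param x report object or nested list of scalars/vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  rep <- as_report(x)
  ok <- tryCatch({
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_validation("cannot write report: %s", path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Convert an object to its plain key-value report form
#'
#' @param x object to convert.
#' @param ... passed to methods.
#' @return A nested list of scalars suitable for [write_report()].
#' @export
as_report <- function(x, ...) UseMethod("as_report")

#' @export
as_report.default <- function(x, ...) x

#' @export
as_report.list <- function(x, ...) lapply(x, as_report)
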