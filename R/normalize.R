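#' Build per-sample normalized measures against a reference assay
#'
#' Converts a (QC-cleaned) long cohort into one row per sample holding
#' the triplicate means as raw measures `x_<assay>` and, for every
#' non-reference assay, the reference-normalized measure
#' `dx_<assay> = x_<assay> - x_<reference>` (the delta-Ct). Subtracting
#' a stably expressed reference removes additive session/sample bias;
#' a constant shift applied to all assays of a session cancels exactly
#' in every `dx`.
#'
#' Samples lacking the reference triplicate (e.g. removed by QC) keep
#' their raw values but no `dx` columns, and are listed in the
#' `excluded` attribute so they are dropped from delta-based analyses
#' with a visible trace rather than silently.
#'
#' @param cohort a [qpcr_cohort()], normally the `cohort` element of an
#'   [apply_qc()] result.
#' @param reference_assay name of the reference assay (e.g. `"U6"`).
#' @return A `measure_table`: data.frame with `sample_id`,
#'   `class_label`, `session`, columns `x_<assay>` and `dx_<assay>`,
#'   and attributes `reference` and `excluded` (sample ids lacking the
#'   reference).
#' @export
normalize_cohort <- function(cohort, reference_assay) {
  assays <- attr(cohort, "assays")
  if (!reference_assay %in% assays) {
    stop_validation("unknown reference assay: %s", reference_assay)
  }
  ids <- unique(cohort$sample_id)
  meta <- cohort[!duplicated(cohort$sample_id),
                 c("sample_id", "class_label", "session")]
  out <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  for (a in assays) {
    sub <- cohort[cohort$assay == a, ]
    out[[paste0("x_", a)]] <- sub$x[match(ids, sub$sample_id)]
  }
  xref <- out[[paste0("x_", reference_assay)]]
  for (a in setdiff(assays, reference_assay)) {
    out[[paste0("dx_", a)]] <- out[[paste0("x_", a)]] - xref
  }
  structure(out,
            reference = reference_assay,
            excluded = sort(ids[!is.finite(xref)]),
            class = c("measure_table", "data.frame"))
}

#' Audit cross-session accuracy of a measure
#'
#' Compares per-session sample means of a measure, separately per
#' class, to decide whether it is stable across experimental sessions
#' or needs normalization. For each class the difference of session
#' means is reported with its standard error combined in quadrature,
#' SE = sqrt(SE_1^2 + SE_2^2); a measure is declared session-stable
#' for a class when |difference| < 2 SE. Audits are per class only:
#' pooling classes would confound class imbalance with session bias.
#'
#' @param measures a `measure_table` from [normalize_cohort()] (or any
#'   data.frame with `sample_id`, `class_label`, `session` and the
#'   measure column).
#' @param measure_name column to audit, e.g. `"x_miR-21"` or
#'   `"dx_miR-21"`.
#' @param classes class labels to audit (default both).
#' @return Object of class `session_audit`: list with `per_session`
#'   (session, class, n, mean, sd, se) and `differences` (class,
#'   sessions compared, difference, se, stable).
#' @export
session_bias_audit <- function(measures, measure_name,
                               classes = c("target", "versus")) {
  if (!measure_name %in% names(measures)) {
    stop_validation("unknown measure: %s", measure_name)
  }
  keep <- measures$class_label %in% classes &
    is.finite(measures[[measure_name]]) & !is.na(measures$session)
  d <- measures[keep, , drop = FALSE]
  sessions <- sort(unique(d$session))
  if (length(sessions) < 2) {
    stop_validation("session audit needs >= 2 sessions, found %d",
                    length(sessions))
  }
  per <- do.call(rbind, lapply(sessions, function(ses) {
    do.call(rbind, lapply(classes, function(cl) {
      v <- d[[measure_name]][d$session == ses & d$class_label == cl]
      if (length(v) < 2) {
        stop_validation("session '%s' class '%s' has < 2 samples", ses, cl)
      }
      data.frame(session = ses, measure = measure_name, class = cl,
                 n = length(v), mean = mean(v), sd = stats::sd(v),
                 se = stats::sd(v) / sqrt(length(v)),
                 stringsAsFactors = FALSE)
    }))
  }))
  pairs <- utils::combn(sessions, 2, simplify = FALSE)
  diffs <- do.call(rbind, lapply(pairs, function(p) {
    do.call(rbind, lapply(classes, function(cl) {
      a <- per[per$session == p[1] & per$class == cl, ]
      b <- per[per$session == p[2] & per$class == cl, ]
      dd <- b$mean - a$mean
      se <- sqrt(a$se^2 + b$se^2)
      data.frame(measure = measure_name, class = cl,
                 session_from = p[1], session_to = p[2],
                 difference = dd, se = se,
                 stable = abs(dd) < 2 * se,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(per_session = per, differences = diffs),
            class = "session_audit")
}

#' @export
print.session_audit <- function(x, ...) {
  print(x$per_session, row.names = FALSE)
  cat("\n")
  print(x$differences, row.names = FALSE)
  invisible(x)
}

#' @export
as_report.session_audit <- function(x, ...) {
  list(per_session = x$per_session, differences = x$differences)
}
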