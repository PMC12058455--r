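#' Classify abruptness metrics into treeline forms
#'
#' Maps the four abruptness metrics to the labels gradual /
#' intermediate / abrupt using conventional threshold values. Absolute
#' metrics (m): gradual below 2 m, abrupt above 3 m, with the gradual
#' cut for the second-maximum metric at 1.5 m; if a krummholz belt is
#' present every absolute cut is reduced by 1 m, because stunted
#' growth forms compress the height scale of the transition.
#' Normalised metrics: gradual below 0.25, abrupt above 0.40,
#' unaffected by krummholz. All cuts are strict inequalities; values
#' between cuts are intermediate. The consensus label is the majority
#' of the defined per-metric labels, except that one metric voting
#' abrupt while another votes gradual yields `conflicting` (such sites
#' need manual assignment); majority ties resolve to intermediate.
#'
#' @param result an `abruptness_result` from [abruptness_metrics()], or
#'   a list with elements `a_abr`, `a_abr2`, `n_abr`, `n_abr2` (NA for
#'   undefined metrics).
#' @param krummholz_present logical; is a krummholz belt present on the
#'   transect?
#' @param thresholds a [classification_thresholds()].
#' @return An object of class `abruptness_class`: `by_metric` (named
#'   labels for `a_abr`, `a_abr2`, `n_abr`, `n_abr2`; `undefined` for
#'   NA metrics), `consensus`, `krummholz_present`, and `boundary`
#'   (names of metrics lying exactly on a cut).
#' @export
classify_abruptness <- function(result, krummholz_present = FALSE,
                                thresholds = classification_thresholds()) {
  th <- thresholds
  red <- if (isTRUE(krummholz_present)) th$krummholz_reduction_m else 0
  cuts <- list(
    a_abr = c(gradual = th$a_abr_gradual_m - red,
              abrupt = th$a_abr_abrupt_m - red),
    a_abr2 = c(gradual = th$a_abr2_gradual_m - red,
               abrupt = th$a_abr_abrupt_m - red),
    n_abr = c(gradual = th$n_abr_gradual, abrupt = th$n_abr_abrupt),
    n_abr2 = c(gradual = th$n_abr_gradual, abrupt = th$n_abr_abrupt))
  vals <- c(a_abr = result$a_abr %||% NA_real_,
            a_abr2 = result$a_abr2 %||% NA_real_,
            n_abr = result$n_abr %||% NA_real_,
            n_abr2 = result$n_abr2 %||% NA_real_)
  lab <- character(4); names(lab) <- names(vals)
  boundary <- character(0)
  for (m in names(vals)) {
    v <- vals[[m]]; cc <- cuts[[m]]
    lab[m] <- if (is.na(v)) "undefined"
              else if (v < cc[["gradual"]]) "gradual"
              else if (v > cc[["abrupt"]]) "abrupt"
              else "intermediate"
    if (!is.na(v) && (v == cc[["gradual"]] || v == cc[["abrupt"]]))
      boundary <- c(boundary, m)
  }
  defined <- lab[lab != "undefined"]
  consensus <-
    if (!length(defined)) "undefined"
    else if (any(defined == "abrupt") && any(defined == "gradual"))
      "conflicting"
    else {
      tab <- table(factor(defined,
                          c("gradual", "intermediate", "abrupt")))
      winners <- names(tab)[tab == max(tab)]
      if (length(winners) == 1L) winners else "intermediate"
    }
  structure(list(by_metric = as.list(lab), consensus = consensus,
                 krummholz_present = isTRUE(krummholz_present),
                 boundary = boundary),
            class = "abruptness_class")
}

#' @export
print.abruptness_class <- function(x, ...) {
  cat("Abruptness classification",
      if (x$krummholz_present) "(krummholz present)" else "", "\n")
  for (m in names(x$by_metric))
    cat(sprintf("  %-7s %s\n", m, x$by_metric[[m]]))
  cat("  consensus:", x$consensus, "\n")
  if (length(x$boundary))
    cat("  note: value exactly on a threshold for:",
        paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a discreteness fit into discrete / diffuse
#'
#' A valid logistic fit with steepness at or above the discreteness
#' cut is a discrete forest edge; below it, diffuse. A fit flagged
#' for low forest cover is diffuse regardless of steepness (no
#' discrete cover transition is possible at such low cover), while
#' fits with the transition midpoint outside the interpretable range,
#' or failed fits, are unclassifiable.
#'
#' @param result a `discreteness_result` from [fit_cover_logistic()],
#'   or a list with elements `s`, `status` (and optionally `C_max`,
#'   `y_l` for the reason string).
#' @param thresholds a [classification_thresholds()].
#' @return An object of class `discreteness_class` with `label`
#'   (`discrete`, `diffuse` or `unclassifiable`), `reason` (which rule
#'   fired) and `boundary` (TRUE if `s` sits exactly on the cut).
#' @export
classify_discreteness <- function(result,
                                  thresholds = classification_thresholds()) {
  st <- result$status
  s_cut <- thresholds$s_discrete
  if (st %in% c("midpoint_below_margin", "midpoint_above_transect",
                "fit_failed")) {
    label <- "unclassifiable"
    reason <- switch(st,
      midpoint_below_margin = paste0("transition midpoint y_l = ",
        signif(result$y_l %||% NA, 4), " m lies at or below the ",
        thresholds$y_l_margin_m, "-m margin"),
      midpoint_above_transect = paste0("transition midpoint y_l = ",
        signif(result$y_l %||% NA, 4), " m lies above the transect"),
      fit_failed = "logistic fit failed or steepness pinned at zero")
  } else if (identical(st, "low_forest_cover")) {
    label <- "diffuse"
    reason <- paste0("fitted forest cover C_max = ",
                     signif(result$C_max %||% NA, 3), " below ",
                     thresholds$c_max_min,
                     ": no discrete cover transition possible")
  } else if (result$s >= s_cut) {
    label <- "discrete"
    reason <- paste0("fitted s = ", signif(result$s, 4), " >= ", s_cut)
  } else {
    label <- "diffuse"
    reason <- paste0("fitted s = ", signif(result$s, 4), " < ", s_cut)
  }
  structure(list(label = label, reason = reason,
                 boundary = !is.na(result$s %||% NA) &&
                   isTRUE(result$s == s_cut)),
            class = "discreteness_class")
}

#' @export
print.discreteness_class <- function(x, ...) {
  cat("Discreteness classification:", x$label, "\n  reason:", x$reason,
      "\n")
  if (isTRUE(x$boundary))
    cat("  note: fitted s sits exactly on the threshold\n")
  invisible(x)
}
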