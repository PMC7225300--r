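#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes incremental cost, incremental QALYs, the ICER
#' \eqn{\Delta C / \Delta Q} and the net monetary benefit
#' \eqn{\mathrm{WTP} \cdot \Delta Q - \Delta C} of a comparator strategy
#' against a reference, with the standard cost-effectiveness-plane
#' dominance taxonomy: a comparator that is cheaper and more effective is
#' `"dominant"`, one that is costlier and less effective is `"dominated"`,
#' and a zero QALY difference yields an `"undefined"` (or `"equivalent"`)
#' label rather than a division error.
#'
#' @param reference,comparator `econ_totals` from [accumulate_economics()]
#'   under the same [model_config()].
#' @param wtp Willingness-to-pay threshold in USD per QALY.
#'
#' @return An object of class `cea_comparison` with elements `reference`,
#'   `comparator`, `delta_cost`, `delta_qaly`, `icer` (numeric; `NA` when
#'   the ratio is meaningless), `label` and `nmb`.
#' @export
icer <- function(reference, comparator, wtp = 150000) {
  stopifnot(inherits(reference, "econ_totals"),
            inherits(comparator, "econ_totals"),
            is.numeric(wtp), wtp >= 0)
  dc <- comparator$total_cost - reference$total_cost
  dq <- comparator$total_qalys - reference$total_qalys
  if (dq == 0) {
    label <- if (dc == 0) "equivalent" else "undefined"
    ratio <- NA_real_
  } else if (dq > 0 && dc <= 0) {
    label <- "dominant"
    ratio <- dc / dq
  } else if (dq < 0 && dc >= 0) {
    label <- "dominated"
    ratio <- dc / dq
  } else {
    label <- "icer"
    ratio <- dc / dq
  }
  structure(
    list(reference = reference, comparator = comparator,
         delta_cost = dc, delta_qaly = dq,
         icer = ratio, label = label,
         nmb = wtp * dq - dc, wtp = wtp),
    class = "cea_comparison"
  )
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("<cea_comparison> %s vs %s\n",
              x$comparator$arm, x$reference$arm))
  cat(sprintf("  incremental cost  $%s\n",
              format(round(x$delta_cost), big.mark = ",")))
  cat(sprintf("  incremental QALYs %.3f\n", x$delta_qaly))
  if (x$label == "icer") {
    cat(sprintf("  ICER              $%s per QALY\n",
                format(round(x$icer), big.mark = ",")))
  } else {
    cat(sprintf("  ICER              %s\n", x$label))
  }
  cat(sprintf("  NMB at $%s/QALY: $%s\n",
              format(x$wtp, big.mark = ","),
              format(round(x$nmb), big.mark = ",")))
  invisible(x)
}

#' Tidiers for a cost-effectiveness comparison
#'
#' `tidy()` returns one row per strategy (cost, QALYs, life-years, with
#' incremental columns on the comparator row), mirroring the usual
#' base-case results table; `glance()` a one-row summary of the
#' comparison.
#'
#' @param x A `cea_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cea_comparison
#' @export
tidy.cea_comparison <- function(x, ...) {
  ref <- glance(x$reference)
  cmp <- glance(x$comparator)
  out <- dplyr::bind_rows(ref, cmp)
  out$incremental_cost <- c(NA_real_, x$delta_cost)
  out$incremental_qalys <- c(NA_real_, x$delta_qaly)
  out$icer <- c(NA_real_, x$icer)
  out$icer_label <- c(NA_character_, x$label)
  out
}

#' @rdname tidy.cea_comparison
#' @method glance cea_comparison
#' @export
glance.cea_comparison <- function(x, ...) {
  tibble::tibble(
    reference = x$reference$arm, comparator = x$comparator$arm,
    cost_reference = x$reference$total_cost,
    cost_comparator = x$comparator$total_cost,
    qalys_reference = x$reference$total_qalys,
    qalys_comparator = x$comparator$total_qalys,
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    icer = x$icer, icer_label = x$label, nmb = x$nmb, wtp = x$wtp
  )
}

#' Price-reduction scenario for one drug in an arm's regimen
#'
#' Returns a copy of the arm with the named drug's unit price in the
#' first-line regimen multiplied by `fraction`; everything else is
#' unchanged.  Composing two applications with fractions `a` then `b`
#' equals one application with `a * b`.
#'
#' @param arm An [arm_spec()].
#' @param drug Drug label present in the arm's first-line regimen.
#' @param fraction Price multiplier in `(0, 1]`.
#'
#' @return A modified [arm_spec()].
#' @export
price_scenario <- function(arm, drug, fraction) {
  stopifnot(inherits(arm, "arm_spec"),
            is.numeric(fraction), fraction > 0, fraction <= 1)
  comp <- arm$regimen$components
  hit <- comp$drug == drug
  if (!any(hit)) {
    rlang::abort(
      sprintf("Drug '%s' is not part of the '%s' regimen.", drug, arm$name),
      class = "renalcea_error_config"
    )
  }
  comp$unit_price[hit] <- comp$unit_price[hit] * fraction
  arm$regimen$components <- comp
  arm
}

#' Apply a subgroup hazard ratio to an arm's survival models
#'
#' For the \eqn{S(t) = \exp(-\lambda t^\gamma)} family a proportional
#' hazard acts multiplicatively on \eqn{\lambda}, so
#' \eqn{S_{\mathrm{new}}(t) = S_{\mathrm{old}}(t)^{\mathrm{HR}}}.  The OS
#' model is modified only when `os_hazard_ratio` is supplied.  No default
#' hazard ratio is provided: the PD-L1-positive subgroup value comes from
#' the trial and must be passed explicitly.
#'
#' @param arm An [arm_spec()].
#' @param pfs_hazard_ratio Positive PFS hazard ratio.
#' @param os_hazard_ratio Optional positive OS hazard ratio.
#'
#' @return A modified [arm_spec()].
#' @export
apply_subgroup <- function(arm, pfs_hazard_ratio, os_hazard_ratio = NULL) {
  stopifnot(inherits(arm, "arm_spec"))
  if (!is.numeric(pfs_hazard_ratio) || length(pfs_hazard_ratio) != 1L ||
      pfs_hazard_ratio <= 0) {
    rlang::abort("`pfs_hazard_ratio` must be a positive number.",
                 class = "renalcea_error_config")
  }
  arm$pfs_model <- weibull_params(arm$pfs_model$scale * pfs_hazard_ratio,
                                  arm$pfs_model$shape)
  if (!is.null(os_hazard_ratio)) {
    if (!is.numeric(os_hazard_ratio) || os_hazard_ratio <= 0) {
      rlang::abort("`os_hazard_ratio` must be a positive number.",
                   class = "renalcea_error_config")
    }
    arm$os_model <- weibull_params(arm$os_model$scale * os_hazard_ratio,
                                   arm$os_model$shape)
  }
  arm
}
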