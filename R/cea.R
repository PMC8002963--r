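#' Net monetary benefit
#'
#' `NMB = WTP * effectiveness - cost`: the monetary value of the health gained
#' at the willingness-to-pay threshold, net of cost. Higher is better.
#'
#' @param cost cumulative discounted cost in USD.
#' @param effectiveness cumulative discounted effectiveness in QALYs.
#' @param wtp willingness-to-pay threshold in USD per QALY, non-negative.
#' @return Net monetary benefit in USD; vectorized.
#' @export
#' @examples
#' net_monetary_benefit(104842, 8.48, 100000)
net_monetary_benefit <- function(cost, effectiveness, wtp) {
  if (any(wtp < 0)) stop("'wtp' must be non-negative", call. = FALSE)
  wtp * effectiveness - cost
}

#' Per-strategy cost-effectiveness result
#'
#' @param label strategy label.
#' @param cost cumulative discounted cost (USD).
#' @param effectiveness cumulative discounted effectiveness (QALY).
#' @param wtp willingness-to-pay (USD/QALY) used for the NMB.
#' @return A list of class `strategy_result` with the inputs plus `nmb`.
#' @export
strategy_result <- function(label, cost, effectiveness, wtp) {
  structure(
    list(label = label, cost = cost, effectiveness = effectiveness,
         wtp = wtp, nmb = net_monetary_benefit(cost, effectiveness, wtp)),
    class = "strategy_result"
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s: cost $%.0f, effectiveness %.4f QALY, NMB $%.0f (WTP $%s/QALY)\n",
              x$label, x$cost, x$effectiveness, x$nmb,
              format(x$wtp, big.mark = ",")), sep = "")
  invisible(x)
}

#' Incremental cost-effectiveness analysis of two strategies
#'
#' Computes incremental cost and effectiveness of strategy `b` relative to
#' reference strategy `a`, the ICER where meaningful, and the dominance
#' classification of `b`: `"dominant"` (cheaper and more effective),
#' `"dominated"` (costlier and less effective), or `"tradeoff"`. Under
#' dominance the ICER is undefined (`NA`) and the NMB difference is the
#' headline comparison; the ICER is likewise undefined when the incremental
#' effectiveness is zero.
#'
#' @param a reference [strategy_result()].
#' @param b comparator [strategy_result()].
#' @param wtp willingness-to-pay; defaults to the strategies' common WTP.
#' @return A list of class `cea_result`: `strategies` (a and b),
#'   `incremental_cost`, `incremental_effectiveness`, `incremental_nmb`
#'   (all b minus a), `icer`, and `dominance` (classification of `b`).
#' @export
incremental_analysis <- function(a, b, wtp = a$wtp) {
  if (!isTRUE(all.equal(a$wtp, b$wtp)))
    stop("strategies were evaluated at different WTP thresholds", call. = FALSE)
  dc <- b$cost - a$cost
  de <- b$effectiveness - a$effectiveness
  dominance <- if (dc < 0 && de > 0) "dominant"
  else if (dc > 0 && de < 0) "dominated"
  else "tradeoff"
  icer <- if (dominance != "tradeoff" || de == 0) NA_real_ else dc / de
  structure(
    list(strategies = list(a = a, b = b),
         incremental_cost = dc, incremental_effectiveness = de,
         incremental_nmb = net_monetary_benefit(dc, de, wtp),
         icer = icer, dominance = dominance, wtp = wtp),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness analysis\n")
  for (s in x$strategies) {
    cat("  "); print(s)
  }
  cat(sprintf("  incremental (%s vs %s): cost $%.0f, effectiveness %.4f QALY\n",
              x$strategies$b$label, x$strategies$a$label,
              x$incremental_cost, x$incremental_effectiveness))
  if (is.na(x$icer)) {
    cat(sprintf("  %s is %s (ICER undefined); incremental NMB $%.0f\n",
                x$strategies$b$label, x$dominance, x$incremental_nmb))
  } else {
    cat(sprintf("  ICER $%.0f per QALY\n", x$icer))
  }
  invisible(x)
}

#' Published base-case reference results
#'
#' The published base-case outputs of the model: cumulative discounted costs
#' and effectiveness per strategy, net monetary benefits at WTP $100,000/QALY,
#' and the incremental comparison (CT/MRI relative to the PET strategy, the
#' published sign convention). Used by [calibrate_structure()] to select the
#' structural variant and by [compare_to_reference()] for benchmarking.
#'
#' @return A named list of reference values.
#' @export
published_base_case <- function() {
  list(pet_cost = 104842, ctmri_cost = 106424,
       pet_qaly = 8.48, ctmri_qaly = 8.37,
       pet_nmb = 742697, ctmri_nmb = 730272,
       incremental_cost = 1581, incremental_effectiveness = -0.11)
}

#' Full set of published scalar results
#'
#' [published_base_case()] plus the published sensitivity-analysis outputs:
#' the minimum PET specificity for superior net monetary benefit (71.5%) and
#' the PET QALY advantage at CT/MRI specificity 65% and 85% (0.18 and 0.06).
#' This is the reference set the structural calibration scores against.
#'
#' @return A named list of reference values.
#' @export
published_reference <- function() {
  c(published_base_case(),
    list(pet_specificity_threshold = 0.715,
         qaly_advantage_ctmri_sp65 = 0.18,
         qaly_advantage_ctmri_sp85 = 0.06))
}

#' Compare model outputs to reference values
#'
#' Per-quantity absolute and relative deviation of computed values against a
#' reference set, with a pass/fail flag at the supplied tolerances.
#'
#' @param values named numeric vector (or list) of computed quantities.
#' @param reference named numeric vector/list of reference values; names must
#'   cover those of `values`.
#' @param tolerances named list per quantity; each element is a list with
#'   either `abs` (absolute tolerance) or `rel` (relative tolerance).
#' @return A data frame with one row per quantity: value, reference, absolute
#'   and relative deviation, tolerance description, pass.
#' @export
compare_to_reference <- function(values, reference, tolerances = NULL) {
  values <- unlist(values)
  reference <- unlist(reference)
  miss <- setdiff(names(values), names(reference))
  if (length(miss))
    stop("no reference value for: ", paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(quantity = names(values),
                    value = as.numeric(values),
                    reference = as.numeric(reference[names(values)]))
  out$abs_dev <- abs(out$value - out$reference)
  out$rel_dev <- ifelse(out$reference == 0, NA_real_,
                        out$abs_dev / abs(out$reference))
  out$tolerance <- NA_character_
  out$pass <- NA
  for (i in seq_len(nrow(out))) {
    tol <- tolerances[[out$quantity[i]]]
    if (is.null(tol)) next
    if (!is.null(tol$abs)) {
      out$tolerance[i] <- sprintf("abs %.4g", tol$abs)
      out$pass[i] <- out$abs_dev[i] <= tol$abs
    } else if (!is.null(tol$rel)) {
      out$tolerance[i] <- sprintf("rel %.4g", tol$rel)
      out$pass[i] <- out$rel_dev[i] <= tol$rel
    }
  }
  out
}
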