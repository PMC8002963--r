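#' Markov health states
#'
#' The cohort model refines the published follow-up / resection / recurrence /
#' death structure into six states so that every input parameter acts on a
#' distinct flow: benign IPMN under surveillance, undetected malignant IPMN
#' under surveillance (false negatives and new transformations), benign
#' post-resection (false positives), malignant post-resection (true positives
#' and delayed detections), recurrent malignant disease, and death (absorbing).
#'
#' @return Character vector of the six state names, in canonical order.
#' @export
health_states <- function() {
  c("SurveillanceBenign", "UndetectedMalignant", "PostResectionBenign",
    "PostResectionMalignant", "Recurrence", "Death")
}

#' Split the cohort by diagnostic outcome
#'
#' Applies a diagnostic test with the given sensitivity and specificity to a
#' cohort with the given pre-test probability of malignancy, yielding the four
#' decision-tree fractions: true positive, false positive, true negative,
#' false negative.
#'
#' @param prevalence pre-test probability of malignancy in `[0, 1]`.
#' @param acc list with `sensitivity` and `specificity` in `[0, 1]`.
#' @return A list of class `cohort_split` with elements `tp`, `fp`, `tn`, `fn`
#'   summing to one.
#' @export
#' @examples
#' classify_cohort(0.52, list(sensitivity = 0.968, specificity = 0.911))
classify_cohort <- function(prevalence, acc) {
  check_prob(prevalence, "prevalence")
  check_prob(acc$sensitivity, "sensitivity")
  check_prob(acc$specificity, "specificity")
  structure(
    list(tp = prevalence * acc$sensitivity,
         fn = prevalence * (1 - acc$sensitivity),
         tn = (1 - prevalence) * acc$specificity,
         fp = (1 - prevalence) * (1 - acc$specificity)),
    class = "cohort_split"
  )
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("cohort split: TP %.5f  FP %.5f  TN %.5f  FN %.5f\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Initial state allocation, upfront costs and utilities
#'
#' Maps the decision-tree outcomes to cycle-0 state occupancy and first-cycle
#' rewards. Test-positive patients (TP and FP) undergo immediate pancreatic
#' surgery: the weighted resection cost plus the bundled readmission cost is
#' charged, the per-surgery perioperative mortality is applied once (moving
#' that fraction to Death), and survivors enter the post-resection states with
#' the resection-year utility. Test-negative patients (TN and FN) continue
#' surveillance at the healthy-IPMN utility. Both strategies are charged one
#' CT/MRI examination at cycle 0; the PET strategy additionally charges one
#' supplemental PET examination.
#'
#' @param split a [classify_cohort()] result.
#' @param p a validated [model_parameters()] object.
#' @param strategy `"ctmri"` or `"pet"`.
#' @return A list of class `initial_allocation` with `state_occupancy` (named
#'   fraction per state, summing to one), `upfront_cost` and `upfront_utility`
#'   (cohort expectations for cycle 0), and a per-pathway breakdown `pathways`.
#' @export
initial_allocation <- function(split, p, strategy = c("ctmri", "pet")) {
  strategy <- match.arg(strategy)
  pm <- p$transitions$perioperative_mortality
  surgery <- surgery_event_cost(p$costs)
  imaging <- p$costs$mri_exam + if (strategy == "pet") p$costs$pet_exam else 0

  pathways <- data.frame(
    pathway = c("tp", "fp", "tn", "fn"),
    fraction = c(split$tp, split$fp, split$tn, split$fn),
    state = c("PostResectionMalignant", "PostResectionBenign",
              "SurveillanceBenign", "UndetectedMalignant"),
    cost = imaging + c(surgery, surgery, 0, 0),
    utility = c(rep((1 - pm) * p$utilities$resection_year, 2L),
                rep(p$utilities$healthy_ipmn, 2L))
  )

  occ <- stats::setNames(numeric(6L), health_states())
  occ["PostResectionMalignant"] <- split$tp * (1 - pm)
  occ["PostResectionBenign"] <- split$fp * (1 - pm)
  occ["SurveillanceBenign"] <- split$tn
  occ["UndetectedMalignant"] <- split$fn
  occ["Death"] <- (split$tp + split$fp) * pm

  structure(
    list(state_occupancy = occ,
         upfront_cost = sum(pathways$fraction * pathways$cost),
         upfront_utility = sum(pathways$fraction * pathways$utility),
         pathways = pathways,
         strategy = strategy),
    class = "initial_allocation"
  )
}

#' @export
print.initial_allocation <- function(x, ...) {
  cat(sprintf("initial allocation (%s strategy)\n", x$strategy))
  occ <- x$state_occupancy[x$state_occupancy > 0]
  for (s in names(occ)) cat(sprintf("  %-24s %.5f\n", s, occ[[s]]))
  cat(sprintf("  upfront cost $%.2f, upfront utility %.5f\n",
              x$upfront_cost, x$upfront_utility))
  invisible(x)
}
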