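#' Base-case model parameters
#'
#' Constructs the complete, validated input set of the IPMN cost-effectiveness
#' model. Defaults are the literature-derived base-case values: diagnostic
#' accuracies from the meta-analytic estimates for CT/MRI (sensitivity 80.9%,
#' specificity 76.2%) and FDG-PET/CT (96.8%, 91.1%), Medicare/literature costs,
#' utilities for the surveillance, post-resection and recurrence states, annual
#' transition probabilities, and the economic settings (WTP $100,000/QALY, 3%
#' annual discount rate, 15 one-year cycles starting at age 64.3, pre-test
#' probability of malignancy 52%).
#'
#' @param ctmri,pet lists with elements `sensitivity` and `specificity`, both
#'   probabilities in `[0, 1]`.
#' @param costs list of non-negative costs in US dollars: `mri_exam`,
#'   `pet_exam`, `pancreatoduodenectomy`, `distal_resection`,
#'   `recurrence_cost`, `readmission_cost`, plus the resection-mix proportions
#'   `head_resection_fraction` and `distal_resection_fraction` (the published
#'   mix is 78%/21%; the weighted surgery cost renormalizes them).
#' @param utilities list of per-year utilities in `[0, 1]`: `healthy_ipmn`,
#'   `resection_year`, `post_resection_longterm`, `recurrence`, `death`
#'   (`death` must be 0).
#' @param transitions list of probabilities in `[0, 1]`:
#'   `malignant_transformation` (annual), `death_malignant_ipmn` (annual,
#'   untreated malignancy), `death_recurrence` (annual),
#'   `perioperative_mortality` (per surgery), `recurrence_probability`
#'   (annual, post-resection malignant), `pet_recurrence_risk_reduction`
#'   (relative reduction applied in the PET strategy).
#' @param economics list: `wtp` (USD/QALY), `discount_rate` (annual fraction),
#'   `horizon` (integer years), `cycle_length` (must be 1 year),
#'   `starting_age` (years, fractional allowed), `pretest_probability`.
#' @param structure a [structure_variant()] list of structural model choices.
#'
#' @return An object of class `ipmn_parameters`.
#' @seealso [load_parameters()], [validate_parameters()], [structure_variant()]
#' @export
#' @examples
#' p <- model_parameters()
#' p$pet$sensitivity
model_parameters <- function(ctmri = list(sensitivity = 0.809, specificity = 0.762),
                             pet = list(sensitivity = 0.968, specificity = 0.911),
                             costs = list(
                               mri_exam = 492,
                               pet_exam = 1551,
                               pancreatoduodenectomy = 28623,
                               distal_resection = 13900,
                               head_resection_fraction = 0.78,
                               distal_resection_fraction = 0.21,
                               recurrence_cost = 78630,
                               readmission_cost = 1930
                             ),
                             utilities = list(
                               healthy_ipmn = 1.00,
                               resection_year = 0.818,
                               post_resection_longterm = 0.896,
                               recurrence = 0.65,
                               death = 0.00
                             ),
                             transitions = list(
                               malignant_transformation = 0.0223,
                               death_malignant_ipmn = 0.027,
                               death_recurrence = 0.283,
                               perioperative_mortality = 0.046,
                               recurrence_probability = 0.167,
                               pet_recurrence_risk_reduction = 0.10
                             ),
                             economics = list(
                               wtp = 100000,
                               discount_rate = 0.03,
                               horizon = 15,
                               cycle_length = 1,
                               starting_age = 64.3,
                               pretest_probability = 0.52
                             ),
                             structure = structure_variant()) {
  p <- structure(
    list(ctmri = ctmri, pet = pet, costs = costs, utilities = utilities,
         transitions = transitions, economics = economics,
         structure = structure),
    class = "ipmn_parameters"
  )
  validate_parameters(p)
}

#' Structural model variants
#'
#' The published model structure leaves several wiring choices open; each is
#' exposed as an explicit variant so that [calibrate_structure()] can enumerate
#' them. The defaults are the combination selected by the calibration harness
#' against the published base-case results (see the package vignette).
#'
#' @param fn_detection how false negatives (and new malignant transformations)
#'   are detected during surveillance: `"annual_retest"` re-tests every cycle
#'   with the strategy's own sensitivity; `"one_year_delay"` detects with
#'   certainty at the next annual scan.
#' @param recurrence_cost_timing when the cost of recurrent disease is charged:
#'   `"entry"` once on entry to the recurrence state, `"cycle"` every cycle
#'   spent in it (phase-based annual cost), or `"entry_and_cycle"` both (an
#'   initial-phase cost on entry plus a continuing-phase annual cost).
#' @param recurrence_model exposure window of the post-resection recurrence
#'   hazard: `"exponential"` (constant annual hazard), `"first_five_years"`,
#'   or `"one_time"` (first post-surgical year only).
#' @param post_resection_imaging logical; charge annual surveillance imaging in
#'   the post-resection states (guideline follow-up after surgery).
#' @param half_cycle_correction logical; average state membership between cycle
#'   boundaries when assigning utility rewards.
#'
#' @return A named list of class `ipmn_structure`.
#' @export
structure_variant <- function(fn_detection = c("annual_retest", "one_year_delay"),
                              recurrence_cost_timing = c("cycle", "entry", "entry_and_cycle"),
                              recurrence_model = c("exponential", "first_five_years", "one_time"),
                              post_resection_imaging = TRUE,
                              half_cycle_correction = FALSE) {
  fn_detection <- match.arg(fn_detection)
  recurrence_cost_timing <- match.arg(recurrence_cost_timing)
  recurrence_model <- match.arg(recurrence_model)
  stopifnot(is.logical(post_resection_imaging), length(post_resection_imaging) == 1L,
            is.logical(half_cycle_correction), length(half_cycle_correction) == 1L)
  structure(
    list(fn_detection = fn_detection,
         recurrence_cost_timing = recurrence_cost_timing,
         recurrence_model = recurrence_model,
         post_resection_imaging = post_resection_imaging,
         half_cycle_correction = half_cycle_correction),
    class = "ipmn_structure"
  )
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1], got %s", field,
                 format(x)), call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a non-negative number, got %s", field,
                 format(x)), call. = FALSE)
  invisible(x)
}

#' Validate a model parameter set
#'
#' Checks every probability and utility lies in `[0, 1]`, every cost is
#' non-negative, and the economic settings are admissible. Emits a warning
#' (not an error) when the head/distal resection proportions do not sum to 1,
#' as with the published 78%/21% mix. Validation is idempotent.
#'
#' @param p an `ipmn_parameters` object (or a plain list with the same shape).
#' @return The validated `ipmn_parameters` object, invisibly classed.
#' @export
validate_parameters <- function(p) {
  required <- c("ctmri", "pet", "costs", "utilities", "transitions",
                "economics", "structure")
  missing <- setdiff(required, names(p))
  if (length(missing))
    stop("parameter set is missing component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  for (s in c("ctmri", "pet")) {
    check_prob(p[[s]]$sensitivity, paste0(s, ".sensitivity"))
    check_prob(p[[s]]$specificity, paste0(s, ".specificity"))
  }
  for (f in c("mri_exam", "pet_exam", "pancreatoduodenectomy",
              "distal_resection", "recurrence_cost", "readmission_cost"))
    check_nonneg(p$costs[[f]], paste0("costs.", f))
  for (f in c("head_resection_fraction", "distal_resection_fraction"))
    check_prob(p$costs[[f]], paste0("costs.", f))
  for (f in c("healthy_ipmn", "resection_year", "post_resection_longterm",
              "recurrence", "death"))
    check_prob(p$utilities[[f]], paste0("utilities.", f))
  if (p$utilities$death != 0)
    stop("'utilities.death' must be 0", call. = FALSE)
  for (f in c("malignant_transformation", "death_malignant_ipmn",
              "death_recurrence", "perioperative_mortality",
              "recurrence_probability", "pet_recurrence_risk_reduction"))
    check_prob(p$transitions[[f]], paste0("transitions.", f))

  e <- p$economics
  check_nonneg(e$wtp, "economics.wtp")
  if (!is.numeric(e$discount_rate) || e$discount_rate < 0 || e$discount_rate >= 1)
    stop("'economics.discount_rate' must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(e$horizon) || e$horizon < 1 || e$horizon != round(e$horizon))
    stop("'economics.horizon' must be a positive integer number of years",
         call. = FALSE)
  if (!identical(as.numeric(e$cycle_length), 1))
    stop("'economics.cycle_length' must be 1 year", call. = FALSE)
  check_nonneg(e$starting_age, "economics.starting_age")
  check_prob(e$pretest_probability, "economics.pretest_probability")

  frac_sum <- p$costs$head_resection_fraction + p$costs$distal_resection_fraction
  if (abs(frac_sum - 1) > 1e-9)
    warning(sprintf(paste0("head and distal resection fractions sum to %.4g, ",
                           "not 1; they are renormalized in the weighted ",
                           "surgery cost"), frac_sum), call. = FALSE)

  if (!inherits(p$structure, "ipmn_structure"))
    p$structure <- do.call(structure_variant, as.list(p$structure))
  if (!inherits(p, "ipmn_parameters")) class(p) <- "ipmn_parameters"
  invisible(p)
}

#' @export
print.ipmn_parameters <- function(x, ...) {
  cat("IPMN cost-effectiveness model parameters\n")
  cat(sprintf("  CT/MRI   Se/Sp : %.3f / %.3f\n",
              x$ctmri$sensitivity, x$ctmri$specificity))
  cat(sprintf("  PET/CT   Se/Sp : %.3f / %.3f\n",
              x$pet$sensitivity, x$pet$specificity))
  cat(sprintf("  Pre-test prob. : %.2f   WTP: $%s/QALY   discount: %.1f%%\n",
              x$economics$pretest_probability,
              format(x$economics$wtp, big.mark = ","),
              100 * x$economics$discount_rate))
  cat(sprintf("  Horizon        : %d one-year cycles from age %.1f\n",
              as.integer(x$economics$horizon), x$economics$starting_age))
  cat(sprintf("  Structure      : fn=%s, rec-cost=%s, rec-model=%s, post-res imaging=%s, HCC=%s\n",
              x$structure$fn_detection, x$structure$recurrence_cost_timing,
              x$structure$recurrence_model,
              x$structure$post_resection_imaging,
              x$structure$half_cycle_correction))
  invisible(x)
}

# Strip "_percent" suffixes, dividing the value by 100. Table-style inputs mix
# percent and fraction notation; the suffix makes the unit explicit per field.
normalize_percent_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  for (i in seq_along(x)) {
    if (is.list(x[[i]])) {
      x[[i]] <- normalize_percent_keys(x[[i]])
    } else if (grepl("_percent$", nm[i])) {
      x[[i]] <- x[[i]] / 100
      nm[i] <- sub("_percent$", "", nm[i])
    }
  }
  names(x) <- nm
  x
}

known_parameter_keys <- function() {
  d <- unclass(suppressWarnings(model_parameters()))
  lapply(d, names)
}

#' Load model parameters from a configuration file
#'
#' Reads a YAML (or JSON) configuration whose sections and keys mirror the
#' model's input table in snake_case (`ctmri`, `pet`, `costs`, `utilities`,
#' `transitions`, `economics`, `structure`). Any numeric key may carry a
#' `_percent` suffix, in which case the value is divided by 100 — the input
#' table mixes percent and fraction notation, and the suffix disambiguates.
#' Unknown keys are an error. Missing fields are filled from the packaged
#' base-case defaults only when `use_defaults` is set (as an argument or as a
#' top-level `use_defaults: true` entry in the file).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @param use_defaults logical; fill unspecified fields from the base case.
#' @return A validated [model_parameters()] object.
#' @export
load_parameters <- function(path, use_defaults = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("config did not parse to a mapping: ", path, call. = FALSE)
  if (!is.null(raw$use_defaults)) {
    use_defaults <- isTRUE(raw$use_defaults)
    raw$use_defaults <- NULL
  }
  raw <- normalize_percent_keys(raw)

  known <- known_parameter_keys()
  bad_top <- setdiff(names(raw), names(known))
  if (length(bad_top))
    stop("unknown top-level config key(s): ", paste(bad_top, collapse = ", "),
         call. = FALSE)
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), known[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }

  base <- unclass(suppressWarnings(model_parameters()))
  if (use_defaults) {
    merged <- base
    for (sec in names(raw)) merged[[sec]][names(raw[[sec]])] <- raw[[sec]]
  } else {
    merged <- raw
    # structure is always defaultable: it is a package-level modelling choice
    if (is.null(merged$structure)) merged$structure <- base$structure
    for (sec in setdiff(names(known), "structure")) {
      if (is.null(merged[[sec]]))
        stop("config section missing (and use_defaults not set): ", sec,
             call. = FALSE)
      miss <- setdiff(known[[sec]], names(merged[[sec]]))
      if (length(miss))
        stop(sprintf("missing key(s) in '%s' (and use_defaults not set): %s",
                     sec, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  merged$structure <- do.call(structure_variant, as.list(merged$structure))
  validate_parameters(structure(merged, class = "ipmn_parameters"))
}

#' Write model parameters to a YAML configuration file
#'
#' Inverse of [load_parameters()]: the written file loads back to an identical
#' parameter set.
#'
#' @param p an `ipmn_parameters` object.
#' @param path output file path (YAML).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  p <- validate_parameters(p)
  x <- rapply(unclass(p), f = identity, how = "replace")
  x$structure <- unclass(x$structure)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Weighted cost of pancreatic surgery
#'
#' The resection mix (78% pancreatic head, 21% distal) does not sum to one as
#' published; the proportions are renormalized rather than assigning the
#' residual to an unpriced third procedure.
#'
#' @param costs the `costs` component of a parameter set.
#' @return Weighted per-surgery cost in USD (excluding readmission).
#' @export
weighted_surgery_cost <- function(costs) {
  w <- costs$head_resection_fraction + costs$distal_resection_fraction
  if (w <= 0) stop("resection fractions sum to zero", call. = FALSE)
  (costs$head_resection_fraction * costs$pancreatoduodenectomy +
      costs$distal_resection_fraction * costs$distal_resection) / w
}

# Full per-surgery cost: weighted resection plus the bundled readmission cost.
surgery_event_cost <- function(costs) {
  weighted_surgery_cost(costs) + costs$readmission_cost
}
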