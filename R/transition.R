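# Shared per-cycle transition dynamics.
#
# Cause-specific risks are combined with background mortality q(age) as
# independent competing risks within a cycle: the probability of surviving
# both is (1 - q) * (1 - q_cause), and the residual probability remains in
# the current state. Detection of undetected malignancy during surveillance
# happens with probability d per cycle (the strategy's own sensitivity under
# annual re-testing, or 1 under the fixed one-year-delay variant); a detected
# patient undergoes surgery in that cycle, with the per-surgery perioperative
# mortality applied once.

# Per-cycle detection probability for undetected malignancy.
detection_probability <- function(p, strategy) {
  if (p$structure$fn_detection == "annual_retest") p[[strategy]]$sensitivity else 1
}

# Post-resection recurrence hazard by time since surgery (tss = 0 during the
# first post-surgical year). The PET strategy's earlier detection reduces the
# hazard by a relative factor. Vectorized over tss.
recurrence_hazard <- function(p, strategy, tss) {
  h <- p$transitions$recurrence_probability
  if (strategy == "pet") h <- h * (1 - p$transitions$pet_recurrence_risk_reduction)
  switch(p$structure$recurrence_model,
         exponential = rep(h, length(tss)),
         first_five_years = h * (tss < 5),
         one_time = h * (tss == 0))
}

# Outcome decomposition for one cycle at a given age. Probabilities are per
# occupant of each state; `um$detected` is the probability of the surgery
# event (used for event costs), which splits into perioperative death and
# arrival in the post-resection malignant state.
transition_dynamics <- function(age, p, strategy, life_table, prm_hazard) {
  q <- lookup_mortality(life_table, age)
  tr <- p$transitions
  d <- detection_probability(p, strategy)

  sb_um <- (1 - q) * tr$malignant_transformation
  sb <- c(stay = 1 - q - sb_um, to_um = sb_um, death = q)

  surv <- (1 - q) * (1 - tr$death_malignant_ipmn)
  detected <- surv * d
  um <- list(
    stay = surv * (1 - d),
    to_prm = detected * (1 - tr$perioperative_mortality),
    death_periop = detected * tr$perioperative_mortality,
    death_natural = 1 - surv,
    detected = detected
  )

  prb <- c(stay = 1 - q, death = q)
  prm <- list(stay = (1 - q) * (1 - prm_hazard),
              to_rec = (1 - q) * prm_hazard,
              death = rep(q, length(prm_hazard)))
  rec_stay <- (1 - q) * (1 - tr$death_recurrence)
  rec <- c(stay = rec_stay, death = 1 - rec_stay)

  list(q = q, sb = sb, um = um, prb = prb, prm = prm, rec = rec)
}

#' Build the per-cycle transition matrix
#'
#' Assembles the six-state transition matrix at a given age for one strategy,
#' combining the cause-specific annual risks with age-adjusted background
#' mortality as independent competing risks. Undetected malignancy is detected
#' with the strategy's per-cycle detection probability and routed through
#' surgery (perioperative mortality applied once) into the post-resection
#' malignant state. The post-resection recurrence hazard may be overridden
#' (used internally for time-since-surgery variants); by default it is the
#' constant annual hazard, reduced in the PET strategy.
#'
#' @param age age in years at the start of the cycle.
#' @param p a validated [model_parameters()] object.
#' @param strategy `"ctmri"` or `"pet"`.
#' @param life_table a [life_table()]; defaults to the packaged table.
#' @param prm_recurrence_hazard optional override of the recurrence hazard.
#' @return A 6x6 row-stochastic matrix over [health_states()], with an
#'   attribute `events` holding the per-occupant probabilities of the
#'   cost-bearing events (`um_surgery`, `prm_recurrence_entry`).
#' @export
build_transition_matrix <- function(age, p, strategy = c("ctmri", "pet"),
                                    life_table = default_life_table(),
                                    prm_recurrence_hazard = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(prm_recurrence_hazard))
    prm_recurrence_hazard <- recurrence_hazard(p, strategy, 0)[1L]
  dyn <- transition_dynamics(age, p, strategy, life_table, prm_recurrence_hazard)
  s <- health_states()
  m <- matrix(0, 6L, 6L, dimnames = list(s, s))
  m["SurveillanceBenign", ] <- c(dyn$sb["stay"], dyn$sb["to_um"], 0, 0, 0,
                                 dyn$sb["death"])
  m["UndetectedMalignant", ] <- c(0, dyn$um$stay, 0, dyn$um$to_prm, 0,
                                  dyn$um$death_periop + dyn$um$death_natural)
  m["PostResectionBenign", ] <- c(0, 0, dyn$prb["stay"], 0, 0, dyn$prb["death"])
  m["PostResectionMalignant", ] <- c(0, 0, 0, dyn$prm$stay[1L], dyn$prm$to_rec[1L],
                                     dyn$prm$death[1L])
  m["Recurrence", ] <- c(0, 0, 0, 0, dyn$rec["stay"], dyn$rec["death"])
  m["Death", "Death"] <- 1

  bad <- abs(rowSums(m) - 1) > 1e-12
  if (any(bad) || any(m < 0) || any(m > 1))
    stop("internal error: transition matrix row(s) not stochastic: ",
         paste(s[bad], collapse = ", "), call. = FALSE)
  attr(m, "events") <- list(um_surgery = dyn$um$detected,
                            prm_recurrence_entry = dyn$prm$to_rec[1L])
  m
}
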