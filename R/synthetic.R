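#' Generate a random valid parameter set
#'
#' Independently perturbs every probability, utility and cost input around the
#' base-case values by a relative scale (multiplicative uniform perturbation,
#' clamped to the field's validity range), leaving the economic settings and
#' structural variant at base. Deterministic given the seed; `scale = 0`
#' returns exactly the base case. Intended for property-style testing of the
#' cohort engine against the microsimulation oracle.
#'
#' @param seed integer RNG seed.
#' @param scale non-negative relative perturbation scale (e.g. `0.2`).
#' @return A validated [model_parameters()] object.
#' @export
generate_parameters <- function(seed, scale = 0.2) {
  if (scale < 0) stop("'scale' must be non-negative", call. = FALSE)
  p <- suppressWarnings(model_parameters())
  if (scale == 0) return(p)
  set.seed(as.integer(seed))
  perturb <- function(v, upper = Inf) {
    pmin(upper, pmax(0, v * (1 + scale * stats::runif(length(v), -1, 1))))
  }
  for (s in c("ctmri", "pet"))
    for (f in c("sensitivity", "specificity"))
      p[[s]][[f]] <- perturb(p[[s]][[f]], 1)
  for (f in c("mri_exam", "pet_exam", "pancreatoduodenectomy",
              "distal_resection", "recurrence_cost", "readmission_cost"))
    p$costs[[f]] <- perturb(p$costs[[f]])
  for (f in c("head_resection_fraction", "distal_resection_fraction"))
    p$costs[[f]] <- perturb(p$costs[[f]], 1)
  for (f in c("healthy_ipmn", "resection_year", "post_resection_longterm",
              "recurrence"))
    p$utilities[[f]] <- perturb(p$utilities[[f]], 1)
  for (f in names(p$transitions))
    p$transitions[[f]] <- perturb(p$transitions[[f]], 1)
  p$economics$pretest_probability <-
    perturb(p$economics$pretest_probability, 1)
  suppressWarnings(validate_parameters(p))
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n` individuals through the identical decision-tree and
#' state-transition process as the cohort engine — same per-cycle transition
#' dynamics, event costs, utilities and discounting — by per-cycle random
#' draws, and returns the mean and standard error of discounted cost and QALY.
#' The cohort engine computes the exact expectation of this process, so the
#' two must agree within sampling error; the oracle draws from the same
#' transition dynamics as the engine, isolating the engine's accumulation and
#' discounting logic as the quantity under test.
#'
#' @param p a validated [model_parameters()] object.
#' @param strategy `"ctmri"` or `"pet"`.
#' @param n number of simulated individuals (>= 1).
#' @param seed integer RNG seed; results are deterministic given the seed.
#' @param life_table a [life_table()].
#' @return A list of class `microsim_result`: `n`, `mean_cost`, `mean_qaly`,
#'   `se_cost`, `se_qaly`, `seed`.
#' @export
microsimulate <- function(p, strategy = c("ctmri", "pet"), n = 200000L,
                          seed = 1L, life_table = default_life_table()) {
  strategy <- match.arg(strategy)
  if (n < 1L) stop("'n' must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  H <- as.integer(p$economics$horizon)
  age0 <- p$economics$starting_age
  df <- (1 + p$economics$discount_rate)^-(0:(H - 1L))
  st <- p$structure
  cs <- p$costs
  acc <- p[[strategy]]
  pm <- p$transitions$perioperative_mortality
  surgery <- surgery_event_cost(cs)
  imaging <- cs$mri_exam + if (strategy == "pet") cs$pet_exam else 0
  rec_entry <- st$recurrence_cost_timing %in% c("entry", "entry_and_cycle")
  rec_cycle <- st$recurrence_cost_timing %in% c("cycle", "entry_and_cycle")

  # states: 1 SurveillanceBenign, 2 UndetectedMalignant, 3 PostResectionBenign,
  #         4 PostResectionMalignant, 5 Recurrence, 6 Death
  S <- matrix(NA_integer_, n, H + 1L)
  diseased <- stats::runif(n) < p$economics$pretest_probability
  positive <- stats::runif(n) < ifelse(diseased, acc$sensitivity,
                                       1 - acc$specificity)
  periop0 <- positive & (stats::runif(n) < pm)
  S[, 1L] <- ifelse(positive,
                    ifelse(periop0, 6L, ifelse(diseased, 4L, 3L)),
                    ifelse(diseased, 2L, 1L))
  dcost <- imaging + surgery * positive # df(0) = 1
  tss <- ifelse(S[, 1L] == 4L, 0L, NA_integer_)

  for (t in 0:(H - 1L)) {
    i <- t + 1L
    s <- S[, i]
    dyn <- transition_dynamics(age0 + t, p, strategy, life_table, 0)
    q <- dyn$q
    nxt <- s
    u <- stats::runif(n)

    k <- which(s == 1L)
    nxt[k] <- ifelse(u[k] < dyn$sb[["death"]], 6L,
                     ifelse(u[k] < dyn$sb[["death"]] + dyn$sb[["to_um"]], 2L, 1L))

    k <- which(s == 2L)
    if (length(k)) {
      c1 <- dyn$um$death_natural
      c2 <- c1 + dyn$um$death_periop
      c3 <- c2 + dyn$um$to_prm
      nxt[k] <- ifelse(u[k] < c1, 6L,
                       ifelse(u[k] < c2, 6L, ifelse(u[k] < c3, 4L, 2L)))
      operated <- k[u[k] >= c1 & u[k] < c3]
      if (t + 1L <= H - 1L)
        dcost[operated] <- dcost[operated] + surgery * df[i + 1L]
      tss[k[u[k] >= c2 & u[k] < c3]] <- -1L # becomes 0 after the increment below
    }

    k <- which(s == 3L)
    nxt[k] <- ifelse(u[k] < q, 6L, 3L)

    k <- which(s == 4L)
    if (length(k)) {
      h <- recurrence_hazard(p, strategy, tss[k])
      prec <- q + (1 - q) * h
      nxt[k] <- ifelse(u[k] < q, 6L, ifelse(u[k] < prec, 5L, 4L))
      recurred <- k[u[k] >= q & u[k] < prec]
      if (rec_entry && t + 1L <= H - 1L)
        dcost[recurred] <- dcost[recurred] + cs$recurrence_cost * df[i + 1L]
    }

    k <- which(s == 5L)
    nxt[k] <- ifelse(u[k] < dyn$rec[["death"]], 6L, 5L)

    in_prm <- nxt == 4L & !is.na(tss)
    tss[in_prm] <- tss[in_prm] + 1L
    tss[nxt != 4L] <- NA_integer_
    S[, i + 1L] <- nxt
  }

  # state costs from cycle 1 onward, mirroring the cohort engine
  for (t in seq_len(H - 1L)) {
    s <- S[, t + 1L]
    sc <- cs$mri_exam * (s == 1L | s == 2L)
    if (st$post_resection_imaging) sc <- sc + cs$mri_exam * (s == 3L | s == 4L)
    if (rec_cycle) sc <- sc + cs$recurrence_cost * (s == 5L)
    dcost <- dcost + sc * df[t + 1L]
  }

  uvec <- c(p$utilities$healthy_ipmn, p$utilities$healthy_ipmn,
            p$utilities$post_resection_longterm,
            p$utilities$post_resection_longterm,
            p$utilities$recurrence, p$utilities$death)
  decr <- p$utilities$post_resection_longterm - p$utilities$resection_year
  dqaly <- numeric(n)
  for (t in 0:(H - 1L)) {
    i <- t + 1L
    ut <- uvec[S[, i]]
    if (st$half_cycle_correction) ut <- (ut + uvec[S[, i + 1L]]) / 2
    if (t == 0L) {
      fresh <- S[, 1L] == 3L | S[, 1L] == 4L
    } else {
      fresh <- S[, i] == 4L & S[, i - 1L] == 2L
    }
    dqaly <- dqaly + (ut - decr * fresh) * df[i]
  }

  structure(
    list(n = n,
         mean_cost = mean(dcost), mean_qaly = mean(dqaly),
         se_cost = if (n > 1L) stats::sd(dcost) / sqrt(n) else 0,
         se_qaly = if (n > 1L) stats::sd(dqaly) / sqrt(n) else 0,
         seed = seed),
    class = "microsim_result"
  )
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("microsimulation (n = %d, seed = %d)\n", x$n, x$seed))
  cat(sprintf("  mean discounted cost : $%.2f (SE %.2f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  mean discounted QALY : %.5f (SE %.5f)\n", x$mean_qaly, x$se_qaly))
  invisible(x)
}
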