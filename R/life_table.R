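#' Construct a life table
#'
#' A life table maps integer age to the annual probability of death `qx`.
#' Ages must be contiguous (strictly increasing by one year) and every `qx`
#' must lie in `[0, 1]`.
#'
#' @param ages integer ages in years, contiguous.
#' @param qx annual death probabilities, one per age.
#' @return A data frame of class `life_table` with columns `age` and `qx`.
#' @export
life_table <- function(ages, qx) {
  ages <- as.numeric(ages)
  qx <- as.numeric(qx)
  if (length(ages) != length(qx) || length(ages) < 1L)
    stop("'ages' and 'qx' must be non-empty and of equal length", call. = FALSE)
  if (any(ages != round(ages)))
    stop("'ages' must be integer years", call. = FALSE)
  if (length(ages) > 1L && any(diff(ages) != 1))
    stop("'ages' must be contiguous (strictly increasing by 1)", call. = FALSE)
  if (any(is.na(qx)) || any(qx < 0) || any(qx > 1))
    stop("every 'qx' must lie in [0, 1]", call. = FALSE)
  structure(data.frame(age = ages, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Read a life table from CSV
#'
#' Expects a two-column CSV with header `age,qx`. Lines starting with `#` are
#' treated as comments.
#'
#' @param path CSV file path.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("age", "qx") %in% names(d)))
    stop("life table CSV must have columns 'age' and 'qx'", call. = FALSE)
  life_table(d$age, d$qx)
}

#' Packaged background-mortality table
#'
#' Annual all-population death probabilities for ages 60-85 used as the default
#' background mortality of the cohort model. The packaged file is a *synthetic*
#' stand-in for the 2017 US all-population life table: it reproduces the level
#' and Gompertz-like age gradient of the published national figures but was
#' generated for this package, not copied from the NVSS publication (see the
#' file header in `inst/extdata`). For sensitivity to this choice, use
#' [synthesize_life_table()] or supply your own CSV via [read_life_table()].
#'
#' @return A [life_table()] covering ages 60-85.
#' @export
default_life_table <- function() {
  read_life_table(system.file("extdata", "us2017_lifetable_synthetic.csv",
                              package = "ipmncea", mustWork = TRUE))
}

#' Age-adjusted annual death probability
#'
#' Looks up the annual probability of death at a (possibly fractional) age by
#' linear interpolation between the bracketing integer ages. Ages above the
#' table's maximum clamp to the last tabulated `qx`; ages below the table's
#' minimum are an error.
#'
#' @param lt a [life_table()].
#' @param age age in years; vectorized.
#' @return Annual death probabilities.
#' @export
lookup_mortality <- function(lt, age) {
  if (any(age < lt$age[1L]))
    stop(sprintf("age %.3g below the life table's first age (%d)",
                 min(age), as.integer(lt$age[1L])), call. = FALSE)
  n <- nrow(lt)
  stats::approx(lt$age, lt$qx, xout = pmin(age, lt$age[n]),
                method = "linear", rule = 2)$y
}

#' Synthesize a Gompertz life table
#'
#' Generates a deterministic parametric life table with
#' `qx(age) = 1 - exp(-a * exp(b * age))`, clamped to `[0, 1]` — the Gompertz
#' form under which the force of mortality grows exponentially with age. With
#' the defaults (`a = 2e-5`, `b = 0.095`) the table is broadly comparable to
#' adult all-population mortality in a high-income country.
#'
#' @param a positive level parameter.
#' @param b positive slope parameter (log-increase of mortality per year).
#' @param ages integer ages to tabulate.
#' @return A [life_table()].
#' @export
synthesize_life_table <- function(a = 2e-5, b = 0.095, ages = 50:100) {
  if (!is.numeric(a) || a <= 0 || !is.numeric(b) || b <= 0)
    stop("Gompertz parameters 'a' and 'b' must be positive", call. = FALSE)
  qx <- 1 - exp(-a * exp(b * ages))
  life_table(ages, pmin(pmax(qx, 0), 1))
}
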