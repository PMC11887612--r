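#' Per-cell outcome probabilities
#'
#' @param p a numeric 2 x 2 x 2 array (or vector of length 8, filled in array
#'   order) of outcome probabilities indexed by \code{[x, m1, m2]}, all in
#'   [0, 1].
#' @return A \code{"cell_probs"} array with dimnames.
#' @export
cell_probs <- function(p) {
  p <- array(as.numeric(p), dim = c(2, 2, 2),
             dimnames = list(x = c("non_black", "black"),
                             m1 = c("opt", "nonopt"), m2 = c("opt", "nonopt")))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("all cell probabilities must lie in [0, 1]")
  structure(p, class = "cell_probs")
}

#' @export
print.cell_probs <- function(x, digits = 4, ...) {
  cat("Outcome probability per (race, BMI class, GWG class) cell\n")
  for (i in 1:2) {
    cat(if (i == 1) " non-Black:\n" else " Black:\n")
    m <- matrix(x[i, , ], 2, 2, dimnames = list(m1 = c("BMI opt", "BMI non-opt"),
                                                m2 = c("GWG opt", "GWG non-opt")))
    print(round(m, digits))
  }
  invisible(x)
}

#' Population-level causal contrasts implied by cell probabilities
#'
#' Forward-computes, from generating cell probabilities and a mediator
#' prevalence table, the true total effect and the three controlled direct
#' effects that the Bayesian model estimates: \code{te} is the
#' prevalence-weighted race contrast of outcome probability; \code{cde_m1}
#' and \code{cde_m2} fix one mediator at its optimal level and weight the
#' remaining cells by their conditional prevalence (the population quantity
#' targeted when pooled counts are fit for an index "treated as missing");
#' \code{cde_m1m2} is the plain (x, 1, 1) cell contrast.
#'
#' @param probs a \code{\link{cell_probs}} array.
#' @param prevalence a \code{\link{prevalence_table}}.
#' @return Named numeric vector \code{te}, \code{cde_m1}, \code{cde_m2},
#'   \code{cde_m1m2}.
#' @export
implied_contrasts <- function(probs, prevalence) {
  w <- rbind(prevalence_fractions(prevalence, 1), prevalence_fractions(prevalence, 2))
  ord <- cell_order()
  marg <- function(race, keep) {
    # keep: logical over the 4 mediator cells
    p <- vapply(seq_len(4), function(j) probs[race, ord$m1[j], ord$m2[j]], numeric(1))
    sum(w[race, keep] * p[keep]) / sum(w[race, keep])
  }
  all4 <- rep(TRUE, 4)
  m1_opt <- ord$m1 == 1L
  m2_opt <- ord$m2 == 1L
  c(te = marg(2, all4) - marg(1, all4),
    cde_m1 = marg(2, m1_opt) - marg(1, m1_opt),
    cde_m2 = marg(2, m2_opt) - marg(1, m2_opt),
    cde_m1m2 = probs[2, 1, 1] - probs[1, 1, 1])
}

#' Solve for cell probabilities hitting target TE and CDE values
#'
#' Inverts the causal contrasts so that simulations can be calibrated to
#' published effect sizes: given a mediator prevalence table, a target total
#' effect and optional controlled-direct-effect targets, returns cell outcome
#' probabilities whose implied contrasts equal the targets.
#'
#' The parameterization is minimal and always linear: every non-Black cell
#' carries the \code{baseline} rate; Black cells constrained by a CDE target
#' carry the required contrast (for a single-mediator target the constrained
#' cells share one rate, so the conditionally-weighted margin equals the
#' target regardless of prevalence); all remaining Black cells share one
#' common rate solved so the prevalence-weighted race contrast equals
#' \code{te_target}. The (non-optimal, non-optimal) cell is never constrained
#' by a CDE, so a solution always exists algebraically; any solved
#' probability outside [0, 1] is an explicit infeasibility error naming the
#' cell.
#'
#' @param prevalence a \code{\link{prevalence_table}}.
#' @param te_target target total effect on the probability-difference scale.
#' @param cde_targets optional named list/vector with any of \code{M1},
#'   \code{M2}, \code{M1M2}: target controlled direct effects.
#' @param baseline outcome probability shared by all non-Black cells.
#' @return A \code{\link{cell_probs}} array; the implied contrasts are
#'   forward-verified against the targets to 1e-12 before returning.
#' @examples
#' prev <- prevalence_table(rep(25, 8))
#' calibrate_cell_probs(prev, te_target = 0.01, baseline = 0.05)
#' @export
calibrate_cell_probs <- function(prevalence, te_target, cde_targets = NULL,
                                 baseline = 0.05) {
  if (missing(te_target) || is.null(te_target) || is.na(te_target))
    stop("te_target is required")
  if (baseline < 0 || baseline > 1) stop("baseline must lie in [0, 1]")
  cde_targets <- as.list(cde_targets)
  unknown <- setdiff(names(cde_targets), c("M1", "M2", "M1M2"))
  if (length(unknown))
    stop("unknown CDE margin(s): ", paste(unknown, collapse = ", "))

  w2 <- matrix(NA_real_, 2, 2)  # Black prevalence fractions [m1, m2]
  ord <- cell_order()
  frac <- prevalence_fractions(prevalence, 2)
  for (j in 1:4) w2[ord$m1[j], ord$m2[j]] <- frac[j]

  p2 <- matrix(NA_real_, 2, 2)  # Black cell rates [m1, m2]; NA = free
  b <- baseline
  if (!is.null(cde_targets[["M1M2"]])) p2[1, 1] <- b + cde_targets[["M1M2"]]
  if (!is.null(cde_targets[["M1"]])) {
    # conditional weights within m1 = 1: w[1,1], w[1,2]
    if (is.na(p2[1, 1])) {
      p2[1, 1] <- p2[1, 2] <- b + cde_targets[["M1"]]
    } else {
      u <- w2[1, ] / sum(w2[1, ])
      if (u[2] == 0) stop("cannot meet M1 target: no prevalence mass in cell PO[2,1,2]")
      p2[1, 2] <- (b + cde_targets[["M1"]] - u[1] * p2[1, 1]) / u[2]
    }
  }
  if (!is.null(cde_targets[["M2"]])) {
    if (is.na(p2[1, 1])) {
      p2[1, 1] <- p2[2, 1] <- b + cde_targets[["M2"]]
    } else {
      v <- w2[, 1] / sum(w2[, 1])
      if (v[2] == 0) stop("cannot meet M2 target: no prevalence mass in cell PO[2,2,1]")
      p2[2, 1] <- (b + cde_targets[["M2"]] - v[1] * p2[1, 1]) / v[2]
    }
  }
  free <- is.na(p2)
  # prevalence-weighted Black mean must equal baseline + te_target
  need <- te_target + b - sum(w2[!free] * p2[!free])
  if (sum(w2[free]) == 0) {
    if (abs(need) > 1e-12)
      stop("over-constrained: no free cell mass left to meet te_target")
  } else {
    p2[free] <- need / sum(w2[free])
  }
  for (m1 in 1:2) for (m2 in 1:2)
    if (p2[m1, m2] < -1e-15 || p2[m1, m2] > 1 + 1e-15)
      stop(sprintf("infeasible: solved probability %.6g outside [0,1] in cell PO[2,%d,%d]",
                   p2[m1, m2], m1, m2))
  p2 <- pmin(pmax(p2, 0), 1)

  probs <- cell_probs(c(rbind(rep(b, 4), as.numeric(p2))))
  got <- implied_contrasts(probs, prevalence)
  want <- c(te = te_target,
            cde_m1 = if (is.null(cde_targets[["M1"]])) NA else cde_targets[["M1"]],
            cde_m2 = if (is.null(cde_targets[["M2"]])) NA else cde_targets[["M2"]],
            cde_m1m2 = if (is.null(cde_targets[["M1M2"]])) NA else cde_targets[["M1M2"]])
  chk <- !is.na(want)
  if (any(abs(got[chk] - want[chk]) > 1e-12))
    stop("internal calibration failure: forward-verified contrasts miss targets")
  probs
}

#' Synthetic-data generator configuration
#'
#' @param n_per_race births per race class; a scalar or a length-2 vector
#'   (non-Black, Black).
#' @param prevalence a \code{\link{prevalence_table}} giving each race's
#'   joint mediator distribution.
#' @param cell_probs a \code{\link{cell_probs}} array (applied to every
#'   outcome), or a named list of them, one per outcome to simulate.
#' @param missing_rates named per-field missingness probabilities in [0, 1].
#'   Recognised names: \code{height}, \code{prepreg_weight},
#'   \code{delivery_weight}, \code{gestation_weeks}, the five outcome names,
#'   and the shorthand \code{outcome} (applied to all five outcome flags).
#'   Unnamed scalar: applied to every field. Default: no missingness.
#' @param seed integer RNG seed.
#' @param level \code{"record"} to emit one row per birth,
#'   \code{"cell"} to emit aggregated \code{\link{cell_counts}} directly.
#' @return A validated \code{"generator_config"} list.
#' @export
generator_config <- function(n_per_race, prevalence, cell_probs,
                             missing_rates = 0, seed = 1L,
                             level = c("record", "cell")) {
  level <- match.arg(level)
  if (length(n_per_race) == 1L) n_per_race <- rep(n_per_race, 2L)
  if (length(n_per_race) != 2L || anyNA(n_per_race) || any(n_per_race < 0))
    stop("n_per_race must be one or two non-negative counts")
  if (!inherits(prevalence, "prevalence_table"))
    prevalence <- prevalence_table(prevalence)
  if (inherits(cell_probs, "cell_probs")) {
    cell_probs <- stats::setNames(rep(list(cell_probs), length(outcome_fields())),
                                  outcome_fields())
  }
  if (!is.list(cell_probs) || is.null(names(cell_probs)) ||
      !all(vapply(cell_probs, inherits, logical(1), "cell_probs")))
    stop("cell_probs must be a cell_probs array or a named list of them")
  mr <- stats::setNames(rep(0, length(c(anthro_fields(), outcome_fields()))),
                        c(anthro_fields(), outcome_fields()))
  if (length(missing_rates) == 1L && is.null(names(missing_rates))) {
    mr[] <- missing_rates
  } else {
    if ("outcome" %in% names(missing_rates)) {
      mr[outcome_fields()] <- missing_rates[["outcome"]]
      missing_rates <- missing_rates[names(missing_rates) != "outcome"]
    }
    bad <- setdiff(names(missing_rates), names(mr))
    if (length(bad)) stop("unknown missing_rates field(s): ", paste(bad, collapse = ", "))
    mr[names(missing_rates)] <- missing_rates
  }
  if (any(mr < 0 | mr > 1)) stop("missing_rates must lie in [0, 1]")
  structure(list(n_per_race = as.numeric(n_per_race), prevalence = prevalence,
                 cell_probs = cell_probs, missing_rates = mr,
                 seed = as.integer(seed), level = level),
            class = "generator_config")
}

# Sample uniformly from a union of intervals, with mass proportional to length.
runif_union <- function(n, intervals) {
  len <- vapply(intervals, function(iv) iv[2] - iv[1], numeric(1))
  pick <- sample.int(length(intervals), n, replace = TRUE, prob = len)
  lo <- vapply(intervals, `[`, numeric(1), 1L)[pick]
  hi <- vapply(intervals, `[`, numeric(1), 2L)[pick]
  stats::runif(n, lo, hi)
}

#' Simulate record-level natality-style data
#'
#' For each race, draws the joint mediator combination from the configured
#' prevalence, back-solves anthropometric fields so that record preparation
#' reproduces the drawn classes (BMI uniform within the class interval —
#' optimal [18.5, 25), non-optimal [15, 18.5) or [25, 45]; adjusted GWG
#' uniform within its interval — optimal [11.5, 16], non-optimal [0, 11.5) or
#' (16, 30]; height uniform 150-180 cm; gestation uniform 37-42 weeks),
#' draws each outcome Bernoulli with the record's cell probability, and
#' applies missing-completely-at-random masking per field.
#'
#' @param config a \code{\link{generator_config}} with \code{level = "record"}.
#' @return A data frame of birth records in the canonical column layout of
#'   \code{\link{read_birth_records}}, rows shuffled across races.
#' @export
simulate_records <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$level != "record")
    stop("config level is '", config$level, "'; expected 'record'")
  set.seed(config$seed)
  ord <- cell_order()
  races <- list()
  for (race in 1:2) {
    n <- config$n_per_race[race]
    if (n == 0) next
    cellj <- sample.int(4L, n, replace = TRUE,
                        prob = prevalence_fractions(config$prevalence, race))
    m1 <- ord$m1[cellj]
    m2 <- ord$m2[cellj]
    bmi <- numeric(n); gwg <- numeric(n)
    opt1 <- m1 == 1L
    bmi[opt1] <- stats::runif(sum(opt1), 18.5, 25.0)
    bmi[!opt1] <- runif_union(sum(!opt1), list(c(15, 18.5), c(25, 45)))
    opt2 <- m2 == 1L
    gwg[opt2] <- stats::runif(sum(opt2), 11.5, 16.0)
    gwg[!opt2] <- runif_union(sum(!opt2), list(c(0, 11.5), c(16.0, 30)))
    height <- stats::runif(n, 150, 180)
    weeks <- stats::runif(n, 37, 42)
    prepreg <- bmi * (height / 100)^2
    delivery <- prepreg + gwg * weeks / 40
    df <- data.frame(race_class = race, height = height, prepreg_weight = prepreg,
                     delivery_weight = delivery, gestation_weeks = weeks)
    bad <- setdiff(names(config$cell_probs), outcome_fields())
    if (length(bad))
      stop("record-level simulation requires canonical outcome names; got: ",
           paste(bad, collapse = ", "))
    for (oc in outcome_fields()) {
      p <- config$cell_probs[[oc]]
      # unconfigured outcome flags are filled with 0 (non-occurrence) so the
      # canonical record layout stays complete
      df[[oc]] <- if (is.null(p)) 0L
      else stats::rbinom(n, 1L, p[cbind(race, m1, m2)])
    }
    races[[race]] <- df
  }
  out <- do.call(rbind, races)
  if (is.null(out))
    return(data.frame(race_class = numeric(0), height = numeric(0),
                      prepreg_weight = numeric(0), delivery_weight = numeric(0),
                      gestation_weeks = numeric(0),
                      stats::setNames(as.data.frame(replicate(5, numeric(0), simplify = FALSE)),
                                      outcome_fields())))
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  for (f in names(config$missing_rates)) {
    rate <- config$missing_rates[[f]]
    if (rate > 0)
      out[[f]][stats::runif(nrow(out)) < rate] <- NA
  }
  out
}

#' Simulate aggregated cell counts
#'
#' Direct simulation at the aggregation level the model consumes: births per
#' cell are the (rounded) expected counts \code{n_per_race * prevalence} and
#' cases are Binomial(n, p) draws with the cell's outcome probability.
#'
#' @param config a \code{\link{generator_config}} with \code{level = "cell"}.
#' @return A named list of \code{\link{cell_counts}}, one per configured
#'   outcome (a single-outcome list if \code{cell_probs} was one array).
#' @export
simulate_cell_counts <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$level != "cell")
    stop("config level is '", config$level, "'; expected 'cell'")
  set.seed(config$seed)
  ord <- cell_order()
  full <- expand.grid(m2 = 1:2, m1 = 1:2, x = 1:2)[, c("x", "m1", "m2")]
  n <- numeric(8)
  for (i in seq_len(8)) {
    j <- which(ord$m1 == full$m1[i] & ord$m2 == full$m2[i])
    n[i] <- round(config$n_per_race[full$x[i]] *
                    prevalence_fractions(config$prevalence, full$x[i])[j])
  }
  out <- lapply(names(config$cell_probs), function(oc) {
    p <- config$cell_probs[[oc]][cbind(full$x, full$m1, full$m2)]
    r <- stats::rbinom(8L, size = n, prob = p)
    cell_counts(full$x, full$m1, full$m2, r, n, outcome = oc)
  })
  stats::setNames(out, names(config$cell_probs))
}
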