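#' Fit the Bayesian potential-outcomes mediation model
#'
#' The central fitting function. For each outcome's eight-cell count table it
#' draws posteriors for every potential-outcome node needed by the
#' disparity decomposition, then forms draw-wise contrasts: the total effect
#' TE = PO[2,NA,NA] - PO[1,NA,NA]; controlled direct effects with prepartum
#' BMI, adjusted GWG, or both fixed at optimal; and the percent of the
#' disparity attributable to each mediator scenario,
#' PA = 100 (TE - CDE) / TE, computed per draw. Summaries follow the
#' reporting conventions of the source model: posterior medians, equal-tailed
#' 95% credible intervals, TE scaled to cases per 1000 births, significance
#' as zero-exclusion.
#'
#' @param cells a \code{\link{cell_counts}} table (one outcome) or a named
#'   list of them.
#' @param S posterior draws per quantity (default 10,000, the kept-iteration
#'   count of the reference MCMC protocol).
#' @param seed master seed; every node's substream derives from it.
#' @param engine \code{"conjugate"} draws each node directly from its exact
#'   Beta posterior (the model factorizes into independent conjugate cells);
#'   \code{"gibbs"} replicates the iterative-sampler protocol (burn-in
#'   discarded, kept iterations pooled over chains) as a fidelity mode with
#'   identical stationary distribution.
#' @param burn_in,chains iterative-sampler settings, used when
#'   \code{engine = "gibbs"}.
#' @return An object of class \code{"po_mediation"}; see
#'   \code{\link{summary.po_mediation}}, \code{\link{coef.po_mediation}},
#'   \code{\link{plot.po_mediation}}, \code{\link{simulate.po_mediation}}.
#' @examples
#' prev <- prevalence_table(rep(25, 8))
#' probs <- calibrate_cell_probs(prev, te_target = 0.01, baseline = 0.05)
#' cfg <- generator_config(1e5, prev, list(cesarean = probs),
#'                         seed = 7, level = "cell")
#' fit <- po_mediate(simulate_cell_counts(cfg), S = 2000, seed = 7)
#' summary(fit)
#' @export
po_mediate <- function(cells, S = 10000, seed = 1L,
                       engine = c("conjugate", "gibbs"),
                       burn_in = 5000, chains = 2) {
  engine <- match.arg(engine)
  if (inherits(cells, "cell_counts"))
    cells <- stats::setNames(list(cells), attr(cells, "outcome"))
  if (!length(cells) || !all(vapply(cells, inherits, logical(1), "cell_counts")))
    stop("cells must be a cell_counts table or a named list of them")
  if (is.null(names(cells)))
    names(cells) <- vapply(cells, attr, character(1), "outcome")
  if (S < 100) stop("S must be at least 100")

  margins <- c("M1", "M2", "M1M2")
  outcomes <- lapply(cells, function(cc) {
    node <- function(x, m1, m2)
      node_draws(cc, x, m1, m2, S = S, seed = seed, engine = engine,
                 burn_in = burn_in, chains = chains)
    te <- posterior_draws(node(2, NA, NA)$values - node(1, NA, NA)$values,
                          seed = seed, master = seed, label = "TE")
    cde <- list(
      M1 = posterior_draws(node(2, 1, NA)$values - node(1, 1, NA)$values,
                           seed = seed, master = seed, label = "CDE_M1"),
      M2 = posterior_draws(node(2, NA, 1)$values - node(1, NA, 1)$values,
                           seed = seed, master = seed, label = "CDE_M2"),
      M1M2 = posterior_draws(node(2, 1, 1)$values - node(1, 1, 1)$values,
                             seed = seed, master = seed, label = "CDE_M1M2"))
    pa <- lapply(cde, function(d) percent_attributable(te, d))
    est <- c(list(TE = summarize_draws(te, "per1000")),
             stats::setNames(lapply(pa, summarize_draws, scale = "percent"),
                             paste0("PA_", margins)))
    list(cells = cc, te = te, cde = cde, pa = pa, estimates = est)
  })
  structure(list(outcomes = outcomes, S = S, seed = seed, engine = engine,
                 call = match.call()),
            class = "po_mediation")
}

# Draws for one PO node under the selected engine. Both engines target the
# same Beta(1 + r, 1 + n - r) posterior of the pooled counts; "gibbs" gets
# there by iterating the full-conditional sweep with burn-in and chains.
node_draws <- function(cells, x, m1, m2, S, seed, engine = "conjugate",
                       burn_in = 5000, chains = 2) {
  if (engine == "conjugate")
    return(posterior_margin(cells, x, m1, m2, S = S, seed = seed))
  pooled <- pool_margin(cells, x, m1, m2)
  lab <- node_label(m1, m2, pooled$r, pooled$n)
  set.seed(substream_seed(seed, lab))
  per <- ceiling(S / chains)
  vals <- numeric(0)
  for (ch in seq_len(chains)) {
    keep <- numeric(per)
    for (it in seq_len(burn_in + per)) {
      p <- stats::rbeta(1L, 1 + pooled$r, 1 + pooled$n - pooled$r)
      if (it > burn_in) keep[it - burn_in] <- p
    }
    vals <- c(vals, keep)
  }
  posterior_draws(vals[seq_len(S)], seed = seed, master = seed,
                  label = sprintf("PO[%d,%s,%s]", x, if (is.na(m1)) "NA" else m1,
                                  if (is.na(m2)) "NA" else m2))
}

#' @export
print.po_mediation <- function(x, ...) {
  cat("Bayesian potential-outcomes mediation fit\n")
  cat(sprintf("  outcomes: %s\n", paste(names(x$outcomes), collapse = ", ")))
  cat(sprintf("  %d posterior draws per quantity, engine = %s, seed = %d\n",
              x$S, x$engine, x$seed))
  cat("Use summary() for the disparity decomposition table.\n")
  invisible(x)
}

#' Disparity decomposition summary
#'
#' One row per outcome: the total racial disparity (cases per 1000 births)
#' and the percent of it eliminated when BMI, GWG, or both are fixed at
#' optimal, each a posterior median with an equal-tailed 95% credible
#' interval. Negative percentages mean the disparity would grow.
#'
#' @param object a \code{\link{po_mediate}} fit.
#' @param ... unused.
#' @return A \code{"summary.po_mediation"} data frame with columns
#'   \code{outcome}, \code{estimate_type}, \code{median}, \code{ci_low},
#'   \code{ci_high}, \code{significant}, \code{scale}.
#' @export
summary.po_mediation <- function(object, ...) {
  rows <- do.call(rbind, lapply(names(object$outcomes), function(oc) {
    est <- object$outcomes[[oc]]$estimates
    do.call(rbind, lapply(names(est), function(ty)
      data.frame(outcome = oc, estimate_type = ty,
                 median = est[[ty]]$median, ci_low = est[[ty]]$ci_low,
                 ci_high = est[[ty]]$ci_high, significant = est[[ty]]$significant,
                 scale = est[[ty]]$scale, stringsAsFactors = FALSE)))
  }))
  rownames(rows) <- NULL
  class(rows) <- c("summary.po_mediation", "data.frame")
  rows
}

#' @export
print.summary.po_mediation <- function(x, digits = 1, ...) {
  cat("Racial disparity and percent attributable to BMI/GWG\n")
  cat(sprintf("%-16s %22s %16s %16s %16s\n", "outcome", "TE (x1000)",
              "PA: BMI", "PA: GWG", "PA: both"))
  fmt <- function(row) {
    s <- sprintf("%.*f (%.*f, %.*f)", digits, row$median, digits, row$ci_low,
                 digits, row$ci_high)
    if (!row$significant) s <- paste0(s, "*")
    s
  }
  for (oc in unique(x$outcome)) {
    sub <- x[x$outcome == oc, ]
    get <- function(ty) fmt(sub[sub$estimate_type == ty, ])
    cat(sprintf("%-16s %22s %16s %16s %16s\n", oc, get("TE"),
                get("PA_M1"), get("PA_M2"), get("PA_M1M2")))
  }
  cat("* 95% credible interval includes zero (non-significant)\n")
  invisible(x)
}

#' @rdname summary.po_mediation
#' @param x a fit.
#' @export
as.data.frame.po_mediation <- function(x, ...) {
  out <- summary(x)
  class(out) <- "data.frame"
  out
}

#' Posterior medians of the reported effects
#'
#' @param object a \code{\link{po_mediate}} fit.
#' @param ... unused.
#' @return A matrix, outcomes by estimate types (\code{TE} on the per-1000
#'   scale; \code{PA_*} in percent), of posterior medians.
#' @export
coef.po_mediation <- function(object, ...) {
  types <- c("TE", "PA_M1", "PA_M2", "PA_M1M2")
  t(vapply(object$outcomes, function(o)
    vapply(types, function(ty) o$estimates[[ty]]$median, numeric(1)),
    numeric(length(types))))
}

#' Credible intervals for the reported effects
#'
#' @param object a \code{\link{po_mediate}} fit.
#' @param parm estimate types to include (default all).
#' @param level only 0.95 is available (the equal-tailed interval of the
#'   stored draws).
#' @param ... unused.
#' @return A matrix with one row per (outcome, estimate type) and columns
#'   \code{2.5 \%}, \code{97.5 \%}.
#' @export
confint.po_mediation <- function(object, parm = c("TE", "PA_M1", "PA_M2", "PA_M1M2"),
                                 level = 0.95, ...) {
  if (!isTRUE(all.equal(level, 0.95)))
    stop("only the stored 95% equal-tailed interval is available")
  parm <- match.arg(parm, several.ok = TRUE)
  rows <- expand.grid(outcome = names(object$outcomes), type = parm,
                      stringsAsFactors = FALSE)
  out <- t(mapply(function(oc, ty) {
    e <- object$outcomes[[oc]]$estimates[[ty]]
    c(e$ci_low, e$ci_high)
  }, rows$outcome, rows$type))
  dimnames(out) <- list(paste(rows$outcome, rows$type, sep = ":"),
                        c("2.5 %", "97.5 %"))
  out
}

#' Posterior density plots
#'
#' Kernel density of the posterior draws of the total effect (per 1000
#' births) for each outcome, with the zero reference line that defines
#' significance.
#'
#' @param x a \code{\link{po_mediate}} fit.
#' @param which \code{"TE"} or one of the PA margins.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.po_mediation <- function(x, which = c("TE", "PA_M1", "PA_M2", "PA_M1M2"), ...) {
  which <- match.arg(which)
  n <- length(x$outcomes)
  old <- graphics::par(mfrow = c(ceiling(n / 2), min(n, 2)))
  on.exit(graphics::par(old))
  for (oc in names(x$outcomes)) {
    o <- x$outcomes[[oc]]
    v <- if (which == "TE") o$te$values * 1000
    else o$pa[[sub("^PA_", "", which)]]$values
    v <- v[!is.na(v)]
    plot(stats::density(v), main = oc,
         xlab = if (which == "TE") "total effect (per 1000 births)"
         else "percent attributable", ...)
    graphics::abline(v = 0, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Posterior-predictive cell counts
#'
#' Simulates replicate case counts: for each replicate, a rate is drawn from
#' each cell's Beta posterior and cases are redrawn Binomial(n, rate) with
#' the observed births.
#'
#' @param object a \code{\link{po_mediate}} fit.
#' @param nsim number of replicate tables per outcome.
#' @param seed optional seed.
#' @param ... unused.
#' @return A named list (per outcome) of lists of \code{\link{cell_counts}}.
#' @export
simulate.po_mediation <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(object$outcomes, function(o) {
    cc <- o$cells
    lapply(seq_len(nsim), function(k) {
      p <- stats::rbeta(8L, 1 + cc$r, 1 + cc$n - cc$r)
      cell_counts(cc$x, cc$m1, cc$m2, stats::rbinom(8L, cc$n, p), cc$n,
                  outcome = attr(cc, "outcome"))
    })
  })
}
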