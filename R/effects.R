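#' Posterior total effect of race
#'
#' The marginal race contrast in outcome probability,
#' Prob(Y | X = 2) - Prob(Y | X = 1), computed draw-wise from the posteriors
#' of the two fully-collapsed margins PO[2, NA, NA] and PO[1, NA, NA].
#'
#' @param cells a \code{\link{cell_counts}} table.
#' @param S number of posterior draws.
#' @param seed master seed (substreams per margin are derived from it, see
#'   \code{\link{posterior_margin}}).
#' @return A \code{\link{posterior_draws}} object with values in [-1, 1].
#' @export
total_effect <- function(cells, S = 10000, seed = 1L) {
  po2 <- posterior_margin(cells, 2, NA, NA, S = S, seed = seed)
  po1 <- posterior_margin(cells, 1, NA, NA, S = S, seed = seed)
  posterior_draws(po2$values - po1$values, seed = seed, master = seed, label = "TE")
}

#' Posterior controlled direct effect
#'
#' The race contrast with one or both mediators fixed at their optimal
#' level 1 and any remaining mediator index treated as missing (collapsed):
#' \itemize{
#'   \item \code{"M1"}: PO[2,1,NA] - PO[1,1,NA]
#'   \item \code{"M2"}: PO[2,NA,1] - PO[1,NA,1]
#'   \item \code{"M1M2"}: PO[2,1,1] - PO[1,1,1]
#' }
#'
#' @param cells a \code{\link{cell_counts}} table.
#' @param margin which mediator(s) to fix at optimal.
#' @param S number of posterior draws.
#' @param seed master seed, shared with \code{\link{total_effect}} so that
#'   draw-wise percent-attributable computation is coherent.
#' @return A \code{\link{posterior_draws}} object.
#' @export
controlled_direct_effect <- function(cells, margin = c("M1", "M2", "M1M2"),
                                     S = 10000, seed = 1L) {
  margin <- match.arg(margin)
  idx <- switch(margin,
                M1 = list(m1 = 1, m2 = NA),
                M2 = list(m1 = NA, m2 = 1),
                M1M2 = list(m1 = 1, m2 = 1))
  po2 <- posterior_margin(cells, 2, idx$m1, idx$m2, S = S, seed = seed)
  po1 <- posterior_margin(cells, 1, idx$m1, idx$m2, S = S, seed = seed)
  posterior_draws(po2$values - po1$values, seed = seed, master = seed,
                  label = paste0("CDE_", margin))
}

#' Posterior percent attributable
#'
#' The share of the racial disparity eliminated by fixing the mediator(s) at
#' optimal, PA = 100 (TE - CDE) / TE, computed per paired posterior draw and
#' never from summarized medians (medians do not commute with ratios).
#' Negative PA means fixing the mediator(s) would increase the disparity.
#'
#' @param te,cde \code{\link{posterior_draws}} of the total effect and a
#'   controlled direct effect, with equal draw counts and drawn under the
#'   same master seed (paired draws).
#' @return A \code{\link{posterior_draws}} of PA values in percent. Draws
#'   where TE equals zero exactly are undefined, propagated as \code{NA} and
#'   excluded from summaries; their count is kept in attribute
#'   \code{"n_undefined"}.
#' @export
percent_attributable <- function(te, cde) {
  stopifnot(inherits(te, "posterior_draws"), inherits(cde, "posterior_draws"))
  if (te$S != cde$S)
    stop("te and cde must hold the same number of draws (paired computation)")
  if (!is.na(te$master) && !is.na(cde$master) && te$master != cde$master)
    stop("te and cde were drawn under different master seeds; PA requires paired draws")
  zero <- te$values == 0
  pa <- 100 * (te$values - cde$values) / te$values
  pa[zero] <- NA_real_
  if (all(zero)) stop("all TE draws are exactly zero; PA is undefined")
  out <- posterior_draws(pa, seed = te$seed, master = te$master,
                         label = paste0("PA_", sub("^CDE_", "", cde$label)))
  attr(out, "n_undefined") <- sum(zero)
  out
}

#' Summarize posterior draws into an effect estimate
#'
#' Posterior median and equal-tailed 95% credible interval (the 2.5 and 97.5
#' percentiles of the draws), with the significance convention that an
#' effect is significant exactly when the interval excludes zero.
#'
#' @param draws a \code{\link{posterior_draws}} object with at least 100
#'   draws.
#' @param scale \code{"raw"} (probability difference), \code{"per1000"}
#'   (multiplied by 1000: cases per 1000 births), or \code{"percent"}
#'   (values already on the percent scale, e.g. PA).
#' @return An \code{"effect_estimate"} list: \code{median}, \code{ci_low},
#'   \code{ci_high}, \code{significant}, \code{scale}, \code{label},
#'   \code{n_undefined} (draws excluded as undefined).
#' @export
summarize_draws <- function(draws, scale = c("raw", "per1000", "percent")) {
  stopifnot(inherits(draws, "posterior_draws"))
  scale <- match.arg(scale)
  v <- draws$values[!is.na(draws$values)]
  if (length(v) < 100)
    stop("need at least 100 defined draws to summarize (got ", length(v), ")")
  mult <- if (scale == "per1000") 1000 else 1
  q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE) * mult
  structure(list(median = q[2], ci_low = q[1], ci_high = q[3],
                 significant = q[1] > 0 || q[3] < 0,
                 scale = scale, label = draws$label,
                 n_undefined = draws$S - length(v)),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 3, ...) {
  unit <- switch(x$scale, raw = "", per1000 = " per 1000", percent = "%")
  cat(sprintf("%s: %.*f%s (95%% CrI %.*f, %.*f)%s\n",
              if (nzchar(x$label)) x$label else "estimate",
              digits, x$median, unit, digits, x$ci_low, digits, x$ci_high,
              if (x$significant) "" else "  [non-significant]"))
  if (x$n_undefined > 0)
    cat(sprintf("  (%d undefined draws excluded)\n", x$n_undefined))
  invisible(x)
}
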