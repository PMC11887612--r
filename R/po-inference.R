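#' Deterministic substream seed
#'
#' Derives a reproducible per-quantity seed from one master seed and a text
#' label, so every table cell of a report can be regenerated in isolation.
#' The label hash is a polynomial rolling hash modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param label character label of the quantity.
#' @return An integer seed in [0, 2^31 - 1).
#' @export
substream_seed <- function(master, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer(((as.numeric(master) %% 2147483647) * 48271 + h) %% 2147483647)
}

#' Posterior draws container
#'
#' @param values numeric draws (rates in [0, 1], or contrasts in [-1, 1] /
#'   unbounded derived quantities).
#' @param seed the substream seed used to draw them.
#' @param label what the draws estimate.
#' @param master the master seed the substream was derived from, if any.
#' @return A \code{"posterior_draws"} list with elements \code{values},
#'   \code{S}, \code{seed}, \code{master}, \code{label}.
#' @export
posterior_draws <- function(values, seed = NA_integer_, label = "",
                            master = NA_integer_) {
  if (length(values) < 1L) stop("posterior draws must contain at least one value")
  structure(list(values = as.numeric(values), S = length(values),
                 seed = seed, master = master, label = label),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  q <- stats::quantile(x$values, c(0.025, 0.5, 0.975), names = FALSE, na.rm = TRUE)
  cat(sprintf("Posterior draws%s: S = %d, median %.5g, 95%% CrI (%.5g, %.5g)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$S, q[2], q[1], q[3]))
  invisible(x)
}

#' Exact conjugate posterior for one cell rate
#'
#' The model fits the case count of a cell as Binomial(n, p) with a
#' Uniform(0, 1) prior on the rate, so the posterior is Beta(1 + r,
#' 1 + n - r) exactly; this function draws from it directly. With no data
#' (n = 0) the draws are from the Uniform prior.
#'
#' @param r case count, \code{0 <= r <= n}.
#' @param n birth count.
#' @param S number of draws (default mirrors the 10,000 kept iterations of
#'   the reference MCMC protocol).
#' @param seed integer seed.
#' @param label optional label stored with the draws.
#' @param master optional master seed recorded for pairing checks.
#' @return A \code{\link{posterior_draws}} object with \code{S} independent
#'   Beta(1 + r, 1 + n - r) draws.
#' @examples
#' d <- posterior_cell(3, 10, S = 10000, seed = 42)
#' median(d$values)               # ~ qbeta(0.5, 4, 8) = 0.3235
#' @export
posterior_cell <- function(r, n, S = 10000, seed = 1L, label = "", master = NA_integer_) {
  if (length(r) != 1L || length(n) != 1L || is.na(r) || is.na(n))
    stop("r and n must be single non-missing counts")
  if (r < 0 || n < 0 || r > n) stop("need 0 <= r <= n (got r = ", r, ", n = ", n, ")")
  if (S < 1) stop("S must be >= 1")
  set.seed(seed)
  posterior_draws(stats::rbeta(S, 1 + r, 1 + n - r), seed = seed,
                  label = label, master = master)
}

# Pool (r, n) over the cells selected by a margin specification.
# m1/m2 = NA means "treated as missing": collapse (sum counts over) that index.
pool_margin <- function(cells, x, m1 = NA, m2 = NA) {
  sel <- cells$x == x &
    (if (is.na(m1)) TRUE else cells$m1 == m1) &
    (if (is.na(m2)) TRUE else cells$m2 == m2)
  list(r = sum(cells$r[sel]), n = sum(cells$n[sel]))
}

# Label identifying a PO node by its collapse pattern and pooled data (not by
# the race index): two nodes holding the same pooled counts under the same
# pattern share a draw stream, which makes race-contrast draws exactly
# antisymmetric under relabelling of the race classes.
node_label <- function(m1, m2, r, n) {
  sprintf("PO[m1=%s,m2=%s|r=%.0f,n=%.0f]",
          if (is.na(m1)) "NA" else m1, if (is.na(m2)) "NA" else m2, r, n)
}

#' Posterior for a cell or collapsed margin
#'
#' Estimates PO[x, m1, m2] where either mediator index may be \code{NA}
#' ("treated as missing"): the case and birth counts are summed over every
#' collapsed index and the pooled counts are fit with the same
#' Binomial-Uniform model, exactly as supplying the aggregated row to the
#' likelihood would.
#'
#' @param cells a \code{\link{cell_counts}} table.
#' @param x race index, 1 or 2.
#' @param m1,m2 mediator indices: 1, 2, or \code{NA} to collapse.
#' @param S number of draws.
#' @param seed master seed; the draw substream is derived from it and from
#'   the node's collapse pattern and pooled counts via
#'   \code{\link{substream_seed}}.
#' @return A \code{\link{posterior_draws}} object. An empty collapse
#'   (pooled n = 0) degrades to the Uniform(0, 1) prior with a warning.
#' @export
posterior_margin <- function(cells, x, m1 = NA, m2 = NA, S = 10000, seed = 1L) {
  stopifnot(inherits(cells, "cell_counts"), x %in% 1:2)
  pooled <- pool_margin(cells, x, m1, m2)
  if (pooled$n == 0)
    warning("margin PO[", x, ",", if (is.na(m1)) "NA" else m1, ",",
            if (is.na(m2)) "NA" else m2,
            "] has no births; posterior equals the Uniform(0,1) prior")
  lab <- node_label(m1, m2, pooled$r, pooled$n)
  posterior_cell(pooled$r, pooled$n, S = S, seed = substream_seed(seed, lab),
                 label = sprintf("PO[%d,%s,%s]", x, if (is.na(m1)) "NA" else m1,
                                 if (is.na(m2)) "NA" else m2),
                 master = seed)
}

#' Gibbs-style iterative sampler over the eight cells
#'
#' A fidelity/validation mode replicating the reference MCMC protocol: each
#' sweep draws every cell rate from its full conditional (which, because the
#' eight binomial cells are a priori independent, is the conjugate
#' Beta(1 + r, 1 + n - r)), a burn-in is discarded, and kept iterations from
#' chains started at disparate values are pooled. The potential scale
#' reduction factor (split-chain R-hat) is reported per cell; values above
#' 1.05 trigger a warning and a convergence flag.
#'
#' @param cells a \code{\link{cell_counts}} table.
#' @param burn_in iterations discarded per chain (default 5000).
#' @param kept iterations collected per chain (default 10000).
#' @param chains number of chains, at least 2 for the diagnostic.
#' @param seed integer seed.
#' @return A named list, one element per cell (name \code{"PO[x,m1,m2]"}),
#'   each a \code{\link{posterior_draws}} of the pooled kept iterations with
#'   attributes \code{rhat} and \code{converged}.
#' @export
gibbs_mode <- function(cells, burn_in = 5000, kept = 10000, chains = 2, seed = 1L) {
  stopifnot(inherits(cells, "cell_counts"))
  if (burn_in < 0 || kept < 1) stop("need burn_in >= 0 and kept >= 1")
  set.seed(seed)
  n_iter <- burn_in + kept
  # disparate deterministic starts spread over (0, 1)
  starts <- seq(0.05, 0.95, length.out = max(chains, 1L))
  draws <- array(NA_real_, dim = c(kept, chains, 8L))
  for (ch in seq_len(chains)) {
    p <- rep(starts[ch], 8L)
    for (it in seq_len(n_iter)) {
      # full-conditional sweep over the 8 cells
      p <- stats::rbeta(8L, 1 + cells$r, 1 + cells$n - cells$r)
      if (it > burn_in) draws[it - burn_in, ch, ] <- p
    }
  }
  out <- vector("list", 8L)
  names(out) <- sprintf("PO[%d,%d,%d]", cells$x, cells$m1, cells$m2)
  for (i in seq_len(8L)) {
    mat <- draws[, , i, drop = FALSE][, , 1L, drop = TRUE]
    mat <- matrix(mat, nrow = kept)
    rhat <- split_rhat(mat)
    pd <- posterior_draws(as.numeric(mat), seed = seed, label = names(out)[i],
                          master = seed)
    attr(pd, "rhat") <- rhat
    attr(pd, "converged") <- is.na(rhat) || rhat <= 1.05
    if (!is.na(rhat) && rhat > 1.05)
      warning("possible non-convergence in ", names(out)[i],
              ": R-hat = ", round(rhat, 3))
    out[[i]] <- pd
  }
  out
}

# Split-chain potential scale reduction factor (Gelman-Rubin).
split_rhat <- function(mat) {
  n <- nrow(mat)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  split <- cbind(mat[seq_len(half), , drop = FALSE],
                 mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split); nn <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
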