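#' Effective sample size of an MCMC trace
#'
#' Spectral-density-at-zero estimate via an AR model fitted by AIC, i.e.
#' `n * var(x) / spec0`, the standard time-series ESS.
#'
#' @param x numeric chain.
#' @return effective sample size (capped at `length(x)`).
#' @export
mcmc_ess <- function(x) {
  n <- length(x)
  if (n < 10 || var(x) == 0) return(n)
  fit <- tryCatch(ar(x, aic = TRUE, order.max = min(30, n %/% 4)),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(n)
  spec0 <- fit$var.pred / (1 - sum(fit$ar))^2
  min(n, n * var(x) / spec0)
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac1` and last `frac2` of a chain,
#' standardised by spectral variance estimates of each window.
#'
#' @param x numeric chain.
#' @param frac1,frac2 window fractions (defaults 0.1 and 0.5).
#' @return z statistic (approximately N(0,1) at stationarity).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  x1 <- x[seq_len(max(2, floor(frac1 * n)))]
  x2 <- x[(n - max(2, floor(frac2 * n)) + 1):n]
  sv <- function(z) {
    nz <- length(z)
    if (var(z) == 0) return(list(v = 0, n = nz))
    fit <- tryCatch(ar(z, aic = TRUE, order.max = min(20, nz %/% 4)),
                    error = function(e) NULL)
    v <- if (is.null(fit) || length(fit$ar) == 0) var(z) else
      fit$var.pred / (1 - sum(fit$ar))^2
    list(v = v, n = nz)
  }
  s1 <- sv(x1); s2 <- sv(x2)
  denom <- sqrt(s1$v / s1$n + s2$v / s2$n)
  if (denom == 0) return(0)
  (mean(x1) - mean(x2)) / denom
}

#' Chain-health report for posterior draws
#'
#' ESS and Geweke z for every fixed effect, every variance, and each
#' region's total spatial effect.
#'
#' @param draws a `"posterior_draws"`.
#' @return data.frame with parameter, ess, geweke_z.
#' @export
chain_health <- function(draws) {
  traces <- as.list(as.data.frame(draws$beta))
  if (!is.null(draws$tau2) && ncol(draws$tau2))
    traces <- c(traces, as.list(as.data.frame(log(draws$tau2))))
  if (!is.null(draws$u)) {
    tot <- draws$u + draws$v
    colnames(tot) <- paste0("spatial:", colnames(tot))
    traces <- c(traces, as.list(as.data.frame(tot, check.names = FALSE)))
  }
  data.frame(parameter = names(traces),
             ess = vapply(traces, mcmc_ess, numeric(1)),
             geweke_z = vapply(traces, geweke_z, numeric(1)),
             row.names = NULL)
}
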