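#' Two-tailed simulation probability
#'
#' Twice the number of simulated values strictly greater than the observed
#' value, divided by the number of simulations, capped at 1. A high value
#' means the observation sits comfortably inside the simulated distribution
#' (failure to reject the scenario); ties count as "not higher".
#'
#' @param values numeric vector of replicate statistics.
#' @param observed observed value of the statistic.
#' @return probability in `[0, 1]`.
#' @export
two_tailed_p <- function(values, observed) {
  if (length(values) == 0L) stop("empty simulated distribution")
  min(1, 2 * sum(values > observed) / length(values))
}

#' Empirical log-likelihood of an observed value under a simulated
#' distribution
#'
#' A histogram (Freedman-Diaconis by default) is fitted to the replicate
#' values. In the default `"product"` mode the log-likelihood is
#' `ln(f(obs) * f_max)`, the product of the empirical density at the
#' observed value and the modal density: sharply concentrated
#' distributions that do cover the observation score higher than diffuse
#' ones, which is what makes scenario recovery work (see the package
#' vignette for the simulation evidence). The alternative `"ratio"` mode
#' normalizes instead, `L = f(obs)/f_max`, so `lnL <= 0` with 0 attained
#' in the modal bin; it ranks scenarios by relative position only and is
#' kept for comparison. Zero-count bins (and an observed value outside the
#' histogram support, which raises a warning) are floored at half a count,
#' `0.5/(n * binwidth)`, so the result is always finite.
#'
#' @param values replicate statistics (at least 10).
#' @param observed observed value.
#' @param mode `"product"` (default) or `"ratio"`.
#' @param bins `"fd"` for Freedman-Diaconis, a single integer for that many
#'   equal-width bins, or a full numeric vector of break points.
#' @return scalar log-likelihood.
#' @export
empirical_lnl <- function(values, observed, mode = c("product", "ratio"),
                          bins = "fd") {
  mode <- match.arg(mode)
  n <- length(values)
  if (n < 10L) stop("need at least 10 replicates for the empirical density")
  if (diff(range(values)) == 0) {
    # degenerate distribution: single unit-width bin
    width <- 1
    dens <- n / (n * width)
    floor_d <- 0.5 / (n * width)
    f_obs <- if (observed == values[1L]) dens else {
      warning("observed value outside histogram support; floored density used")
      floor_d
    }
    return(if (mode == "ratio") log(f_obs) - log(dens) else log(f_obs * dens))
  }
  breaks <- if (identical(bins, "fd")) "FD"
            else if (length(bins) == 1L) as.integer(bins)
            else as.numeric(bins)
  hh <- hist(values, breaks = breaks, plot = FALSE,
             include.lowest = TRUE, right = FALSE)
  width <- diff(hh$breaks)
  dens <- hh$counts / (n * width)
  floor_d <- 0.5 / (n * mean(width))
  dens[dens == 0] <- 0.5 / (n * width[dens == 0])
  f_max <- max(dens)
  bin <- findInterval(observed, hh$breaks, rightmost.closed = TRUE)
  if (bin < 1L || bin > length(dens)) {
    warning("observed value outside histogram support; floored density used")
    f_obs <- floor_d
  } else {
    f_obs <- dens[bin]
  }
  if (mode == "ratio") log(f_obs) - log(f_max) else log(f_obs * f_max)
}

#' Akaike table from per-scenario log-likelihoods
#'
#' `AIC = -2 lnL + 2K`, `dAIC = AIC - min(AIC)`, raw weights
#' `exp(-dAIC/2)` normalized to sum to one across the compared scenarios.
#' Scenarios within `dAIC < 2` of the best are flagged as equally
#' plausible. Non-finite log-likelihoods drop the scenario with a warning.
#'
#' @param lnl named numeric vector of log-likelihoods (>= 2 scenarios).
#' @param K free parameters per scenario (2 throughout this design).
#' @return data.frame with `scenario`, `lnL`, `AIC`, `delta_aic`, `aicw`,
#'   `plausible`.
#' @export
aic_table <- function(lnl, K = 2) {
  if (is.null(names(lnl))) names(lnl) <- paste0("model", seq_along(lnl))
  bad <- !is.finite(lnl)
  if (any(bad)) {
    warning("excluding scenarios with non-finite lnL: ",
            paste(names(lnl)[bad], collapse = ", "))
    lnl <- lnl[!bad]
  }
  if (length(lnl) < 2L) stop("need at least 2 scenarios to compare")
  aic <- -2 * lnl + 2 * K
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  data.frame(scenario = names(lnl), lnL = unname(lnl), AIC = unname(aic),
             delta_aic = unname(delta), aicw = unname(w / sum(w)),
             plausible = unname(delta < 2),
             stringsAsFactors = FALSE)
}

#' Akaike weights straight from delta-AIC values
#'
#' Convenience for recomputing weight columns from published delta-AIC
#' values: `exp(-d/2)` normalized to sum to one.
#' @param delta_aic numeric vector of delta-AIC values.
#' @return numeric vector of weights summing to 1.
#' @export
aicw_from_delta <- function(delta_aic) {
  w <- exp(-delta_aic / 2)
  w / sum(w)
}

#' Compare observed diversity against simulated scenario distributions
#'
#' The model-selection core: for every locus and statistic, the observed
#' value is scored against each scenario's replicate distribution by the
#' two-tailed probability and the empirical log-likelihood, and scenarios
#' are ranked by Akaike weight. The best scenario per statistic is the one
#' with maximal AICw; the overall best treats the statistics as independent
#' evidence, summing log-likelihoods across them into one combined AIC
#' comparison (the scenarios share the same K, which is not summed).
#'
#' @param observed data.frame with columns `locus`, `statistic` (`"h"` or
#'   `"pi"`) and `value`.
#' @param sims nested list: `sims[[locus]][[scenario]]` is a
#'   `simulated_distribution` (see [run_scenario_replicates()]).
#' @param lnl_mode,bins passed to [empirical_lnl()].
#' @param K free parameters per scenario.
#' @return object of class `scenario_selection` with the long-format
#'   `table`, the per-statistic `best` data.frame, `overall_best`, and the
#'   call parameters. Has `print`, `summary` and `plot` methods.
#' @export
select_scenarios <- function(observed, sims, lnl_mode = "product",
                             bins = "fd", K = 2) {
  stopifnot(all(c("locus", "statistic", "value") %in% names(observed)))
  rows <- list()
  for (i in seq_len(nrow(observed))) {
    loc <- observed$locus[i]
    stat <- observed$statistic[i]
    obs <- observed$value[i]
    if (is.null(sims[[loc]]))
      stop("no simulated distributions for locus ", loc)
    scen_names <- names(sims[[loc]])
    lnl <- setNames(numeric(length(scen_names)), scen_names)
    pval <- lnl
    for (s in scen_names) {
      dist <- sims[[loc]][[s]]
      vals <- dist[[stat]]
      if (is.null(vals))
        stop("scenario ", s, " has no simulated '", stat, "' distribution")
      pval[s] <- two_tailed_p(vals, obs)
      lnl[s] <- empirical_lnl(vals, obs, mode = lnl_mode, bins = bins)
    }
    tab <- aic_table(lnl, K = K)
    tab$P <- unname(pval[tab$scenario])
    tab$locus <- loc
    tab$statistic <- stat
    tab$observed <- obs
    rows[[length(rows) + 1L]] <- tab
  }
  table <- do.call(rbind, rows)
  table <- table[, c("locus", "statistic", "observed", "scenario", "P",
                     "lnL", "AIC", "delta_aic", "aicw", "plausible")]
  best <- do.call(rbind, lapply(split(table, paste(table$locus, table$statistic)),
    function(g) g[which.max(g$aicw),
                  c("locus", "statistic", "scenario", "aicw")]))
  rownames(best) <- NULL
  tot_lnl <- tapply(table$lnL, table$scenario, sum)
  combined <- aic_table(setNames(as.numeric(tot_lnl), names(tot_lnl)), K = K)
  structure(list(table = table, best = best, combined = combined,
                 overall_best = combined$scenario[which.max(combined$aicw)],
                 lnl_mode = lnl_mode, bins = bins, K = K,
                 sims = sims, observed = observed),
            class = "scenario_selection")
}

#' @export
print.scenario_selection <- function(x, digits = 3, ...) {
  cat("Scenario selection by empirical likelihood / Akaike weights\n")
  tab <- x$table
  tab$P <- round(tab$P, digits)
  tab$lnL <- round(tab$lnL, digits)
  tab$delta_aic <- round(tab$delta_aic, digits)
  tab$aicw <- round(tab$aicw, digits)
  print(tab[, c("locus", "statistic", "scenario", "P", "delta_aic",
                "aicw", "plausible")], row.names = FALSE)
  cat("overall best scenario:", x$overall_best, "\n")
  invisible(x)
}

#' @export
summary.scenario_selection <- function(object, ...) {
  cat("Best scenario per statistic:\n")
  print(object$best, row.names = FALSE)
  cat("\nCombined evidence (summed lnL across statistics):\n")
  comb <- object$combined
  comb[-1L] <- lapply(comb[-1L], function(v) if (is.numeric(v)) round(v, 4) else v)
  print(comb, row.names = FALSE)
  cat("\noverall best scenario:", object$overall_best, "\n")
  invisible(object)
}

#' @export
plot.scenario_selection <- function(x, locus = NULL, statistic = "h", ...) {
  locus <- locus %||% x$observed$locus[1L]
  scen <- names(x$sims[[locus]])
  obs <- x$observed$value[x$observed$locus == locus &
                          x$observed$statistic == statistic][1L]
  op <- par(mfrow = c(length(scen), 1L), mar = c(3, 4, 2, 1))
  on.exit(par(op))
  for (s in scen) {
    vals <- x$sims[[locus]][[s]][[statistic]]
    hist(vals, breaks = "FD", main = paste(s, "-", locus, statistic),
         xlab = statistic, col = "grey85", border = "grey60",
         xlim = range(c(vals, obs)))
    abline(v = obs, col = "red3", lwd = 2)
  }
  invisible(x)
}
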