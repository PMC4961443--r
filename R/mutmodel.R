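#' GTR-family finite-sites mutation model
#'
#' Builds the scaled rate matrix for a nested GTR-family model with optional
#' continuous gamma rate heterogeneity. Exchangeabilities are given in the
#' order (AC, AG, AT, CG, CT, GT) and are constrained by model class:
#'
#' * `JC`: all equal, uniform base frequencies;
#' * `HKY`: transitions (AG, CT) share one rate, transversions another;
#' * `TVM`: AG = CT, the four transversions free;
#' * `TIM2`: AC = AT and CG = GT, transitions free;
#' * `GTR`: all six free.
#'
#' The generator is scaled so the mean substitution rate per site equals 1;
#' the per-site per-generation rate is then `mu` times the site's gamma
#' multiplier. Multipliers are continuous draws from `Gamma(alpha, alpha)`
#' (mean 1), drawn once per simulated locus.
#'
#' @param model one of `"JC"`, `"HKY"`, `"TVM"`, `"TIM2"`, `"GTR"`.
#' @param mu per-site per-generation mutation rate.
#' @param L number of sites.
#' @param gamma_shape gamma shape `alpha` (> 0) or `NULL`/`Inf` for uniform
#'   rates.
#' @param freqs base frequencies (A, C, G, T); default uniform. Fitting a
#'   model to data usually supplies the empirical frequencies here.
#' @param exchangeabilities named or positional numeric of length 6
#'   (AC, AG, AT, CG, CT, GT); defaults to 1 within the class constraints.
#' @return object of class `mutation_model` with the scaled generator `Q`.
#' @export
mutation_model <- function(model = c("JC", "HKY", "TVM", "TIM2", "GTR"),
                           mu, L, gamma_shape = NULL, freqs = NULL,
                           exchangeabilities = NULL) {
  model <- match.arg(toupper(model[1L]), c("JC", "HKY", "TVM", "TIM2", "GTR"))
  stopifnot(mu >= 0, L >= 1)
  if (is.null(freqs)) freqs <- rep(0.25, 4)
  if (length(freqs) != 4 || any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("freqs must be 4 non-negative values summing to 1")
  s <- exchangeabilities %||% rep(1, 6)
  if (length(s) != 6 || any(s < 0)) stop("need 6 non-negative exchangeabilities")
  names(s) <- c("AC", "AG", "AT", "CG", "CT", "GT")
  # enforce class constraints by averaging the tied entries
  tie <- function(s, i, j) { s[c(i, j)] <- mean(s[c(i, j)]); s }
  s <- switch(model,
    JC = rep(mean(s), 6),
    HKY = { s <- tie(s, "AG", "CT")
            s[c("AC", "AT", "CG", "GT")] <- mean(s[c("AC", "AT", "CG", "GT")]); s },
    TVM = tie(s, "AG", "CT"),
    TIM2 = tie(tie(s, "AC", "AT"), "CG", "GT"),
    GTR = s)
  if (model == "JC") freqs <- rep(0.25, 4)
  names(s) <- c("AC", "AG", "AT", "CG", "CT", "GT")
  bases <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (p in seq_len(6)) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    Q[i, j] <- s[p] * freqs[j]
    Q[j, i] <- s[p] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix")
  Q <- Q / scale
  if (!is.null(gamma_shape) && is.finite(gamma_shape) && gamma_shape <= 0)
    stop("gamma_shape must be positive")
  structure(list(model = model, mu = mu, L = as.integer(L),
                 gamma_shape = gamma_shape, freqs = freqs,
                 exchangeabilities = s, Q = Q),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  g <- if (is.null(x$gamma_shape) || !is.finite(x$gamma_shape)) "uniform rates"
       else sprintf("+G alpha = %.4g", x$gamma_shape)
  cat(sprintf("<mutation_model> %s (%s), mu = %.4g /site/generation, L = %d\n",
              x$model, g, x$mu, x$L))
  invisible(x)
}

# per-site rates (mu x gamma multiplier); draws L gamma variates
draw_site_rates <- function(model) {
  a <- model$gamma_shape
  if (is.null(a) || !is.finite(a)) return(rep(model$mu, model$L))
  model$mu * rgamma(model$L, shape = a, rate = a)
}
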