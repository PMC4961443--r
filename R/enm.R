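#' True Skill Statistic
#'
#' `TSS = sensitivity + specificity - 1` from a presence/absence confusion
#' table: `a` presences predicted present, `b` absences predicted present,
#' `c` presences predicted absent, `d` absences predicted absent.
#' Invariant to scaling all counts; 1 for a perfect prediction, 0 for one
#' independent of the truth.
#'
#' @param a,b,c,d confusion counts, or `a` may be a length-4 vector
#'   `(a, b, c, d)`.
#' @return TSS in `[-1, 1]`.
#' @export
tss <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b) && length(a) == 4L) { b <- a[2L]; c <- a[3L]; d <- a[4L]; a <- a[1L] }
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("negative confusion counts")
  if (a + c <= 0 || b + d <= 0)
    stop("TSS undefined: empty presence or absence margin")
  unname(a / (a + c) + d / (b + d) - 1)
}

#' Suitability stack container
#'
#' A 4-d array of suitability predictions indexed by
#' (cell, ENM method, AOGCM, time), values in `[0, 1]`, complete crossing
#' of methods and climate models within each time.
#'
#' @param values numeric array `cells x enm x aogcm x time` (dimnames
#'   optional; defaults are generated).
#' @return object of class `suitability_stack` (the validated array).
#' @export
suitability_stack <- function(values) {
  stopifnot(is.array(values), length(dim(values)) == 4L)
  if (any(values < 0 | values > 1)) stop("suitability values must be in [0, 1]")
  dn <- dimnames(values) %||% vector("list", 4L)
  defaults <- list(paste0("cell", seq_len(dim(values)[1L])),
                   paste0("enm", seq_len(dim(values)[2L])),
                   paste0("gcm", seq_len(dim(values)[3L])),
                   paste0("time", seq_len(dim(values)[4L])))
  for (i in 1:4) if (is.null(dn[[i]])) dn[[i]] <- defaults[[i]]
  dimnames(values) <- dn
  structure(values, class = c("suitability_stack", "array"))
}

#' TSS-weighted ensemble consensus
#'
#' Model instances (ENM x AOGCM) with `TSS < tss_min` are dropped; the
#' remaining suitabilities are averaged per cell and time with the TSS
#' values as weights.
#'
#' @param stack a [suitability_stack()].
#' @param tss_weights numeric matrix `enm x aogcm` of TSS scores (or a
#'   vector recycled across AOGCMs).
#' @param tss_min filtering threshold (default 0.5).
#' @return matrix `cells x time` of consensus suitability, with the
#'   surviving weights as attribute `weights`.
#' @export
weighted_consensus <- function(stack, tss_weights, tss_min = 0.5) {
  stopifnot(inherits(stack, "suitability_stack"))
  d <- dim(stack)
  if (is.vector(tss_weights))
    tss_weights <- matrix(tss_weights, d[2L], d[3L])
  stopifnot(all(dim(tss_weights) == d[2:3]))
  keep <- tss_weights >= tss_min
  if (!any(keep)) stop("all models filtered out at TSS < ", tss_min)
  w <- ifelse(keep, tss_weights, 0)
  out <- matrix(0, d[1L], d[4L],
                dimnames = list(dimnames(stack)[[1L]], dimnames(stack)[[4L]]))
  for (t in seq_len(d[4L])) {
    acc <- matrix(0, d[1L], 1L)
    for (e in seq_len(d[2L]))
      for (g in seq_len(d[3L]))
        if (w[e, g] > 0) acc <- acc + w[e, g] * stack[, e, g, t]
    out[, t] <- acc / sum(w)
  }
  attr(out, "weights") <- w
  out
}

#' Lowest-presence percentile threshold
#'
#' The presence threshold is the 10th percentile (linear interpolation
#' between order statistics, `stats::quantile` type 7) of the consensus
#' suitability at the presence cells; cells at or above it are predicted
#' present.
#'
#' @param consensus numeric vector of per-cell consensus suitability (one
#'   time slice).
#' @param presence_cells indices of cells with occurrence records.
#' @param prob percentile (default 0.10).
#' @return list with `threshold` and logical `present`.
#' @export
presence_threshold_10pct <- function(consensus, presence_cells, prob = 0.10) {
  if (length(presence_cells) < 1L) stop("need at least one presence cell")
  thr <- unname(quantile(consensus[presence_cells], prob, type = 7))
  list(threshold = thr, present = consensus >= thr)
}

#' Hierarchical ANOVA variance partitioning of a suitability stack
#'
#' Per cell, the total sum of squares of the `enm x aogcm x time` response
#' is split into a time component (between time means), ENM and AOGCM
#' components nested in time (two-way factorial within each period, summed
#' across periods), their within-time interaction, and a residual defined
#' as the remainder (zero in this saturated design up to rounding).
#' Proportions sum to one per cell; cells with a constant response are
#' flagged `NA`.
#'
#' @param stack a [suitability_stack()].
#' @return object of class `variance_partition`: matrix `cells x 5` of
#'   proportional sums of squares (`time`, `enm`, `aogcm`, `interaction`,
#'   `residual`), with the pooled (SS-weighted) summary as attribute
#'   `pooled` and per-cell total SS as attribute `ss_total`.
#' @export
hierarchical_anova <- function(stack) {
  stopifnot(inherits(stack, "suitability_stack"))
  d <- dim(stack)
  nc <- d[1L]; E <- d[2L]; A <- d[3L]; TT <- d[4L]
  x <- unclass(stack)
  grand <- apply(x, 1L, mean)
  ss_total <- apply(sweep(x, 1L, grand)^2, 1L, sum)
  m_t <- apply(x, c(1L, 4L), mean)             # cells x time
  ss_time <- E * A * rowSums((m_t - grand)^2)
  ss_enm <- ss_aogcm <- ss_int <- numeric(nc)
  for (t in seq_len(TT)) {
    xt <- x[, , , t, drop = FALSE]
    dim(xt) <- c(nc, E, A)
    m_e <- apply(xt, c(1L, 2L), mean)          # cells x E
    m_a <- apply(xt, c(1L, 3L), mean)          # cells x A
    ss_enm <- ss_enm + A * rowSums((m_e - m_t[, t])^2)
    ss_aogcm <- ss_aogcm + E * rowSums((m_a - m_t[, t])^2)
    pred <- array(0, c(nc, E, A))
    for (e in seq_len(E)) for (g in seq_len(A))
      pred[, e, g] <- m_e[, e] + m_a[, g] - m_t[, t]
    ss_int <- ss_int + apply((xt - pred)^2, 1L, sum)
  }
  ss_res <- ss_total - ss_time - ss_enm - ss_aogcm - ss_int
  props <- cbind(time = ss_time, enm = ss_enm, aogcm = ss_aogcm,
                 interaction = ss_int, residual = ss_res) / ss_total
  props[ss_total == 0, ] <- NA_real_
  rownames(props) <- dimnames(stack)[[1L]]
  pooled <- colSums(props * ss_total, na.rm = TRUE) /
    sum(ss_total[ss_total > 0])
  structure(props, class = c("variance_partition", "matrix"),
            pooled = pooled, ss_total = ss_total)
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("<variance_partition> %d cells; pooled proportional SS:\n", nrow(x)))
  print(round(attr(x, "pooled"), 4))
  invisible(x)
}
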