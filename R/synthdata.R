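#' Specification of a synthetic sequence study
#'
#' Describes a complete synthetic input set mirroring the study design: 18
#' populations with the published sample sizes (235 samples), one
#' organellar locus of 1519 usable sites (TVM+G, alpha = 0.017, ploidy
#' factor 1) and one nuclear ITS-like locus of 506 usable sites (TIM2+G,
#' alpha = 0.094, ploidy factor 2), evolved under a named demographic
#' scenario at the default mutation rate of 3.12e-7 /site/generation.
#'
#' @param scenario scenario name (see [build_scenario()]).
#' @param seed master seed; every artifact is reproducible from
#'   `(spec, seed)` alone.
#' @param sample_sizes named per-population sample sizes.
#' @param loci list of per-locus settings (`L`, `model`, `gamma_shape`,
#'   `ploidy_factor`).
#' @param mu per-site per-generation mutation rate.
#' @return object of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(scenario = "RETRACTION", seed = 1L,
                                   sample_sizes = study_sample_sizes(),
                                   loci = default_loci(), mu = 3.12e-7) {
  scn <- build_scenario(scenario)
  stopifnot(sum(sample_sizes) >= 2, all(sample_sizes >= 0))
  if (length(sample_sizes) != scn$demes)
    stop("sample sizes must have one entry per deme")
  structure(list(scenario = scn, seed = as.integer(seed),
                 sample_sizes = sample_sizes, loci = loci, mu = mu),
            class = "synthetic_dataset_spec")
}

#' @rdname synthetic_dataset_spec
#' @export
default_loci <- function() {
  list(cpDNA = list(L = 1519L, model = "TVM", gamma_shape = 0.0170,
                    ploidy_factor = 1),
       ITS = list(L = 506L, model = "TIM2", gamma_shape = 0.0940,
                  ploidy_factor = 2))
}

# deterministic synthetic coordinates: population centroids scattered over
# a central-Brazil-like window, individuals jittered around them
.synth_coordinates <- function(pop_names, sample_sizes, seed) {
  set.seed(derive_seed(seed, "coords"))
  lat0 <- runif(length(pop_names), -24, -6)
  lon0 <- runif(length(pop_names), -58, -40)
  data.frame(
    sample_id = unlist(lapply(seq_along(pop_names), function(i)
      sprintf("%s_%02d", pop_names[i], seq_len(sample_sizes[i])))),
    population = rep(pop_names, sample_sizes),
    lat = rep(lat0, sample_sizes) + runif(sum(sample_sizes), -0.05, 0.05),
    lon = rep(lon0, sample_sizes) + runif(sum(sample_sizes), -0.05, 0.05),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic sequence dataset
#'
#' Runs the structured coalescent once per locus under the scenario in the
#' spec, evolves sequences, and (optionally) writes per-locus FASTA files,
#' the population map CSV and a truth record JSON (scenario, seeds, TMRCAs)
#' for recovery tests. Outputs are byte-identical across reruns with the
#' same spec.
#'
#' @param spec a [synthetic_dataset_spec()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list with `alignments` (named [locus_alignment()]s), `popmap`,
#'   `truth`, and file `paths` when written.
#' @export
generate_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  pops <- names(spec$sample_sizes) %||%
    sprintf("P%02d", seq_along(spec$sample_sizes))
  popmap <- .synth_coordinates(pops, spec$sample_sizes, spec$seed)
  alignments <- list()
  truth <- list(scenario = spec$scenario$name, seed = spec$seed,
                mu = spec$mu, tmrca = list(), locus_seed = list())
  for (locus in names(spec$loci)) {
    cfg <- spec$loci[[locus]]
    lseed <- derive_seed(spec$seed, paste0("locus:", locus))
    set.seed(lseed)
    trajs <- scenario_trajectories(spec$scenario,
                                   ploidy_factor = cfg$ploidy_factor)
    gen <- simulate_genealogy(trajs, spec$sample_sizes,
                              spec$scenario$migration)
    model <- mutation_model(cfg$model, mu = spec$mu, L = cfg$L,
                            gamma_shape = cfg$gamma_shape)
    aln <- evolve_sequences(gen, model, sample_ids = popmap$sample_id,
                            locus_name = locus)
    alignments[[locus]] <- aln
    truth$tmrca[[locus]] <- gen$tmrca
    truth$locus_seed[[locus]] <- lseed
  }
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(popmap = file.path(out_dir, "popmap.csv"),
                  truth = file.path(out_dir, "truth.json"))
    write.csv(popmap, paths$popmap, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    for (locus in names(alignments)) {
      paths[[locus]] <- file.path(out_dir, paste0(locus, ".fasta"))
      write_alignment(alignments[[locus]], paths[[locus]])
    }
  }
  list(alignments = alignments, popmap = popmap, truth = truth,
       paths = paths)
}

#' Generate a synthetic suitability stack with known variance structure
#'
#' Builds a `cells x enm x aogcm x time` suitability array as the logistic
#' transform of orthogonal effect components constructed per cell to carry
#' exact target shares of the linear-scale sum of squares: a time effect,
#' ENM and AOGCM effects nested in time, and the within-time interaction
#' holding the remainder. Also emits synthetic presence/absence confusion
#' counts per model instance (from a drawn skill level) and the ground
#' truth for recovery tests.
#'
#' @param n_cells number of grid cells.
#' @param shares named numeric: target proportional SS for `time`, `enm`,
#'   `aogcm` (remainder goes to the interaction); must sum to < 1.
#' @param n_enm,n_aogcm,n_time ensemble dimensions (defaults 12, 5, 3).
#' @param effect_sd linear-predictor scale; small values keep the logistic
#'   link near-linear around 0.5.
#' @param seed integer seed.
#' @param n_presence,n_absence evaluation counts behind the confusion
#'   tables.
#' @return list with `stack` (a [suitability_stack()]), `tss_weights`
#'   matrix, `confusion` (per-model counts), and `truth` (target shares,
#'   model skills, seed).
#' @export
generate_suitability_stack <- function(n_cells,
                                       shares = c(time = 0.5, enm = 0.3,
                                                  aogcm = 0.2),
                                       n_enm = 12L, n_aogcm = 5L,
                                       n_time = 3L, effect_sd = 0.25,
                                       seed = 1L, n_presence = 33L,
                                       n_absence = 33L) {
  stopifnot(n_cells >= 1, all(shares >= 0), sum(shares) <= 1)
  set.seed(derive_seed(seed, "suitability"))
  share_int <- 1 - sum(shares)
  # orthogonal unit-SS components per cell, then scaled to target shares
  comp <- function(draw) {
    ss <- sum(draw^2)
    if (ss == 0) draw else draw / sqrt(ss)
  }
  x <- array(0, c(n_cells, n_enm, n_aogcm, n_time))
  for (cell in seq_len(n_cells)) {
    t_eff <- comp(scale(rnorm(n_time), scale = FALSE)[, 1L])
    lin <- array(0, c(n_enm, n_aogcm, n_time))
    for (t in seq_len(n_time))
      lin[, , t] <- sqrt(shares[["time"]]) * t_eff[t] /
        sqrt(n_enm * n_aogcm)
    e_eff <- matrix(rnorm(n_enm * n_time), n_enm, n_time)
    e_eff <- sweep(e_eff, 2L, colMeans(e_eff))
    e_eff <- e_eff / sqrt(sum(e_eff^2))
    a_eff <- matrix(rnorm(n_aogcm * n_time), n_aogcm, n_time)
    a_eff <- sweep(a_eff, 2L, colMeans(a_eff))
    a_eff <- a_eff / sqrt(sum(a_eff^2))
    i_eff <- array(rnorm(n_enm * n_aogcm * n_time),
                   c(n_enm, n_aogcm, n_time))
    for (t in seq_len(n_time)) {
      m <- i_eff[, , t]
      m <- m - outer(rowMeans(m), rep(1, n_aogcm)) -
        outer(rep(1, n_enm), colMeans(m)) + mean(m)
      i_eff[, , t] <- m
    }
    i_eff <- i_eff / sqrt(sum(i_eff^2))
    for (t in seq_len(n_time)) {
      lin[, , t] <- lin[, , t] +
        sqrt(shares[["enm"]]) * matrix(e_eff[, t], n_enm, n_aogcm) /
          sqrt(n_aogcm) +
        sqrt(shares[["aogcm"]]) *
          matrix(a_eff[, t], n_enm, n_aogcm, byrow = TRUE) / sqrt(n_enm) +
        sqrt(share_int) * i_eff[, , t]
    }
    x[cell, , , ] <- stats::plogis(effect_sd * sqrt(n_enm * n_aogcm * n_time) *
                                   lin)
  }
  stack <- suitability_stack(x)
  skills <- matrix(runif(n_enm * n_aogcm, 0.3, 0.9), n_enm, n_aogcm)
  confusion <- vector("list", n_enm * n_aogcm)
  dim(confusion) <- c(n_enm, n_aogcm)
  tss_w <- matrix(0, n_enm, n_aogcm)
  for (e in seq_len(n_enm)) {
    for (g in seq_len(n_aogcm)) {
      sens <- spec_ <- (skills[e, g] + 1) / 2
      a <- round(sens * n_presence); cc <- n_presence - a
      d <- round(spec_ * n_absence); b <- n_absence - d
      confusion[[e, g]] <- c(a = a, b = b, c = cc, d = d)
      tss_w[e, g] <- tss(a, b, cc, d)
    }
  }
  list(stack = stack, tss_weights = tss_w, confusion = confusion,
       truth = list(shares = c(shares, interaction = share_int),
                    skills = skills, seed = seed))
}
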