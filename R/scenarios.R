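#' Study sample sizes per population
#'
#' The 18-population sampling design (235 individuals total), in the same
#' alphabetical population order used throughout the package.
#' @return named integer vector summing to 235.
#' @export
study_sample_sizes <- function() {
  c(ALT = 29L, ARA = 1L, BAG = 17L, BOD = 25L, BRA = 9L, GSV = 2L,
    ILS = 23L, MOC = 6L, MOO = 4L, PAN = 5L, PNA = 10L, PNI = 7L,
    POS = 21L, POT = 26L, SCA = 3L, SEL = 38L, SRQ = 2L, SUM = 7L)
}

.scenario_n1 <- c(PLAH = 10000, PPPH = 500, BOTH = 50000, RETRACTION = 100)
.scenario_ext <- c(PLAH = FALSE, PPPH = TRUE, BOTH = FALSE, RETRACTION = TRUE)

.canon_scenario_name <- function(name) {
  key <- toupper(gsub("[^A-Za-z+]", "", name))
  canon <- c(PLAH = "PLAH", PPPH = "PPPH", BOTH = "BOTH",
             "PLAH+PPPH" = "BOTH", RETRACTION = "RETRACTION",
             RANGERETRACTION = "RETRACTION")
  if (!key %in% names(canon))
    stop("unknown scenario '", name, "'; valid names: ",
         "PLAH, PPPH, Both (PLAH+PPPH), Retraction (Range Retraction)")
  unname(canon[key])
}

#' Build a named demographic scenario
#'
#' The four competing hypotheses share 18 demes of present size
#' `n0 = 1000`, a per-generation one-way migration probability of 0.01
#' toward the source deme, and 1750 generations between present and the
#' LGM (21 ky at a 12-year generation time). They differ in the deme size
#' at the LGM and in whether demes 2-18 go extinct backward at the LGM:
#'
#' * `PLAH` (Pleistocene Arc): `n1 = 10000`, no extinction — growth is
#'   positive backward (larger LGM populations);
#' * `Both` (`PLAH+PPPH`): `n1 = 50000`, no extinction;
#' * `PPPH` (Amazonian dry-forest shift): `n1 = 500`, extinction on;
#' * `Retraction`: `n1 = 100`, extinction on — lineages migrate to the
#'   source deme as the others shrink to extinction.
#'
#' Names are case-insensitive and accept the synonyms `"Range Retraction"`
#' and `"PLAH+PPPH"`. Every field can be overridden.
#'
#' @param name scenario name (or an existing `scenario`, returned as is
#'   after applying overrides).
#' @param ... field overrides (`n0`, `n1`, `demes`, `t_lgm`, `migration`,
#'   `extinction`, `n_reps`, `generation_time`).
#' @return object of class `scenario`.
#' @export
build_scenario <- function(name, ...) {
  if (inherits(name, "scenario")) {
    scn <- name
  } else {
    canon <- .canon_scenario_name(name)
    scn <- structure(list(name = canon, demes = 18L, n0 = 1000,
                          n1 = .scenario_n1[[canon]], t_lgm = 1750,
                          migration = 0.01,
                          extinction = .scenario_ext[[canon]],
                          n_reps = 2000L, generation_time = 12),
                     class = "scenario")
  }
  dots <- list(...)
  for (f in names(dots)) {
    if (!f %in% names(scn)) stop("unknown scenario field: ", f)
    scn[[f]] <- dots[[f]]
  }
  stopifnot(scn$n0 > 0, scn$n1 > 0, scn$t_lgm > 0, scn$demes >= 1)
  scn
}

#' Backward exponential growth rate of a scenario
#'
#' `r = ln(n1/n0) / t_lgm` per generation; negative when the population is
#' larger now than at the LGM (Retraction, PPPH), positive when it was
#' larger at the LGM (PLAH, Both).
#' @param scenario a [build_scenario()] result or name.
#' @export
growth_rate <- function(scenario) {
  scn <- build_scenario(scenario)
  log(scn$n1 / scn$n0) / scn$t_lgm
}

#' Per-deme trajectories implied by a scenario
#'
#' All demes share the scenario trajectory; when the extinction flag is on,
#' demes 2..D go extinct (backward) at the LGM and their lineages transfer
#' to the source deme.
#' @param scenario a [build_scenario()] result or name.
#' @param ploidy_factor gene-copy multiplier for nuclear loci (default 1).
#' @return list of [deme_trajectory()].
#' @export
scenario_trajectories <- function(scenario, ploidy_factor = 1) {
  scn <- build_scenario(scenario)
  lapply(seq_len(scn$demes), function(d)
    deme_trajectory(scn$n0 * ploidy_factor, scn$n1 * ploidy_factor,
                    scn$t_lgm,
                    extinct_at = if (scn$extinction && d > 1L) scn$t_lgm
                                 else NA))
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %d demes, N0 = %g -> N1 = %g at t = %g generations\n",
              x$name, x$demes, x$n0, x$n1, x$t_lgm))
  cat(sprintf("  migration to source deme %.3g/generation; extinction of demes 2-%d: %s\n",
              x$migration, x$demes, if (x$extinction) "on" else "off"))
  cat(sprintf("  backward growth rate r = %.6g/generation; %d replicates; generation time %g y\n",
              growth_rate(x), x$n_reps, x$generation_time))
  invisible(x)
}

#' Write / read a scenario as a flat key-value config file
#'
#' Plain `key = value` text; round-trips exactly.
#' @param scenario a `scenario`.
#' @param path file path.
#' @export
write_scenario_config <- function(scenario, path) {
  scn <- build_scenario(scenario)
  vals <- vapply(scn, function(v) format(v, digits = 17), "")
  writeLines(paste(names(scn), vals, sep = " = "), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
  build_scenario(vals[["name"]],
                 demes = as.integer(vals[["demes"]]),
                 n0 = as.numeric(vals[["n0"]]),
                 n1 = as.numeric(vals[["n1"]]),
                 t_lgm = as.numeric(vals[["t_lgm"]]),
                 migration = as.numeric(vals[["migration"]]),
                 extinction = as.logical(vals[["extinction"]]),
                 n_reps = as.integer(vals[["n_reps"]]),
                 generation_time = as.numeric(vals[["generation_time"]]))
}

#' Generations between two epochs at a given generation time
#'
#' The 21 ky separating the present from the LGM correspond to 1750
#' generations at the 12-year generation time used throughout.
#' @param years elapsed years (default 21000).
#' @param generation_time years per generation (default 12).
#' @export
generations_between <- function(years = 21000, generation_time = 12) {
  years / generation_time
}
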