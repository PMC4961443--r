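#' Read a pipeline run configuration
#'
#' YAML with the fields used by [run_full_analysis()]: a named `loci` map
#' (each entry: `fasta` path, `model`, `gamma_shape`, `ploidy_factor`),
#' `popmap` path, optional `scenarios` vector, `n_reps`, `seed`,
#' `out_dir`, `mu`, `lnl_mode`, `min_run`.
#'
#' @param path YAML file path.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg$loci), length(cfg$loci) >= 1L)
  cfg
}

#' Run the full scenario-testing analysis from one configuration
#'
#' Orchestrates the pipeline: read and post-process each locus alignment
#' (mask polymorphic mononucleotide repeats, code indels as single events),
#' compute observed pooled haplotype and nucleotide diversity, simulate the
#' replicate distributions for every demographic scenario and locus, and
#' select the best scenario by empirical likelihood and Akaike weights.
#' Every stage draws from a seed stream derived from the single top-level
#' seed, so the whole report bundle is regenerable from config + seed; a
#' plain-text log records versions, seeds and resolved parameters.
#'
#' A configured locus whose FASTA file is missing is dropped with a warning
#' and the analysis proceeds on the remaining loci.
#'
#' @param config list (see [read_run_config()]) or a YAML path. In-memory
#'   alignments can be supplied directly as `config$alignments` (named
#'   [locus_alignment()] list) with `config$popmap` a data.frame.
#' @return object of class `pipeline_result`: the `scenario_selection`,
#'   observed statistics, per-locus diversity tables, distributions, and
#'   output paths when `out_dir` is set.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- config$seed %||% 1L
  n_reps <- config$n_reps %||% 2000L
  mu <- config$mu %||% 3.12e-7
  scen_names <- config$scenarios %||% c("PLAH", "PPPH", "BOTH", "RETRACTION")
  min_run <- config$min_run %||% 5L
  lnl_mode <- config$lnl_mode %||% "product"
  bins <- config$bins %||% "fd"
  out_dir <- config$out_dir

  # ---- load inputs ---------------------------------------------------
  popmap <- config$popmap
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  alns <- config$alignments %||% list()
  if (length(alns) == 0L) {
    for (locus in names(config$loci)) {
      path <- config$loci[[locus]]$fasta
      if (is.null(path) || !file.exists(path)) {
        warning("locus ", locus, " has no readable FASTA (", path %||% "unset",
                "); continuing without it")
        next
      }
      aln <- read_alignment(path, locus)
      aln <- filter_mononucleotide_repeats(aln, min_run = min_run)
      aln <- code_indels(aln)
      alns[[locus]] <- aln
    }
  }
  if (length(alns) == 0L) stop("input stage: no usable loci")
  loci <- names(alns)

  # ---- observed statistics -------------------------------------------
  observed <- NULL
  stats_tables <- list()
  hapsets <- list()
  for (locus in loci) {
    hs <- collapse_haplotypes(alns[[locus]],
                              if (!is.null(popmap)) popmap else NULL)
    hapsets[[locus]] <- hs
    nd <- nucleotide_diversity(hs)
    observed <- rbind(observed,
                      data.frame(locus = locus, statistic = c("h", "pi"),
                                 value = c(haplotype_diversity(hs), nd$pi),
                                 stringsAsFactors = FALSE))
    if (!is.null(popmap))
      stats_tables[[locus]] <- population_diversity(alns[[locus]], popmap)
  }

  # ---- simulated distributions ---------------------------------------
  if (!is.null(popmap)) {
    ord <- names(study_sample_sizes())
    tab <- table(popmap$population)
    sample_sizes <- as.integer(tab)
    names(sample_sizes) <- names(tab)
  } else {
    sample_sizes <- study_sample_sizes()
  }
  sims <- list()
  for (locus in loci) {
    cfg <- config$loci[[locus]] %||% list()
    model <- mutation_model(cfg$model %||% "JC", mu = cfg$mu %||% mu,
                            L = usable_sites(alns[[locus]]),
                            gamma_shape = cfg$gamma_shape)
    sims[[locus]] <- list()
    for (s in scen_names) {
      scn <- build_scenario(s, demes = length(sample_sizes))
      sims[[locus]][[scn$name]] <- run_scenario_replicates(
        scn, model, sample_sizes = sample_sizes, n_reps = n_reps,
        seed = derive_seed(seed, paste("simulate", scn$name, locus)),
        ploidy_factor = cfg$ploidy_factor %||% 1, locus = locus)
    }
  }

  # ---- model selection -----------------------------------------------
  selection <- select_scenarios(observed, sims, lnl_mode = lnl_mode,
                                bins = bins)

  # ---- report bundle --------------------------------------------------
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(selection_tsv = file.path(out_dir, "selection.tsv"),
                  selection_json = file.path(out_dir, "selection.json"),
                  log = file.path(out_dir, "run.log"))
    write_tsv(selection$table, paths$selection_tsv)
    jsonlite::write_json(
      list(observed = observed, table = selection$table,
           best = selection$best, overall_best = selection$overall_best),
      paths$selection_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    for (locus in names(stats_tables)) {
      p <- file.path(out_dir, paste0("stats_", locus, ".tsv"))
      write_tsv(stats_tables[[locus]], p)
      paths[[paste0("stats_", locus)]] <- p
    }
    for (locus in loci) {
      for (s in names(sims[[locus]])) {
        p <- file.path(out_dir, sprintf("dist_%s_%s.tsv", locus, s))
        d <- sims[[locus]][[s]]
        write_tsv(data.frame(replicate = seq_len(d$n_reps), h = d$h,
                             pi = d$pi, seed = d$seeds), p)
        paths[[sprintf("dist_%s_%s", locus, s)]] <- p
      }
    }
    log_lines <- c(
      sprintf("coalscen %s", as.character(utils::packageVersion("coalscen"))),
      sprintf("R %s", as.character(getRversion())),
      sprintf("date (run): %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      sprintf("seed: %d", seed),
      sprintf("n_reps: %d", n_reps),
      sprintf("mu: %g", mu),
      sprintf("scenarios: %s", paste(scen_names, collapse = ", ")),
      sprintf("loci: %s", paste(loci, collapse = ", ")),
      sprintf("lnl_mode: %s; bins: %s", lnl_mode, paste(bins, collapse = ",")),
      sprintf("stage seeds: %s",
              paste(vapply(loci, function(l) paste0(
                l, "=", paste(vapply(scen_names, function(s)
                  as.character(derive_seed(seed, paste("simulate", s, l))),
                  ""), collapse = "/")), ""), collapse = "; ")))
    writeLines(log_lines, paths$log)
  }

  structure(list(selection = selection, observed = observed,
                 stats_tables = stats_tables, sims = sims,
                 hapsets = hapsets, seed = seed, n_reps = n_reps,
                 paths = paths),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Full scenario-testing pipeline result\n")
  print(x$selection)
  invisible(x)
}
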