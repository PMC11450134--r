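# Orchestration: filter -> annotate -> concordance -> context -> triage,
# with stage TSV outputs and a JSON summary.

#' Assemble and validate a pipeline run configuration
#'
#' @param proteome Path to the proteome FASTA.
#' @param psm_tables Character vector of PSM TSV paths.
#' @param predictions Path to the TargetP2-style prediction file.
#' @param output_dir Output directory for stage tables and the summary.
#' @param chemistry_by_dataset Named map dataset_id -> chemistry name;
#'   every dataset appearing in the PSM tables must be covered.
#' @param thresholds A [filter_thresholds()] object (or a list of its
#'   arguments).
#' @param window Concordance window half-width (default 5).
#' @param logo_width Mature-residue width of the PFM windows (default 10).
#' @param decoy_prefix Decoy accession prefix.
#' @param contaminant_accessions Contaminant accession list.
#' @return A validated `run_config` list.
#' @export
run_config <- function(proteome, psm_tables, predictions, output_dir,
                       chemistry_by_dataset,
                       thresholds = filter_thresholds(), window = 5L,
                       logo_width = 10L, decoy_prefix = "REV_",
                       contaminant_accessions = character()) {
  if (is.list(thresholds) && !inherits(thresholds, "filter_thresholds")) {
    thresholds <- do.call(filter_thresholds, thresholds)
  }
  cfg <- structure(
    list(proteome = proteome, psm_tables = psm_tables,
         predictions = predictions, output_dir = output_dir,
         chemistry_by_dataset = chemistry_by_dataset,
         thresholds = thresholds, window = as.integer(window),
         logo_width = as.integer(logo_width), decoy_prefix = decoy_prefix,
         contaminant_accessions = contaminant_accessions),
    class = "run_config"
  )
  for (p in c(cfg$proteome, cfg$psm_tables, cfg$predictions)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  if (is.null(names(cfg$chemistry_by_dataset)) ||
      !length(cfg$chemistry_by_dataset)) {
    stop("chemistry_by_dataset must be a non-empty named map")
  }
  vapply(cfg$chemistry_by_dataset,
         function(x) label_chemistry(as.character(x))$name, character(1))
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Expected keys mirror the [run_config()] arguments; `thresholds` may be a
#' mapping of threshold names to values.
#'
#' @param path YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  required <- c("proteome", "psm_tables", "predictions", "output_dir",
                "chemistry_by_dataset")
  missing <- setdiff(required, names(y))
  if (length(missing)) {
    stop("config is missing required key(s): ", paste(missing, collapse = ", "))
  }
  run_config(
    proteome = y$proteome, psm_tables = unlist(y$psm_tables),
    predictions = y$predictions, output_dir = y$output_dir,
    chemistry_by_dataset = unlist(y$chemistry_by_dataset),
    thresholds = if (is.null(y$thresholds)) filter_thresholds() else y$thresholds,
    window = if (is.null(y$window)) 5L else y$window,
    logo_width = if (is.null(y$logo_width)) 10L else y$logo_width,
    decoy_prefix = if (is.null(y$decoy_prefix)) "REV_" else y$decoy_prefix,
    contaminant_accessions = if (is.null(y$contaminants)) character() else
      unlist(y$contaminants)
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full N-terminome annotation pipeline
#'
#' Executes the stages in order - read inputs, filter identifications,
#' enumerate proteoform N-termini, cleavage-site concordance, sequence
#' context, dual-targeting triage - writing one TSV per stage plus
#' `summary.json` into the configured output directory. Outputs are pure
#' functions of inputs and configuration: re-running an identical
#' configuration reproduces them byte-for-byte.
#'
#' @param config A `run_config` (from [run_config()] or
#'   [read_run_config()]), or the path of a YAML config file.
#' @return An `ntermscope_run` object: list with `summary` (the written
#'   summary), `observations`, `records`, `confirmed`, `fdr`, `files`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  proteome <- .stage("read_proteome", read_proteome(
    config$proteome, config$decoy_prefix, config$contaminant_accessions))
  psms <- .stage("read_psm_tables", do.call(rbind, lapply(
    config$psm_tables, read_psm_table)))
  predictions <- .stage("read_predictions",
                        read_targetp_short(config$predictions))
  .stage("validate_config", {
    missing <- setdiff(unique(psms$dataset_id),
                       names(config$chemistry_by_dataset))
    if (length(missing)) {
      stop("no chemistry assignment for dataset(s): ",
           paste(missing, collapse = ", "))
    }
  })

  accepted <- .stage("filter", filter_psms(
    psms, config$thresholds, config$contaminant_accessions))
  fdr_pep <- compute_decoy_fdr(accepted, "peptide", config$decoy_prefix)
  fdr_prot <- compute_decoy_fdr(accepted, "protein", config$decoy_prefix)

  observations <- .stage("annotate", enumerate_observations(
    accepted, proteome, config$chemistry_by_dataset,
    decoy_prefix = config$decoy_prefix))
  hist_tab <- start_index_histogram(observations)
  tpp <- termini_per_protein(observations)

  records <- .stage("concordance", offset_records(
    observations, predictions, config$window))
  concord <- build_concordance(observations, predictions, config$window)
  confirmed <- confirmed_cleavages(observations, predictions, config$window)
  breakdown <- state_breakdown_at_sites(records)

  pfms <- .stage("context", {
    states <- c("free", "acetyl", "monomethyl")
    stats::setNames(lapply(states, function(s) {
      build_pfm(observations, proteome, state_filter = s,
                width = config$logo_width)
    }), states)
  })

  triage_calls <- .stage("triage", {
    cand <- records[records$signal_class == "mTP" &
                      records$state == "acetyl", , drop = FALSE]
    if (!nrow(cand)) {
      data.frame(accession = character(), category = character(),
                 evidence = character(), stringsAsFactors = FALSE)
    } else {
      seqs <- stats::setNames(proteome$sequence, proteome$accession)
      obs_key <- paste(observations$accession, observations$start_index,
                       observations$state, sep = "\r")
      inputs <- lapply(seq_len(nrow(cand)), function(i) {
        ob <- observations[match(
          paste(cand$accession[i], cand$start_index[i], "acetyl", sep = "\r"),
          obs_key), ]
        triage_input(
          accession = cand$accession[i],
          observation = as.list(ob),
          prediction = list(signal_class = "mTP",
                            p1_prime = cand$start_index[i] - cand$dif[i]),
          protein_sequence = seqs[[cand$accession[i]]]
        )
      })
      triage_table(inputs)
    }
  })

  state_tab <- if (nrow(observations)) {
    tab <- table(factor(observations$state, levels = MOD_STATES))
    as.list(as.numeric(tab) / nrow(observations))
  } else {
    as.list(stats::setNames(numeric(length(MOD_STATES)), MOD_STATES))
  }
  names(state_tab) <- MOD_STATES

  dif0 <- lapply(split(records, records$signal_class), function(g) {
    sum(g$dif == 0) / nrow(g)
  })

  summary <- list(
    n_psms_total = nrow(psms),
    n_psms_accepted = nrow(accepted),
    fdr = list(
      peptide = list(n_target = fdr_pep$n_target, n_decoy = fdr_pep$n_decoy,
                     fdr = fdr_pep$fdr),
      protein = list(n_target = fdr_prot$n_target, n_decoy = fdr_prot$n_decoy,
                     fdr = fdr_prot$fdr)
    ),
    n_ntermini_proteoforms = nrow(observations),
    n_ntermini_positions = if (nrow(observations)) {
      nrow(unique(observations[, c("accession", "start_index")]))
    } else 0L,
    n_proteins = length(unique(observations$accession)),
    state_fractions = state_tab,
    start_index_histogram = hist_tab,
    termini_per_protein = tpp,
    confirmed_cleavages = confirmed,
    dif0_fraction = dif0,
    thresholds = unclass(config$thresholds),
    window = config$window
  )

  files <- list(
    observations = file.path(config$output_dir, "observations.tsv"),
    offset_records = file.path(config$output_dir, "offset_records.tsv"),
    concordance = file.path(config$output_dir, "concordance_by_class.tsv"),
    confirmed = file.path(config$output_dir, "confirmed_cleavages.tsv"),
    breakdown = file.path(config$output_dir, "state_breakdown.tsv"),
    triage = file.path(config$output_dir, "triage_calls.tsv"),
    summary = file.path(config$output_dir, "summary.json")
  )
  write_report_tsv(observations, files$observations)
  write_report_tsv(records, files$offset_records)
  write_report_tsv(concord, files$concordance)
  write_report_tsv(confirmed, files$confirmed)
  write_report_tsv(breakdown, files$breakdown)
  write_report_tsv(triage_calls, files$triage)
  for (s in names(pfms)) {
    f <- file.path(config$output_dir, sprintf("pfm_%s.tsv", s))
    write_pfm(pfms[[s]], f)
    files[[paste0("pfm_", s)]] <- f
  }
  jsonlite::write_json(summary, files$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(
    list(summary = summary, observations = observations, records = records,
         confirmed = confirmed, breakdown = breakdown, pfms = pfms,
         triage_calls = triage_calls,
         fdr = list(peptide = fdr_pep, protein = fdr_prot),
         files = files, config = config),
    class = "ntermscope_run"
  )
}

#' @export
print.ntermscope_run <- function(x, ...) {
  s <- x$summary
  cat("N-terminome pipeline run\n")
  cat(sprintf("  PSMs: %d total, %d accepted (peptide FDR %.3g%%, protein FDR %.3g%%)\n",
              s$n_psms_total, s$n_psms_accepted,
              100 * s$fdr$peptide$fdr, 100 * s$fdr$protein$fdr))
  cat(sprintf("  N-termini: %d proteoforms at %d positions in %d proteins\n",
              s$n_ntermini_proteoforms, s$n_ntermini_positions, s$n_proteins))
  sf <- unlist(s$state_fractions)
  cat(sprintf("  states: %s\n",
              paste(sprintf("%s %.1f%%", names(sf), 100 * sf), collapse = ", ")))
  if (nrow(x$confirmed)) {
    cat(sprintf("  confirmed cleavages: %s\n",
                paste(sprintf("%s %d", x$confirmed$signal_class,
                              x$confirmed$n_proteins), collapse = ", ")))
  }
  cat("  outputs:", x$config$output_dir, "\n")
  invisible(x)
}

#' @export
summary.ntermscope_run <- function(object, ...) object$summary
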