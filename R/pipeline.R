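#' Run the end-to-end simulate / call / stats / detect pipeline
#'
#' Orchestrates the full analysis on simulated data: (1) simulate the
#' chromosomal D-D amplicon library and the excision-circle amplicon;
#' (2) call and decompose junctions; (3) aggregate clonotypes, fit the
#' junction-length mixture and summarize insertions/deletions; (4) run the
#' conservative D2-motif detector on a simulated D1-J2 table and call
#' signal joints on the circle reads. All stage outputs are written under
#' `config$outdir` and a JSON manifest with per-stage row counts and summary
#' metrics is returned (and written). Identical config and seed give an
#' identical manifest.
#'
#' @param config Path to a YAML configuration, or an equivalent named list.
#'   Recognized keys (all optional except `seed`):
#'   \describe{
#'     \item{reference}{`genes`, `flanks`, `primers` paths; omit to use the
#'       bundled reference.}
#'     \item{simulate}{`n_events`, `p_signal`, `trim_mean`, `error_rate`,
#'       `clone_size_alpha`, `both_strands`.}
#'     \item{caller}{`max_mismatch`, `min_germline`.}
#'     \item{detect}{`n_rows`, `spike_fraction` for the D1-J2 detector
#'       stage.}
#'     \item{outdir}{Output directory (default: a temporary directory).}
#'     \item{seed}{Integer seed; mandatory.}
#'   }
#' @return The manifest, invisibly (a named list, also written to
#'   `outdir/manifest.json`).
#' @export
run_dd_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_pipeline_config(cfg)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  ref <- if (is.null(cfg$reference)) {
    dd_example_reference()
  } else {
    read_trb_reference(cfg$reference$genes, cfg$reference$flanks, cfg$reference$primers)
  }
  sim <- cfg$simulate %||% list()
  params <- sim_params(
    p_signal = sim$p_signal %||% 0.5,
    trim_mean = sim$trim_mean %||% 5,
    n_events = sim$n_events %||% 5000L,
    clone_size_alpha = sim$clone_size_alpha %||% 2.5,
    error_rate = sim$error_rate %||% 0,
    both_strands = sim$both_strands %||% FALSE,
    seed = cfg$seed
  )
  manifest <- list(config = cfg, stages = list())

  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      dd_abort(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        "ddloop_stage_error"
      )
    })
  }

  ## 1: simulate -------------------------------------------------------------
  fq_dd <- file.path(outdir, "dd_reads.fastq")
  fq_sj <- file.path(outdir, "sj_reads.fastq")
  truth <- stage("simulate", function() {
    tr <- simulate_dd_reads(params, ref, fq_dd)
    simulate_signal_joint_reads(params, ref, fq_sj,
      n = max(200L, params$n_events %/% 10L)
    )
    tr
  })
  write_tsv(truth, file.path(outdir, "truth.tsv"))
  manifest$stages$simulate <- list(
    fastq = fq_dd, circle_fastq = fq_sj, truth = file.path(outdir, "truth.tsv"),
    n_events = nrow(truth), n_reads = sum(truth$clone_count)
  )

  ## 2: call -----------------------------------------------------------------
  calls <- stage("call", function() {
    call_junctions(fq_dd, ref,
      max_mismatch = cfg$caller$max_mismatch,
      min_germline = cfg$caller$min_germline %||% 7L
    )
  })
  write_tsv(calls, file.path(outdir, "calls.tsv"))
  manifest$stages$call <- list(
    calls = file.path(outdir, "calls.tsv"),
    n_reads = nrow(calls),
    n_called = sum(calls$status == "called"),
    no_call_rate = mean(calls$status != "called"),
    class_fractions = as.list(prop.table(table(calls$klass[calls$status == "called"])))
  )

  ## 3: stats ----------------------------------------------------------------
  stats_out <- stage("stats", function() {
    clono <- aggregate_clonotypes(calls, sample_id = "sim")
    fit <- fit_length_mixture(nchar(calls$junction[calls$status == "called"]))
    indel <- indel_stats(clono, ref)
    list(clono = clono, fit = fit, indel = indel)
  })
  write_tsv(stats_out$clono, file.path(outdir, "clonotypes.tsv"))
  write_tsv(stats_out$indel, file.path(outdir, "indel_stats.tsv"))
  manifest$stages$stats <- list(
    clonotypes = file.path(outdir, "clonotypes.tsv"),
    n_clonotypes = nrow(stats_out$clono),
    mixture = list(
      family = stats_out$fit$family,
      means = stats_out$fit$means,
      weights = stats_out$fit$weights,
      converged = stats_out$fit$converged
    )
  )

  ## 4: detect ---------------------------------------------------------------
  det <- stage("detect", function() {
    d2_set <- build_motif_set(ref_gene(ref, "TRBD2", allele = NULL), 7L)
    tab <- simulate_junction_table(
      "d1_j2",
      n = cfg$detect$n_rows %||% 2000L,
      spike_fraction = cfg$detect$spike_fraction %||% 0.2,
      params = params, ref = ref, seed = cfg$seed + 1L
    )
    list(
      det = detect_motif_fraction(tab, d2_set),
      sj = call_signal_joints(fq_sj, ref)
    )
  })
  manifest$stages$detect <- list(
    ddj_fraction = det$det$summary$fraction,
    sj_summary = as.list(summarize_signal_joints(det$sj))
  )

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) {
    dd_abort("config must be a list or a YAML path", "ddloop_config_error")
  }
  if (is.null(cfg$seed)) {
    dd_abort("config$seed is mandatory", "ddloop_config_error")
  }
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$reference)) {
    for (p in unlist(cfg$reference)) {
      if (!file.exists(p)) {
        dd_abort(sprintf("reference path does not exist: %s", p), "ddloop_config_error")
      }
    }
  }
  cfg$outdir <- cfg$outdir %||% tempfile("ddloop_run_")
  cfg
}

write_tsv <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = ""
  )
  invisible(path)
}
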