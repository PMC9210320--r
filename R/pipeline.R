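# Orchestration: run configuration, validation, stage sequencing,
# logging, and the manifest enabling byte-identical reruns.

#' Build a pipeline run configuration
#'
#' Collects input paths, stage parameters (every screen threshold, at its
#' standard default), the run seed and the output directory. The seed is
#' fanned out to per-stage child seeds (see [stage_seed()]).
#'
#' @param outdir Output directory for the run.
#' @param stages Stages to execute, in pipeline order; any suffix of the
#'   full pipeline is allowed given precomputed inputs.
#' @param seed Integer run seed.
#' @param inputs Named list of input paths for stages whose upstream is
#'   not being run: `reads` (Tn-seq FASTQ), `genome` (FASTA), `gff`
#'   (GFF3), `counts` (TSV), `samples` (TSV), `catalog` (TSV),
#'   `barseq_manifest` (TSV: sample_id, fastq).
#' @param sim A [sim_config()] for the `simulate` stage.
#' @param params Named list overriding stage parameters; see
#'   [default_params()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir, stages = c("simulate", "tnseq_map",
                                          "barseq_count", "rh_test"),
                       seed = 1, inputs = list(), sim = sim_config(),
                       params = list()) {
  p <- default_params()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown)) {
    stop(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")))
  }
  p[names(params)] <- params
  cfg <- list(outdir = outdir, stages = stages, seed = seed,
              inputs = inputs, sim = sim, params = p)
  class(cfg) <- "run_config"
  cfg
}

#' Default stage parameters
#'
#' The screen's standard thresholds: 2 mismatches for arm search, flank
#' match and fragment mapping; barcode-collapse dominance ratio 10;
#' genotype CV ceiling 2.0 and 1.1-normalized-read floor; at least 3
#' genotypes per allele; pooled-t CV ceiling 10; hit rule adjusted
#' P < 0.05 with effect size < -0.5; 10,000 resamples; gene-set size
#' bounds \[5, 200\]; two-stage promotion below 0.1.
#'
#' @return Named list of parameter defaults.
#' @export
default_params <- function() {
  list(
    max_mismatches = 2,
    max_flank_mismatches = 2,
    max_map_mismatches = 2,
    dominance_ratio = 10,
    k = 15,
    strong_margin = 2,
    min_fragment = 30,
    cv_max = 2.0,
    min_norm_reads = 1.1,
    min_genotypes = 3,
    cv_t_max = 10,
    p_max = 0.05,
    effect_max = -0.5,
    zero_pseudo = 0.5,
    cv_on = "abundance",
    n_resamples = 10000,
    go_min_size = 5,
    go_max_size = 200,
    promote_below = 0.1,
    n1 = 100
  )
}

#' Validate a run configuration
#'
#' Reports every violated invariant at once, naming the offending fields.
#'
#' @param config A `run_config`.
#' @return Character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  known_stages <- c("simulate", "tnseq_map", "barseq_count", "rh_test")
  bad <- setdiff(config$stages, known_stages)
  if (length(bad)) add(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    add("seed: must be a single number")
  }
  p <- config$params
  need_pos <- c("max_mismatches", "max_flank_mismatches", "max_map_mismatches",
                "dominance_ratio", "k", "strong_margin", "min_fragment",
                "cv_max", "min_norm_reads", "min_genotypes", "cv_t_max",
                "n_resamples", "go_min_size", "go_max_size", "n1")
  for (f in need_pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] < 0) {
      add(sprintf("%s: must be a non-negative number", f))
    }
  }
  if (is.numeric(p$p_max) && (p$p_max <= 0 || p$p_max > 1)) add("p_max: must be in (0, 1]")
  if (is.numeric(p$promote_below) && (p$promote_below < 0 || p$promote_below > 1)) {
    add("promote_below: must be in [0, 1]")
  }
  if (is.numeric(p$go_min_size) && is.numeric(p$go_max_size) &&
      p$go_min_size > p$go_max_size) {
    add("go_min_size/go_max_size: lower bound exceeds upper bound")
  }
  if ("simulate" %in% config$stages) {
    v <- tryCatch({ validate_sim_config(config$sim); NULL },
                  error = function(e) conditionMessage(e))
    if (!is.null(v)) add(v)
  }
  # stages run without their upstream need the corresponding inputs
  if (!("simulate" %in% config$stages)) {
    if ("tnseq_map" %in% config$stages) {
      for (f in c("reads", "genome", "gff")) {
        if (is.null(config$inputs[[f]])) add(sprintf("missing input: %s", f))
      }
    }
    if ("barseq_count" %in% config$stages || "rh_test" %in% config$stages) {
      if (is.null(config$inputs$samples)) add("missing input: samples")
    }
    if ("rh_test" %in% config$stages && !("barseq_count" %in% config$stages) &&
        is.null(config$inputs$counts)) {
      add("missing input: counts")
    }
    if (("barseq_count" %in% config$stages || "rh_test" %in% config$stages) &&
        !("tnseq_map" %in% config$stages) && is.null(config$inputs$catalog)) {
      add("missing input: catalog")
    }
    if ("barseq_count" %in% config$stages &&
        is.null(config$inputs$barseq_manifest) && is.null(config$inputs$counts)) {
      add("missing input: barseq_manifest or counts")
    }
  }
  errs
}

#' Read a YAML run configuration
#'
#' Strict schema: unknown top-level or parameter keys are rejected.
#'
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("outdir", "stages", "seed", "inputs", "sim", "params")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  sim <- if (is.null(y$sim)) sim_config() else do.call(sim_config, y$sim)
  run_config(outdir = y$outdir %||% ".",
             stages = y$stages %||% c("simulate", "tnseq_map", "barseq_count", "rh_test"),
             seed = y$seed %||% 1,
             inputs = y$inputs %||% list(),
             sim = sim,
             params = y$params %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_line <- function(con, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Execute the pipeline
#'
#' Runs the configured stages in order (simulate, tnseq_map,
#' barseq_count, rh_test), writes every intermediate table into the
#' output directory, and records a manifest (seed, parameter values,
#' per-stage record counts) that makes reruns byte-identical. A stage
#' failure aborts with the stage name and reason and leaves a FAILED
#' marker next to the partial outputs.
#'
#' @param config A `run_config`.
#' @return The output directory path, invisibly; the manifest is at
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop(paste(c("invalid run configuration:", errs), collapse = "\n  "))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  manifest <- list(seed = config$seed, stages = config$stages,
                   params = config$params, counts = list())
  p <- config$params
  state <- list()

  run_stage <- function(name, fn) {
    log_line(logcon, sprintf("stage %s: start", name))
    res <- tryCatch(fn(), error = function(e) {
      writeLines(sprintf("FAILED at stage %s: %s", name, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    log_line(logcon, sprintf("stage %s: done", name))
    res
  }

  if ("simulate" %in% config$stages) {
    state <- run_stage("simulate", function() {
      sim <- simulate_experiment(config$sim, seed = config$seed)
      write_genome(sim$genome, file.path(outdir, "genome.fa"))
      write_annotation(sim$annotation, file.path(outdir, "annotation.gff3"))
      write_fastq(sim$tnseq_reads, file.path(outdir, "tnseq_reads.fq"))
      write_truth(sim$truth, file.path(outdir, "truth.tsv"))
      write_counts(sim$counts, file.path(outdir, "barseq_counts_raw.tsv"))
      write_sample_sheet(sim$samples, file.path(outdir, "samples.tsv"))
      manifest$counts$simulate <<- list(
        clones = length(unique(sim$truth$barcode)),
        insertion_sites = nrow(sim$truth),
        tnseq_reads = length(sim$tnseq_reads),
        samples = nrow(sim$samples)
      )
      sim
    })
  } else {
    if (!is.null(config$inputs$genome)) state$genome <- read_genome(config$inputs$genome)
    if (!is.null(config$inputs$gff)) {
      state$annotation <- read_annotation(config$inputs$gff, genome = state$genome)
    }
    if (!is.null(config$inputs$reads)) state$tnseq_reads <- read_fastq(config$inputs$reads)
    if (!is.null(config$inputs$counts)) state$counts <- read_counts(config$inputs$counts)
    if (!is.null(config$inputs$samples)) state$samples <- read_sample_sheet(config$inputs$samples)
  }

  catalog <- NULL
  if ("tnseq_map" %in% config$stages) {
    catalog <- run_stage("tnseq_map", function() {
      arm <- config$sim$sequences$tn_arm
      gap <- nchar(config$sim$sequences$u1_spacer) + (nchar(arm) - 22L)
      cat <- tnseq_map(state$tnseq_reads, state$genome, state$annotation, arm,
                       barcode_length = config$sim$barcode_length,
                       barcode_gap = gap,
                       min_fragment = p$min_fragment,
                       max_mismatches = p$max_mismatches,
                       dominance_ratio = p$dominance_ratio,
                       k = p$k, max_map_mismatches = p$max_map_mismatches,
                       strong_margin = p$strong_margin)
      write_catalog(cat, file.path(outdir, "catalog.tsv"),
                    qc_path = file.path(outdir, "catalog_qc.json"))
      manifest$counts$tnseq_map <<- cat$qc
      cat
    })
  } else if (!is.null(config$inputs$catalog)) {
    catalog <- read_catalog(config$inputs$catalog)
  }

  counts <- NULL
  if ("barseq_count" %in% config$stages) {
    counts <- run_stage("barseq_count", function() {
      if (!is.null(config$inputs$barseq_manifest)) {
        man <- read_tsv(config$inputs$barseq_manifest)
        reads <- lapply(stats::setNames(man$fastq, man$sample_id), read_fastq)
        bc <- count_barcodes(reads, catalog, state$samples,
                             upstream_flank = config$sim$sequences$bar_up,
                             downstream_flank = config$sim$sequences$bar_dn,
                             barcode_length = config$sim$barcode_length,
                             max_flank_mismatches = p$max_flank_mismatches)
        manifest$counts$barseq_count <<- list(samples = length(reads),
                                              qc = bc$qc)
        bc$counts
      } else {
        rc <- restrict_counts(state$counts, catalog)
        manifest$counts$barseq_count <<- list(
          input_barcodes = nrow(state$counts),
          catalog_barcodes = nrow(rc$counts),
          orphan_barcodes = rc$orphan_barcodes
        )
        rc$counts
      }
    })
    write_counts(counts, file.path(outdir, "counts.tsv"))
  } else if (!is.null(state$counts)) {
    counts <- state$counts
  }

  if ("rh_test" %in% config$stages) {
    run_stage("rh_test", function() {
      if (is.null(counts)) stop("missing input: counts")
      if (is.null(catalog)) stop("missing input: catalog")
      rp <- rh_params(cv_max = p$cv_max, min_norm_reads = p$min_norm_reads,
                      min_genotypes = p$min_genotypes, cv_t_max = p$cv_t_max,
                      p_max = p$p_max, effect_max = p$effect_max,
                      zero_pseudo = p$zero_pseudo, cv_on = p$cv_on)
      res <- rh_test(counts, catalog, state$samples, params = rp)
      write_tsv(res$genes, file.path(outdir, "results.tsv"))
      write_tsv(res$genotypes, file.path(outdir, "genotype_t.tsv"))
      jsonlite::write_json(res$qc, file.path(outdir, "rh_qc.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      manifest$counts$rh_test <<- res$qc
      res
    })
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line(logcon, "pipeline complete")
  invisible(outdir)
}
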