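#' Run the PESCA pipeline from a configuration
#'
#' Orchestrates the stages — `simulate` (synthetic screen), `select`
#' (GRE panel from a peak fixture or peak files), `count` (read
#' deconvolution to UMI matrices), `enrich` (fold-enrichment,
#' consistency, NB-LRT) and `power` (binomial-thinning) — in order,
#' writing each stage's outputs under `out_dir` and a reproducibility
#' manifest (package version, seeds, per-file md5 checksums and row
#' counts) that makes reruns byte-comparable. A failing stage aborts
#' with the stage named; files it had written are retained with a
#' `.partial` suffix.
#'
#' @param config Configuration list, or path to a YAML file with the
#'   same structure. Top level: `seed`, `stages` (character vector,
#'   any of simulate/select/count/enrich/power) and one section per
#'   stage. Later stages default their inputs to earlier stages'
#'   outputs; explicit file paths override.
#' @param out_dir Output directory.
#' @param seed Optional master seed overriding the config's.
#' @return The manifest, invisibly. Also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_config("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or YAML path")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  stages <- config$stages %||%
    c("simulate", "select", "count", "enrich", "power")
  known <- c("simulate", "select", "count", "enrich", "power")
  if (!all(stages %in% known))
    stop_config("unknown stage(s): ",
                paste(setdiff(stages, known), collapse = ", "))
  stages <- known[known %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  check_exists <- function(path, what) {
    if (!file.exists(path))
      stop_config(what, " not found: ", path)
    path
  }

  manifest <- list(package = "pesca",
                   version = as.character(utils::packageVersion("pesca")),
                   seed = seed, stages = stages, outputs = list())
  state <- new.env(parent = emptyenv())

  record <- function(stage, files, rows) {
    manifest$outputs[[stage]] <<- list(
      files = lapply(files, function(f) list(
        path = basename(f), md5 = unname(tools::md5sum(f)))),
      rows = rows)
  }

  run_stage <- function(stage, fun) {
    sdir <- file.path(out_dir, stage)
    dir.create(sdir, showWarnings = FALSE)
    tryCatch(fun(sdir), error = function(e) {
      for (f in list.files(sdir, full.names = TRUE))
        file.rename(f, paste0(f, ".partial"))
      stop(errorCondition(
        paste0("stage '", stage, "' failed: ", conditionMessage(e)),
        class = unique(c("pesca_stage_error", class(e)))))
    })
  }

  for (stage in stages) {
    switch(stage,
      simulate = run_stage("simulate", function(sdir) {
        cfg <- config$simulate %||% list()
        n_cells <- cfg$n_cells %||% 2000L
        cfg$n_cells <- NULL
        cfg$true_fold <- unlist(cfg$true_fold) %||% 1
        cfg$cell_type_proportions <- unlist(cfg$cell_type_proportions)
        if (is.null(cfg$cell_type_proportions))
          cfg$cell_type_proportions <- NULL
        cfg$seed <- cfg$seed %||% derive_seed(seed, 11L)
        truth <- do.call(screen_truth, cfg)
        scr <- simulate_screen(truth, n_cells)
        write_screen(scr, sdir)
        state$screen <- scr
        record("simulate",
               file.path(sdir, c("reads.tsv", "labels.tsv",
                                 "gre_map.tsv", "barcodes.tsv")),
               rows = c(reads = nrow(scr$reads), cells = n_cells))
      }),
      select = run_stage("select", function(sdir) {
        cfg <- config$select %||% list()
        if (!is.null(cfg$peaks_bed)) {
          for (f in c(cfg$peaks_bed, cfg$signal_tsv, cfg$conservation_tsv))
            if (!file.exists(f))
              stop_config("select input not found: ", f)
          iv <- read_bed(cfg$peaks_bed)
          sig <- utils::read.table(cfg$signal_tsv, sep = "\t",
                                   header = TRUE, row.names = 1L)
          cons <- utils::read.table(cfg$conservation_tsv, sep = "\t",
                                    header = TRUE, row.names = 1L)
          pt <- peak_table(iv, as.matrix(sig)[iv$id, , drop = FALSE],
                           cons[iv$id, 1L])
          if (is.null(cfg$control_scores_tsv))
            stop_config("select from files needs 'control_scores_tsv'")
          control_scores <- utils::read.table(
            cfg$control_scores_tsv, sep = "\t", header = TRUE)[[1L]]
        } else {
          fx <- simulate_peak_fixture(
            n_peaks = cfg$n_peaks %||% 1000L,
            n_celltypes = cfg$n_celltypes %||% 3L,
            n_specific = cfg$n_specific %||% 20L,
            seed = derive_seed(seed, 12L))
          pt <- fx$peaks
          control_scores <- fx$control_scores
          cfg$target <- cfg$target %||% fx$target
          write_tsv(fx$truth, file.path(sdir, "fixture_truth.tsv"))
        }
        panel <- select_gres(
          pt, control_scores, target = cfg$target,
          k = cfg$k %||% min(287L, nrow(pt$intervals)),
          conservation_percentile = cfg$conservation_percentile %||% 95,
          signal_scale = cfg$signal_scale %||% 1e7,
          atac_pseudocount = cfg$atac_pseudocount %||% 0.5)
        write_tsv(panel, file.path(sdir, "panel.tsv"))
        bed <- panel[, c("chrom", "start", "end", "id", "score")]
        write_bed(bed, file.path(sdir, "panel.bed"))
        state$panel <- panel
        record("select", file.path(sdir, c("panel.tsv", "panel.bed")),
               rows = c(panel = nrow(panel)))
      }),
      count = run_stage("count", function(sdir) {
        cfg <- config$count %||% list()
        reads <- if (!is.null(cfg$reads))
          read_reads(check_exists(cfg$reads, "read table"))
          else if (!is.null(state$screen)) state$screen$reads
          else stop_config("count stage needs 'reads' (or the simulate ",
                           "stage)")
        set <- if (!is.null(cfg$barcodes))
          read_barcodes_tsv(check_exists(cfg$barcodes, "barcode set"))
          else if (!is.null(state$screen)) state$screen$barcode_set
          else stop_config("count stage needs 'barcodes'")
        res <- count_umis(reads, set,
                          max_mismatch = cfg$max_mismatch %||% 1L,
                          uniqueness_radius =
                            cfg$uniqueness_radius %||% 2L)
        write_counts_mtx(res$counts, file.path(sdir, "counts"))
        jsonlite::write_json(res$qc, file.path(sdir, "qc.json"),
                             auto_unbox = TRUE, digits = NA)
        state$counts <- res$counts
        record("count",
               file.path(sdir, c("counts/matrix.mtx", "qc.json")),
               rows = c(cells = nrow(res$counts),
                        molecules = res$qc$n_molecules))
      }),
      enrich = run_stage("enrich", function(sdir) {
        cfg <- config$enrich %||% list()
        counts <- if (!is.null(cfg$counts))
          read_counts_mtx(check_exists(
            file.path(cfg$counts, "matrix.mtx"), "counts matrix") |>
              dirname())
          else state$counts %||%
            stop_config("enrich stage needs 'counts' (or the count ",
                        "stage)")
        labels <- if (!is.null(cfg$labels))
          read_labels(check_exists(cfg$labels, "labels table"))
          else if (!is.null(state$screen)) state$screen$labels
          else stop_config("enrich stage needs 'labels'")
        map <- if (!is.null(cfg$map))
          read_gre_map(check_exists(cfg$map, "GRE map"))
          else if (!is.null(state$screen)) state$screen$map
          else stop_config("enrich stage needs 'map'")
        target <- cfg$target %||%
          if (!is.null(state$screen)) state$screen$truth$target_type
          else stop_config("enrich stage needs 'target'")
        fit <- enrich_screen(
          counts, map, labels, target,
          expr_pseudocount = cfg$expr_pseudocount %||% 0.01,
          normalize_scale = cfg$normalize_scale %||% 1e4,
          fdr_threshold = cfg$fdr %||% 0.01,
          n_shuffles = cfg$n_shuffles %||% 1000L,
          seed = derive_seed(seed, 13L))
        write_enrichment(fit, file.path(sdir, "enrichment.tsv"))
        write_tsv(fit$consistency, file.path(sdir, "consistency.tsv"))
        jsonlite::write_json(
          list(mean = fit$null$mean, sd = fit$null$sd,
               n_shuffles = fit$null$n_shuffles),
          file.path(sdir, "shuffle_null.json"),
          auto_unbox = TRUE, digits = NA)
        state$fit <- fit
        state$labels <- labels
        state$target <- target
        record("enrich",
               file.path(sdir, c("enrichment.tsv", "consistency.tsv",
                                 "shuffle_null.json")),
               rows = c(gres = nrow(fit$table)))
      }),
      power = run_stage("power", function(sdir) {
        cfg <- config$power %||% list()
        counts <- if (!is.null(cfg$counts))
          read_counts_mtx(check_exists(
            file.path(cfg$counts, "matrix.mtx"), "counts matrix") |>
              dirname())
          else state$fit$gre_counts %||%
            stop_config("power stage needs 'counts' (or the enrich ",
                        "stage)")
        labels <- if (!is.null(cfg$labels))
          read_labels(check_exists(cfg$labels, "labels table"))
          else state$labels %||% stop_config("power stage needs 'labels'")
        target <- cfg$target %||% state$target %||%
          stop_config("power stage needs 'target'")
        sub <- subsample_power(
          counts, labels, target,
          probabilities = cfg$probabilities %||%
            c(0.5, 0.25, 0.125, 0.0625),
          replicates = cfg$replicates %||% 10L,
          seed = derive_seed(seed, 14L),
          fdr_threshold = cfg$fdr %||% 0.01)
        write_tsv(sub$report, file.path(sdir, "subsample_report.tsv"))
        record("power", file.path(sdir, "subsample_report.tsv"),
               rows = c(rows = nrow(sub$report)))
      }))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
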