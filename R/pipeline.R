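# End-to-end orchestration: simulate -> expression -> motifs -> screen ->
# report. Stages communicate only via files; every stage writes a manifest
# (inputs, parameters, seed, checksums) sufficient to re-run it alone.

#' Pipeline configuration
#'
#' @param seed global seed propagated (with per-stage offsets) to every
#'   stochastic stage.
#' @param out_dir output directory.
#' @param stages character vector of stages to run, in dependency order,
#'   from: "simulate", "expression", "motifs", "screen", "report".
#' @param simulate parameters for the synthetic stage (passed to
#'   \code{\link{simulation_config}}), as a named list.
#' @param expression list: \code{span}, \code{fdr} and optionally
#'   \code{elements}/\code{design} file paths when not simulating.
#' @param motifs list: \code{score_threshold_quantile}, \code{methods},
#'   \code{fdr}, \code{n_library} (size of the random motif library used
#'   when no matrix file is given) and optionally \code{matrices} (a
#'   TRANSFAC-format file), \code{promoters} (FASTA), \code{targets},
#'   \code{background} (gene-list files).
#' @param screen list: \code{table} (screen-table TSV; default the
#'   packaged replica), \code{fdr}.
#' @param n_promoter_background number of background promoters simulated.
#' @param log_level "quiet" or "info".
#' @return object of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("ldbscreen_run_"),
                            stages = c("simulate", "expression", "motifs",
                                       "screen", "report"),
                            simulate = list(),
                            expression = list(span = 0.3, fdr = 0.05),
                            motifs = list(score_threshold_quantile = 0.999,
                                          methods = c("prima", "demon"),
                                          fdr = 0.05, n_library = 10),
                            screen = list(fdr = 0.05),
                            n_promoter_background = 500,
                            log_level = c("info", "quiet")) {
  stages <- match.arg(stages, c("simulate", "expression", "motifs",
                                "screen", "report"), several.ok = TRUE)
  structure(list(seed = assert_count(seed, "seed", min = 0L),
                 out_dir = out_dir, stages = stages, simulate = simulate,
                 expression = expression, motifs = motifs, screen = screen,
                 n_promoter_background =
                   assert_count(n_promoter_background, "n_promoter_background"),
                 log_level = match.arg(log_level)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{pipeline_config}};
#' per-stage parameter blocks are nested maps.
#'
#' @param path YAML file.
#' @return a \code{PipelineConfig}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

pl_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) {
    message(sprintf(paste0("[ldbscreen] ", fmt), ...))
  }
}

write_manifest <- function(dir, stage, params, inputs, outputs) {
  files <- unlist(outputs, use.names = FALSE)
  manifest <- list(stage = stage, params = params, inputs = inputs,
                   outputs = as.list(setNames(
                     unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order. Each stage writes
#' TSV outputs plus a JSON manifest recording parameters, input files,
#' seed and output checksums. A stage failure halts the run with the
#' failing stage named; outputs of completed stages are retained.
#'
#' @param config a \code{\link{pipeline_config}} (or path to a YAML file).
#' @return invisibly, a list of per-stage output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  # pre-flight: referenced input files must exist before any stage runs
  for (stage in config$stages) {
    blk <- config[[stage]]
    for (key in c("elements", "design", "matrices", "promoters",
                  "targets", "background", "table")) {
      f <- blk[[key]]
      if (!is.null(f) && !file.exists(f)) {
        stop(sprintf("stage '%s': input file '%s' does not exist",
                     stage, f), call. = FALSE)
      }
    }
  }

  results <- list()
  for (stage in config$stages) {
    results[[stage]] <- tryCatch(
      switch(stage,
             simulate = stage_simulate(config),
             expression = stage_expression(config, results),
             motifs = stage_motifs(config, results),
             screen = stage_screen(config, results),
             report = list(report = make_report(out))),
      error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)), call. = FALSE)
      })
    pl_log(config, "stage '%s' complete", stage)
  }
  invisible(results)
}

stage_simulate <- function(config) {
  out <- config$out_dir
  sim_args <- config$simulate
  sim_args$seed <- child_seed(config$seed, 1L)
  cfg <- do.call(simulation_config, sim_args)

  exp <- generate_expression_experiment(cfg)
  write_array_experiment(exp, out)

  promoters <- generate_promoter_set(cfg, config$n_promoter_background)
  lib_n <- config$motifs$n_library %||% 10L
  library_motifs <- random_motif_library(lib_n, width = 8L,
                                         seed = child_seed(config$seed, 2L))
  planted <- library_motifs[[1]]
  # plant the first library matrix into the promoters of the true DE genes'
  # stand-ins (the first n_de promoter ids) at the target rate, and into
  # the rest at the background rate
  n_target <- max(1L, round(0.1 * length(promoters)))
  tgt_ids <- names(promoters)[seq_len(n_target)]
  bg_ids <- setdiff(names(promoters), tgt_ids)
  p1 <- plant_motif_sites(promoters[tgt_ids], planted,
                          cfg$plant_rate_target, cfg$affinity_jitter,
                          seed = child_seed(config$seed, 3L))
  p2 <- plant_motif_sites(promoters[bg_ids], planted,
                          cfg$plant_rate_background, cfg$affinity_jitter,
                          seed = child_seed(config$seed, 4L))
  all_prom <- c(p1$promoters, p2$promoters)[names(promoters)]

  paths <- list(
    promoters = file.path(out, "promoters.fasta"),
    matrices = file.path(out, "matrices.transfac"),
    planted_sites = file.path(out, "planted_sites.tsv"),
    target_ids = file.path(out, "promoter_targets.txt"),
    background_ids = file.path(out, "promoter_background.txt"),
    elements = file.path(out, "elements.tsv"),
    design = file.path(out, "design.tsv"),
    truth = file.path(out, "truth.tsv"))
  write_promoters_fasta(all_prom, paths$promoters)
  write_transfac_matrices(library_motifs, paths$matrices)
  write_tsv(rbind(p1$sites, p2$sites), paths$planted_sites)
  write_gene_list(tgt_ids, paths$target_ids)
  write_gene_list(names(promoters), paths$background_ids)
  write_manifest(out, "simulate",
                 params = c(unclass(cfg), list(global_seed = config$seed)),
                 inputs = list(), outputs = paths)
  paths
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_expression <- function(config, results) {
  out <- config$out_dir
  blk <- config$expression
  elements <- blk$elements %||% results$simulate$elements
  design <- blk$design %||% results$simulate$design
  if (is.null(elements) || is.null(design)) {
    stop("expression stage needs element/design tables (simulate first or supply files)")
  }
  exp <- read_array_experiment(elements, design)
  exp <- filter_low_intensity(exp)
  norm <- normalize_within_array(exp, span = blk$span %||% 0.3)
  norm <- normalize_between_arrays(norm)
  de <- anova_differential(norm)
  targets <- select_targets(de, threshold = blk$fdr %||% 0.05)
  paths <- list(de = file.path(out, "de_results.tsv"),
                down = file.path(out, "targets_down.txt"),
                up = file.path(out, "targets_up.txt"))
  write_de_result(de, paths$de)
  write_gene_list(targets$down, paths$down)
  write_gene_list(targets$up, paths$up)
  write_manifest(out, "expression",
                 params = list(span = blk$span %||% 0.3,
                               fdr = blk$fdr %||% 0.05),
                 inputs = list(elements = elements, design = design),
                 outputs = paths)
  paths
}

stage_motifs <- function(config, results) {
  out <- config$out_dir
  blk <- config$motifs
  prom_file <- blk$promoters %||% results$simulate$promoters
  mat_file <- blk$matrices %||% results$simulate$matrices
  tgt_file <- blk$targets %||% results$simulate$target_ids
  bg_file <- blk$background %||% results$simulate$background_ids
  if (is.null(prom_file) || is.null(mat_file) || is.null(tgt_file) ||
      is.null(bg_file)) {
    stop("motifs stage needs promoters, matrices, targets and background (simulate first or supply files)")
  }
  promoters <- read_promoters_fasta(prom_file)
  matrices <- load_transfac_matrices(mat_file)
  target_ids <- read_gene_list(tgt_file)
  background_ids <- read_gene_list(bg_file)
  res <- run_enrichment(promoters, list(all = target_ids), background_ids,
                        matrices,
                        methods = blk$methods %||% c("prima", "demon"),
                        fdr_threshold = blk$fdr %||% 0.05,
                        score_threshold_quantile =
                          blk$score_threshold_quantile %||% 0.999)
  paths <- list(enrichment = file.path(out, "enrichment.tsv"))
  write_tsv(as.data.frame(res), paths$enrichment)
  write_manifest(out, "motifs",
                 params = list(methods = blk$methods %||% c("prima", "demon"),
                               fdr = blk$fdr %||% 0.05),
                 inputs = list(promoters = prom_file, matrices = mat_file,
                               targets = tgt_file, background = bg_file),
                 outputs = paths)
  paths
}

stage_screen <- function(config, results) {
  out <- config$out_dir
  blk <- config$screen
  table_file <- blk$table %||% system.file("extdata", "screen_table.tsv",
                                           package = "ldbscreen",
                                           mustWork = TRUE)
  tab <- parse_screen_table(table_file)
  summ <- summarize_screen(tab)
  paths <- list(summary = file.path(out, "screen_summary.tsv"),
                bristle = file.path(out, "screen_bristle_summary.json"))
  write_tsv(summ$per_column, paths$summary)
  jsonlite::write_json(summ$bristle, paths$bristle, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write_manifest(out, "screen", params = list(fdr = blk$fdr %||% 0.05),
                 inputs = list(table = table_file), outputs = paths)
  paths
}

#' Assemble a human-readable report from pipeline outputs
#'
#' Aggregates whatever stage outputs are present in the run directory into
#' a plain-text report (selected genes, enrichment tables, screen
#' summary); sections whose outputs are missing are marked absent and the
#' report still completes. Optionally writes diagnostic plots.
#'
#' @param out_dir a pipeline output directory.
#' @param plots if TRUE, writes an enrichment p-value histogram and a
#'   DE volcano-style plot as PNGs alongside the report.
#' @return the report text (character vector of lines), invisibly; the
#'   report is written to \code{report.txt} in \code{out_dir}.
#' @export
make_report <- function(out_dir, plots = FALSE) {
  lines <- c("ldbscreen pipeline report", strrep("=", 25), "")
  de_file <- file.path(out_dir, "de_results.tsv")
  if (file.exists(de_file)) {
    de <- read_tsv(de_file)
    sel <- de[!is.na(de$q) & de$q < 0.05, ]
    lines <- c(lines, "Differential expression",
               sprintf("  genes tested: %d", sum(!is.na(de$p))),
               sprintf("  selected (q < 0.05): %d (%d down, %d up)",
                       nrow(sel), sum(sel$direction == "down"),
                       sum(sel$direction == "up")), "")
    if (plots) {
      grDevices::png(file.path(out_dir, "de_pvalues.png"), 600, 400)
      graphics::hist(de$p, breaks = 40, main = "raw p-values", xlab = "p")
      grDevices::dev.off()
    }
  } else {
    lines <- c(lines, "Differential expression: absent", "")
  }
  enr_file <- file.path(out_dir, "enrichment.tsv")
  if (file.exists(enr_file)) {
    enr <- read_tsv(enr_file)
    lines <- c(lines, "Binding-site enrichment (top 5 per method):")
    for (meth in unique(enr$method)) {
      sub <- head(enr[enr$method == meth, c("motif_id", "set", "p", "q")], 5)
      lines <- c(lines, sprintf("  [%s]", meth),
                 sprintf("    %-12s %-5s p=%.3g q=%.3g", sub$motif_id,
                         sub$set, sub$p, sub$q))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "Binding-site enrichment: absent", "")
  }
  scr_file <- file.path(out_dir, "screen_summary.tsv")
  if (file.exists(scr_file)) {
    scr <- read_tsv(scr_file)
    lines <- c(lines, "Genetic interaction screen:",
               utils::capture.output(print(scr, row.names = FALSE)), "")
  } else {
    lines <- c(lines, "Genetic interaction screen: absent", "")
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(lines)
}
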