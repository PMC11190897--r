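# Config-driven orchestration: run the enabled stages over synthetic or
# user-supplied data, write per-stage TSVs, a machine-readable summary JSON
# and a human-readable report. A stage runs when its block is present in the
# config; per-stage seeds are derived from the global seed by stable hashing
# of the stage name, so one seed fixes the whole run.

known_stages <- c("bulk_de", "enrichment", "receptor_map", "calcium",
                  "nerve", "cellcount")

#' Run the end-to-end pipeline from a configuration
#'
#' The configuration is a YAML file or a nested list with a global `seed` and
#' a `stages` block; each stage block either names input files or carries a
#' `simulate` block of generator arguments. Stages run in dependency order
#' (differential expression feeds enrichment and the receptor screen); every
#' stage writes its table under `out_dir` and contributes to `summary.json`
#' and `report.md`. Unknown stage names are rejected before anything runs,
#' and the fully resolved configuration is echoed to the output directory.
#'
#' @param config Path to a YAML file or a list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the summary list (also written as JSON).
#' @examples
#' \donttest{
#' cfg <- list(seed = 1, stages = list(
#'   bulk_de = list(simulate = list(n_genes = 200, n_samples_per_group = 4),
#'                  group_a = "case", group_b = "control")))
#' run_pipeline(cfg, tempfile())
#' }
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1
  stages <- config$stages %||% list()
  unknown <- setdiff(names(stages), known_stages)
  if (length(unknown) > 0) {
    abort(paste("unknown stage(s) in config:", paste(unknown, collapse = ", ")))
  }
  # fail on missing inputs before any stage runs
  for (st in names(stages)) {
    for (key in intersect(names(stages[[st]]),
                          c("counts", "groups", "gmt", "cells", "map",
                            "traces", "windows", "rois", "recording",
                            "green", "blue"))) {
      p <- stages[[st]][[key]]
      if (is.character(p) && !file.exists(p)) {
        abort(paste0("stage ", st, ": input file not found: ", p))
      }
    }
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  resolved <- config
  resolved$seed <- seed
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))

  summary <- list(seed = seed)
  de <- NULL

  if ("bulk_de" %in% names(stages)) {
    cfg <- stages$bulk_de
    if (!is.null(cfg$simulate)) {
      args <- cfg$simulate
      args$seed <- args$seed %||% derive_seed(seed, "bulk_de")
      sim <- do.call(simulate_bulk_counts, args)
      counts <- sim$counts; groups <- sim$groups
    } else {
      counts <- read_counts_tsv(cfg$counts)
      groups <- read_groups_tsv(cfg$groups)
    }
    de <- run_de(counts, groups,
                 cfg$group_a %||% "case", cfg$group_b %||% "control",
                 min_cpm = cfg$min_cpm %||% 1,
                 min_samples_per_group = cfg$min_samples_per_group %||% 2)
    readr::write_tsv(de, file.path(out_dir, "de.tsv"))
    alpha <- cfg$alpha %||% 1e-4
    summary$bulk_de <- list(n_tested = nrow(de),
                            n_up = sum(de$fdr <= alpha & de$log2_fc > 0),
                            n_down = sum(de$fdr <= alpha & de$log2_fc < 0))
  }

  if ("enrichment" %in% names(stages)) {
    cfg <- stages$enrichment
    if (is.null(de)) abort("enrichment stage requires the bulk_de stage")
    lib <- read_gmt(cfg$gmt)
    alpha <- cfg$alpha %||% 1e-4
    query <- de$gene_id[de$fdr <= alpha & de$log2_fc > 0]
    enr <- enrich(query, lib, universe = de$gene_id,
                  n_permutations = cfg$n_permutations %||% 1000,
                  seed = derive_seed(seed, "enrichment"))
    out <- mutate(enr, overlap_genes = map_chr(.data$overlap_genes,
                                               paste, collapse = ";"))
    readr::write_tsv(out, file.path(out_dir, "enrichment.tsv"))
    summary$enrichment <- list(n_terms = nrow(enr),
                               n_significant = sum(enr$p_adj < 0.05),
                               top_term = enr$term[1])
  }

  if ("receptor_map" %in% names(stages)) {
    cfg <- stages$receptor_map
    if (is.null(de)) abort("receptor_map stage requires the bulk_de stage")
    map_tbl <- if (is.character(cfg$map)) read_mediator_map(cfg$map)
    else as_tibble(cfg$map)
    if (!is.null(cfg$simulate)) {
      args <- cfg$simulate
      args$seed <- args$seed %||% derive_seed(seed, "receptor_map")
      args$gene_spec <- as_tibble(args$gene_spec)
      args$populations <- if (is.list(args$populations)) {
        as_tibble(args$populations)
      } else args$populations
      cells <- do.call(simulate_neuron_expression, args)$tpm
    } else {
      cells <- read_counts_tsv(cfg$cells)
    }
    pri <- prioritize_mediators(de, map_tbl, cells,
                                tpm_threshold = cfg$tpm_threshold %||% 0,
                                alpha = cfg$alpha %||% 1e-4,
                                min_coverage = cfg$min_coverage %||% 0.10)
    readr::write_tsv(pri, file.path(out_dir, "prioritization.tsv"))
    summary$receptor_map <- list(n_mediators = nrow(pri),
                                 n_selected = sum(pri$selected),
                                 top = if (nrow(pri) > 0) pri$mediator[1]
                                 else NA_character_)
  }

  if ("calcium" %in% names(stages)) {
    cfg <- stages$calcium
    if (!is.null(cfg$simulate)) {
      args <- cfg$simulate
      args$seed <- args$seed %||% derive_seed(seed, "calcium")
      ts <- do.call(simulate_trace_set, args)
      background <- ts$background_f
    } else {
      ts <- read_trace_set_csv(cfg$traces, cfg$windows, cfg$rois)
      background <- cfg$background %||% 0
    }
    calls <- classify_responses(ts$traces, ts$windows,
                                background = background,
                                threshold = cfg$threshold %||% 0.1,
                                response_window_s = cfg$response_window_s %||% 90)
    readr::write_tsv(calls, file.path(out_dir, "calcium_calls.tsv"))
    rs <- response_summary(calls)
    summary$calcium <- list(n_included = rs$n_included,
                            n_responsive = rs$n_responsive,
                            responder_pct = rs$pct)
  }

  if ("nerve" %in% names(stages)) {
    cfg <- stages$nerve
    if (!is.null(cfg$simulate)) {
      args <- cfg$simulate
      args$seed <- args$seed %||% derive_seed(seed, "nerve")
      if (!is.null(args$units)) args$units <- as_tibble(args$units)
      rec <- do.call(simulate_recording, args)$recording
    } else {
      rec <- read_recording_csv(cfg$recording, cfg$fs_hz,
                                unlist(cfg$drug_window))
    }
    spikes <- detect_spikes(rec)
    onset <- (rec$drug_window %||% unlist(cfg$drug_window))[1]
    pc <- rate_and_peak_change(spikes, onset)
    readr::write_tsv(spikes, file.path(out_dir, "spikes.tsv"))
    readr::write_tsv(pc$summary, file.path(out_dir, "peak_change.tsv"))
    summary$nerve <- as.list(pc$summary)
  }

  if ("cellcount" %in% names(stages)) {
    cfg <- stages$cellcount
    if (!is.null(cfg$simulate)) {
      args <- cfg$simulate
      args$seed <- args$seed %||% derive_seed(seed, "cellcount")
      img <- do.call(simulate_micrograph, args)
      green <- img$green; blue <- img$blue
    } else {
      green <- read_channel_image(cfg$green)
      blue <- read_channel_image(cfg$blue)
    }
    cc <- count_cells(green, blue, min_area_px = cfg$min_area_px %||% 30)
    readr::write_tsv(cc, file.path(out_dir, "cell_counts.tsv"))
    summary$cellcount <- as.list(cc)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report(summary, out_dir)
  invisible(summary)
}

#' Write a human-readable report from a pipeline summary
#'
#' Renders `report.md` in the output directory with one section per stage
#' that ran; empty stages are omitted.
#'
#' @param summary Summary list as produced by [run_pipeline()].
#' @param out_dir Output directory.
#' @return The report path, invisibly.
#' @export
write_report <- function(summary, out_dir) {
  lines <- c("# Pipeline report", "",
             paste0("Global seed: ", summary$seed), "")
  fmt <- function(x) {
    if (is.numeric(x)) format(signif(x, 4)) else as.character(x)
  }
  for (st in intersect(known_stages, names(summary))) {
    block <- summary[[st]]
    lines <- c(lines, paste0("## ", st), "")
    for (key in names(block)) {
      lines <- c(lines, paste0("- ", key, ": ", fmt(block[[key]])))
    }
    lines <- c(lines, "")
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
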