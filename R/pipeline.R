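pipeline_param_defaults <- function() {
  list(
    fc_threshold = 1.5,   # linear fold-change bound for DE selection
    de_alpha = 0.05,      # p-value bound for DE selection (strict)
    class_cutoff = 0.5,   # strict >50% compartment-enrichment rule
    flank = 2000,         # metagene / TSS-window half-width, bp
    corr_alpha = 0.001,   # significance rule for class correlations
    enrich_alpha = 0.01,  # significance rule for class enrichment
    fc_filter = 1,        # |log2fc| filter used by the filtered correlation
    bin_size = 10,        # coverage bin, bp
    pseudocount = 1,      # log2-ratio stabilizer, signal units
    spike_fraction_hint = 0.15,  # expected spike-in share of each library
    unions = FALSE        # allow union expression classes
  )
}

pipeline_top_keys <- c(
  "seed", "output_dir", "simulate", "annotation", "chrom_sizes",
  "spike_prefix", "samples", "input", "expression_profiles", "de_table",
  "term_map", "parameters"
)

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), rejects unknown
#' keys, injects documented parameter defaults, checks parameter ranges and
#' verifies that every referenced input file exists. A configuration either
#' names input files (`annotation`, `chrom_sizes`, `samples`, `input`, and
#' optionally `expression_profiles`, `de_table`, `term_map`) or carries a
#' `simulate` block of [simulation_config()] arguments, in which case inputs
#' are generated into the output directory.
#'
#' @param config Path to a YAML file, or a list.
#' @return A validated list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      cx_abort(sprintf("Config file not found: %s", config), "cx_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    cx_abort("Config must be a YAML file or a list.", "cx_validation_error")
  }
  unknown <- setdiff(names(config), pipeline_top_keys)
  if (length(unknown) > 0L) {
    cx_abort(sprintf("Unknown config key(s): %s.",
                     paste(unknown, collapse = ", ")),
             "cx_validation_error")
  }
  defaults <- pipeline_param_defaults()
  params <- config$parameters %||% list()
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L) {
    cx_abort(sprintf("Unknown parameter key(s): %s.",
                     paste(unknown, collapse = ", ")),
             "cx_validation_error")
  }
  config$parameters <- utils::modifyList(defaults, params)
  p <- config$parameters
  check_scalar_number(p$fc_threshold, "fc_threshold", min = 1,
                      strict_min = TRUE)
  check_scalar_number(p$de_alpha, "de_alpha", min = 0, max = 1,
                      strict_min = TRUE, strict_max = TRUE)
  check_scalar_number(p$class_cutoff, "class_cutoff", min = 0, max = 1,
                      strict_min = TRUE, strict_max = TRUE)
  check_scalar_number(p$corr_alpha, "corr_alpha", min = 0, max = 1,
                      strict_min = TRUE, strict_max = TRUE)
  check_scalar_number(p$enrich_alpha, "enrich_alpha", min = 0, max = 1,
                      strict_min = TRUE, strict_max = TRUE)
  check_scalar_number(p$flank, "flank", min = 0, strict_min = TRUE)
  check_scalar_number(p$bin_size, "bin_size", min = 1)
  check_scalar_number(p$fc_filter, "fc_filter", min = 0)
  check_scalar_number(p$pseudocount, "pseudocount", min = 0,
                      strict_min = TRUE)
  config$seed <- as.integer(config$seed %||% 42L)
  config$spike_prefix <- config$spike_prefix %||% "spike_"
  if (is.null(config$simulate)) {
    for (key in c("annotation", "chrom_sizes", "samples", "input")) {
      if (is.null(config[[key]])) {
        cx_abort(sprintf("Config needs '%s' (or a 'simulate' block).", key),
                 "cx_validation_error")
      }
    }
    paths <- c(
      config$annotation, config$chrom_sizes, config$expression_profiles,
      config$de_table, config$term_map,
      unlist(map(config$samples, "fragments")),
      unlist(config$input)
    )
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) {
      cx_abort(sprintf("Missing input file(s): %s.",
                       paste(missing, collapse = ", ")), "cx_io_error")
    }
    for (s in config$samples) {
      if (is.null(s$mark) || is.null(s$condition) || is.null(s$fragments)) {
        cx_abort("Each sample needs 'mark', 'condition' and 'fragments'.",
                 "cx_validation_error")
      }
    }
  }
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage in dependency order: (optional) input
#' simulation; fragment ingestion with dual-genome partition and
#' deduplication; spike-in scale factors; input-subtracted coverage tracks
#' (replicates normalized independently and averaged at the subtracted
#' stage); expression classification; DE threshold selection; per-class
#' TSS metagene profiles with between-condition log2 ratios; per-class
#' correlation of promoter mark changes with expression changes (with and
#' without the fold-change filter); and hypergeometric class enrichment of
#' the DE lists. Stages whose inputs are absent (e.g. no DE table) are
#' skipped with an explicit notice. Every output file is listed, with an
#' MD5 checksum, in `manifest.json`; a rerun with the same configuration is
#' byte-identical.
#'
#' @param config A [validate_config()] result, a config list, or a YAML
#'   path.
#' @param out_dir Output directory (overrides the config's `output_dir`).
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest` (the parsed manifest).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$output_dir
  if (is.null(out_dir)) {
    cx_abort("An output directory is required (config 'output_dir' or `out_dir`).",
             "cx_validation_error")
  }
  for (d in file.path(out_dir, c("", "tracks", "tables"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  p <- config$parameters
  outputs <- character()
  notices <- character()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      cx_abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
               "cx_stage_error")
    })
  }

  # -- stage: simulate (optional) --------------------------------------
  if (!is.null(config$simulate)) {
    stage("simulate", {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% config$seed
      sim <- do.call(simulation_config, sim_args)
      sim <- simulate_experiment(sim)
      paths <- write_simulation(sim, file.path(out_dir, "inputs"))
      config$annotation <- paths$annotation
      config$chrom_sizes <- paths$chrom_sizes
      config$expression_profiles <- paths$expression_profiles
      config$de_table <- paths$de_table
      combos <- expand.grid(mark = CHIP_MARKS,
                            condition = c("control", "knockdown"),
                            stringsAsFactors = FALSE)
      config$samples <- pmap(combos, function(mark, condition) {
        list(mark = mark, condition = condition,
             fragments = paths[[paste0("fragments_", mark, "_", condition)]])
      })
      config$input <- list(
        control = paths$fragments_input_control,
        knockdown = paths$fragments_input_knockdown
      )
      outputs <- c(outputs, unlist(paths))
    })
  }

  # -- stage: ingest ----------------------------------------------------
  space <- genes <- NULL
  stage("ingest", {
    space <- read_chrom_sizes(config$chrom_sizes,
                               spike_prefix = config$spike_prefix)
    genes <- read_annotation(config$annotation, space)
  })

  # -- stage: normalize -------------------------------------------------
  sample_log <- list()
  load_sample <- function(path, mark, condition) {
    frags <- read_fragments(path, space)
    part <- partition_fragments(frags, space)
    target <- deduplicate_fragments(part$target)
    spike <- deduplicate_fragments(part$spike)
    sf <- spike_scale_factor(nrow(spike))
    sample_log[[length(sample_log) + 1L]] <<- list(
      file = basename(path), mark = mark, condition = condition,
      n_target = nrow(target), n_spike = nrow(spike), alpha = sf$alpha
    )
    cov <- fragment_coverage(target, space, bin_size = p$bin_size,
                             sample_id = basename(path), mark = mark,
                             condition = condition)
    scale_track(cov, sf)
  }
  subtracted <- list()  # per mark_condition, replicate-averaged
  scaled_chip <- list()
  stage("normalize", {
    input_scaled <- map(
      setNames(names(config$input), names(config$input)),
      function(cond) {
        reps <- map(as.character(unlist(config$input[[cond]])),
                    load_sample, mark = "input", condition = cond)
        average_tracks(reps)
      }
    )
    for (s in config$samples) {
      key <- paste(s$mark, s$condition, sep = "_")
      reps <- map(as.character(unlist(s$fragments)), load_sample,
                  mark = s$mark, condition = s$condition)
      sub_reps <- map(reps, function(chip) {
        out <- chip
        out$values <- map(
          setNames(names(chip$values), names(chip$values)),
          ~ chip$values[[.x]] - input_scaled[[s$condition]]$values[[.x]]
        )
        out$state <- "subtracted"
        out
      })
      scaled_chip[[key]] <- average_tracks(reps)
      subtracted[[key]] <- average_tracks(sub_reps)
      path <- file.path(out_dir, "tracks",
                        paste0(key, "_subtracted.bedGraph"))
      write_bedgraph(subtracted[[key]], path)
      outputs <- c(outputs, path)
    }
  })

  # -- stage: classify --------------------------------------------------
  classes <- NULL
  if (!is.null(config$expression_profiles)) {
    stage("classify", {
      profiles <- readr::read_tsv(config$expression_profiles,
                                  col_types = "cddd", progress = FALSE)
      classes <- classify_expression(profiles, unions = isTRUE(p$unions),
                                      cutoff = p$class_cutoff)
      path <- file.path(out_dir, "tables", "classes.tsv")
      readr::write_tsv(classes, path)
      outputs <- c(outputs, path)
    })
  } else {
    notices <- c(notices,
                 "No expression-profile table: classification skipped.")
  }

  # -- stage: differential ----------------------------------------------
  de_sel <- NULL
  if (!is.null(config$de_table)) {
    stage("differential", {
      de_tab <- readr::read_tsv(config$de_table, col_types = "cdd",
                                progress = FALSE)
      de_sel <- select_de(de_tab, fc_threshold = p$fc_threshold,
                           alpha = p$de_alpha)
      path <- file.path(out_dir, "tables", "de_status.tsv")
      readr::write_tsv(de_sel$table, path)
      outputs <- c(outputs, path)
    })
  } else {
    notices <- c(notices, "No DE table: differential stage skipped.")
  }

  # -- stage: metagene --------------------------------------------------
  metagene <- list()
  if (!is.null(classes)) {
    stage("metagene", {
      for (mark in unique(map_chr(config$samples, "mark"))) {
        prof <- map(c(control = "control", knockdown = "knockdown"),
                    function(cond) {
                      pm <- tss_profile_matrix(
                        subtracted[[paste(mark, cond, sep = "_")]],
                        genes, flank = p$flank)
                      metagene_aggregate(pm, classes)
                    })
        scaled_prof <- map(c(control = "control", knockdown = "knockdown"),
                           function(cond) {
                             pm <- tss_profile_matrix(
                               scaled_chip[[paste(mark, cond, sep = "_")]],
                               genes, flank = p$flank)
                             metagene_aggregate(pm, classes)
                           })
        ratio <- log2_ratio_profile(scaled_prof$knockdown,
                                    scaled_prof$control,
                                    pseudocount = p$pseudocount)
        combined <- bind_rows(
          mutate(prof$control, condition = "control"),
          mutate(prof$knockdown, condition = "knockdown")
        )
        path_prof <- file.path(out_dir, "tables",
                               paste0("metagene_", mark, ".tsv"))
        path_ratio <- file.path(out_dir, "tables",
                                paste0("metagene_ratio_", mark, ".tsv"))
        readr::write_tsv(combined, path_prof)
        readr::write_tsv(ratio, path_ratio)
        outputs <- c(outputs, path_prof, path_ratio)
        metagene[[mark]] <- list(profiles = prof, ratio = ratio)
      }
    })
  } else {
    notices <- c(notices, "No classification: metagene stage skipped.")
  }

  # -- stage: correlate -------------------------------------------------
  correlations <- NULL
  if (!is.null(de_sel) && !is.null(classes)) {
    stage("correlate", {
      changes <- bind_rows(map(
        unique(map_chr(config$samples, "mark")),
        function(mark) {
          gene_signal_change(
            subtracted[[paste(mark, "knockdown", sep = "_")]],
            subtracted[[paste(mark, "control", sep = "_")]],
            genes, region = "tss_window", window = p$flank
          ) |>
            mutate(mark = mark)
        }
      ))
      correlations <- bind_rows(
        correlate_by_class(de_sel$table, changes, classes,
                           fc_filter = "none", corr_alpha = p$corr_alpha),
        correlate_by_class(de_sel$table, changes, classes,
                           fc_filter = "abs_log2fc_ge_1",
                           corr_alpha = p$corr_alpha)
      )
      path <- file.path(out_dir, "tables", "correlations.tsv")
      readr::write_tsv(correlations, path)
      outputs <- c(outputs, path)
    })
  } else {
    notices <- c(notices,
                 "Correlation stage skipped (needs DE table and classes).")
  }

  # -- stage: enrich ----------------------------------------------------
  enrichment <- NULL
  if (!is.null(de_sel) && !is.null(classes)) {
    stage("enrich", {
      universe_de <- semi_join(classes, de_sel$table, by = "gene_id")
      enrichment <- enrich_de_lists(
        intersect(de_sel$up, universe_de$gene_id),
        intersect(de_sel$down, universe_de$gene_id),
        classes, alpha = p$enrich_alpha
      )
      path <- file.path(out_dir, "tables", "enrichment.tsv")
      readr::write_tsv(enrichment, path)
      outputs <- c(outputs, path)
      if (!is.null(config$term_map)) {
        term_map <- readr::read_tsv(config$term_map, col_types = "cc",
                                    progress = FALSE)
        terms <- bind_rows(
          mutate(term_enrichment(de_sel$up, term_map, de_sel$table),
                 direction = "up"),
          mutate(term_enrichment(de_sel$down, term_map, de_sel$table),
                 direction = "down")
        )
        path <- file.path(out_dir, "tables", "term_enrichment.tsv")
        readr::write_tsv(terms, path)
        outputs <- c(outputs, path)
      }
    })
  } else {
    notices <- c(notices,
                 "Enrichment stage skipped (needs DE table and classes).")
  }

  # -- manifest ---------------------------------------------------------
  outputs <- unique(outputs)
  manifest <- list(
    parameters = config$parameters,
    seed = config$seed,
    samples = sample_log,
    notices = as.list(notices),
    outputs = map(setNames(outputs, relative_to(outputs, out_dir)),
                  ~ unname(tools::md5sum(.x)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  walk(notices, rlang::inform)
  invisible(list(
    config = config, space = space, genes = genes, classes = classes,
    de = de_sel, metagene = metagene, correlations = correlations,
    enrichment = enrichment, manifest = manifest,
    manifest_path = manifest_path
  ))
}

relative_to <- function(paths, root) {
  sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", root), "/?"),
      "", paths)
}
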