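#' Build a pipeline run configuration
#'
#' Gathers input paths, sample-group files and module thresholds (the
#' defaults are the published filter/window/sweep thresholds) for a
#' one-command reproduction run over a VCF, an optional IBD segment
#' table and optional field-collection tables. Group membership
#' (e.g. island vs global isotype lists, externally assigned ancestry
#' populations) is consumed as input lists, never inferred here.
#'
#' @param vcf Path to the multi-sample VCF.
#' @param out_dir Output directory for stage outputs and the manifest.
#' @param ibd Optional IBD segment TSV; when absent, segments are
#'   detected internally with [detect_ibd_segments()].
#' @param collections,isolations,env_table Optional field-data CSVs.
#' @param samples_a,samples_b Optional files listing isotype names (one
#'   per line) for the two compared samples; `samples_b` enables F_ST.
#' @param window_size,step Window grid (defaults 10 kb / 1 kb).
#' @param concordance_threshold Isotype rule (default 0.999).
#' @param min_ibd_length,sweep_min_bp,sweep_min_ratio Sweep thresholds.
#' @param seed Seed recorded in the manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf, out_dir, ibd = NULL, collections = NULL,
                       isolations = NULL, env_table = NULL,
                       samples_a = NULL, samples_b = NULL,
                       window_size = 10000, step = 1000,
                       concordance_threshold = 0.999,
                       min_ibd_length = 1e6, sweep_min_bp = 1e6,
                       sweep_min_ratio = 0.03, seed = 1L) {
  for (p in c(vcf, ibd, collections, isolations, env_table,
              samples_a, samples_b)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured input does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(vcf = vcf, out_dir = out_dir, ibd = ibd,
                 collections = collections, isolations = isolations,
                 env_table = env_table, samples_a = samples_a,
                 samples_b = samples_b, window_size = window_size,
                 step = step,
                 concordance_threshold = concordance_threshold,
                 min_ibd_length = min_ibd_length,
                 sweep_min_bp = sweep_min_bp,
                 sweep_min_ratio = sweep_min_ratio,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML-style key: value file
#'
#' @param path Config file: one `key: value` pair per line; keys as in
#'   [run_config()]. Relative paths resolve against the file location.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*)\\s*$",
                                  lines))
  args <- list()
  for (m in kv) {
    if (length(m) == 3) args[[m[2]]] <- utils::type.convert(m[3],
                                                            as.is = TRUE)
  }
  base <- dirname(normalizePath(path))
  for (k in c("vcf", "out_dir", "ibd", "collections", "isolations",
              "env_table", "samples_a", "samples_b")) {
    if (!is.null(args[[k]]) && !startsWith(as.character(args[[k]]), "/")) {
      args[[k]] <- file.path(base, args[[k]])
    }
  }
  do.call(run_config, args)
}

stage_defs <- function(cfg) {
  list(
    filter = list(inputs = cfg$vcf,
                  outputs = file.path(cfg$out_dir, "filtered.vcf")),
    isotype = list(inputs = file.path(cfg$out_dir, "filtered.vcf"),
                   outputs = file.path(cfg$out_dir,
                                       c("concordance.tsv",
                                         "isotypes.tsv"))),
    stats = list(inputs = file.path(cfg$out_dir, "filtered.vcf"),
                 outputs = file.path(cfg$out_dir, "window_stats.tsv")),
    sweep = list(inputs = c(file.path(cfg$out_dir, "filtered.vcf"),
                            cfg$ibd),
                 outputs = file.path(cfg$out_dir,
                                     c("haplotype_blocks.tsv",
                                       "swept_calls.tsv"))),
    eco = list(inputs = c(cfg$collections, cfg$isolations, cfg$env_table),
               outputs = file.path(cfg$out_dir, "ecology_tallies.tsv"))
  )
}

#' Run the full analysis pipeline
#'
#' Executes filter -> isotype -> stats -> sweep -> eco in dependency
#' order over a [run_config()], writing stage outputs and a JSON run
#' manifest (input checksums, parameter values, completed stages) to
#' the output directory. A stage whose outputs exist and whose recorded
#' input checksums match the current inputs is skipped (reported
#' `cached`); deleting an intermediate re-runs only that stage and its
#' dependents. Any stage failure aborts with the stage name.
#'
#' @param cfg A [run_config()].
#' @return The manifest (a list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  prev <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  defs <- stage_defs(cfg)
  params <- cfg[setdiff(names(cfg), c("vcf", "out_dir", "ibd",
                                      "collections", "isolations",
                                      "env_table"))]
  manifest <- list(created = NA, parameters = params, stages = list())

  checksum <- function(paths) {
    paths <- paths[!is.na(paths) & file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  fresh <- function(stage) {
    d <- defs[[stage]]
    if (!all(file.exists(d$outputs))) return(FALSE)
    rec <- prev$stages[[stage]]
    if (is.null(rec)) return(FALSE)
    identical(as.list(rec$input_md5), checksum(d$inputs)) &&
      identical(rec$parameters_md5, params_md5(params))
  }
  params_md5 <- function(p) {
    tmp <- tempfile(); on.exit(unlink(tmp))
    writeLines(paste(names(p), vapply(p, paste, "", collapse = ","),
                     sep = "="), tmp)
    unname(tools::md5sum(tmp))
  }

  run_stage <- function(stage, fun) {
    if (fresh(stage)) {
      message("[", stage, "] cached")
      status <- "cached"
    } else {
      message("[", stage, "] running")
      ok <- tryCatch({fun(); TRUE},
                     error = function(e) {
                       stop("stage '", stage, "' failed: ",
                            conditionMessage(e), call. = FALSE)
                     })
      status <- "completed"
    }
    manifest$stages[[stage]] <<- list(
      status = status,
      inputs = as.list(defs[[stage]]$inputs),
      input_md5 = checksum(defs[[stage]]$inputs),
      outputs = as.list(defs[[stage]]$outputs),
      parameters_md5 = params_md5(params)
    )
  }

  read_list <- function(path) if (is.null(path)) NULL else readLines(path)

  run_stage("filter", function() {
    g <- read_vcf_genotypes(cfg$vcf)
    g <- hard_filter(g, filter_thresholds("population"))
    write_genotypes_vcf(g, defs$filter$outputs)
  })
  g <- read_vcf_genotypes(defs$filter$outputs)

  run_stage("isotype", function() {
    cm <- pairwise_concordance(g)
    utils::write.table(concordance_pairs(cm), defs$isotype$outputs[1],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    part <- assign_isotypes(cm, cfg$concordance_threshold)
    utils::write.table(part, defs$isotype$outputs[2], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  run_stage("stats", function() {
    sa <- read_list(cfg$samples_a) %||% g$samples
    ws <- window_stats(g, sa, cfg$window_size, cfg$step)
    ws$sample <- "sample_a"
    sb <- read_list(cfg$samples_b)
    if (!is.null(sb)) {
      wsb <- window_stats(g, sb, cfg$window_size, cfg$step)
      wsb$sample <- "sample_b"
      fst <- window_hudson_fst(g, sa, sb, cfg$window_size, cfg$step)
      ws$fst <- fst$fst[match(paste(ws$chrom, ws$start),
                              paste(fst$chrom, fst$start))]
      wsb$fst <- NA_real_
      ws <- rbind(ws, wsb)
    }
    utils::write.table(ws, defs$stats$outputs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  run_stage("sweep", function() {
    segs <- if (!is.null(cfg$ibd)) read_ibd_segments(cfg$ibd) else
      detect_ibd_segments(g, min_length = cfg$min_ibd_length)
    blocks <- infer_haplotype_blocks(segs, g$samples)
    utils::write.table(blocks, defs$sweep$outputs[1], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    swept <- identify_swept_haplotype(blocks)
    calls <- classify_swept_chromosomes(blocks, swept, g$contig_lengths,
                                        isotypes = g$samples,
                                        min_bp = cfg$sweep_min_bp,
                                        min_ratio = cfg$sweep_min_ratio)
    utils::write.table(calls, defs$sweep$outputs[2], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  run_stage("eco", function() {
    if (is.null(cfg$collections)) {
      writeLines("no field data supplied", defs$eco$outputs)
      return(invisible())
    }
    rec <- read_collections(cfg$collections)
    tal <- tally_categories(rec)
    utils::write.table(tal$by_island, defs$eco$outputs, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  manifest$created <- "run manifest"
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
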