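#' Run a pipeline stage from a configuration
#'
#' Wires the package's stages into reproducible file-to-file runs. Each
#' stage reads its inputs, executes the corresponding functions, writes
#' tabular outputs into `out_dir`, and records a `run_metadata.json` with
#' the stage, inputs, parameters, seed, package version, a configuration
#' hash and headline output counts. All randomness flows from the single
#' `seed` via named per-stage substreams ([substream_seed()]), so stages are
#' individually reproducible.
#'
#' Stages and their outputs:
#' * `simulate`: candidate manifest CSV, discovery genotype TSV + labels
#'   sidecar, and (when a cross block is configured) progeny genotypes and
#'   truth-segment BED.
#' * `design`: selected-panel manifest CSV, provenance TSV, coverage report
#'   TSV, unmet-constraints JSON.
#' * `polymorphism`: pair-count TSV, group-pair summary TSV, subgroup
#'   heatmap matrix TSV, spacing-statistics JSON.
#' * `introgress`: coded-genotype TSV (A/B/H/NC grid), detected segments
#'   BED, foreground/background report JSON.
#' * `diversity`: Newick tree, distance matrix TSV, PCA scores TSV,
#'   explained-variance JSON.
#'
#' @param stage One of `"simulate"`, `"design"`, `"polymorphism"`,
#'   `"introgress"`, `"diversity"`.
#' @param config A named list of stage settings, or the path to a YAML/JSON
#'   file holding one. See the package vignette for the recognised fields
#'   per stage.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer top-level seed.
#' @return Invisibly, a list of the stage's main in-memory results.
#' @export
run_stage <- function(stage = c("simulate", "design", "polymorphism",
                                "introgress", "diversity"),
                      config = list(), out_dir, seed = 1L) {
  stage <- match.arg(stage)
  config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(stage,
    simulate = stage_simulate(config, out_dir, seed),
    design = stage_design(config, out_dir, seed),
    polymorphism = stage_polymorphism(config, out_dir, seed),
    introgress = stage_introgress(config, out_dir, seed),
    diversity = stage_diversity(config, out_dir, seed))
  meta <- list(stage = stage, seed = seed,
               version = as.character(utils::packageVersion("ricepanel")),
               config_hash = config_hash(config),
               config = config[setdiff(names(config), "chromosome_lengths")],
               counts = res$counts, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(res)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(paste0("no such config file: ", config))
    if (grepl("\\.json$", config)) {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        abort("reading YAML configs requires the yaml package")
      }
      config <- yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  config
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)))
}

stage_simulate <- function(config, out_dir, seed) {
  cat_args <- config$catalog %||% list()
  if (!is.null(cat_args$chromosome_lengths)) {
    cat_args$chromosome_lengths <- unlist(cat_args$chromosome_lengths)
  }
  cat_cfg <- do.call(catalog_sim_config,
                     c(cat_args,
                       list(seed = substream_seed(seed, "catalog"))))
  manifest <- simulate_catalog(cat_cfg)
  pan_args <- config$panel %||% list()
  if (!is.null(pan_args$n_per_group)) {
    pan_args$n_per_group <- unlist(pan_args$n_per_group)
  }
  if (!is.null(pan_args$fst_per_group)) {
    pan_args$fst_per_group <- unlist(pan_args$fst_per_group)
  }
  pan_cfg <- do.call(panel_sim_config,
                     c(pan_args, list(seed = substream_seed(seed, "panel"))))
  geno <- simulate_panel(manifest, pan_cfg)
  write_manifest(manifest, file.path(out_dir, "catalog.csv"))
  write_genotypes(geno, file.path(out_dir, "genotypes.tsv"),
                  file.path(out_dir, "labels.tsv"))
  counts <- list(n_markers = nrow(manifest),
                 n_accessions = length(geno_accessions(geno)))
  cross <- NULL
  if (!is.null(config$cross)) {
    cr_args <- config$cross
    if (!is.null(cr_args$target)) cr_args$target <- as_interval_tbl(cr_args$target)
    cr_cfg <- do.call(cross_sim_config,
                      c(cr_args, list(seed = substream_seed(seed, "cross"))))
    cross <- simulate_cross(geno, cr_cfg)
    write_genotypes(cross$geno, file.path(out_dir, "progeny_genotypes.tsv"),
                    file.path(out_dir, "progeny_labels.tsv"))
    write_segments_bed(cross$truth, file.path(out_dir, "truth_segments.bed"))
    counts$n_progeny <- length(geno_accessions(cross$geno))
  }
  list(manifest = manifest, geno = geno, cross = cross, counts = counts)
}

read_stage_inputs <- function(config) {
  geno <- read_genotypes(config$genotypes, format = config$format %||% "table",
                         labels_path = config$labels)
  manifest <- if (!is.null(config$manifest)) read_manifest(config$manifest)
  lens <- if (!is.null(manifest)) {
    ln <- tapply(manifest$position, manifest$chromosome, max)
    setNames(ceiling(as.numeric(ln) / 1e6) * 1e6, names(ln))
  }
  if (!is.null(config$chromosome_lengths)) {
    lens <- unlist(config$chromosome_lengths)
  }
  attr(geno, "chromosome_lengths") <- lens
  list(geno = geno, manifest = manifest, lens = lens)
}

stage_design <- function(config, out_dir, seed) {
  inp <- read_stage_inputs(config)
  manifest <- inp$manifest
  if (is.null(manifest)) abort("design stage needs a manifest")
  if (!is.null(inp$lens)) attr(manifest, "chromosome_lengths") <- inp$lens
  pol_args <- config$policy %||% list()
  if (!is.null(pol_args$crosses)) {
    pol_args$crosses <- lapply(pol_args$crosses, unlist)
  }
  policy <- do.call(design_policy, pol_args)
  legacy <- if (!is.null(config$legacy)) {
    readr::read_lines(config$legacy)
  } else character()
  design <- design_panel(inp$geno, manifest, policy, legacy = legacy)
  write_manifest(design$selected, file.path(out_dir, "panel.csv"))
  readr::write_tsv(design$provenance, file.path(out_dir, "provenance.tsv"),
                   progress = FALSE)
  readr::write_tsv(design$coverage, file.path(out_dir, "coverage.tsv"),
                   progress = FALSE)
  jsonlite::write_json(design$unmet_constraints,
                       file.path(out_dir, "unmet_constraints.json"),
                       auto_unbox = TRUE, na = "null")
  list(design = design,
       counts = list(n_selected = nrow(design$selected),
                     n_unmet = nrow(design$unmet_constraints)))
}

stage_polymorphism <- function(config, out_dir, seed) {
  inp <- read_stage_inputs(config)
  summ <- all_pairs_summary(inp$geno,
                            het_handling = config$het_handling %||%
                              "differ_counts")
  sp <- spacing_stats(geno_markers(inp$geno),
                      thresholds = config$thresholds %||% c(60e3, 220e3))
  readr::write_tsv(summ$pairs, file.path(out_dir, "pair_counts.tsv"),
                   progress = FALSE)
  readr::write_tsv(summ$groups, file.path(out_dir, "group_summary.tsv"),
                   progress = FALSE)
  utils::write.table(summ$group_matrix,
                     file.path(out_dir, "heatmap_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(mean_adjacent_gap_bp = sp$mean_adjacent_gap_bp,
         median_adjacent_gap_bp = sp$median_adjacent_gap_bp,
         thresholds = sp$thresholds),
    file.path(out_dir, "spacing_stats.json"), auto_unbox = TRUE, digits = NA)
  list(summary = summ, spacing = sp,
       counts = list(n_pairs = nrow(summ$pairs)))
}

stage_introgress <- function(config, out_dir, seed) {
  inp <- read_stage_inputs(config)
  coded <- classify_progeny(inp$geno, config$recurrent, config$donor)
  segs <- detect_segments(coded)
  out <- list(coded = coded, segments = segs)
  readr::write_tsv(as_tibble(coded), file.path(out_dir, "coded_genotypes.tsv"),
                   progress = FALSE)
  if (nrow(segs) > 0L) {
    bed <- segs
    bed$start <- bed$min_start
    bed$end <- bed$min_end
    write_segments_bed(bed, file.path(out_dir, "segments.bed"))
  }
  report <- list(n_informative = nrow(coded), n_segments = nrow(segs))
  if (!is.null(config$qtl)) {
    qtl <- as_interval_tbl(config$qtl)
    fg <- foreground_status(coded, qtl)
    bg <- background_recovery(coded, exclude = qtl)
    readr::write_tsv(fg, file.path(out_dir, "foreground.tsv"),
                     progress = FALSE)
    readr::write_tsv(bg, file.path(out_dir, "background.tsv"),
                     progress = FALSE)
    report$foreground <- as.list(table(fg$status))
    report$mean_background_recovery <- mean(bg$recovery)
    out$foreground <- fg
    out$background <- bg
  }
  jsonlite::write_json(report, file.path(out_dir, "introgress_report.json"),
                       auto_unbox = TRUE, digits = NA)
  out$counts <- list(n_informative = nrow(coded), n_segments = nrow(segs))
  out
}

stage_diversity <- function(config, out_dir, seed) {
  inp <- read_stage_inputs(config)
  geno <- filter_loci(inp$geno,
                      min_mac = config$min_mac %||% 5,
                      min_call_rate = config$min_call_rate %||% 0.8)
  tree <- bootstrap_tree(geno, method = config$method %||% "p_distance",
                         n_reps = config$bootstrap %||% 100,
                         seed = substream_seed(seed, "bootstrap"))
  d <- genotype_distance(geno, method = config$method %||% "p_distance")
  p <- pca_genotypes(geno, n_components = config$pca %||% 3)
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  utils::write.table(as.matrix(d), file.path(out_dir, "distances.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  readr::write_tsv(p$scores, file.path(out_dir, "pca_scores.tsv"),
                   progress = FALSE)
  jsonlite::write_json(list(explained_variance = p$explained_variance),
                       file.path(out_dir, "pca_variance.json"),
                       auto_unbox = TRUE, digits = NA)
  list(tree = tree, dist = d, pca = p,
       counts = list(n_loci = nrow(geno),
                     n_accessions = length(geno_accessions(geno))))
}

#' Command-line entry point
#'
#' Thin argv parser over [run_stage()], used by the `inst/cli/ricepanel`
#' Rscript wrapper: `ricepanel <stage> --config cfg.yaml --out dir
#' [--seed N]`. Unknown stages or missing arguments produce a one-line
#' diagnostic on stderr and a non-zero status.
#'
#' @param args Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 on success).
#' @export
rice_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- c("simulate", "design", "polymorphism", "introgress", "diversity")
  usage <- paste0("usage: ricepanel <",
                  paste(stages, collapse = "|"),
                  "> --config FILE --out DIR [--seed N]")
  fail <- function(msg) {
    message(msg)
    invisible(1L)
  }
  if (length(args) < 1L) return(fail(usage))
  stage <- args[1]
  if (!stage %in% stages) {
    return(fail(paste0("unknown subcommand '", stage, "'\n", usage)))
  }
  opt <- list(seed = 1L)
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- rest[i]
    if (!key %in% c("--config", "--out", "--seed")) {
      return(fail(paste0("unknown flag '", key, "'\n", usage)))
    }
    if (i == length(rest)) return(fail(paste0("missing value for ", key)))
    val <- rest[i + 1L]
    opt[[sub("^--", "", key)]] <- val
    i <- i + 2L
  }
  if (is.null(opt$out)) return(fail("missing --out\n"))
  status <- tryCatch({
    run_stage(stage, config = opt$config %||% list(), out_dir = opt$out,
              seed = as.integer(opt$seed))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
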