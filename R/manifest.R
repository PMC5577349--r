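#' Marker manifests
#'
#' A marker manifest is an ordered tibble of candidate or panel SNPs, one row
#' per marker, sorted by (chromosome, position) with natural chromosome
#' ordering. It is the in-memory analogue of an array content table: the fixed
#' description of where each assayed SNP sits and what is known about its
#' flanking context from the discovery panel.
#'
#' Required columns: `marker_id`, `chromosome`, `position` (1-based bp),
#' `ref`, `alt`. Optional annotation columns default to benign values when
#' absent: `is_indel` (FALSE), `is_repetitive` (FALSE), `designable` (TRUE),
#' `global_maf` (NA), `flank_variants` (empty), `source` (`"resequencing"`).
#' `flank_variants` is a list-column: each element a tibble with `offset`
#' (signed bp from the target SNP, never 0) and `minor_hom` (count of minor
#' homozygotes observed at that flanking variant in the discovery panel).
#'
#' @param x A data frame with at least the required columns.
#' @param chromosome_lengths Named numeric vector of chromosome lengths in bp.
#'   Optional; required by operations that bin the genome.
#' @return A tibble of class `marker_manifest`, sorted, with duplicate
#'   (chromosome, position) rows collapsed to the first occurrence (with a
#'   warning). The number of collapsed duplicates is recorded in attribute
#'   `n_duplicates_dropped`.
#' @export
marker_manifest <- function(x, chromosome_lengths = NULL) {
  x <- as_tibble(x)
  required <- c("marker_id", "chromosome", "position", "ref", "alt")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0("manifest is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(x$position) || anyNA(x$position) ||
      any(x$position != floor(x$position))) {
    abort("manifest `position` must be integer bp with no missing values")
  }
  if (any(x$position < 1)) abort("manifest positions must be >= 1 (1-based)")
  if (any(x$ref == x$alt)) abort("ref and alt alleles must differ")

  if (!"is_indel" %in% names(x)) x$is_indel <- FALSE
  if (!"is_repetitive" %in% names(x)) x$is_repetitive <- FALSE
  if (!"designable" %in% names(x)) x$designable <- TRUE
  if (!"global_maf" %in% names(x)) x$global_maf <- NA_real_
  if (!"flank_variants" %in% names(x)) {
    x$flank_variants <- rep(list(empty_flanks()), nrow(x))
  }
  if (!"source" %in% names(x)) x$source <- "resequencing"
  bad_maf <- !is.na(x$global_maf) & (x$global_maf < 0 | x$global_maf > 0.5)
  if (any(bad_maf)) abort("global_maf must lie in [0, 0.5]")
  for (fv in x$flank_variants) {
    if (nrow(fv) > 0L && any(fv$offset == 0)) {
      abort("flank_variants offsets must be non-zero")
    }
  }

  x <- arrange_genome(x)
  key <- paste(x$chromosome, x$position)
  dup <- duplicated(key)
  if (any(dup)) {
    warn(sprintf("%d duplicate (chromosome, position) record(s) collapsed to first",
                 sum(dup)))
    x <- x[!dup, , drop = FALSE]
  }
  if (!is.null(chromosome_lengths)) {
    stopifnot(!is.null(names(chromosome_lengths)))
    unknown <- setdiff(unique(x$chromosome), names(chromosome_lengths))
    if (length(unknown) > 0L) {
      abort(paste0("chromosome(s) missing from chromosome_lengths: ",
                   paste(unknown, collapse = ", ")))
    }
    too_far <- x$position > chromosome_lengths[x$chromosome]
    if (any(too_far)) {
      abort(sprintf("%d marker position(s) exceed their chromosome length",
                    sum(too_far)))
    }
  }
  attr(x, "chromosome_lengths") <- chromosome_lengths
  attr(x, "n_duplicates_dropped") <- sum(dup)
  class(x) <- c("marker_manifest", class(tibble()))
  x
}

empty_flanks <- function() tibble(offset = integer(), minor_hom = integer())

#' @rdname marker_manifest
#' @export
chromosome_lengths <- function(x) attr(x, "chromosome_lengths")

#' Read a marker manifest from CSV
#'
#' Expects columns `marker_id`, `chromosome`, `position`, `ref`, `alt`;
#' optional `is_indel`, `is_repetitive`, `designable`, `global_maf`,
#' `flank_variants` (semicolon-separated `offset:count` pairs) and `source`.
#' Rows are returned sorted by (chromosome, position); duplicated coordinates
#' are collapsed to the first record with a warning.
#'
#' @param path Path to a CSV file.
#' @param chromosome_lengths Optional named vector of chromosome lengths (bp).
#' @return A [marker_manifest] tibble.
#' @export
read_manifest <- function(path, chromosome_lengths = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("marker_id", "chromosome", "position", "ref", "alt")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0("manifest file ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(x$position)) {
    abort(paste0("non-integer position column in ", path))
  }
  if ("flank_variants" %in% names(x)) {
    x$flank_variants <- parse_flank_field(x$flank_variants)
  }
  marker_manifest(x, chromosome_lengths = chromosome_lengths)
}

parse_flank_field <- function(s) {
  lapply(s, function(si) {
    if (is.na(si) || !nzchar(si)) return(empty_flanks())
    parts <- strsplit(si, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    ok <- vapply(kv, length, integer(1)) == 2L
    if (!all(ok)) abort("malformed flank_variants field; expected 'offset:count;...'")
    tibble(offset = as.integer(vapply(kv, `[`, "", 1L)),
           minor_hom = as.integer(vapply(kv, `[`, "", 2L)))
  })
}

format_flank_field <- function(fv_list) {
  vapply(fv_list, function(fv) {
    if (is.null(fv) || nrow(fv) == 0L) return("")
    paste(sprintf("%d:%d", as.integer(fv$offset), as.integer(fv$minor_hom)),
          collapse = ";")
  }, character(1))
}

#' Write a marker manifest to CSV
#'
#' Inverse of [read_manifest()]: `flank_variants` list-columns are serialised
#' as semicolon-separated `offset:count` pairs.
#'
#' @param manifest A [marker_manifest].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  x <- as_tibble(manifest)
  x$flank_variants <- format_flank_field(x$flank_variants)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Marker spacing statistics
#'
#' Computes adjacent-gap and nearest-neighbor spacing statistics for a marker
#' panel: the distribution of gaps between consecutive markers within each
#' chromosome, and for each marker the distance to its closest neighbor (the
#' smaller of its two flanking gaps; markers at chromosome ends have a single
#' flank). Fractions are computed over all markers on chromosomes carrying at
#' least two markers, and "within a threshold" is inclusive (`<=`).
#'
#' @param manifest A [marker_manifest] (or any tibble with `chromosome` and
#'   `position` columns).
#' @param thresholds Numeric vector of nearest-neighbor distance thresholds
#'   in bp at which to evaluate the cumulative fraction.
#' @return A list of class `spacing_stats` with elements
#'   `mean_adjacent_gap_bp`, `median_adjacent_gap_bp`, `gaps` (tibble of
#'   per-chromosome adjacent gaps), `nn` (tibble of per-marker
#'   nearest-neighbor distances) and `thresholds` (tibble with `threshold_bp`,
#'   `frac_within`, `frac_beyond`).
#' @export
spacing_stats <- function(manifest, thresholds = c(60e3, 220e3)) {
  x <- arrange_genome(as_tibble(manifest)[, c("chromosome", "position")])
  per_chr <- split(x$position, x$chromosome)
  per_chr <- per_chr[vapply(per_chr, length, integer(1)) >= 2L]
  if (length(per_chr) == 0L) {
    abort("no gaps defined: every chromosome has fewer than 2 markers")
  }
  gaps <- bind_rows(lapply(names(per_chr), function(ch) {
    tibble(chromosome = ch, gap_bp = diff(sort(per_chr[[ch]])))
  }))
  nn <- bind_rows(lapply(names(per_chr), function(ch) {
    p <- sort(per_chr[[ch]])
    g <- diff(p)
    left <- c(Inf, g)
    right <- c(g, Inf)
    tibble(chromosome = ch, position = p, nn_bp = pmin(left, right))
  }))
  thr <- tibble(
    threshold_bp = as.numeric(thresholds),
    frac_within = vapply(thresholds, function(t) mean(nn$nn_bp <= t), 0),
    frac_beyond = vapply(thresholds, function(t) mean(nn$nn_bp > t), 0)
  )
  structure(list(mean_adjacent_gap_bp = mean(gaps$gap_bp),
                 median_adjacent_gap_bp = median(gaps$gap_bp),
                 gaps = gaps, nn = nn, thresholds = thr),
            class = "spacing_stats")
}

#' @exportS3Method base::print
print.spacing_stats <- function(x, ...) {
  cat(sprintf("Marker spacing over %d gaps on %d chromosome(s)\n",
              nrow(x$gaps), length(unique(x$gaps$chromosome))))
  cat(sprintf("  mean adjacent gap:   %.1f kb\n", x$mean_adjacent_gap_bp / 1e3))
  cat(sprintf("  median adjacent gap: %.1f kb\n",
              x$median_adjacent_gap_bp / 1e3))
  for (i in seq_len(nrow(x$thresholds))) {
    cat(sprintf("  nearest neighbor <= %.0f kb: %.1f%%\n",
                x$thresholds$threshold_bp[i] / 1e3,
                100 * x$thresholds$frac_within[i]))
  }
  invisible(x)
}
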