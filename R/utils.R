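#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows distinct n rename across all_of pull row_number
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats rbeta rbinom rpois runif median setNames complete.cases
#' @importFrom utils head tail
NULL

# Natural chromosome ordering: "chr2" before "chr10"; non-numeric names sort
# lexicographically after numeric ones.
chrom_rank <- function(chromosome) {
  num <- suppressWarnings(as.numeric(sub("^[Cc]hr", "", chromosome)))
  order_key <- ifelse(is.na(num), Inf, num)
  rank(order_key, ties.method = "min") * 0 + order_key  # numeric key
}

chrom_levels <- function(chromosome) {
  u <- unique(chromosome)
  u[order(chrom_rank(u), u)]
}

# Sort a marker-style tibble by (chromosome, position) in natural order.
arrange_genome <- function(tbl) {
  tbl[order(chrom_rank(tbl$chromosome), tbl$chromosome, tbl$position), ,
      drop = FALSE]
}

#' Deterministic per-stage seed derived from a single top-level seed
#'
#' All pipeline stages draw their randomness from one user-supplied seed via
#' named substreams, so each stage is individually reproducible.
#'
#' @param seed Integer top-level seed.
#' @param stage Stage name, e.g. `"panel"`, `"catalog"`, `"cross"`.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x)

#' Describe a genomic interval
#'
#' Intervals are 1-based and inclusive on both ends throughout the package,
#' matching the physical-position convention of the rice MSUv7 assembly.
#' BED exports convert to 0-based half-open coordinates.
#'
#' @param chromosome Chromosome name, e.g. `"chr9"`.
#' @param start,end 1-based inclusive bp coordinates, `start <= end`.
#' @return A one-row tibble with columns `chromosome`, `start`, `end`.
#' @examples
#' genomic_interval("chr9", 6388840, 6658011)
#' @export
genomic_interval <- function(chromosome, start, end) {
  stopifnot(length(chromosome) == 1L, is_count(start), is_count(end),
            start >= 1, start <= end)
  tibble(chromosome = as.character(chromosome),
         start = as.numeric(start), end = as.numeric(end))
}

as_interval_tbl <- function(x) {
  if (is_tibble(x) || is.data.frame(x)) {
    stopifnot(all(c("chromosome", "start", "end") %in% names(x)))
    return(as_tibble(x)[, c("chromosome", "start", "end")])
  }
  if (is.list(x) && all(c("chromosome", "start", "end") %in% names(x))) {
    return(genomic_interval(x$chromosome, x$start, x$end))
  }
  abort("cannot interpret `x` as a genomic interval")
}

# positions inside any of a set of intervals (same chromosome handling)
pos_in_intervals <- function(chromosome, position, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(rep(FALSE, length(position)))
  }
  hit <- rep(FALSE, length(position))
  for (k in seq_len(nrow(intervals))) {
    hit <- hit | (chromosome == intervals$chromosome[k] &
                    position >= intervals$start[k] &
                    position <= intervals$end[k])
  }
  hit
}
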