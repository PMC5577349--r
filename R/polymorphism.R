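#' Count polymorphic SNPs between two accessions
#'
#' A locus counts as polymorphic between a pair when both calls are
#' non-missing and differ. Under `het_handling = "differ_counts"` (default)
#' any call difference counts (0 vs 1, 1 vs 2, 0 vs 2); under `"hom_only"`
#' both calls must additionally be homozygous, so only opposite homozygotes
#' (0 vs 2) count — the strict criterion used when scoring markers for
#' biparental fixed-line work. Loci with a no-call in either accession are
#' excluded (no imputation).
#'
#' @param geno A [geno_tbl].
#' @param a,b Accession ids. `a == b` returns 0.
#' @param het_handling `"differ_counts"` or `"hom_only"`.
#' @return Integer count.
#' @export
pairwise_polymorphic_count <- function(geno, a, b,
                                       het_handling = c("differ_counts",
                                                        "hom_only")) {
  het_handling <- match.arg(het_handling)
  calls <- geno_calls(geno)
  for (p in c(a, b)) {
    if (!p %in% colnames(calls)) abort(paste0("unknown accession: ", p))
  }
  ga <- calls[, a]
  gb <- calls[, b]
  ok <- !is.na(ga) & !is.na(gb)
  if (het_handling == "hom_only") ok <- ok & ga != 1L & gb != 1L
  sum(ok & ga != gb)
}

#' Pairwise polymorphism summary over all accession pairs
#'
#' Computes the polymorphic-SNP count for every unordered accession pair and
#' aggregates per group pair (number of pairs, mean/median/min/max counts).
#' The full accession-by-accession count matrix is kept for heatmap display,
#' together with a group-level mean matrix.
#'
#' @inheritParams pairwise_polymorphic_count
#' @return An object of class `pair_summary`: list with `pairs` (tibble `a`,
#'   `b`, `group_a`, `group_b`, `count`), `groups` (per group-pair summary),
#'   `matrix` (accession x accession counts) and `group_matrix` (group-pair
#'   means).
#' @export
all_pairs_summary <- function(geno, het_handling = c("differ_counts",
                                                     "hom_only")) {
  het_handling <- match.arg(het_handling)
  calls <- geno_calls(geno)
  n_acc <- ncol(calls)
  if (n_acc < 2L) abort("need at least 2 accessions")
  # indicator crossproducts: counts of loci with joint codes (k, l)
  ind <- lapply(c(0L, 1L, 2L), function(k) {
    m <- (calls == k)
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  names(ind) <- c("0", "1", "2")
  if (het_handling == "differ_counts") {
    called <- ind[["0"]] + ind[["1"]] + ind[["2"]]
    both_called <- crossprod(called)
    same <- crossprod(ind[["0"]]) + crossprod(ind[["1"]]) +
      crossprod(ind[["2"]])
    cnt <- both_called - same
  } else {
    cnt <- crossprod(ind[["0"]], ind[["2"]]) +
      crossprod(ind[["2"]], ind[["0"]])
  }
  diag(cnt) <- 0
  grp <- group_of(geno)[colnames(calls)]
  ut <- which(upper.tri(cnt), arr.ind = TRUE)
  pairs <- tibble(a = colnames(calls)[ut[, 1]], b = colnames(calls)[ut[, 2]],
                  group_a = unname(grp[ut[, 1]]),
                  group_b = unname(grp[ut[, 2]]),
                  count = as.integer(cnt[ut]))
  gp <- t(apply(pairs[, c("group_a", "group_b")], 1L, sort))
  pairs$group_pair <- paste(gp[, 1], gp[, 2], sep = " vs ")
  groups <- pairs |>
    group_by(.data$group_pair) |>
    summarise(n_pairs = dplyr::n(), mean = mean(.data$count),
              median = median(.data$count), min = min(.data$count),
              max = max(.data$count), .groups = "drop")
  glev <- sort(unique(grp))
  gm <- matrix(NA_real_, length(glev), length(glev),
               dimnames = list(glev, glev))
  for (i in seq_along(glev)) {
    for (j in seq_along(glev)) {
      key <- paste(sort(c(glev[i], glev[j])), collapse = " vs ")
      sub <- pairs$count[pairs$group_pair == key]
      if (length(sub) > 0L) gm[i, j] <- mean(sub)
    }
  }
  structure(list(pairs = pairs, groups = groups, matrix = cnt,
                 group_matrix = gm, het_handling = het_handling),
            class = "pair_summary")
}

#' @exportS3Method base::print
print.pair_summary <- function(x, ...) {
  cat(sprintf("<pair_summary> %d pairs, policy = %s\n", nrow(x$pairs),
              x$het_handling))
  cat(sprintf("  overall mean polymorphic SNPs/pair: %.0f\n",
              mean(x$pairs$count)))
  print(x$groups, n = 10)
  invisible(x)
}

#' @rdname all_pairs_summary
#' @param x A `pair_summary`.
#' @param what `"pairs"` (default) or `"groups"`.
#' @param ... Unused.
#' @method tidy pair_summary
#' @export
tidy.pair_summary <- function(x, what = c("pairs", "groups"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' @rdname all_pairs_summary
#' @method glance pair_summary
#' @export
glance.pair_summary <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), mean_count = mean(x$pairs$count),
         min_count = min(x$pairs$count), max_count = max(x$pairs$count),
         het_handling = x$het_handling)
}
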