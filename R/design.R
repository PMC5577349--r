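#' Panel design policy
#'
#' Bundles the thresholds governing candidate filtering, marker
#' qualification and panel selection:
#'
#' * Basic filtering of the candidate catalog: candidates are dropped when a
#'   flanking variant sits within `flank_exclusion_bp` of the target on
#'   either side; when the `hom_window_bp` windows violate the
#'   minor-homozygote rule (a side violates if any flanking variant within
#'   the window has a minor-homozygote count above `minor_hom_max`;
#'   `hom_window_sides` controls whether both sides or either side must
#'   violate); when the candidate is an indel; or when it lies in repetitive
#'   sequence or has discovery-panel MAF below `global_maf_min`.
#' * Subpopulation qualification: a marker qualifies for a subpopulation
#'   when, among that group's accessions, MAF exceeds `subpop_maf_min` and
#'   the observation (call) rate exceeds `subpop_obs_min` — both strict.
#' * Selection: each target cross must end with at least
#'   `min_snps_per_mb_per_cross` informative SNPs in every 1 Mb bin, and each
#'   of the five cultivated subpopulations contributes `quota_per_subpop`
#'   markers from its qualified set, non-overlapping across subpopulations.
#'
#' @param flank_exclusion_bp No flanking variant allowed within this many bp
#'   of the target (default 10).
#' @param hom_window_bp Window for the minor-homozygote rule (default 35).
#' @param minor_hom_max Maximum tolerated minor-homozygote count within the
#'   window (default 4).
#' @param hom_window_sides `"both"` (default: removed only when both sides
#'   violate) or `"either"`.
#' @param global_maf_min Minimum discovery-panel MAF (default 0.05).
#' @param subpop_maf_min Within-subpopulation MAF threshold, strict
#'   (default 0.20).
#' @param subpop_obs_min Within-subpopulation call-rate threshold, strict
#'   (default 0.80).
#' @param min_snps_per_mb_per_cross Spacing guarantee (default 1).
#' @param quota_per_subpop Markers per subpopulation quota (default 400).
#' @param crosses List of length-2 character vectors `(parent_a, parent_b)`.
#' @param partial_bin_min_mb Trailing partial megabase bins shorter than this
#'   are not treated as constraints (default 0.5).
#' @return A classed list of settings.
#' @export
design_policy <- function(flank_exclusion_bp = 10, hom_window_bp = 35,
                          minor_hom_max = 4,
                          hom_window_sides = c("both", "either"),
                          global_maf_min = 0.05, subpop_maf_min = 0.20,
                          subpop_obs_min = 0.80,
                          min_snps_per_mb_per_cross = 1,
                          quota_per_subpop = 400, crosses = list(),
                          partial_bin_min_mb = 0.5) {
  hom_window_sides <- match.arg(hom_window_sides)
  stopifnot(flank_exclusion_bp > 0, hom_window_bp > 0, minor_hom_max >= 0,
            global_maf_min >= 0, global_maf_min <= 1,
            subpop_maf_min >= 0, subpop_maf_min <= 0.5,
            subpop_obs_min >= 0, subpop_obs_min <= 1,
            min_snps_per_mb_per_cross >= 0, quota_per_subpop >= 0)
  structure(list(flank_exclusion_bp = flank_exclusion_bp,
                 hom_window_bp = hom_window_bp, minor_hom_max = minor_hom_max,
                 hom_window_sides = hom_window_sides,
                 global_maf_min = global_maf_min,
                 subpop_maf_min = subpop_maf_min,
                 subpop_obs_min = subpop_obs_min,
                 min_snps_per_mb_per_cross = min_snps_per_mb_per_cross,
                 quota_per_subpop = quota_per_subpop, crosses = crosses,
                 partial_bin_min_mb = partial_bin_min_mb),
            class = "design_policy")
}

cultivated_groups <- function() {
  c("indica", "aus", "tropical_japonica", "temperate_japonica", "aromatic")
}

#' Basic candidate filtering
#'
#' Applies the four candidate-level exclusion rules of the design policy to a
#' manifest, in a fixed order (the rules are independent predicates, so the
#' order affects only the per-rule attribution in the report, not the
#' retained set):
#'
#' 1. `flank_proximal`: a flanking variant within `flank_exclusion_bp` of the
#'    target on either side;
#' 2. `minor_hom_window`: the `hom_window_bp` minor-homozygote rule (see
#'    [design_policy()]);
#' 3. `indel`: the candidate is an indel;
#' 4. `repetitive_or_rare`: repetitive sequence, or discovery-panel MAF below
#'    `global_maf_min`.
#'
#' @param manifest An annotated [marker_manifest] (needs `flank_variants`,
#'   `is_indel`, `is_repetitive`, `global_maf`).
#' @param policy A [design_policy()].
#' @return The filtered manifest, with attribute `"filter_report"`: a tibble
#'   of per-rule removal counts (retrievable via [design_filter_report()]).
#' @export
basic_filter <- function(manifest, policy = design_policy()) {
  need <- c("flank_variants", "is_indel", "is_repetitive", "global_maf")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols) > 0L) {
    abort(paste0("manifest lacks annotation column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(manifest$global_maf)) {
    abort("manifest global_maf contains missing values; annotate before filtering")
  }
  fv <- manifest$flank_variants
  rule_flank <- vapply(fv, function(f) {
    nrow(f) > 0L && any(abs(f$offset) <= policy$flank_exclusion_bp)
  }, logical(1))
  side_violates <- function(f, side) {
    if (nrow(f) == 0L) return(FALSE)
    inside <- abs(f$offset) <= policy$hom_window_bp
    onside <- if (side == "left") f$offset < 0 else f$offset > 0
    any(inside & onside & f$minor_hom > policy$minor_hom_max)
  }
  rule_homwin <- vapply(fv, function(f) {
    l <- side_violates(f, "left")
    r <- side_violates(f, "right")
    if (policy$hom_window_sides == "both") l && r else l || r
  }, logical(1))
  rule_indel <- manifest$is_indel
  rule_rep <- manifest$is_repetitive |
    manifest$global_maf < policy$global_maf_min

  removed_by <- rep(NA_character_, nrow(manifest))
  for (r in list(c("flank_proximal", "rule_flank"),
                 c("minor_hom_window", "rule_homwin"),
                 c("indel", "rule_indel"),
                 c("repetitive_or_rare", "rule_rep"))) {
    hit <- get(r[2]) & is.na(removed_by)
    removed_by[hit] <- r[1]
  }
  report <- tibble(
    rule = c("flank_proximal", "minor_hom_window", "indel",
             "repetitive_or_rare"),
    n_removed = vapply(c("flank_proximal", "minor_hom_window", "indel",
                         "repetitive_or_rare"),
                       function(r) sum(removed_by == r, na.rm = TRUE),
                       integer(1))
  )
  out <- manifest[is.na(removed_by), , drop = FALSE]
  attr(out, "chromosome_lengths") <- chromosome_lengths(manifest)
  attr(out, "filter_report") <- report
  class(out) <- class(manifest)
  out
}

#' @rdname basic_filter
#' @export
design_filter_report <- function(manifest) attr(manifest, "filter_report")

#' Qualify markers by within-subpopulation segregation
#'
#' A marker qualifies for a subpopulation when, computed over that group's
#' accessions only, its call rate strictly exceeds `subpop_obs_min` and its
#' MAF strictly exceeds `subpop_maf_min`. Groups with fewer than 2 accessions
#' are skipped with a warning.
#'
#' @param geno A [geno_tbl] with group labels.
#' @param policy A [design_policy()].
#' @param groups Character vector of groups to qualify (default: the five
#'   cultivated subpopulations present in the labels).
#' @return A tibble `group`, `marker_id`, one row per qualification.
#' @export
subpop_qualify <- function(geno, policy = design_policy(), groups = NULL) {
  lab <- geno_labels(geno)
  if (is.null(groups)) groups <- intersect(cultivated_groups(),
                                           unique(lab$group))
  out <- list()
  for (g in groups) {
    acc <- lab$accession_id[lab$group == g]
    if (length(acc) < 2L) {
      warn(paste0("group '", g, "' has fewer than 2 accessions; skipped"))
      next
    }
    st <- locus_stats(geno, accessions = acc)
    ok <- !is.na(st$maf) & st$maf > policy$subpop_maf_min &
      st$call_rate > policy$subpop_obs_min
    out[[g]] <- tibble(group = g, marker_id = st$marker_id[ok])
  }
  bind_rows(out)
}

#' Qualify markers by segregation in target crosses
#'
#' A marker is informative for a cross when both parents carry non-missing
#' opposite homozygous calls (0 vs 2), so that progeny segregation is
#' scorable in a fixed-line design.
#'
#' @param geno A [geno_tbl] containing all parents.
#' @param crosses List of length-2 character vectors `(parent_a, parent_b)`.
#' @return A tibble `cross`, `parent_a`, `parent_b`, `marker_id`; the cross
#'   label is `"parent_a x parent_b"`.
#' @export
cross_qualify <- function(geno, crosses) {
  calls <- geno_calls(geno)
  out <- list()
  for (cr in crosses) {
    stopifnot(length(cr) == 2L)
    for (p in cr) {
      if (!p %in% colnames(calls)) {
        abort(paste0("unknown parent id: ", p))
      }
    }
    a <- calls[, cr[1]]
    b <- calls[, cr[2]]
    ok <- !is.na(a) & !is.na(b) & ((a == 0L & b == 2L) | (a == 2L & b == 0L))
    out[[paste(cr, collapse = " x ")]] <-
      tibble(cross = paste(cr, collapse = " x "),
             parent_a = cr[1], parent_b = cr[2],
             marker_id = rownames(calls)[ok] %||% geno$marker_id[ok])
  }
  bind_rows(out)
}

#' Union of subpopulation- and cross-qualified markers
#'
#' Markers become candidates for the array when they satisfy either the
#' subpopulation allele-frequency criteria or the cross segregation criteria.
#'
#' @param subpop_q Output of [subpop_qualify()].
#' @param cross_q Output of [cross_qualify()].
#' @return Character vector of unique marker ids.
#' @export
union_candidates <- function(subpop_q, cross_q) {
  unique(c(if (!is.null(subpop_q)) subpop_q$marker_id,
           if (!is.null(cross_q)) cross_q$marker_id))
}

# Megabase bins per chromosome; trailing partial bins shorter than
# partial_bin_min_mb are not constraints. Bin k covers
# [(k-1)e6 + 1, min(k * 1e6, len)] in 1-based coordinates.
mb_bins <- function(chromosome_lengths, partial_bin_min_mb = 0.5) {
  bind_rows(lapply(names(chromosome_lengths), function(ch) {
    len <- chromosome_lengths[[ch]]
    n_full <- floor(len / 1e6)
    tail_len <- len - n_full * 1e6
    n <- n_full + as.integer(tail_len >= partial_bin_min_mb * 1e6)
    if (n == 0L) return(NULL)
    tibble(chromosome = ch, bin = seq_len(n),
           start = (seq_len(n) - 1) * 1e6 + 1,
           end = pmin(seq_len(n) * 1e6, len))
  }))
}

#' Select the fixed panel under spacing and quota constraints
#'
#' Three-phase deterministic greedy selection:
#'
#' 1. **Legacy phase** — legacy markers are fixed content: always included,
#'    bypassing all filters.
#' 2. **Coverage phase** — each chromosome is partitioned into 1 Mb bins; for
#'    every target cross, while any (cross, bin) cell holds fewer than
#'    `min_snps_per_mb_per_cross` informative selected SNPs and an eligible
#'    candidate exists, the candidate covering the most currently-unmet
#'    (cross, bin) cells is added (ties broken by lower chromosome, then
#'    lower position). Cells left short go to `unmet_constraints`.
#' 3. **Quota phase** — for each cultivated subpopulation in the fixed order
#'    indica, aus, tropical japonica, temperate japonica, aromatic,
#'    `quota_per_subpop` markers are drawn from its qualified set, excluding
#'    markers already selected or used for another subpopulation's quota
#'    (quotas are non-overlapping). Each draw takes the candidate maximizing
#'    the distance to the nearest already-selected marker on its chromosome
#'    (ties as above). Short quotas go to `unmet_constraints`.
#'
#' @param manifest The basic-filtered candidate [marker_manifest] (must carry
#'   chromosome lengths; legacy markers may be included regardless of
#'   filters).
#' @param candidates Character vector of candidate marker ids (normally
#'   [union_candidates()] intersected with the filtered manifest).
#' @param subpop_q,cross_q Qualification tibbles from [subpop_qualify()] /
#'   [cross_qualify()].
#' @param legacy Character vector of legacy marker ids (fixed content).
#' @param policy A [design_policy()].
#' @return An object of class `panel_design`: a list with `selected` (the
#'   selected manifest rows), `provenance` (tibble `marker_id`, `reason`),
#'   `coverage` (per cross/chromosome/bin informative counts),
#'   `unmet_constraints` (tibble), and `policy`.
#' @seealso [design_panel()] for the one-call wrapper.
#' @export
select_panel <- function(manifest, candidates, subpop_q, cross_q,
                         legacy = character(), policy = design_policy()) {
  lens <- chromosome_lengths(manifest)
  if (is.null(lens)) abort("manifest must carry chromosome_lengths")
  n <- nrow(manifest)
  id <- manifest$marker_id
  idx_of <- setNames(seq_len(n), id)
  sel <- rep(FALSE, n)
  prov <- list()

  # phase 1: legacy
  legacy_idx <- idx_of[intersect(legacy, id)]
  sel[legacy_idx] <- TRUE
  if (length(legacy_idx) > 0L) {
    prov[[length(prov) + 1L]] <- tibble(marker_id = id[legacy_idx],
                                        reason = "legacy")
  }

  bins <- mb_bins(lens, policy$partial_bin_min_mb)
  bins$key <- paste(bins$chromosome, bins$bin)
  bin_of <- rep(NA_character_, n)
  bnum <- floor((manifest$position - 1) / 1e6) + 1
  key <- paste(manifest$chromosome, bnum)
  bin_of[key %in% bins$key] <- key[key %in% bins$key]

  crosses <- unique(cross_q$cross)
  inform_mat <- matrix(FALSE, nrow = n, ncol = length(crosses),
                       dimnames = list(NULL, crosses))
  for (cr in crosses) {
    hits <- idx_of[intersect(cross_q$marker_id[cross_q$cross == cr], id)]
    inform_mat[hits, cr] <- TRUE
  }

  cand <- rep(FALSE, n)
  cand[idx_of[intersect(candidates, id)]] <- TRUE

  unmet <- list()

  # phase 2: coverage
  if (length(crosses) > 0L && policy$min_snps_per_mb_per_cross > 0) {
    # U[key, cross]: remaining required count
    U <- matrix(policy$min_snps_per_mb_per_cross, nrow = nrow(bins),
                ncol = length(crosses), dimnames = list(bins$key, crosses))
    # credit already-selected (legacy) markers
    for (i in which(sel)) {
      if (is.na(bin_of[i])) next
      for (cr in crosses[inform_mat[i, ]]) {
        U[bin_of[i], cr] <- max(0, U[bin_of[i], cr] - 1)
      }
    }
    eligible <- cand & !sel & !is.na(bin_of)
    cover <- integer(n)
    recompute <- function(i_set) {
      for (i in i_set) {
        cover[i] <<- if (eligible[i]) {
          sum(U[bin_of[i], ] > 0 & inform_mat[i, ])
        } else 0L
      }
    }
    recompute(which(eligible))
    while (any(U > 0) && any(cover > 0)) {
      pick <- which.max(cover)  # manifest order = (chromosome, position)
      k <- bin_of[pick]
      served <- crosses[inform_mat[pick, ] & U[k, ] > 0]
      sel[pick] <- TRUE
      eligible[pick] <- FALSE
      cover[pick] <- 0L
      U[k, inform_mat[pick, ] & U[k, ] > 0] <-
        U[k, inform_mat[pick, ] & U[k, ] > 0] - 1
      prov[[length(prov) + 1L]] <-
        tibble(marker_id = id[pick],
               reason = c("spacing", paste0("cross:", served)))
      recompute(which(eligible & bin_of == k))
    }
    short <- which(U > 0, arr.ind = TRUE)
    if (nrow(short) > 0L) {
      unmet[[length(unmet) + 1L]] <- tibble(
        constraint = "coverage",
        cross = crosses[short[, 2]],
        group = NA_character_,
        chromosome = sub(" [0-9]+$", "", rownames(U)[short[, 1]]),
        bin = as.integer(sub("^.* ", "", rownames(U)[short[, 1]])),
        shortfall = U[short])
    }
  }

  # phase 3: subpopulation quotas
  quota_used <- rep(FALSE, n)
  if (policy$quota_per_subpop > 0 && nrow(subpop_q) > 0L) {
    # nearest-selected distance per marker, maintained incrementally
    nearest <- rep(Inf, n)
    for (ch in unique(manifest$chromosome)) {
      on_ch <- which(manifest$chromosome == ch)
      sel_pos <- sort(manifest$position[on_ch[sel[on_ch]]])
      if (length(sel_pos) == 0L) next
      p <- manifest$position[on_ch]
      j <- findInterval(p, sel_pos)
      left <- ifelse(j >= 1L, p - sel_pos[pmax(j, 1L)], Inf)
      right <- ifelse(j < length(sel_pos), sel_pos[pmin(j + 1L,
                                                        length(sel_pos))] - p,
                      Inf)
      nearest[on_ch] <- pmin(abs(left), abs(right))
    }
    for (g in intersect(cultivated_groups(), unique(subpop_q$group))) {
      pool_ids <- subpop_q$marker_id[subpop_q$group == g]
      pool <- idx_of[intersect(pool_ids, id)]
      taken <- 0L
      picked_ids <- character(0)
      while (taken < policy$quota_per_subpop) {
        avail <- pool[cand[pool] & !sel[pool] & !quota_used[pool]]
        if (length(avail) == 0L) break
        best <- avail[which.max(nearest[avail])]  # ties: manifest order
        sel[best] <- TRUE
        quota_used[best] <- TRUE
        picked_ids <- c(picked_ids, id[best])
        taken <- taken + 1L
        ch <- manifest$chromosome[best]
        on_ch <- which(manifest$chromosome == ch)
        nearest[on_ch] <- pmin(nearest[on_ch],
                               abs(manifest$position[on_ch] -
                                     manifest$position[best]))
      }
      if (length(picked_ids) > 0L) {
        prov[[length(prov) + 1L]] <- tibble(marker_id = picked_ids,
                                            reason = paste0("subpop:", g))
      }
      if (taken < policy$quota_per_subpop) {
        unmet[[length(unmet) + 1L]] <- tibble(
          constraint = "quota", cross = NA_character_, group = g,
          chromosome = NA_character_, bin = NA_integer_,
          shortfall = policy$quota_per_subpop - taken)
      }
    }
  }

  provenance <- bind_rows(prov)
  selected <- manifest[sel, , drop = FALSE]
  attr(selected, "chromosome_lengths") <- lens
  class(selected) <- class(manifest)
  design <- structure(
    list(selected = selected,
         provenance = provenance,
         unmet_constraints = if (length(unmet) > 0L) bind_rows(unmet) else
           tibble(constraint = character(), cross = character(),
                  group = character(), chromosome = character(),
                  bin = integer(), shortfall = numeric()),
         policy = policy,
         chromosome_lengths = lens),
    class = "panel_design")
  design$coverage <- density_report(design, cross_q)
  design
}

#' One-call panel design from genotypes and a candidate catalog
#'
#' Runs the full design flow: basic candidate filtering, subpopulation and
#' cross qualification on the discovery genotypes, union-set formation, and
#' quota/spacing-constrained selection.
#'
#' @param geno Discovery-panel [geno_tbl] (typically covering the candidate
#'   catalog loci).
#' @param manifest Annotated candidate [marker_manifest].
#' @param policy A [design_policy()] (its `crosses` field names the target
#'   parent pairs).
#' @param legacy Character vector of fixed legacy marker ids.
#' @return A `panel_design` (see [select_panel()]); additionally carries
#'   `basic_filter_report`, `subpop_q` and `cross_q`.
#' @export
design_panel <- function(geno, manifest, policy = design_policy(),
                         legacy = character()) {
  filtered <- basic_filter(manifest, policy)
  subpop_q <- subpop_qualify(geno, policy)
  cross_q <- if (length(policy$crosses) > 0L) {
    cross_qualify(geno, policy$crosses)
  } else {
    tibble(cross = character(), parent_a = character(),
           parent_b = character(), marker_id = character())
  }
  cands <- intersect(union_candidates(subpop_q, cross_q),
                     filtered$marker_id)
  design <- select_panel(filtered, cands, subpop_q, cross_q,
                         legacy = legacy, policy = policy)
  design$basic_filter_report <- design_filter_report(filtered)
  design$subpop_q <- subpop_q
  design$cross_q <- cross_q
  design
}

#' Per-megabase informative-SNP density of a design
#'
#' Counts, for every (cross, chromosome, 1 Mb bin) cell, the selected markers
#' informative for that cross, and summarises min/mean/max per cross. The
#' sum of a cross's bin counts equals its total informative selected markers
#' within constraint bins.
#'
#' @param design A `panel_design` (or a list with `selected` and
#'   `chromosome_lengths`).
#' @param cross_q A [cross_qualify()] tibble.
#' @return A tibble `cross`, `chromosome`, `bin`, `start`, `end`,
#'   `n_informative`, with attribute `"summary"` (tibble `cross`, `min_bin`,
#'   `mean_bin`, `max_bin`).
#' @export
density_report <- function(design, cross_q) {
  lens <- design$chromosome_lengths
  bins <- mb_bins(lens, design$policy$partial_bin_min_mb %||% 0.5)
  sel <- design$selected
  crosses <- unique(cross_q$cross)
  out <- list()
  for (cr in crosses) {
    inf_ids <- cross_q$marker_id[cross_q$cross == cr]
    hit <- sel$marker_id %in% inf_ids
    b <- bins
    b$cross <- cr
    b$n_informative <- 0L
    if (any(hit)) {
      key <- paste(sel$chromosome[hit],
                   floor((sel$position[hit] - 1) / 1e6) + 1)
      tab <- table(key)
      m <- match(paste(b$chromosome, b$bin), names(tab))
      b$n_informative <- ifelse(is.na(m), 0L, as.integer(tab[m]))
    }
    out[[cr]] <- b[, c("cross", "chromosome", "bin", "start", "end",
                       "n_informative")]
  }
  res <- if (length(out) > 0L) bind_rows(out) else
    tibble(cross = character(), chromosome = character(), bin = integer(),
           start = numeric(), end = numeric(), n_informative = integer())
  summ <- if (nrow(res) > 0L) {
    res |>
      group_by(.data$cross) |>
      summarise(min_bin = min(.data$n_informative),
                mean_bin = mean(.data$n_informative),
                max_bin = max(.data$n_informative), .groups = "drop")
  } else {
    tibble(cross = character(), min_bin = integer(), mean_bin = numeric(),
           max_bin = integer())
  }
  attr(res, "summary") <- summ
  res
}

#' @exportS3Method base::print
print.panel_design <- function(x, ...) {
  cat(sprintf("<panel_design> %d selected markers\n", nrow(x$selected)))
  tab <- table(x$provenance$reason)
  for (r in names(tab)) cat(sprintf("  %-24s %d\n", r, tab[[r]]))
  if (nrow(x$unmet_constraints) > 0L) {
    cat(sprintf("  unmet constraints: %d\n", nrow(x$unmet_constraints)))
  } else {
    cat("  all constraints met\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a panel design into one row per selected marker
#'
#' @param x A `panel_design`.
#' @param ... Unused.
#' @return A tibble: the selected manifest plus a `reasons` column collapsing
#'   the marker's provenance (semicolon-separated).
#' @method tidy panel_design
#' @export
tidy.panel_design <- function(x, ...) {
  reasons <- x$provenance |>
    group_by(.data$marker_id) |>
    summarise(reasons = paste(sort(unique(.data$reason)), collapse = ";"),
              .groups = "drop")
  out <- as_tibble(x$selected)
  out$flank_variants <- NULL
  left_join(out, reasons, by = "marker_id")
}

#' @rdname tidy.panel_design
#' @return For `glance()`: a one-row tibble with marker counts and constraint
#'   status.
#' @method glance panel_design
#' @export
glance.panel_design <- function(x, ...) {
  tibble(n_selected = nrow(x$selected),
         n_legacy = sum(x$provenance$reason == "legacy"),
         n_quota = sum(startsWith(x$provenance$reason, "subpop:")),
         n_coverage = sum(x$provenance$reason == "spacing"),
         n_unmet = nrow(x$unmet_constraints),
         min_bin_density = if (nrow(x$coverage) > 0L)
           min(x$coverage$n_informative) else NA_integer_)
}
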