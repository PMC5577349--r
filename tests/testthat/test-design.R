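# Brute-force oracles for the design rules, kept independent of the
# implementation they check.
brute_subpop_qualify <- function(geno, policy) {
  lab <- geno_labels(geno)
  calls <- geno_calls(geno)
  out <- list()
  for (g in intersect(cultivated <- c("indica", "aus", "tropical_japonica",
                                      "temperate_japonica", "aromatic"),
                      unique(lab$group))) {
    acc <- lab$accession_id[lab$group == g]
    if (length(acc) < 2) next
    for (i in seq_len(nrow(calls))) {
      v <- calls[i, acc]
      n_called <- sum(!is.na(v))
      cr <- n_called / length(acc)
      alt <- sum(v, na.rm = TRUE)
      mac <- min(alt, 2 * n_called - alt)
      maf <- if (n_called > 0) mac / (2 * n_called) else NA
      if (!is.na(maf) && maf > policy$subpop_maf_min &&
          cr > policy$subpop_obs_min) {
        out[[length(out) + 1L]] <- c(g, rownames(calls)[i])
      }
    }
  }
  do.call(rbind, out)
}

test_that("basic filtering applies the four exclusion rules in order", {
  m <- tiny_manifest(n = 10)
  m$flank_variants[[4]] <- flanks(-8)              # rule i: within 10 bp
  m$flank_variants[[5]] <- flanks(c(-20, 22), 6)   # rule ii: both sides
  m$is_indel[c(1, 2)] <- TRUE                      # rule iii
  m$is_repetitive[7] <- TRUE                       # rule iv
  out <- basic_filter(m, design_policy())
  expect_equal(nrow(out), 5L)
  rep_tbl <- design_filter_report(out)
  expect_equal(setNames(rep_tbl$n_removed, rep_tbl$rule),
               c(flank_proximal = 1L, minor_hom_window = 1L, indel = 2L,
                 repetitive_or_rare = 1L))
})

test_that("flank-window boundaries are inclusive at 10 bp and exclusive at 11", {
  m <- tiny_manifest(n = 2)
  m$flank_variants[[1]] <- flanks(10)   # removed: |offset| <= 10
  m$flank_variants[[2]] <- flanks(11)   # retained: 11 > 10
  out <- basic_filter(m, design_policy())
  expect_equal(out$marker_id, "m2")
})

test_that("minor-homozygote window rule distinguishes both vs either sides", {
  m <- tiny_manifest(n = 3)
  m$flank_variants[[1]] <- flanks(c(-30, 30), 6)   # violates both sides
  m$flank_variants[[2]] <- flanks(-30, 6)          # one side only
  m$flank_variants[[3]] <- flanks(c(-30, 30), 4)   # count 4 not > 4
  out_both <- basic_filter(m, design_policy(hom_window_sides = "both"))
  expect_setequal(out_both$marker_id, c("m2", "m3"))
  out_either <- basic_filter(m, design_policy(hom_window_sides = "either"))
  expect_setequal(out_either$marker_id, "m3")
  # variants beyond the 35 bp window never count
  m2 <- tiny_manifest(n = 1)
  m2$flank_variants[[1]] <- flanks(c(-36, 36), 9)
  expect_equal(nrow(basic_filter(m2, design_policy())), 1L)
})

test_that("basic filtering rejects unannotated manifests and is rule-order
           insensitive", {
  m <- tiny_manifest(n = 3)
  m$global_maf <- NULL
  m$global_maf <- NA_real_
  expect_error(basic_filter(m, design_policy()), "global_maf")

  # retained set equals the intersection of the individual rule survivors
  set.seed(99)
  man <- simulate_catalog(catalog_sim_config(
    chromosome_lengths = c(chr1 = 2e6), snp_density_per_kb = 0.3,
    indel_fraction = 0.2, repetitive_fraction = 0.2,
    flank_variant_rate_per_bp = 0.05, seed = 77))
  pol <- design_policy()
  full <- basic_filter(man, pol)$marker_id
  surv <- man$marker_id
  keep_i <- !vapply(man$flank_variants,
                    function(f) nrow(f) > 0 && any(abs(f$offset) <= 10),
                    logical(1))
  keep_ii <- !vapply(man$flank_variants, function(f) {
    l <- any(f$offset < 0 & abs(f$offset) <= 35 & f$minor_hom > 4)
    r <- any(f$offset > 0 & abs(f$offset) <= 35 & f$minor_hom > 4)
    l && r
  }, logical(1))
  keep_iii <- !man$is_indel
  keep_iv <- !(man$is_repetitive | man$global_maf < 0.05)
  expect_setequal(full, man$marker_id[keep_i & keep_ii & keep_iii & keep_iv])
})

test_that("subpopulation qualification uses strict thresholds", {
  # within-group maf 0.25, call rate 0.9 qualifies; maf exactly 0.20 does not
  grp <- rep(c("indica", "aus"), each = 10)
  mk <- function(ind, aus) rbind(c(ind, aus))
  # locus 1: indica 5 hom-alt of 10 called (maf .5); locus 2: 2 hom-alt ->
  # maf 0.2 exactly -> fails strict
  calls <- rbind(
    c(rep(2L, 5), rep(0L, 5), rep(0L, 10)),
    c(rep(2L, 2), rep(0L, 8), rep(0L, 10)),
    c(rep(2L, 3), rep(0L, 6), NA, rep(2L, 10)))
  g <- tiny_geno(calls, groups = grp)
  q <- subpop_qualify(g, design_policy())
  ind <- q$marker_id[q$group == "indica"]
  expect_true("m1" %in% ind)
  expect_false("m2" %in% ind)   # maf exactly 0.20
  expect_true("m3" %in% ind)    # maf 6/18 = 0.33, call rate 0.9
  expect_false(any(q$group == "aus"))  # aus monomorphic everywhere

  # groups with < 2 accessions are skipped with a warning
  g2 <- tiny_geno(calls[, c(1:10, 11)], groups = c(rep("indica", 10), "aus"))
  expect_warning(subpop_qualify(g2, design_policy()), "fewer than 2")
})

test_that("subpopulation qualification matches the brute-force oracle", {
  man <- simulate_catalog(catalog_sim_config(
    chromosome_lengths = c(chr1 = 1e6), snp_density_per_kb = 0.2, seed = 15))
  g <- simulate_panel(man, panel_sim_config(
    n_per_group = c(indica = 6, aus = 6, tropical_japonica = 6,
                    temperate_japonica = 6, aromatic = 6),
    fst_per_group = setNames(rep(0.3, 5),
                             c("indica", "aus", "tropical_japonica",
                               "temperate_japonica", "aromatic")),
    no_call_rate = 0.1, seed = 16))
  pol <- design_policy()
  got <- subpop_qualify(g, pol)
  want <- brute_subpop_qualify(g, pol)
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$group, got$marker_id),
                  paste(want[, 1], want[, 2]))
})

test_that("cross qualification requires opposite parental homozygotes", {
  calls <- rbind(c(0L, 2L, 1L, 0L),
                 c(0L, 1L, 2L, 0L),
                 c(2L, 0L, 0L, NA),
                 c(0L, 0L, 2L, 0L),
                 c(NA, 2L, 0L, 0L))
  colnames(calls) <- c("p1", "p2", "p3", "p4")
  g <- tiny_geno(calls)
  q <- cross_qualify(g, list(c("p1", "p2"), c("p3", "p4")))
  expect_setequal(q$marker_id[q$cross == "p1 x p2"], c("m1", "m3"))
  expect_setequal(q$marker_id[q$cross == "p3 x p4"], c("m2", "m4"))
  expect_false("m5" %in% q$marker_id[q$cross == "p3 x p4"])  # both hom-ref
  expect_error(cross_qualify(g, list(c("p1", "nope"))), "unknown parent")

  # brute-force scan over a simulated panel
  g2 <- two_group_panel(n_loci = 100, n_per_group = 3, seed = 44)
  pr <- c("indica_01", "tropical_japonica_02")
  q2 <- cross_qualify(g2, list(pr))
  calls2 <- geno_calls(g2)
  want <- g2$marker_id[!is.na(calls2[, pr[1]]) & !is.na(calls2[, pr[2]]) &
                         calls2[, pr[1]] != 1 & calls2[, pr[2]] != 1 &
                         calls2[, pr[1]] != calls2[, pr[2]]]
  expect_setequal(q2$marker_id, want)
})

test_that("union of qualification sets is an exact set union", {
  s <- tibble::tibble(group = c("indica", "indica", "aus"),
                      marker_id = c("a", "b", "b"))
  cr <- tibble::tibble(cross = "x", parent_a = "p", parent_b = "q",
                       marker_id = c("c", "a"))
  expect_setequal(union_candidates(s, cr), c("a", "b", "c"))
  expect_setequal(union_candidates(s, s[0, ]), c("a", "b"))
  expect_setequal(union_candidates(s, cr), union(s$marker_id, cr$marker_id))
})

test_that("coverage phase fills every megabase bin with candidates available", {
  # 1 chromosome of 5 Mb, 1 cross, one cross-qualified candidate per Mb
  man <- marker_manifest(tibble::tibble(
    marker_id = paste0("c", 1:5), chromosome = "chr1",
    position = c(0.5, 1.5, 2.5, 3.5, 4.5) * 1e6,
    ref = "A", alt = "G", global_maf = 0.3),
    chromosome_lengths = c(chr1 = 5e6))
  cross_q <- tibble::tibble(cross = "pA x pB", parent_a = "pA",
                            parent_b = "pB", marker_id = man$marker_id)
  des <- select_panel(man, man$marker_id,
                      subpop_q = tibble::tibble(group = character(),
                                                marker_id = character()),
                      cross_q = cross_q, policy = design_policy())
  expect_equal(nrow(des$selected), 5L)
  expect_true(all(des$coverage$n_informative == 1L))
  expect_equal(nrow(des$unmet_constraints), 0L)
  expect_equal(attr(des$coverage, "summary")$min_bin, 1)
})

test_that("coverage shortfalls and empty candidate sets are reported, not
           raised", {
  man <- marker_manifest(tibble::tibble(
    marker_id = c("c1", "c2"), chromosome = "chr1",
    position = c(0.5e6, 1.5e6), ref = "A", alt = "G", global_maf = 0.3),
    chromosome_lengths = c(chr1 = 4e6))
  cross_q <- tibble::tibble(cross = "pA x pB", parent_a = "pA",
                            parent_b = "pB", marker_id = c("c1", "c2"))
  des <- select_panel(man, man$marker_id,
                      tibble::tibble(group = character(),
                                     marker_id = character()),
                      cross_q, policy = design_policy())
  expect_equal(nrow(des$selected), 2L)
  expect_equal(sum(des$unmet_constraints$constraint == "coverage"), 2L)

  des0 <- select_panel(man, character(),
                       tibble::tibble(group = character(),
                                      marker_id = character()),
                       cross_q, policy = design_policy())
  expect_equal(nrow(des0$selected), 0L)
  expect_gt(nrow(des0$unmet_constraints), 0L)
})

test_that("legacy markers are fixed content and count toward coverage", {
  man <- marker_manifest(tibble::tibble(
    marker_id = c("leg1", "c1", "c2"), chromosome = "chr1",
    position = c(0.4e6, 0.6e6, 1.5e6), ref = "A", alt = "G",
    global_maf = c(0.01, 0.3, 0.3)),  # legacy fails global maf; still kept
    chromosome_lengths = c(chr1 = 2e6))
  cross_q <- tibble::tibble(cross = "pA x pB", parent_a = "pA",
                            parent_b = "pB",
                            marker_id = c("leg1", "c1", "c2"))
  des <- select_panel(man, c("c1", "c2"),
                      tibble::tibble(group = character(),
                                     marker_id = character()),
                      cross_q, legacy = "leg1", policy = design_policy())
  expect_true("leg1" %in% des$selected$marker_id)
  # bin 1 already covered by the legacy marker; only c2 added for bin 2
  expect_false("c1" %in% des$selected$marker_id)
  expect_true("c2" %in% des$selected$marker_id)
  expect_equal(des$provenance$reason[des$provenance$marker_id == "leg1"],
               "legacy")
})

test_that("quota phase meets quotas with disjoint per-subpopulation sets", {
  # ample disjoint qualified sets: 5 groups x 30 markers, quota 10
  n_per <- 30
  groups <- c("indica", "aus", "tropical_japonica", "temperate_japonica",
              "aromatic")
  man <- marker_manifest(tibble::tibble(
    marker_id = paste0("q", seq_len(n_per * 5)), chromosome = "chr1",
    position = seq_len(n_per * 5) * 1e4, ref = "A", alt = "G",
    global_maf = 0.3), chromosome_lengths = c(chr1 = 2e6))
  subpop_q <- tibble::tibble(
    group = rep(groups, each = n_per),
    marker_id = man$marker_id)
  des <- select_panel(man, man$marker_id, subpop_q,
                      tibble::tibble(cross = character(),
                                     parent_a = character(),
                                     parent_b = character(),
                                     marker_id = character()),
                      policy = design_policy(quota_per_subpop = 10))
  quota_prov <- des$provenance[startsWith(des$provenance$reason, "subpop:"), ]
  counts <- table(quota_prov$reason)
  expect_equal(unname(as.integer(counts)), rep(10L, 5))
  expect_equal(anyDuplicated(quota_prov$marker_id), 0L)
  expect_equal(nrow(des$unmet_constraints), 0L)

  # short qualified sets produce explicit quota shortfalls
  des2 <- select_panel(man, man$marker_id[1:12], subpop_q,
                       tibble::tibble(cross = character(),
                                      parent_a = character(),
                                      parent_b = character(),
                                      marker_id = character()),
                       policy = design_policy(quota_per_subpop = 10))
  expect_true(any(des2$unmet_constraints$constraint == "quota"))
})

test_that("quota picks maximize distance to the nearest selected marker", {
  # markers at 1..5 Mb, the 3 Mb one is legacy; quota 2 from all five:
  # first pick must be the farthest from 3 Mb (tie 1 vs 5 -> lower position)
  man <- marker_manifest(tibble::tibble(
    marker_id = paste0("m", 1:5), chromosome = "chr1",
    position = (1:5) * 1e6, ref = "A", alt = "G", global_maf = 0.3),
    chromosome_lengths = c(chr1 = 6e6))
  subpop_q <- tibble::tibble(group = "indica", marker_id = man$marker_id)
  des <- select_panel(man, man$marker_id, subpop_q,
                      tibble::tibble(cross = character(),
                                     parent_a = character(),
                                     parent_b = character(),
                                     marker_id = character()),
                      legacy = "m3",
                      policy = design_policy(quota_per_subpop = 2))
  quota_ids <- des$provenance$marker_id[
    startsWith(des$provenance$reason, "subpop:")]
  expect_equal(quota_ids, c("m1", "m5"))
})

test_that("selection is deterministic", {
  man <- simulate_catalog(catalog_sim_config(
    chromosome_lengths = c(chr1 = 3e6, chr2 = 2e6),
    snp_density_per_kb = 0.2, seed = 5))
  g <- simulate_panel(man, panel_sim_config(
    n_per_group = c(indica = 8, aus = 8),
    fst_per_group = c(indica = 0.3, aus = 0.3), seed = 6))
  pol <- design_policy(quota_per_subpop = 5,
                       crosses = list(c("indica_01", "aus_01")))
  d1 <- design_panel(g, man, pol)
  d2 <- design_panel(g, man, pol)
  expect_identical(d1$selected$marker_id, d2$selected$marker_id)
  expect_identical(d1$provenance, d2$provenance)
})

test_that("density report counts partition the informative selection", {
  man <- simulate_catalog(catalog_sim_config(
    chromosome_lengths = c(chr1 = 4e6), snp_density_per_kb = 0.2, seed = 8))
  g <- simulate_panel(man, panel_sim_config(
    n_per_group = c(indica = 6, aus = 6),
    fst_per_group = c(indica = 0.4, aus = 0.4), no_call_rate = 0, seed = 9))
  pol <- design_policy(quota_per_subpop = 3,
                       crosses = list(c("indica_01", "aus_01")))
  des <- design_panel(g, man, pol)
  cov <- des$coverage
  inf_sel <- intersect(des$selected$marker_id,
                       des$cross_q$marker_id)
  # bins partition the chromosome, so bin counts sum to the informative
  # selected markers lying inside constraint bins
  expect_equal(sum(cov$n_informative),
               sum(des$selected$position[des$selected$marker_id %in%
                                           inf_sel] <= 4e6))
  # empty design -> all-zero table
  des0 <- select_panel(
    basic_filter(man, pol), character(),
    tibble::tibble(group = character(), marker_id = character()),
    des$cross_q, policy = pol)
  expect_true(all(des0$coverage$n_informative == 0L))
})

test_that("quota-selected markers satisfy the subpopulation criteria post hoc", {
  man <- simulate_catalog(catalog_sim_config(
    chromosome_lengths = c(chr1 = 3e6), snp_density_per_kb = 0.3, seed = 10))
  g <- simulate_panel(man, panel_sim_config(
    n_per_group = c(indica = 10, aus = 10, tropical_japonica = 10,
                    temperate_japonica = 10, aromatic = 10),
    fst_per_group = setNames(rep(0.3, 5), cultivated_names <-
                               c("indica", "aus", "tropical_japonica",
                                 "temperate_japonica", "aromatic")),
    seed = 11))
  pol <- design_policy(quota_per_subpop = 8)
  des <- design_panel(g, man, pol)
  quota <- des$provenance[startsWith(des$provenance$reason, "subpop:"), ]
  lab <- geno_labels(g)
  for (i in seq_len(nrow(quota))) {
    grp <- sub("^subpop:", "", quota$reason[i])
    acc <- lab$accession_id[lab$group == grp]
    st <- locus_stats(g, loci = quota$marker_id[i], accessions = acc)
    expect_gt(st$maf, 0.20)
    expect_gt(st$call_rate, 0.80)
  }
})
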