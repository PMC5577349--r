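#' Simulation configurations
#'
#' Configuration constructors for the three simulators. All rates are
#' fractions in `[0, 1]`; all simulators are bit-reproducible given `seed`.
#'
#' `panel_sim_config()` describes a structured diversity panel: accession
#' counts per group (defaults emulate a re-sequenced discovery panel of 128
#' genomes: 21 indica, 16 aus, 18 tropical japonica, 19 temperate japonica,
#' 11 aromatic, 28 rufipogon, 9 nivara, 3 admixed, 3 outgroup), a per-group
#' Balding-Nichols divergence parameter F (wild groups get a lower F, giving
#' them more internal diversity; the outgroup a much higher one), the
#' ancestral minor-allele-frequency window, a residual heterozygosity rate
#' (rice accessions are largely inbred) and a flat no-call rate.
#'
#' @param n_per_group Named integer vector: accessions per group.
#' @param fst_per_group Named numeric vector of divergence parameters in
#'   (0, 1); names must cover `n_per_group`. Groups named `"admixed"` ignore
#'   F and are drawn as 50/50 mixtures of two random non-admixed groups.
#' @param ancestral_maf_dist Length-2 numeric `(low, high)` for the uniform
#'   draw of the ancestral allele frequency.
#' @param residual_het_rate Per-call probability of forcing a heterozygote.
#' @param no_call_rate Per-call probability of a no-call.
#' @param seed Integer seed.
#' @return A classed list of settings.
#' @export
panel_sim_config <- function(n_per_group = NULL, fst_per_group = NULL,
                             ancestral_maf_dist = c(0.1, 0.5),
                             residual_het_rate = 0.005,
                             no_call_rate = 0.02, seed = 1L) {
  if (is.null(n_per_group)) {
    n_per_group <- c(indica = 21, aus = 16, tropical_japonica = 18,
                     temperate_japonica = 19, aromatic = 11, rufipogon = 28,
                     nivara = 9, admixed = 3, outgroup = 3)
  }
  if (is.null(fst_per_group)) {
    fst_per_group <- setNames(rep(0.4, length(n_per_group)),
                              names(n_per_group))
    fst_per_group[names(fst_per_group) %in% c("rufipogon", "nivara")] <- 0.15
    fst_per_group[names(fst_per_group) == "outgroup"] <- 0.8
  }
  stopifnot(!is.null(names(n_per_group)), all(n_per_group >= 1),
            all(names(n_per_group) %in%
                  c(names(fst_per_group), "admixed")),
            all(fst_per_group > 0 & fst_per_group < 1),
            length(ancestral_maf_dist) == 2L,
            ancestral_maf_dist[1] <= ancestral_maf_dist[2],
            residual_het_rate >= 0, residual_het_rate <= 1,
            no_call_rate >= 0, no_call_rate <= 1)
  structure(list(n_per_group = n_per_group, fst_per_group = fst_per_group,
                 ancestral_maf_dist = ancestral_maf_dist,
                 residual_het_rate = residual_het_rate,
                 no_call_rate = no_call_rate, seed = as.integer(seed)),
            class = "panel_sim_config")
}

#' @rdname panel_sim_config
#' @param chromosome_lengths Named vector of chromosome lengths in bp.
#'   Default: 12 rice-like chromosomes (43, 30, 36, 35, 30, 31, 30, 28, 23,
#'   23, 29, 27 Mb).
#' @param snp_density_per_kb Candidate SNPs per kb (Poisson rate).
#' @param indel_fraction,repetitive_fraction Fractions of candidates flagged
#'   as indels / in repetitive sequence.
#' @param flank_variant_rate_per_bp Rate of flanking variants per bp within
#'   +/- 100 bp of each candidate.
#' @export
catalog_sim_config <- function(chromosome_lengths = NULL,
                               snp_density_per_kb = 0.05,
                               indel_fraction = 0.05,
                               repetitive_fraction = 0.05,
                               flank_variant_rate_per_bp = 0.01,
                               seed = 1L) {
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- setNames(
      c(43, 30, 36, 35, 30, 31, 30, 28, 23, 23, 29, 27) * 1e6,
      paste0("chr", 1:12))
  }
  stopifnot(!is.null(names(chromosome_lengths)), all(chromosome_lengths > 0),
            snp_density_per_kb > 0,
            indel_fraction >= 0, indel_fraction <= 1,
            repetitive_fraction >= 0, repetitive_fraction <= 1,
            flank_variant_rate_per_bp >= 0)
  structure(list(chromosome_lengths = chromosome_lengths,
                 snp_density_per_kb = snp_density_per_kb,
                 indel_fraction = indel_fraction,
                 repetitive_fraction = repetitive_fraction,
                 flank_variant_rate_per_bp = flank_variant_rate_per_bp,
                 seed = as.integer(seed)),
            class = "catalog_sim_config")
}

#' @rdname panel_sim_config
#' @param parent_a,parent_b Accession ids of the recurrent (A) and donor (B)
#'   parents.
#' @param scheme Cross scheme string such as `"F2"`, `"BC2F1"` or `"BC3F2"`:
#'   the number of backcrosses to parent A followed by the filial
#'   (self-pollinated) generation.
#' @param n_progeny Number of progeny to simulate.
#' @param cm_per_mb Recombination rate in cM/Mb (default 4.0; the rice map is
#'   roughly 1500 cM over ~380 Mb).
#' @param target Optional [genomic_interval()]: rejection-sample progeny so
#'   the donor segment covers the whole target (CSSL mode).
#' @export
cross_sim_config <- function(parent_a, parent_b, scheme = "BC2F1",
                             n_progeny = 100L, cm_per_mb = 4.0,
                             target = NULL, seed = 1L) {
  parsed <- parse_scheme(scheme)
  stopifnot(n_progeny >= 1, cm_per_mb > 0)
  if (!is.null(target)) target <- as_interval_tbl(target)
  structure(list(parent_a = parent_a, parent_b = parent_b, scheme = scheme,
                 n_backcrosses = parsed$n_backcrosses, n_selfs = parsed$n_selfs,
                 n_progeny = as.integer(n_progeny), cm_per_mb = cm_per_mb,
                 target = target, seed = as.integer(seed)),
            class = "cross_sim_config")
}

parse_scheme <- function(scheme) {
  m <- regmatches(scheme, regexec("^(?:BC([0-9]+))?F([0-9]+)$", scheme))[[1]]
  if (length(m) == 0L) {
    abort(paste0("cannot parse cross scheme '", scheme,
                 "'; expected e.g. F2, BC2F1, BC3F2"))
  }
  n_bc <- if (nzchar(m[2])) as.integer(m[2]) else 0L
  f_gen <- as.integer(m[3])
  if (f_gen < 1L) abort("filial generation must be >= 1")
  list(n_backcrosses = n_bc, n_selfs = f_gen - 1L)
}

#' Simulate a dense candidate-variant catalog
#'
#' Candidate SNP positions are laid down by a homogeneous Poisson process at
#' `snp_density_per_kb` along each chromosome. Each candidate gets an indel /
#' repetitive-sequence flag at the configured fractions, a discovery-panel
#' minor allele frequency drawn uniformly on `[0, 0.5]`, and flanking
#' variants placed by a Poisson process within +/- 100 bp of the target, each
#' with a small minor-homozygote count (Poisson, mean 2).
#'
#' @param config A [catalog_sim_config()].
#' @return A [marker_manifest].
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "catalog_sim_config"))
  withr::local_seed(config$seed)
  lens <- config$chromosome_lengths
  nucs <- c("A", "C", "G", "T")
  per_chr <- lapply(names(lens), function(ch) {
    n <- rpois(1L, lens[[ch]] / 1e3 * config$snp_density_per_kb)
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(lens[[ch]], n, replace = FALSE))
    tibble(chromosome = ch, position = pos)
  })
  x <- bind_rows(per_chr)
  n <- nrow(x)
  if (n == 0L) abort("simulated catalog is empty; raise snp_density_per_kb")
  x$marker_id <- sprintf("cand_%s_%d", x$chromosome, x$position)
  x$ref <- sample(nucs, n, replace = TRUE)
  x$alt <- vapply(x$ref, function(r) sample(setdiff(nucs, r), 1L), "")
  x$is_indel <- runif(n) < config$indel_fraction
  x$is_repetitive <- runif(n) < config$repetitive_fraction
  x$designable <- TRUE
  x$global_maf <- runif(n, 0, 0.5)
  n_fl <- rpois(n, config$flank_variant_rate_per_bp * 200)
  x$flank_variants <- lapply(n_fl, function(k) {
    if (k == 0L) return(empty_flanks())
    off <- sample(c(-100:-1, 1:100), k, replace = FALSE)
    tibble(offset = as.integer(sort(off)),
           minor_hom = rpois(k, 2))
  })
  x$source <- "resequencing"
  marker_manifest(x, chromosome_lengths = lens)
}

#' Simulate a structured diversity panel
#'
#' Genotypes follow the Balding-Nichols model: for each locus an ancestral
#' alternate-allele frequency `p` is drawn uniformly from
#' `ancestral_maf_dist`, and each group's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with the group's divergence parameter F.
#' Accessions are drawn as inbred lines (homozygous alternate with the group
#' frequency), then overlaid with residual heterozygotes and no-calls at the
#' configured flat rates. Accessions in a group named `"admixed"` each draw
#' their frequencies as the average of two random non-admixed groups.
#'
#' @param manifest A [marker_manifest] giving the loci to simulate.
#' @param config A [panel_sim_config()].
#' @return A [geno_tbl] with group labels attached.
#' @export
simulate_panel <- function(manifest, config) {
  stopifnot(inherits(config, "panel_sim_config"), nrow(manifest) > 0L)
  withr::local_seed(config$seed)
  n_loci <- nrow(manifest)
  groups <- names(config$n_per_group)
  core_groups <- setdiff(groups, "admixed")
  p <- runif(n_loci, config$ancestral_maf_dist[1], config$ancestral_maf_dist[2])
  freq <- sapply(core_groups, function(g) {
    f <- config$fst_per_group[[g]]
    rbeta(n_loci, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  })
  acc_ids <- character(0)
  acc_groups <- character(0)
  cols <- list()
  for (g in groups) {
    n_g <- config$n_per_group[[g]]
    ids <- sprintf("%s_%02d", g, seq_len(n_g))
    for (i in seq_len(n_g)) {
      q <- if (g == "admixed") {
        mix <- sample(core_groups, 2L)
        (freq[, mix[1]] + freq[, mix[2]]) / 2
      } else {
        freq[, g]
      }
      call <- 2L * rbinom(n_loci, 1L, q)
      het <- runif(n_loci) < config$residual_het_rate
      call[het] <- 1L
      nc <- runif(n_loci) < config$no_call_rate
      call[nc] <- NA_integer_
      cols[[ids[i]]] <- call
    }
    acc_ids <- c(acc_ids, ids)
    acc_groups <- c(acc_groups, rep(g, n_g))
  }
  calls <- do.call(cbind, cols)
  colnames(calls) <- acc_ids
  geno_tbl(as_tibble(manifest)[, c("marker_id", "chromosome", "position",
                                   "ref", "alt")],
           calls,
           tibble(accession_id = acc_ids, group = acc_groups),
           chromosome_lengths = chromosome_lengths(manifest))
}

# ---- cross simulation ------------------------------------------------------

# A haplotype along one chromosome is a breakpoint representation:
# list(bp = c(b1, ..., bk, L), anc = c(a1, ..., ak+? )):
# segment i covers (prev_bp, bp[i]] with ancestry anc[i] in {1 = A, 2 = B}.
new_hap <- function(len, anc) list(bp = len, anc = anc)

# ancestry of a haplotype at given positions
hap_ancestry <- function(hap, pos) {
  idx <- findInterval(pos, hap$bp, left.open = TRUE) + 1L
  hap$anc[idx]
}

# recombinant gamete from two parental haplotypes on one chromosome
make_gamete <- function(h1, h2, len, cm_per_mb) {
  n_xo <- rpois(1L, len / 1e6 * cm_per_mb / 100)
  start_first <- sample.int(2L, 1L)
  if (n_xo == 0L) return(if (start_first == 1L) h1 else h2)
  xo <- sort(runif(n_xo, 0, len))
  haps <- list(h1, h2)
  cuts <- c(xo, len)
  active <- start_first
  bp <- numeric(0)
  anc <- integer(0)
  prev <- 0
  for (ci in cuts) {
    h <- haps[[active]]
    keep <- which(h$bp > prev & c(0, head(h$bp, -1)) < ci)
    seg_ends <- pmin(h$bp[keep], ci)
    bp <- c(bp, seg_ends)
    anc <- c(anc, h$anc[keep])
    prev <- ci
    active <- 3L - active
  }
  # merge adjacent segments with equal ancestry
  same <- c(FALSE, anc[-1] == head(anc, -1))
  list(bp = bp[!c(same[-1], FALSE)], anc = anc[!same])
}

# donor (ancestry 2) intervals of a diploid, with zygosity: elementary
# intervals from the union of both haplotypes' breakpoints, classified by
# donor dosage (2 = hom, 1 = het), adjacent equal-dosage runs merged.
# Returns a matrix with columns start, end, dosage.
donor_segments_diploid <- function(hap1, hap2, len) {
  bp <- sort(unique(c(hap1$bp, hap2$bp)))
  mid <- (c(0, head(bp, -1)) + bp) / 2
  dose <- (hap_ancestry(hap1, mid) == 2L) + (hap_ancestry(hap2, mid) == 2L)
  r <- rle(dose)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- which(r$values > 0L)
  if (length(keep) == 0L) return(matrix(numeric(0), ncol = 3))
  cbind(start = c(0, bp)[starts_i[keep]], end = bp[ends_i[keep]],
        dosage = r$values[keep])
}

# merged union of donor presence (either haplotype), in bp
donor_union <- function(hap1, hap2, len) {
  segs <- donor_segments_diploid(hap1, hap2, len)
  if (nrow(segs) == 0L) return(segs[, 1:2, drop = FALSE])
  out <- segs[1, 1:2, drop = FALSE]
  for (i in seq_len(nrow(segs))[-1]) {
    if (segs[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], segs[i, 2])
    } else {
      out <- rbind(out, segs[i, 1:2])
    }
  }
  out
}

#' Simulate a backcross or CSSL population from two inbred parents
#'
#' Gametes are formed with crossover counts that are Poisson with mean
#' `length_Mb * cm_per_mb / 100` per chromosome per meiosis (Haldane's
#' no-interference model), crossover positions uniform. The scheme string is
#' applied literally: an F1 is made from A x B, backcrossed `n` times to
#' parent A, then self-pollinated down to the requested filial generation.
#' Progeny genotypes are read off the parental genotypes at the loci of the
#' parents' genotype table; the true donor-ancestry intervals of every
#' progeny are returned alongside. Parents are treated as fully inbred:
#' heterozygous parental calls are resolved to a random homozygote (with a
#' warning), and loci where the contributing parent has a no-call give
#' no-call progeny alleles.
#'
#' If `config$target` is set, progeny are rejection-sampled until the donor
#' ancestry (on either haplotype) covers the whole target interval.
#'
#' @param geno A [geno_tbl] containing both parents.
#' @param config A [cross_sim_config()].
#' @return A list with `geno` (progeny [geno_tbl], accessions
#'   `progeny_001`...), and `truth` (tibble `progeny`, `chromosome`, `start`,
#'   `end`, `zygosity` of true donor-ancestry intervals, 1-based inclusive
#'   bp; `hom` = donor on both haplotypes, `het` = on one).
#' @export
simulate_cross <- function(geno, config) {
  stopifnot(inherits(config, "cross_sim_config"))
  acc <- geno_accessions(geno)
  for (p in c(config$parent_a, config$parent_b)) {
    if (!p %in% acc) abort(paste0("parent not in genotype table: ", p))
  }
  lens <- attr(geno, "chromosome_lengths")
  if (is.null(lens)) {
    lens <- tapply(geno$position, geno$chromosome, max)
    lens <- setNames(as.numeric(lens), names(lens))
  }
  withr::local_seed(config$seed)
  calls <- geno_calls(geno)
  pa <- calls[, config$parent_a]
  pb <- calls[, config$parent_b]
  n_het <- sum(pa == 1L | pb == 1L, na.rm = TRUE)
  if (n_het > 0L) {
    warn(sprintf("%d heterozygous parental call(s) resolved to random homozygotes",
                 n_het))
    pa[!is.na(pa) & pa == 1L] <- 2L * rbinom(sum(pa == 1L, na.rm = TRUE), 1L, 0.5)
    pb[!is.na(pb) & pb == 1L] <- 2L * rbinom(sum(pb == 1L, na.rm = TRUE), 1L, 0.5)
  }
  chroms <- chrom_levels(geno$chromosome)
  chroms <- intersect(names(lens)[order(chrom_rank(names(lens)))],
                      c(chroms, names(lens)))
  loci_by_chr <- lapply(chroms, function(ch) which(geno$chromosome == ch))
  names(loci_by_chr) <- chroms

  sim_one <- function() {
    # per chromosome: individual = list(hap1, hap2); start from F1
    ind <- lapply(chroms, function(ch) {
      list(new_hap(lens[[ch]], 1L), new_hap(lens[[ch]], 2L))
    })
    names(ind) <- chroms
    for (b in seq_len(config$n_backcrosses)) {
      ind <- lapply(chroms, function(ch) {
        list(make_gamete(ind[[ch]][[1]], ind[[ch]][[2]], lens[[ch]],
                         config$cm_per_mb),
             new_hap(lens[[ch]], 1L))
      })
      names(ind) <- chroms
    }
    for (s in seq_len(config$n_selfs)) {
      ind <- lapply(chroms, function(ch) {
        list(make_gamete(ind[[ch]][[1]], ind[[ch]][[2]], lens[[ch]],
                         config$cm_per_mb),
             make_gamete(ind[[ch]][[1]], ind[[ch]][[2]], lens[[ch]],
                         config$cm_per_mb))
      })
      names(ind) <- chroms
    }
    ind
  }

  covers_target <- function(ind) {
    t <- config$target
    if (is.null(t)) return(TRUE)
    ok <- TRUE
    for (k in seq_len(nrow(t))) {
      ch <- t$chromosome[k]
      if (!ch %in% chroms) return(FALSE)
      du <- donor_union(ind[[ch]][[1]], ind[[ch]][[2]], lens[[ch]])
      # need union of donor segments to cover [start-1, end] continuously
      covered <- FALSE
      if (nrow(du) > 0L) {
        for (i in seq_len(nrow(du))) {
          if (du[i, 1] <= t$start[k] - 1 && du[i, 2] >= t$end[k]) {
            covered <- TRUE
          }
        }
      }
      ok <- ok && covered
    }
    ok
  }

  n_prog <- config$n_progeny
  prog_ids <- sprintf("progeny_%03d", seq_len(n_prog))
  calls_out <- matrix(NA_integer_, nrow = nrow(geno), ncol = n_prog,
                      dimnames = list(NULL, prog_ids))
  truth <- vector("list", n_prog)
  for (j in seq_len(n_prog)) {
    tries <- 0L
    repeat {
      ind <- sim_one()
      tries <- tries + 1L
      if (covers_target(ind)) break
      if (tries >= 5000L) {
        abort("rejection sampling failed: target interval rarely inherited")
      }
    }
    tr <- list()
    for (ch in chroms) {
      idx <- loci_by_chr[[ch]]
      h1 <- ind[[ch]][[1]]; h2 <- ind[[ch]][[2]]
      if (length(idx) > 0L) {
        a1 <- hap_ancestry(h1, geno$position[idx])
        a2 <- hap_ancestry(h2, geno$position[idx])
        al1 <- ifelse(a1 == 1L, pa[idx], pb[idx]) / 2L
        al2 <- ifelse(a2 == 1L, pa[idx], pb[idx]) / 2L
        calls_out[idx, j] <- as.integer(al1 + al2)
      }
      du <- donor_segments_diploid(h1, h2, lens[[ch]])
      if (nrow(du) > 0L) {
        seg <- tibble(progeny = prog_ids[j], chromosome = ch,
                      start = floor(du[, 1]) + 1, end = floor(du[, 2]),
                      zygosity = ifelse(du[, 3] == 2, "hom", "het"))
        tr[[ch]] <- seg[seg$end >= seg$start, , drop = FALSE]
      }
    }
    truth[[j]] <- bind_rows(tr)
  }
  truth <- bind_rows(truth)
  lab <- tibble(accession_id = prog_ids,
                group = paste0(config$parent_a, "x", config$parent_b))
  out <- geno_tbl(geno_markers(geno), calls_out, lab,
                  chromosome_lengths = lens)
  list(geno = out, truth = truth)
}

#' True donor genome fraction per progeny
#'
#' Computes each progeny's donor genome fraction from the truth segments of
#' [simulate_cross()]: homozygous donor intervals count fully, heterozygous
#' ones half (haplotype dosage), divided by the total genome length. The
#' expectation after n backcrosses to the recurrent parent is `(1/2)^(n+1)`.
#'
#' @param truth The `truth` tibble from [simulate_cross()].
#' @param progeny Character vector of all progeny ids (so lines with no
#'   donor segment report 0).
#' @param chromosome_lengths Named vector of chromosome lengths in bp.
#' @return A tibble `progeny`, `donor_fraction`.
#' @export
donor_genome_fraction <- function(truth, progeny, chromosome_lengths) {
  total <- sum(chromosome_lengths)
  w <- (truth$end - truth$start + 1) *
    ifelse(truth$zygosity == "hom", 1, 0.5)
  agg <- tapply(w, truth$progeny, sum)
  tibble(progeny = progeny,
         donor_fraction = as.numeric(ifelse(progeny %in% names(agg),
                                            agg[progeny], 0)) / total)
}

#' Convert donor truth or detected segments to BED
#'
#' Writes 0-based half-open BED records from the package's 1-based inclusive
#' intervals; the `name` column carries the progeny/line id.
#'
#' @param segments Tibble with `chromosome`, `start`, `end` and a line id
#'   column (`progeny` or `line`).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  id_col <- intersect(c("progeny", "line"), names(segments))[1]
  if (is.na(id_col)) id_col <- NULL
  bed <- tibble(chrom = segments$chromosome,
                chromStart = as.integer(segments$start) - 1L,
                chromEnd = as.integer(segments$end),
                name = if (is.null(id_col)) "." else segments[[id_col]])
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
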