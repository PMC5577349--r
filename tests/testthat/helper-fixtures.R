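# Hand-built fixtures shared across tests. Everything is constructed in code;
# no data files.

# A tiny genotype table from an explicit call matrix (loci x accessions).
tiny_geno <- function(calls, groups = NULL, chromosome = NULL,
                      position = NULL, ref = NULL, alt = NULL,
                      chromosome_lengths = NULL) {
  n_loci <- nrow(calls)
  if (is.null(colnames(calls))) {
    colnames(calls) <- paste0("acc", seq_len(ncol(calls)))
  }
  if (is.null(groups)) groups <- rep("other", ncol(calls))
  if (is.null(chromosome)) chromosome <- rep("chr1", n_loci)
  if (is.null(position)) position <- seq_len(n_loci) * 1000
  markers <- tibble::tibble(
    marker_id = paste0("m", seq_len(n_loci)),
    chromosome = chromosome, position = position,
    ref = if (is.null(ref)) rep("A", n_loci) else ref,
    alt = if (is.null(alt)) rep("G", n_loci) else alt)
  geno_tbl(markers, calls,
           tibble::tibble(accession_id = colnames(calls), group = groups),
           chromosome_lengths = chromosome_lengths)
}

# A small annotated manifest for design tests.
tiny_manifest <- function(n = 10, chromosome = "chr1", spacing = 1e5,
                          chromosome_lengths = NULL) {
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- setNames(n * spacing + spacing, chromosome)
  }
  marker_manifest(tibble::tibble(
    marker_id = paste0("m", seq_len(n)),
    chromosome = chromosome, position = seq_len(n) * spacing,
    ref = "A", alt = "G", global_maf = 0.3),
    chromosome_lengths = chromosome_lengths)
}

flanks <- function(offset, minor_hom = 0) {
  tibble::tibble(offset = as.integer(offset),
                 minor_hom = as.integer(rep_len(minor_hom, length(offset))))
}

# Two-group panel used by several modules: high between-group divergence.
two_group_panel <- function(n_loci = 300, n_per_group = 10, fst = 0.4,
                            seed = 42) {
  man <- simulate_catalog(catalog_sim_config(
    chromosome_lengths = c(chr1 = n_loci * 2e3), snp_density_per_kb = 0.5,
    indel_fraction = 0, repetitive_fraction = 0,
    flank_variant_rate_per_bp = 0, seed = seed))
  simulate_panel(man, panel_sim_config(
    n_per_group = c(indica = n_per_group, tropical_japonica = n_per_group),
    fst_per_group = c(indica = fst, tropical_japonica = fst),
    residual_het_rate = 0, no_call_rate = 0, seed = seed))
}

# A coded population built directly from code strings (one string per line,
# characters A/B/H/N where N = NC), markers every Mb on one chromosome.
coded_from_strings <- function(lines, positions = NULL, chromosome = "chr1",
                               chromosome_lengths = NULL) {
  n_loci <- nchar(lines[[1]])
  if (is.null(positions)) positions <- seq_len(n_loci) * 1e6
  cols <- lapply(lines, function(s) {
    v <- strsplit(s, "")[[1]]
    v[v == "N"] <- "NC"
    v
  })
  if (is.null(names(cols))) {
    names(cols) <- paste0("line", seq_along(cols))
  }
  x <- dplyr::bind_cols(
    tibble::tibble(marker_id = paste0("m", seq_len(n_loci)),
                   chromosome = chromosome, position = positions),
    tibble::as_tibble(cols))
  attr(x, "chromosome_lengths") <- chromosome_lengths
  class(x) <- c("coded_pop", class(tibble::tibble()))
  x
}
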