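#' Genotype tables
#'
#' The package's genotype container is a tibble with one row per locus and
#' one column per accession. The first columns are `marker_id`, `chromosome`
#' and `position`; every remaining column holds the calls for one accession
#' coded as unphased biallelic dosages of the alternate allele: `0` =
#' homozygous reference, `1` = heterozygous, `2` = homozygous alternate, `NA`
#' = no-call. Loci are sorted by (chromosome, position). Subpopulation labels
#' travel with the table as an attribute (a tibble `accession_id`, `group`);
#' dplyr verbs that rebuild the tibble drop attributes, so use
#' [geno_labels()] / [set_geno_labels()] around such pipelines.
#'
#' @param markers Tibble with columns `marker_id`, `chromosome`, `position`
#'   (and optionally `ref`, `alt`).
#' @param calls Integer matrix, loci x accessions, values in `{0, 1, 2, NA}`;
#'   column names are accession ids.
#' @param labels Tibble with columns `accession_id` and `group`, covering
#'   every accession. Typical groups: `indica`, `aus`, `aromatic`,
#'   `tropical_japonica`, `temperate_japonica`, `rufipogon`, `nivara`,
#'   `meridionalis`, `admixed`, `other`.
#' @param chromosome_lengths Optional named vector of chromosome lengths (bp).
#' @return A tibble of class `geno_tbl`.
#' @export
geno_tbl <- function(markers, calls, labels, chromosome_lengths = NULL) {
  markers <- as_tibble(markers)
  stopifnot(all(c("marker_id", "chromosome", "position") %in% names(markers)))
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(markers)) {
    abort("calls must have one row per marker")
  }
  if (is.null(colnames(calls))) abort("calls must have accession column names")
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) abort("genotype calls must be 0, 1, 2 or NA")
  labels <- as_tibble(labels)
  stopifnot(all(c("accession_id", "group") %in% names(labels)))
  missing_lab <- setdiff(colnames(calls), labels$accession_id)
  if (length(missing_lab) > 0L) {
    abort(paste0("accession(s) without a group label: ",
                 paste(missing_lab, collapse = ", ")))
  }
  labels <- labels[match(colnames(calls), labels$accession_id), ]
  x <- dplyr::bind_cols(markers,
                        as_tibble(as.data.frame(calls), .name_repair = "minimal"))
  x <- arrange_genome(x)
  attr(x, "labels") <- labels
  attr(x, "chromosome_lengths") <- chromosome_lengths
  class(x) <- c("geno_tbl", class(tibble()))
  x
}

marker_cols <- function() c("marker_id", "chromosome", "position", "ref", "alt")

#' @rdname geno_tbl
#' @export
geno_accessions <- function(geno) setdiff(names(geno), marker_cols())

#' @rdname geno_tbl
#' @param geno A `geno_tbl`.
#' @export
geno_calls <- function(geno) {
  acc <- geno_accessions(geno)
  m <- as.matrix(as.data.frame(geno)[, acc, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- geno$marker_id
  m
}

#' @rdname geno_tbl
#' @export
geno_labels <- function(geno) attr(geno, "labels")

#' @rdname geno_tbl
#' @param labels Tibble with `accession_id`, `group`.
#' @export
set_geno_labels <- function(geno, labels) {
  labels <- as_tibble(labels)
  stopifnot(all(c("accession_id", "group") %in% names(labels)))
  missing_lab <- setdiff(geno_accessions(geno), labels$accession_id)
  if (length(missing_lab) > 0L) {
    abort(paste0("accession(s) without a group label: ",
                 paste(missing_lab, collapse = ", ")))
  }
  attr(geno, "labels") <- labels[match(geno_accessions(geno),
                                       labels$accession_id), ]
  geno
}

#' @rdname geno_tbl
#' @export
geno_markers <- function(geno) {
  as_tibble(geno)[, intersect(marker_cols(), names(geno))]
}

group_of <- function(geno) {
  lab <- geno_labels(geno)
  setNames(lab$group, lab$accession_id)
}

#' Read genotypes from a tabular file or VCF
#'
#' The tabular dialect is TSV with columns `marker_id`, `chromosome`,
#' `position`, then one column per accession with values in `{0, 1, 2, NA}`.
#' Subpopulation labels come from a sidecar TSV with columns `accession_id`
#' and `group`. VCF input (v4.x, uncompressed or bgzipped) keeps biallelic
#' SNP records only; multi-allelic or indel records are dropped with a
#' message naming how many were rejected.
#'
#' @param path Genotype file path.
#' @param format `"table"` or `"vcf"`.
#' @param labels_path Path to the labels sidecar TSV. Optional; if omitted
#'   every accession is labelled `"other"`.
#' @param chromosome_lengths Optional named vector of chromosome lengths.
#' @return A [geno_tbl].
#' @export
read_genotypes <- function(path, format = c("table", "vcf"),
                           labels_path = NULL, chromosome_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "table") {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA", "NC"))
    required <- c("marker_id", "chromosome", "position")
    if (!all(required %in% names(x))) {
      abort(paste0("genotype table ", path, " must start with columns ",
                   paste(required, collapse = ", ")))
    }
    acc <- setdiff(names(x), marker_cols())
    if (length(acc) == 0L) abort("genotype table has no accession columns")
    calls <- as.matrix(as.data.frame(x)[, acc, drop = FALSE])
    suppressWarnings(storage.mode(calls) <- "integer")
    markers <- x[, intersect(marker_cols(), names(x))]
  } else {
    parsed <- read_vcf_calls(path)
    markers <- parsed$markers
    calls <- parsed$calls
  }
  labels <- if (!is.null(labels_path)) {
    lab <- readr::read_tsv(labels_path, show_col_types = FALSE,
                           progress = FALSE)
    if (!all(c("accession_id", "group") %in% names(lab))) {
      abort("labels sidecar must have columns accession_id and group")
    }
    lab
  } else {
    tibble(accession_id = colnames(calls), group = "other")
  }
  geno_tbl(markers, calls, labels, chromosome_lengths = chromosome_lengths)
}

read_vcf_calls <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  alt <- fix$ALT
  ref <- fix$REF
  snp <- !grepl(",", alt, fixed = TRUE) & nchar(ref) == 1L &
    nchar(alt) == 1L & !is.na(alt)
  n_rejected <- sum(!snp)
  if (n_rejected > 0L) {
    inform(sprintf("dropped %d non-biallelic-SNP VCF record(s)", n_rejected))
  }
  if (sum(snp) == 0L) abort("no biallelic SNP records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  dose <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  calls <- apply(gt, 2L, dose)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = sum(snp),
                                           dimnames = list(NULL, colnames(gt)))
  ids <- fix$ID[snp]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[snp][no_id], "_", fix$POS[snp][no_id])
  markers <- tibble(marker_id = ids, chromosome = fix$CHROM[snp],
                    position = as.numeric(fix$POS[snp]),
                    ref = ref[snp], alt = alt[snp])
  list(markers = markers, calls = calls, n_rejected = n_rejected)
}

#' Write genotypes as a tabular file with a labels sidecar
#'
#' @param geno A [geno_tbl].
#' @param path Output TSV path.
#' @param labels_path Optional output path for the labels sidecar TSV.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, labels_path = NULL) {
  readr::write_tsv(as_tibble(geno), path, progress = FALSE)
  if (!is.null(labels_path)) {
    readr::write_tsv(geno_labels(geno), labels_path, progress = FALSE)
  }
  invisible(path)
}

#' Per-locus call-rate and allele-frequency statistics
#'
#' Allele counting follows the usual biallelic convention: a homozygote
#' contributes two copies of its allele, a heterozygote one of each, and
#' no-calls are excluded from every denominator. The minor allele count (MAC)
#' is the smaller of the two allele counts; MAF = MAC / (2 x n called). A
#' locus with no calls gets `call_rate = 0` and `NA` frequencies.
#'
#' @param geno A [geno_tbl].
#' @param loci Optional integer indices or marker ids restricting the output.
#' @param accessions Optional accession ids over which to compute the
#'   statistics (defaults to all).
#' @return A tibble with one row per locus: `marker_id`, `n_called`,
#'   `call_rate`, `mac`, `maf`, `n_alleles_observed`.
#' @export
locus_stats <- function(geno, loci = NULL, accessions = NULL) {
  calls <- geno_calls(geno)
  if (!is.null(accessions)) {
    missing_acc <- setdiff(accessions, colnames(calls))
    if (length(missing_acc) > 0L) {
      abort(paste0("unknown accession(s): ", paste(missing_acc, collapse = ", ")))
    }
    calls <- calls[, accessions, drop = FALSE]
  }
  idx <- seq_len(nrow(calls))
  if (!is.null(loci)) {
    idx <- if (is.character(loci)) match(loci, geno$marker_id) else as.integer(loci)
    if (anyNA(idx) || any(idx < 1L | idx > nrow(calls))) {
      abort("invalid locus index or unknown marker id")
    }
    calls <- calls[idx, , drop = FALSE]
  }
  n_acc <- ncol(calls)
  called <- !is.na(calls)
  n_called <- unname(rowSums(called))
  alt_count <- unname(rowSums(calls, na.rm = TRUE))
  ref_count <- 2 * n_called - alt_count
  mac <- pmin(ref_count, alt_count)
  maf <- ifelse(n_called > 0, mac / (2 * n_called), NA_real_)
  n_alleles <- (ref_count > 0) + (alt_count > 0)
  tibble(marker_id = geno$marker_id[idx],
         n_called = as.integer(n_called),
         call_rate = if (n_acc > 0) n_called / n_acc else NA_real_,
         mac = as.integer(mac),
         maf = maf,
         n_alleles_observed = as.integer(n_alleles))
}

#' Filter loci on minor allele count and call rate
#'
#' Retains loci with `mac >= min_mac` and `call_rate >= min_call_rate`
#' (both inclusive, the usual convention for stated MAC/call-rate cutoffs in
#' genotype-QC tools). The removed loci and the rule each one failed are
#' attached as attribute `"removed"` and retrievable with [filter_report()].
#'
#' @param geno A [geno_tbl].
#' @param min_mac Minimum minor allele count (default 5).
#' @param min_call_rate Minimum fraction of non-missing calls (default 0.8).
#' @return The filtered [geno_tbl].
#' @examples
#' g <- simulate_panel(simulate_catalog(catalog_sim_config(
#'   chromosome_lengths = c(chr1 = 2e6), seed = 1)),
#'   panel_sim_config(n_per_group = c(indica = 6, aus = 6), seed = 1))
#' filtered <- filter_loci(g, min_mac = 5, min_call_rate = 0.8)
#' filter_report(filtered)
#' @export
filter_loci <- function(geno, min_mac = 5, min_call_rate = 0.8) {
  stopifnot(min_mac >= 0, min_call_rate >= 0)
  st <- locus_stats(geno)
  keep <- !is.na(st$maf) & st$mac >= min_mac & st$call_rate >= min_call_rate
  keep[is.na(keep)] <- FALSE
  reason <- dplyr::case_when(
    st$call_rate < min_call_rate & (is.na(st$mac) | st$mac < min_mac) ~
      "low_call_rate;low_mac",
    st$call_rate < min_call_rate ~ "low_call_rate",
    is.na(st$maf) ~ "no_calls",
    st$mac < min_mac ~ "low_mac",
    TRUE ~ NA_character_
  )
  removed <- tibble(marker_id = st$marker_id[!keep], reason = reason[!keep])
  out <- geno[keep, , drop = FALSE]
  attr(out, "labels") <- geno_labels(geno)
  attr(out, "chromosome_lengths") <- attr(geno, "chromosome_lengths")
  attr(out, "removed") <- removed
  class(out) <- class(geno)
  out
}

#' @rdname filter_loci
#' @export
filter_report <- function(geno) attr(geno, "removed")
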