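#' Parent-relative graphical genotype coding
#'
#' Re-codes a progeny population relative to a recurrent and a donor parent.
#' Informative loci are those where both parents carry non-missing opposite
#' homozygous calls; at those loci each progeny call maps to `A` (matches the
#' recurrent parent's homozygote), `B` (matches the donor's), `H`
#' (heterozygous) or `NC` (no-call).
#'
#' @param geno A [geno_tbl] containing the parents and progeny.
#' @param recurrent,donor Accession ids of the parents.
#' @param progeny Accession ids to code (default: all accessions except the
#'   two parents).
#' @return A tibble of class `coded_pop`: columns `marker_id`, `chromosome`,
#'   `position`, then one character column per progeny with values
#'   `A`/`B`/`H`/`NC`. Attributes: `recurrent`, `donor`,
#'   `chromosome_lengths`.
#' @export
classify_progeny <- function(geno, recurrent, donor, progeny = NULL) {
  calls <- geno_calls(geno)
  for (p in c(recurrent, donor)) {
    if (!p %in% colnames(calls)) abort(paste0("unknown parent id: ", p))
  }
  if (is.null(progeny)) {
    progeny <- setdiff(colnames(calls), c(recurrent, donor))
  }
  pr <- calls[, recurrent]
  pd <- calls[, donor]
  informative <- !is.na(pr) & !is.na(pd) & pr != 1L & pd != 1L & pr != pd
  if (!any(informative)) {
    abort(paste0("no informative loci between parents ", recurrent, " and ",
                 donor))
  }
  codes <- lapply(progeny, function(pg) {
    g <- calls[informative, pg]
    out <- rep("NC", sum(informative))
    out[!is.na(g) & g == pr[informative]] <- "A"
    out[!is.na(g) & g == pd[informative]] <- "B"
    out[!is.na(g) & g == 1L] <- "H"
    out
  })
  names(codes) <- progeny
  x <- dplyr::bind_cols(
    geno_markers(geno)[informative, c("marker_id", "chromosome", "position")],
    as_tibble(codes, .name_repair = "minimal"))
  attr(x, "recurrent") <- recurrent
  attr(x, "donor") <- donor
  attr(x, "chromosome_lengths") <- attr(geno, "chromosome_lengths")
  class(x) <- c("coded_pop", class(tibble()))
  x
}

coded_progeny <- function(coded) {
  setdiff(names(coded), c("marker_id", "chromosome", "position"))
}

#' Delimit donor introgression segments in a coded line
#'
#' A donor segment is a maximal run of consecutive `B`/`H` codes along a
#' chromosome; `NC` codes are transparent (they neither break nor extend a
#' run). The minimal interval spans the outermost donor-coded markers of the
#' run; the maximal interval extends to one bp inside the nearest flanking
#' `A` markers (the true breakpoint lies strictly between markers), or to
#' the chromosome ends when there is no flanking `A`.
#'
#' @param coded A [classify_progeny()] result.
#' @param progeny Ids of the lines to scan (default: all).
#' @return A tibble: `progeny`, `chromosome`, `min_start`, `min_end`,
#'   `max_start`, `max_end`, `n_markers`, `zygosity`
#'   (`hom` = all B, `het` = all H, else `mixed`).
#' @export
detect_segments <- function(coded, progeny = NULL) {
  if (is.null(progeny)) progeny <- coded_progeny(coded)
  lens <- attr(coded, "chromosome_lengths")
  out <- list()
  for (pg in progeny) {
    if (!pg %in% names(coded)) abort(paste0("unknown progeny id: ", pg))
    for (ch in chrom_levels(coded$chromosome)) {
      on_ch <- coded$chromosome == ch
      pos <- coded$position[on_ch]
      code <- coded[[pg]][on_ch]
      obs <- code != "NC"
      if (!any(obs)) next
      pos_o <- pos[obs]
      code_o <- code[obs]
      donor <- code_o %in% c("B", "H")
      r <- rle(donor)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      chr_end <- if (!is.null(lens) && ch %in% names(lens)) lens[[ch]] else
        max(pos)
      for (k in which(r$values)) {
        i0 <- starts[k]; i1 <- ends[k]
        seg_codes <- code_o[i0:i1]
        zyg <- if (all(seg_codes == "B")) "hom" else
          if (all(seg_codes == "H")) "het" else "mixed"
        out[[length(out) + 1L]] <- tibble(
          progeny = pg, chromosome = ch,
          min_start = pos_o[i0], min_end = pos_o[i1],
          max_start = if (i0 > 1L) pos_o[i0 - 1L] + 1 else 1,
          max_end = if (i1 < length(pos_o)) pos_o[i1 + 1L] - 1 else chr_end,
          n_markers = i1 - i0 + 1L, zygosity = zyg)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(progeny = character(), chromosome = character(),
                  min_start = numeric(), min_end = numeric(),
                  max_start = numeric(), max_end = numeric(),
                  n_markers = integer(), zygosity = character()))
  }
  bind_rows(out)
}

#' Foreground (QTL) status of a progeny line
#'
#' Decides whether a line carries the donor allele across a target QTL
#' interval from the informative markers inside the interval; when no
#' non-missing informative marker lies inside, the decision falls back on
#' the two nearest flanking markers (one on each side where available) —
#' the usual situation when an array marker pair brackets, rather than
#' covers, a mapped QTL. Status: `donor` when all consulted markers are `B`;
#' `recurrent` when all are `A`; `het` when an `H` is present without both
#' `A` and `B`; `unknown` when both `A` and `B` appear (a recombination
#' between the consulted markers) or all are `NC`.
#'
#' @param coded A [classify_progeny()] result.
#' @param qtl A [genomic_interval()].
#' @param progeny Ids to score (default: all).
#' @return A tibble: `progeny`, `status`, `n_markers_used`, `used_flanking`.
#' @export
foreground_status <- function(coded, qtl, progeny = NULL) {
  qtl <- as_interval_tbl(qtl)
  stopifnot(nrow(qtl) == 1L)
  if (is.null(progeny)) progeny <- coded_progeny(coded)
  on_ch <- coded$chromosome == qtl$chromosome
  if (!any(on_ch)) {
    abort(paste0("no informative markers on chromosome ", qtl$chromosome))
  }
  pos <- coded$position[on_ch]
  inside <- pos >= qtl$start & pos <= qtl$end
  res <- lapply(progeny, function(pg) {
    code <- coded[[pg]][on_ch]
    use <- inside & code != "NC"
    used_flanking <- FALSE
    if (!any(use)) {
      used_flanking <- TRUE
      left <- which(pos < qtl$start & code != "NC")
      right <- which(pos > qtl$end & code != "NC")
      pick <- c(if (length(left) > 0L) left[which.max(pos[left])],
                if (length(right) > 0L) right[which.min(pos[right])])
      use <- seq_along(pos) %in% pick
    }
    obs <- code[use]
    status <- if (length(obs) == 0L) {
      "unknown"
    } else if (all(obs == "B")) {
      "donor"
    } else if (all(obs == "A")) {
      "recurrent"
    } else if (any(obs == "H") && !(any(obs == "A") && any(obs == "B"))) {
      "het"
    } else {
      "unknown"
    }
    tibble(progeny = pg, status = status,
           n_markers_used = sum(use), used_flanking = used_flanking)
  })
  bind_rows(res)
}

#' Background recurrent-parent genome recovery
#'
#' Scores each line's background (informative markers outside all excluded
#' intervals, typically the foreground QTL region(s)) as the mean of A = 1,
#' H = 0.5, B = 0 over non-missing markers — the standard recurrent-genome
#' recovery statistic of marker-assisted backcrossing. Also reports the
#' per-chromosome breakdown and the number of residual donor segments in the
#' background.
#'
#' @param coded A [classify_progeny()] result.
#' @param exclude Optional tibble of [genomic_interval()] rows to mask
#'   (foreground regions).
#' @param progeny Ids to score (default: all).
#' @return A tibble `progeny`, `recovery`, `n_markers`,
#'   `n_donor_segments`, with attribute `"per_chromosome"` (tibble `progeny`,
#'   `chromosome`, `recovery`, `n_markers`).
#' @export
background_recovery <- function(coded, exclude = NULL, progeny = NULL) {
  if (is.null(progeny)) progeny <- coded_progeny(coded)
  if (!is.null(exclude)) exclude <- as_interval_tbl(exclude)
  masked <- pos_in_intervals(coded$chromosome, coded$position, exclude)
  if (all(masked)) abort("no background markers outside excluded intervals")
  bg <- coded[!masked, , drop = FALSE]
  attr(bg, "chromosome_lengths") <- attr(coded, "chromosome_lengths")
  class(bg) <- class(coded)
  score_of <- c(A = 1, H = 0.5, B = 0)
  segs <- detect_segments(bg, progeny = progeny)
  per_chr <- list()
  rows <- lapply(progeny, function(pg) {
    code <- bg[[pg]]
    obs <- code != "NC"
    if (!any(obs)) {
      abort(paste0("no scored background markers for ", pg))
    }
    s <- score_of[code[obs]]
    ch <- bg$chromosome[obs]
    per_chr[[pg]] <<- tibble(progeny = pg,
                             chromosome = names(tapply(s, ch, mean)),
                             recovery = as.numeric(tapply(s, ch, mean)),
                             n_markers = as.integer(table(ch)[
                               names(tapply(s, ch, mean))]))
    tibble(progeny = pg, recovery = mean(s), n_markers = sum(obs),
           n_donor_segments = sum(segs$progeny == pg))
  })
  out <- bind_rows(rows)
  attr(out, "per_chromosome") <- bind_rows(per_chr)
  out
}

#' Narrow a causal region from contrasting line classes
#'
#' Implements multi-line region narrowing for a trait scored on a set of
#' coded lines (e.g. CSSL survival/sterility): the causal region is where
#' every unaffected line is non-`B` at every non-missing marker while at
#' least one affected line is homozygous donor (`B`) at that marker. The
#' maximal run of consecutive markers satisfying both conditions delimits
#' the region; its endpoints are the outermost satisfying markers and the
#' width is their coordinate difference.
#'
#' @param coded A [classify_progeny()] result.
#' @param line_classes Named character vector (or tibble `progeny`, `class`)
#'   assigning each line to `"affected"` or `"unaffected"`; lines not listed
#'   are ignored.
#' @return A one-row tibble `chromosome`, `start`, `end`, `width_bp`,
#'   `n_markers` for the widest satisfying run (zero rows when no marker
#'   satisfies the condition). All satisfying runs are attached as attribute
#'   `"runs"`.
#' @export
narrow_region <- function(coded, line_classes) {
  if (is_tibble(line_classes) || is.data.frame(line_classes)) {
    line_classes <- setNames(line_classes$class, line_classes$progeny)
  }
  stopifnot(all(line_classes %in% c("affected", "unaffected")))
  unaff <- names(line_classes)[line_classes == "unaffected"]
  aff <- names(line_classes)[line_classes == "affected"]
  if (length(unaff) == 0L) abort("need at least one unaffected line")
  missing_ln <- setdiff(c(unaff, aff), coded_progeny(coded))
  if (length(missing_ln) > 0L) {
    abort(paste0("unknown line id(s): ", paste(missing_ln, collapse = ", ")))
  }
  unaff_ok <- rep(TRUE, nrow(coded))
  for (ln in unaff) unaff_ok <- unaff_ok & coded[[ln]] != "B"
  aff_b <- rep(FALSE, nrow(coded))
  for (ln in aff) aff_b <- aff_b | coded[[ln]] == "B"
  satisfied <- unaff_ok & aff_b
  runs <- list()
  for (ch in chrom_levels(coded$chromosome)) {
    on_ch <- which(coded$chromosome == ch)
    s <- satisfied[on_ch]
    if (!any(s)) next
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- on_ch[starts[k]]; i1 <- on_ch[ends[k]]
      runs[[length(runs) + 1L]] <- tibble(
        chromosome = ch, start = coded$position[i0],
        end = coded$position[i1],
        width_bp = coded$position[i1] - coded$position[i0],
        n_markers = ends[k] - starts[k] + 1L)
    }
  }
  empty <- tibble(chromosome = character(), start = numeric(),
                  end = numeric(), width_bp = numeric(),
                  n_markers = integer())
  if (length(runs) == 0L) {
    attr(empty, "runs") <- empty
    return(empty)
  }
  runs <- bind_rows(runs)
  best <- runs[order(-runs$width_bp, chrom_rank(runs$chromosome),
                     runs$start), ][1, , drop = FALSE]
  attr(best, "runs") <- runs
  best
}

#' CSSL library coverage of the genome
#'
#' Evaluates how a set of lines' donor segments tile the genome: per
#' chromosome, the union of the (minimal) segment intervals, the covered
#' fraction of the chromosome, the list of uncovered gaps, and the pairwise
#' overlap between lines' segments.
#'
#' @param segments A [detect_segments()] tibble (uses `min_start`/`min_end`
#'   when present, else `start`/`end`); line ids in `progeny` or `line`.
#' @param chromosome_lengths Named vector of chromosome lengths in bp.
#' @return A list of class `cssl_coverage`: `per_chromosome` (tibble
#'   `chromosome`, `covered_bp`, `covered_fraction`, `n_gaps`), `gaps`
#'   (tibble `chromosome`, `start`, `end`), `overlaps` (tibble `chromosome`,
#'   `line_a`, `line_b`, `overlap_bp`).
#' @export
cssl_coverage <- function(segments, chromosome_lengths) {
  stopifnot(!is.null(names(chromosome_lengths)))
  segs <- as_tibble(segments)
  if (all(c("min_start", "min_end") %in% names(segs))) {
    segs$start <- segs$min_start
    segs$end <- segs$min_end
  }
  id_col <- intersect(c("progeny", "line"), names(segs))[1]
  if (is.na(id_col)) {
    segs$line <- "line"
    id_col <- "line"
  }
  per_chr <- list(); gaps_all <- list(); overlaps <- list()
  for (ch in names(chromosome_lengths)) {
    len <- chromosome_lengths[[ch]]
    sub <- segs[segs$chromosome == ch, , drop = FALSE]
    if (nrow(sub) == 0L) {
      per_chr[[ch]] <- tibble(chromosome = ch, covered_bp = 0,
                              covered_fraction = 0, n_gaps = 1L)
      gaps_all[[ch]] <- tibble(chromosome = ch, start = 1, end = len)
      next
    }
    ir <- IRanges::IRanges(start = sub$start, end = sub$end)
    red <- IRanges::reduce(ir)
    covered <- sum(IRanges::width(red))
    gap <- IRanges::gaps(red, start = 1L, end = as.integer(len))
    per_chr[[ch]] <- tibble(chromosome = ch, covered_bp = covered,
                            covered_fraction = covered / len,
                            n_gaps = length(gap))
    if (length(gap) > 0L) {
      gaps_all[[ch]] <- tibble(chromosome = ch,
                               start = IRanges::start(gap),
                               end = IRanges::end(gap))
    }
    lines_here <- unique(sub[[id_col]])
    if (length(lines_here) >= 2L) {
      for (i in seq_along(lines_here)[-length(lines_here)]) {
        for (j in (i + 1):length(lines_here)) {
          ir_i <- IRanges::reduce(IRanges::IRanges(
            start = sub$start[sub[[id_col]] == lines_here[i]],
            end = sub$end[sub[[id_col]] == lines_here[i]]))
          ir_j <- IRanges::reduce(IRanges::IRanges(
            start = sub$start[sub[[id_col]] == lines_here[j]],
            end = sub$end[sub[[id_col]] == lines_here[j]]))
          ov <- IRanges::intersect(ir_i, ir_j)
          overlaps[[length(overlaps) + 1L]] <- tibble(
            chromosome = ch, line_a = lines_here[i], line_b = lines_here[j],
            overlap_bp = sum(IRanges::width(ov)))
        }
      }
    }
  }
  structure(list(per_chromosome = bind_rows(per_chr),
                 gaps = if (length(gaps_all) > 0L) bind_rows(gaps_all) else
                   tibble(chromosome = character(), start = numeric(),
                          end = numeric()),
                 overlaps = if (length(overlaps) > 0L) bind_rows(overlaps)
                 else tibble(chromosome = character(), line_a = character(),
                             line_b = character(), overlap_bp = numeric())),
            class = "cssl_coverage")
}

#' @exportS3Method base::print
print.cssl_coverage <- function(x, ...) {
  cat("<cssl_coverage>\n")
  print(x$per_chromosome, n = 15)
  invisible(x)
}
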