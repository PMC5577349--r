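#' Pairwise genetic distances between accessions
#'
#' `p_distance` (default) is the mean allele-sharing dissimilarity over loci
#' called in both accessions: 0 for identical calls, 0.5 for a
#' homozygote-heterozygote pair, 1 for opposite homozygotes. `tamura_nei`
#' renders each accession as a pseudo-sequence over the panel's SNPs (hets as
#' fractional base counts, no-calls as missing) and computes the Tamura-Nei
#' (TN93) distance with transition/transversion and base-frequency terms
#' accumulated from those fractional counts. Concatenated SNP genotypes are
#' not a homogeneous nucleotide sequence, so the TN93 model is a deliberate
#' approximation here, provided for comparability with sequence-based
#' pipelines; `p_distance` is the recommended default.
#'
#' @param geno A [geno_tbl] with at least 3 accessions; `tamura_nei` needs
#'   `ref`/`alt` columns.
#' @param method `"p_distance"` or `"tamura_nei"`.
#' @return A symmetric `dist`-compatible matrix (class `matrix`) with zero
#'   diagonal and attribute `method`.
#' @export
genotype_distance <- function(geno, method = c("p_distance", "tamura_nei")) {
  method <- match.arg(method)
  calls <- geno_calls(geno)
  if (ncol(calls) < 3L) abort("need at least 3 accessions")
  if (method == "p_distance") {
    ind <- lapply(c(0L, 1L, 2L), function(k) {
      m <- (calls == k)
      m[is.na(m)] <- FALSE
      storage.mode(m) <- "double"
      m
    })
    called <- ind[[1]] + ind[[2]] + ind[[3]]
    n_ab <- crossprod(called)
    half <- crossprod(ind[[1]], ind[[2]]) + crossprod(ind[[2]], ind[[1]]) +
      crossprod(ind[[2]], ind[[3]]) + crossprod(ind[[3]], ind[[2]])
    full <- crossprod(ind[[1]], ind[[3]]) + crossprod(ind[[3]], ind[[1]])
    check_comparable(n_ab, colnames(calls))
    d <- (0.5 * half + full) / n_ab
  } else {
    d <- tn93_distance(geno, calls)
  }
  diag(d) <- 0
  dimnames(d) <- list(colnames(calls), colnames(calls))
  attr(d, "method") <- method
  d
}

check_comparable <- function(n_ab, ids) {
  bad <- which(n_ab == 0 & upper.tri(n_ab), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(paste0("no comparable loci for pair ", ids[bad[1, 1]], " / ",
                 ids[bad[1, 2]]))
  }
}

tn93_distance <- function(geno, calls) {
  if (!all(c("ref", "alt") %in% names(geno))) {
    abort("tamura_nei distance needs ref/alt allele columns")
  }
  bases <- c("A", "C", "G", "T")
  n_loci <- nrow(calls)
  n_acc <- ncol(calls)
  f <- lapply(bases, function(b) matrix(0, n_loci, n_acc))
  names(f) <- bases
  for (b in bases) {
    is_ref <- geno$ref == b
    is_alt <- geno$alt == b
    w_ref <- ifelse(is.na(calls), 0, (2 - calls) / 2)  # ref dosage fraction
    w_alt <- ifelse(is.na(calls), 0, calls / 2)
    f[[b]] <- w_ref * is_ref + w_alt * is_alt
  }
  called <- f$A + f$C + f$G + f$T
  n_ab <- crossprod(called)
  check_comparable(n_ab, colnames(calls))
  xp <- function(x, y) {
    m <- crossprod(f[[x]], f[[y]])
    m + t(m)
  }
  P1 <- xp("A", "G") / n_ab
  P2 <- xp("C", "T") / n_ab
  Q <- (xp("A", "C") + xp("A", "T") + xp("G", "C") + xp("G", "T")) / n_ab
  gfreq <- function(x) {
    m <- crossprod(f[[x]], called)
    (m + t(m)) / (2 * n_ab)
  }
  gA <- gfreq("A"); gC <- gfreq("C"); gG <- gfreq("G"); gT <- gfreq("T")
  gR <- gA + gG
  gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  term <- function(k, arg) {
    out <- -k * log(arg)
    out[k == 0 | !is.finite(k)] <- 0
    out
  }
  a1 <- 1 - P1 / k1 - Q / (2 * gR)
  a2 <- 1 - P2 / k2 - Q / (2 * gY)
  a3 <- 1 - Q / (2 * gR * gY)
  if (any(a1 <= 0 | a2 <= 0 | a3 <= 0, na.rm = TRUE)) {
    warn("Tamura-Nei distance saturated for some pair(s); returning NA there")
  }
  d <- term(k1, a1) + term(k2, a2) + term(k3, a3)
  d[a1 <= 0 | a2 <= 0 | a3 <= 0] <- NA_real_
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' A from-scratch Saitou-Nei neighbor-joining agglomeration with the
#' standard Q-criterion, deterministic tie-breaking (the lexicographically
#' lowest active-index pair among minima), and the standard limb-length
#' formulas. The output is an unrooted tree in `ape`-compatible `phylo`
#' form (tips `1..n`, internal nodes numbered in preorder from a
#' trifurcating base node). Negative branch-length estimates are clamped to
#' zero; the number clamped is recorded in attribute `n_clamped`.
#'
#' @param d Symmetric non-negative distance matrix with labelled rows.
#' @return An object of class `phylo` with elements `edge`, `edge.length`,
#'   `tip.label`, `Nnode`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) abort("need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) || any(d < 0)) {
    abort("distance matrix must be symmetric and non-negative")
  }
  labels <- rownames(d)
  # adjacency over node ids: tips 1..n, internal n+1 ...
  nbr <- vector("list", 2L * n - 2L)
  len <- vector("list", 2L * n - 2L)
  add_edge <- function(u, v, w) {
    nbr[[u]] <<- c(nbr[[u]], v); len[[u]] <<- c(len[[u]], w)
    nbr[[v]] <<- c(nbr[[v]], u); len[[v]] <<- c(len[[v]], w)
  }
  active <- seq_len(n)   # node ids of active clusters
  D <- d
  next_node <- n + 1L
  n_clamped <- 0L
  clamp <- function(x) {
    if (x < 0) {
      n_clamped <<- n_clamped + 1L
      0
    } else x
  }
  while (length(active) > 3L) {
    r <- length(active)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    m <- min(Q)
    cand <- which(Q <= m + 1e-12 * max(1, abs(m)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    new_id <- next_node
    next_node <- next_node + 1L
    add_edge(new_id, active[i], clamp(li))
    add_edge(new_id, active[j], clamp(lj))
    Dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], Dk[keep]),
               c(Dk[keep], 0))
    active <- c(active[keep], new_id)
  }
  # join the last three clusters at a trifurcating base node
  base <- next_node
  dab <- D[1, 2]; dac <- D[1, 3]; dbc <- D[2, 3]
  la <- (dab + dac - dbc) / 2
  lb <- (dab + dbc - dac) / 2
  lc <- (dac + dbc - dab) / 2
  add_edge(base, active[1], clamp(la))
  add_edge(base, active[2], clamp(lb))
  add_edge(base, active[3], clamp(lc))

  # renumber internal nodes in preorder from the base for a canonical phylo
  n_internal <- base - n
  new_id <- integer(base)
  new_id[seq_len(n)] <- seq_len(n)
  counter <- n
  edge <- matrix(0L, nrow = 2L * n - 3L, ncol = 2L)
  elen <- numeric(2L * n - 3L)
  e_i <- 0L
  assign_num <- function(node) {
    counter <<- counter + 1L
    new_id[node] <<- counter
  }
  visit <- function(node, parent) {
    if (node > n) assign_num(node)
    for (k in seq_along(nbr[[node]])) {
      child <- nbr[[node]][k]
      if (!is.null(parent) && child == parent) next
      e_i <<- e_i + 1L
      my_edge <- e_i
      # child number known only after its subtree visit for internals;
      # record and patch below
      edge[my_edge, 1] <<- node
      edge[my_edge, 2] <<- child
      elen[my_edge] <<- len[[node]][k]
      visit(child, node)
    }
  }
  visit(base, NULL)
  edge[, 1] <- new_id[edge[, 1]]
  edge[, 2] <- new_id[edge[, 2]]
  tree <- list(edge = edge, edge.length = elen, tip.label = labels,
               Nnode = n_internal)
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  attr(tree, "n_clamped") <- n_clamped
  tree
}

# Non-trivial bipartitions of an unrooted phylo as canonical keys.
# Each internal edge splits the tips; the canonical key lists the side not
# containing the first tip label (order-invariant up to relabeling).
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  below <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(tree$edge[kids[[as.character(node)]], 2], below))
  }
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) next
    side <- below(child)
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (tree$tip.label[1] %in% side) {
      side <- setdiff(tree$tip.label, side)
    }
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  keys
}

#' Neighbor-joining tree with locus bootstrap support
#'
#' Builds the point-estimate NJ tree from all loci, then resamples loci with
#' replacement `n_reps` times, rebuilds the tree each time, and annotates
#' each internal edge of the point tree with the percentage of replicates
#' containing the same leaf-set bipartition (branch lengths ignored in the
#' comparison).
#'
#' @param geno A [geno_tbl] with at least 3 accessions.
#' @param method Distance method, see [genotype_distance()].
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the resampling.
#' @return A `phylo` tree with `node.label` holding integer support values
#'   (the base node is unlabelled).
#' @export
bootstrap_tree <- function(geno, method = "p_distance", n_reps = 100,
                           seed = 1L) {
  stopifnot(n_reps >= 1)
  calls <- geno_calls(geno)
  if (ncol(calls) < 3L) abort("need at least 3 accessions")
  point <- nj_tree(genotype_distance(geno, method = method))
  withr::local_seed(seed)
  n_loci <- nrow(geno)
  rep_keys <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n_loci, n_loci, replace = TRUE)
    g_r <- geno[idx, , drop = FALSE]
    attr(g_r, "labels") <- geno_labels(geno)
    class(g_r) <- class(geno)
    d_r <- genotype_distance(g_r, method = method)
    rep_keys[[r]] <- unique(tree_bipartitions(nj_tree(d_r)))
  }
  all_rep <- unlist(rep_keys)
  n <- length(point$tip.label)
  node_support <- rep(NA_real_, point$Nnode)
  kids <- split(seq_len(nrow(point$edge)), point$edge[, 1])
  below <- function(node) {
    if (node <= n) return(point$tip.label[node])
    unlist(lapply(point$edge[kids[[as.character(node)]], 2], below))
  }
  for (e in seq_len(nrow(point$edge))) {
    child <- point$edge[e, 2]
    if (child <= n) next
    side <- below(child)
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (point$tip.label[1] %in% side) side <- setdiff(point$tip.label, side)
    key <- paste(sort(side), collapse = "\r")
    node_support[child - n] <- round(100 * sum(all_rep == key) / n_reps)
  }
  point$node.label <- ifelse(is.na(node_support), "",
                             as.character(as.integer(node_support)))
  attr(point, "n_reps") <- n_reps
  point
}

#' Write a tree in Newick format
#'
#' Standard Newick with branch lengths; integer bootstrap supports (when
#' present as `node.label`) are written as internal node labels. Labels
#' containing spaces or Newick metacharacters are single-quoted.
#'
#' @param tree A `phylo` tree (as from [nj_tree()] / [bootstrap_tree()]).
#' @param path Output file path.
#' @return The Newick string, invisibly (also written to `path` unless
#'   `NULL`).
#' @export
write_newick <- function(tree, path = NULL) {
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  quote_label <- function(x) {
    if (grepl("[^A-Za-z0-9_.|/-]", x)) {
      paste0("'", gsub("'", "''", x), "'")
    } else x
  }
  fmt_len <- function(w) {
    if (is.null(w) || is.na(w)) "" else paste0(":", format(w, digits = 10))
  }
  render <- function(node, blen) {
    if (node <= n) {
      return(paste0(quote_label(tree$tip.label[node]), fmt_len(blen)))
    }
    e <- kids[[as.character(node)]]
    parts <- vapply(e, function(ei) {
      render(tree$edge[ei, 2], tree$edge.length[ei])
    }, "")
    lab <- if (!is.null(tree$node.label)) tree$node.label[node - n] else ""
    paste0("(", paste(parts, collapse = ","), ")", lab, fmt_len(blen))
  }
  root <- n + 1L
  s <- paste0(render(root, NA), ";")
  if (!is.null(path)) writeLines(s, path)
  invisible(s)
}

#' Principal component analysis of a genotype table
#'
#' Accessions are projected onto the leading principal components of the
#' locus-centred genotype matrix (no variance scaling). No-calls are
#' mean-imputed per locus before centring. The sign of each component is
#' fixed so that its largest-magnitude locus loading is positive.
#'
#' @param geno A [geno_tbl] with at least 2 accessions and 2 loci.
#' @param n_components Number of components to report (default 3).
#' @return An object of class `geno_pca`: list with `scores` (tibble
#'   `accession_id`, `group`, `PC1`, ...), `explained_variance` (fractions,
#'   non-increasing), `loadings` (matrix loci x components).
#' @export
pca_genotypes <- function(geno, n_components = 3) {
  calls <- geno_calls(geno)
  if (ncol(calls) < 2L || nrow(calls) < 2L) {
    abort("need at least 2 accessions and 2 loci")
  }
  X <- t(calls)  # accessions x loci
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0L)) X[is.na(X[, j]), j] <- mu[j]
  keep <- apply(X, 2L, function(v) stats::var(v) > 0)
  if (!any(keep)) abort("no variance: all loci constant after imputation")
  X <- X[, keep, drop = FALSE]
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  sc <- p$x[, seq_len(k), drop = FALSE]
  for (c_i in seq_len(k)) {
    i_max <- which.max(abs(rot[, c_i]))
    if (rot[i_max, c_i] < 0) {
      rot[, c_i] <- -rot[, c_i]
      sc[, c_i] <- -sc[, c_i]
    }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  grp <- group_of(geno)
  scores <- dplyr::bind_cols(
    tibble(accession_id = rownames(X),
           group = unname(grp[rownames(X)])),
    as_tibble(sc, .name_repair = "minimal"))
  structure(list(scores = scores, explained_variance = ev[seq_len(k)],
                 loadings = rot),
            class = "geno_pca")
}

#' @exportS3Method base::print
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d accessions, %d components\n",
              nrow(x$scores), ncol(x$loadings)))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname pca_genotypes
#' @param x A `geno_pca`.
#' @param ... Unused.
#' @method tidy geno_pca
#' @export
tidy.geno_pca <- function(x, ...) x$scores

#' @rdname pca_genotypes
#' @method glance geno_pca
#' @export
glance.geno_pca <- function(x, ...) {
  tibble(n_accessions = nrow(x$scores),
         n_components = ncol(x$loadings),
         var_pc1 = x$explained_variance[1],
         var_total = sum(x$explained_variance))
}
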