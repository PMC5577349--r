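# Build an additive distance matrix from a known unrooted binary tree by
# summing path lengths; used as the exactness oracle for neighbor joining.
additive_matrix_5taxa <- function() {
  # ((a:2, b:3):1, (c:4, d:1):2, e:5) at a central node
  # path lengths via explicit enumeration
  d <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  limb <- c(a = 2, b = 3, c = 4, d = 1, e = 5)
  inner <- c(ab = 1, cd = 2)   # internal edges to the center
  path <- function(x, y) {
    up <- function(z) switch(z, a = inner[["ab"]], b = inner[["ab"]],
                             c = inner[["cd"]], d = inner[["cd"]], e = 0)
    same_cherry <- (x %in% c("a", "b") && y %in% c("a", "b")) ||
      (x %in% c("c", "d") && y %in% c("c", "d"))
    if (same_cherry) limb[[x]] + limb[[y]] else
      limb[[x]] + up(x) + up(y) + limb[[y]]
  }
  for (x in letters[1:5]) for (y in letters[1:5]) {
    if (x != y) d[x, y] <- path(x, y)
  }
  d
}

tree_dist <- function(tree) {
  # pairwise tip distances from a phylo edge list (independent traversal)
  n <- length(tree$tip.label)
  nodes <- max(tree$edge)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[u]] <- rbind(adj[[u]], c(v, w))
    adj[[v]] <- rbind(adj[[v]], c(u, w))
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0L) {
      u <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[u]]))) {
        v <- adj[[u]][k, 1]
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + adj[[u]][k, 2]
          queue <- c(queue, v)
        }
      }
    }
    d[s, ] <- dist[seq_len(n)]
  }
  d
}

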