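# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths and the libraries
# they delegate to.

# 8-connected component count / labeling by queue-based flood fill.
oracle_flood_fill <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L; cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# Connected components of an undirected graph given as an edge list over
# nodes 1..n, by breadth-first search.
oracle_bfs_components <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges) > 0) for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# O(n^3) UPGMA: cluster distance = mean of all original cross-pair
# distances; returns the cophenetic distance matrix, which determines the
# tree uniquely.
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best[1]) best <- c(dd, i, j)
    }
    i <- best[2]; j <- best[3]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- best[1]; coph[b, a] <- best[1]
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# Explained-variance ratios by eigen-decomposition of the covariance matrix.
oracle_pca_evr <- function(x) {
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  (ev / sum(ev))[seq_len(min(nrow(x) - 1, ncol(x)))]
}

# All-pairs shared-border scan: counts 4-connected straddling pixel pairs
# for every label pair by explicit loops.
oracle_adjacency <- function(lab, min_shared = 1L) {
  nr <- nrow(lab); nc <- ncol(lab)
  counts <- new.env()
  bump <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    a <- lab[r, cc]
    if (a == 0) next
    if (r < nr && lab[r + 1, cc] != a && lab[r + 1, cc] > 0) bump(a, lab[r + 1, cc])
    if (cc < nc && lab[r, cc + 1] != a && lab[r, cc + 1] > 0) bump(a, lab[r, cc + 1])
  }
  keys <- ls(counts)
  keep <- keys[vapply(keys, function(k) counts[[k]] >= min_shared, logical(1))]
  if (length(keep) == 0) return(matrix(integer(), ncol = 2))
  out <- do.call(rbind, lapply(strsplit(keep, " "), as.integer))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Rasterize a disk for constructed-object tests.
raster_disk <- function(r, pad = 5L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  matrix((g$x - ctr)^2 + (g$y - ctr)^2 <= r^2, n, n)
}

# Brute-force boundary ring: pixels of the retained cell whose Euclidean
# distance to the nearest non-cell pixel is at most `width`.
ring_of <- function(cells, width) {
  lab <- cells$labels
  nr <- nrow(lab); nc <- ncol(lab)
  inside <- which(lab == cells$retained[1])
  outside <- which(lab != cells$retained[1])
  orow <- ((outside - 1L) %% nr) + 1L
  ocol <- ((outside - 1L) %/% nr) + 1L
  ring <- matrix(FALSE, nr, nc)
  for (p in inside) {
    r <- ((p - 1L) %% nr) + 1L; cc <- ((p - 1L) %/% nr) + 1L
    if (min((orow - r)^2 + (ocol - cc)^2) <= width^2) ring[p] <- TRUE
  }
  ring
}
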