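#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Derive a child seed from a master seed and a stage/index key.
# Counter-based so that per-area streams are independent and parallel-safe.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  # 31-bit multiplicative string hash, kept exact in double arithmetic
  h <- 17
  for (ch in utf8ToInt(key))
    h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

# 8-connected labeling of a binary mask. EBImage::bwlabel is 4-connected,
# so components are taken on the pixel adjacency graph instead.
label8 <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(out)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  # neighbor offsets S, E, SE, NE cover all 8-neighbor pairs once
  pairs <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= nr & cc + dc >= 1L & cc + dc <= nc
    j <- idx[ok] + dr + dc * nr
    keep <- mask[j]
    cbind(pos[idx[ok][keep]], pos[j[keep]])
  }
  e <- rbind(pairs(1L, 0L), pairs(0L, 1L), pairs(1L, 1L), pairs(-1L, 1L))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(e) > 0) g <- igraph::add_edges(g, t(e))
  memb <- igraph::components(g)$membership
  out[idx] <- as.integer(memb)
  # relabel contiguous 1..K in first-pixel order for determinism
  first <- !duplicated(out[idx])
  remap <- integer(max(out))
  remap[out[idx][first]] <- seq_len(sum(first))
  out[idx] <- remap[out[idx]]
  out
}

# Crofton perimeter estimate from intercept counts in 4 directions.
crofton_perimeter <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  c0   <- sum(p[-1, ] != p[-nrow(p), ])
  c90  <- sum(p[, -1] != p[, -ncol(p)])
  c45  <- sum(p[-1, -1] != p[-nrow(p), -ncol(p)])
  c135 <- sum(p[-1, -ncol(p)] != p[-nrow(p), -1])
  pi / 4 * (c0 / 2 + c90 / 2 + c45 / (2 * sqrt(2)) + c135 / (2 * sqrt(2)))
}

# Relabel a label matrix to contiguous 1..K ordered by centroid (row-major).
relabel_rowmajor <- function(labels) {
  labs <- sort(unique(labels[labels > 0]))
  if (length(labs) == 0L) return(matrix(0L, nrow(labels), ncol(labels)))
  nr <- nrow(labels)
  idx <- which(labels > 0)
  l <- labels[idx]
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  cr <- tapply(r, l, mean)[as.character(labs)]
  ccm <- tapply(cc, l, mean)[as.character(labs)]
  ord <- order(cr, ccm)
  remap <- integer(max(labs))
  remap[labs[ord]] <- seq_along(labs)
  out <- labels
  out[idx] <- remap[l]
  storage.mode(out) <- "integer"
  out
}

# Gaussian blur wrapper keeping plain matrices (EBImage works in [0,1]-ish
# doubles but gblur is linear, so raw intensity scales pass through).
gblur_mat <- function(x, sigma) {
  if (sigma <= 0) return(x)
  as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma = sigma)))
}

# Bounding box (with padding, clipped to frame) of a set of pixel indices.
bbox_of <- function(idx, nr, nc, pad = 1L) {
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  list(r0 = max(1L, min(r) - pad), r1 = min(nr, max(r) + pad),
       c0 = max(1L, min(cc) - pad), c1 = min(nc, max(cc) + pad))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
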