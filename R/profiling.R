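#' Z-score standardize a feature table
#'
#' Per-feature standardization across areas: subtract the column mean and
#' divide by the sample standard deviation (denominator `n - 1`).
#' Zero-variance features become all-zero columns (reported via the
#' `degenerate` attribute and a message).
#'
#' @param table a feature table (tibble); annotation columns named in
#'   `annotations` are passed through untouched.
#' @param annotations character vector of non-feature columns.
#' @return The standardized tibble, with attribute `degenerate` listing
#'   constant features.
#' @export
normalize_features <- function(table,
                               annotations = c("cell_model", "treatment",
                                               "replicate", "area")) {
  ann <- intersect(annotations, names(table))
  feats <- setdiff(names(table), ann)
  if (nrow(table) < 2) abort("need >= 2 rows to standardize")
  degenerate <- character()
  out <- table
  for (f in feats) {
    v <- table[[f]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      out[[f]] <- rep(0, length(v))
      degenerate <- c(degenerate, f)
    } else out[[f]] <- (v - mean(v)) / s
  }
  if (length(degenerate) > 0)
    message("zero-variance features set to 0: ",
            paste(degenerate, collapse = ", "))
  attr(out, "degenerate") <- degenerate
  out
}

#' Principal component analysis of a standardized feature table
#'
#' Scores and loadings from the singular value decomposition of the
#' column-centered matrix; `explained_variance_ratio[j] = s_j^2 / sum s^2`.
#' The sign convention is deterministic: within each component, the
#' largest-magnitude loading is made positive.
#'
#' @param table standardized feature table (tibble).
#' @param k number of components, `<= min(rows - 1, features)`.
#' @param annotations non-feature columns.
#' @return A list with `scores` (tibble, annotations + PC columns),
#'   `loadings` (feature x component matrix), and
#'   `explained_variance_ratio`.
#' @export
pca_profile <- function(table, k = 3,
                        annotations = c("cell_model", "treatment",
                                        "replicate", "area")) {
  ann <- intersect(annotations, names(table))
  feats <- setdiff(names(table), ann)
  x <- as.matrix(table[, feats])
  n <- nrow(x)
  if (n < 2) abort("need >= 2 rows")
  if (k > min(n - 1, ncol(x))) abort("k out of range")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  evr <- sv$d^2 / sum(sv$d^2)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, `*`)
  rownames(loadings) <- feats
  colnames(loadings) <- paste0("PC", seq_len(k))
  sc <- as_tibble(as.data.frame(scores))
  names(sc) <- paste0("PC", seq_len(k))
  list(scores = dplyr::bind_cols(table[, ann], sc),
       loadings = loadings,
       explained_variance_ratio = evr[seq_len(min(n - 1, ncol(x)))])
}

#' Hierarchical clustering of areas (UPGMA)
#'
#' Pairwise Euclidean distances between standardized area rows,
#' average-linkage (UPGMA) agglomeration, and a deterministic leaf order:
#' the dendrogram is reordered by each leaf's average feature value.
#'
#' @inheritParams pca_profile
#' @return A list with `hclust` (the [stats::hclust] tree), `leaf_order`
#'   (row indices in display order) and `merge_heights`.
#' @export
hcluster <- function(table, annotations = c("cell_model", "treatment",
                                            "replicate", "area")) {
  ann <- intersect(annotations, names(table))
  x <- as.matrix(table[, setdiff(names(table), ann)])
  if (nrow(x) < 2) abort("need >= 2 rows")
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "average")
  dend <- stats::as.dendrogram(hc)
  dend <- stats::reorder(dend, rowMeans(x), agglo.FUN = mean)
  leaf_order <- as.integer(stats::order.dendrogram(dend))
  list(hclust = hc, leaf_order = leaf_order, merge_heights = hc$height)
}

#' Multivariate phenotypic profile of an experiment
#'
#' Standardizes the feature table, then runs PCA and UPGMA hierarchical
#' clustering — the population-level view in which distinct endothelial
#' models form discrete clusters.
#'
#' @param table raw feature table from [analyze_experiment()].
#' @param k number of principal components.
#' @param annotations non-feature columns.
#' @return An object of class `ec_profile` with elements `table`
#'   (standardized), `pca`, `clustering`, `annotations`.
#' @export
profile_features <- function(table, k = 3,
                             annotations = c("cell_model", "treatment",
                                             "replicate", "area")) {
  std <- normalize_features(table, annotations)
  structure(list(table = std,
                 pca = pca_profile(std, k, annotations),
                 clustering = hcluster(std, annotations),
                 annotations = intersect(annotations, names(table))),
            class = "ec_profile")
}

#' @export
print.ec_profile <- function(x, ...) {
  evr <- x$pca$explained_variance_ratio
  cat(sprintf("<ec_profile> %d areas x %d features\n", nrow(x$table),
              ncol(x$table) - length(x$annotations)))
  cat(sprintf("  PC1..PC3 cumulative explained variance: %s\n",
              paste(sprintf("%.0f%%", cumsum(evr[seq_len(min(3, length(evr)))]) * 100),
                    collapse = " / ")))
  invisible(x)
}

#' Tidy the component scores of a profile
#' @param x an `ec_profile`.
#' @param ... unused.
#' @return A tibble of annotations plus PC score columns.
#' @export
tidy.ec_profile <- function(x, ...) x$pca$scores

#' One-row summary of a profile
#' @param x an `ec_profile`.
#' @param ... unused.
#' @return A tibble with the number of areas and features and the variance
#'   explained by the first three components.
#' @export
glance.ec_profile <- function(x, ...) {
  evr <- x$pca$explained_variance_ratio
  cum <- cumsum(evr)
  tibble(n_areas = nrow(x$table),
         n_features = ncol(x$table) - length(x$annotations),
         evr_pc1 = evr[1],
         cum_evr_pc2 = cum[min(2, length(cum))],
         cum_evr_pc3 = cum[min(3, length(cum))])
}

#' Score plot of a profile
#' @param object an `ec_profile`.
#' @param ... unused.
#' @return A ggplot of PC1 vs PC2 scores, colored by cell model and shaped
#'   by treatment when those annotations exist.
#' @export
autoplot.ec_profile <- function(object, ...) {
  sc <- object$pca$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("cell_model" %in% names(sc))
    p <- p + ggplot2::aes(colour = .data$cell_model)
  if ("treatment" %in% names(sc))
    p <- p + ggplot2::aes(shape = .data$treatment)
  evr <- object$pca$explained_variance_ratio
  p + ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * evr[1]),
                  y = sprintf("PC2 (%.0f%%)", 100 * evr[2])) +
    ggplot2::theme_minimal()
}

#' Dendrogram plot of the area clustering
#' @param profile an `ec_profile`.
#' @return A ggplot dendrogram of merge heights with annotated leaves.
#' @export
plot_dendrogram <- function(profile) {
  hc <- profile$clustering$hclust
  lab <- profile$table
  leaf_names <- if (all(c("cell_model", "treatment") %in% names(lab)))
    paste(lab$cell_model, lab$treatment, lab$replicate, lab$area, sep = "_")
  else as.character(seq_len(nrow(lab)))
  hc$labels <- leaf_names
  dd <- stats::as.dendrogram(hc)
  # simple segment extraction
  segs <- dendro_segments(dd)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::labs(x = NULL, y = "merge height") +
    ggplot2::theme_minimal()
}

dendro_segments <- function(dend) {
  segs <- list()
  leaf_x <- 0
  rec <- function(d) {
    if (is.leaf(d)) {
      leaf_x <<- leaf_x + 1
      return(list(x = leaf_x, y = 0))
    }
    h <- attr(d, "height")
    kids <- lapply(seq_along(d), function(i) rec(d[[i]]))
    xs <- vapply(kids, `[[`, numeric(1), "x")
    ys <- vapply(kids, `[[`, numeric(1), "y")
    for (i in seq_along(kids)) {
      segs[[length(segs) + 1]] <<- data.frame(x = xs[i], y = ys[i],
                                              xend = xs[i], yend = h)
    }
    segs[[length(segs) + 1]] <<- data.frame(x = min(xs), y = h,
                                            xend = max(xs), yend = h)
    list(x = mean(xs), y = h)
  }
  rec(dend)
  do.call(rbind, segs)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy
#' @export
generics::glance
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
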