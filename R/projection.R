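#' Project embeddings into a 2D landscape
#'
#' Maps the term-by-dimension embedding matrix to two coordinates per term
#' for landscape visualization. The default backend is deterministic PCA on
#' L2-normalized, mean-centered vectors (normalization makes Euclidean PCA
#' geometry approximate the cosine geometry used everywhere else). The
#' projection is visualization-only: no downstream statistic depends on it,
#' and only aggregate topology (community separation) is asserted, not exact
#' coordinates. \code{nNeighbors} and \code{iterations} parameterize
#' neighbor-based backends and are recorded in the metadata.
#'
#' @param embedding an \code{EventEmbedding} or numeric matrix with row
#'   names.
#' @param nNeighbors neighborhood size metadata, default 20.
#' @param iterations iteration-count metadata, default 450.
#' @param method projection backend; currently \code{"pca"}.
#' @param seed integer seed recorded in the metadata (PCA is deterministic).
#' @return data.frame with columns \code{term}, \code{x}, \code{y},
#'   \code{system}; attribute \code{"method"} holds the metadata list.
#' @export
projectEmbedding <- function(embedding, nNeighbors = 20L,
                             iterations = 450L, method = "pca",
                             seed = 1L) {
  m <- if (is(embedding, "EventEmbedding")) embeddingVectors(embedding)
       else embedding
  if (nrow(m) < nNeighbors + 1)
    stop("too few terms: need at least nNeighbors + 1")
  method <- match.arg(method, "pca")
  x <- l2normalize(m)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2)
  coords <- pc$x[, 1:2, drop = FALSE]
  # deterministic sign convention
  for (j in 1:2) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  sys <- if (is(embedding, "EventEmbedding")) {
    vocab <- vocabulary(embedding)
    stats::setNames(vocab$system, vocab$token)[rownames(m)]
  } else rep(NA_character_, nrow(m))
  out <- data.frame(term = rownames(m), x = coords[, 1], y = coords[, 2],
                    system = unname(sys), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- list(method = method, nNeighbors = nNeighbors,
                              iterations = iterations, metric = "cosine",
                              seed = seed)
  out
}

#' Kernel density estimate of the projected landscape
#'
#' 2D Gaussian KDE over the projected coordinates on a regular grid
#' (bandwidth by the normal reference rule unless given). The returned
#' surface is non-negative and integrates to approximately 1 over the grid.
#'
#' @param projection data.frame from \code{\link{projectEmbedding}} (or any
#'   data.frame with \code{x}, \code{y}).
#' @param gridSize grid resolution per axis, default 100.
#' @param bandwidth optional length-2 bandwidth; default
#'   \code{MASS::bandwidth.nrd} per axis.
#' @param expand fraction by which the grid extends beyond the data range,
#'   default 0.3 (so the density mass is captured).
#' @return list with \code{x}, \code{y} (grid axes) and \code{z} (density
#'   matrix).
#' @export
landscapeDensity <- function(projection, gridSize = 100L,
                             bandwidth = NULL, expand = 0.3) {
  if (nrow(projection) < 2) stop("need at least 2 points")
  px <- projection$x; py <- projection$y
  if (stats::sd(px) == 0 || stats::sd(py) == 0)
    stop("zero-variance coordinates: density undefined")
  if (is.null(bandwidth))
    bandwidth <- c(MASS::bandwidth.nrd(px), MASS::bandwidth.nrd(py))
  rx <- range(px); ry <- range(py)
  padx <- max(diff(rx) * expand, bandwidth[1] * 3)
  pady <- max(diff(ry) * expand, bandwidth[2] * 3)
  MASS::kde2d(px, py, h = bandwidth, n = gridSize,
              lims = c(rx[1] - padx, rx[2] + padx,
                       ry[1] - pady, ry[2] + pady))
}

#' Overlay coordinates for highlighted terms
#'
#' Subsets the projection to a query set (e.g. the sleep-related terms), for
#' plotting over the landscape density. Terms absent from the projection are
#' listed in the \code{"missing"} attribute.
#'
#' @param projection data.frame from \code{\link{projectEmbedding}}.
#' @param terms character vector of terms to highlight.
#' @return data.frame subset of the projection; attribute \code{"missing"}.
#' @export
highlightTerms <- function(projection, terms) {
  sel <- projection$term %in% terms
  out <- projection[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing") <- setdiff(terms, projection$term)
  out
}

#' Plot the embedding landscape
#'
#' Scatter of projected terms colored by code system over optional KDE
#' contours, with an optional highlighted query subset. Requires ggplot2.
#'
#' @param projection data.frame from \code{\link{projectEmbedding}}.
#' @param density optional result of \code{\link{landscapeDensity}}.
#' @param highlight optional data.frame from \code{\link{highlightTerms}}.
#' @return a ggplot object.
#' @export
plotLandscape <- function(projection, density = NULL, highlight = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  p <- ggplot2::ggplot(projection, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(density)) {
    dd <- expand.grid(x = density$x, y = density$y)
    dd$z <- as.vector(density$z)
    p <- p + ggplot2::geom_contour(
      data = dd, ggplot2::aes(z = .data$z), colour = "grey70")
  }
  p <- p + ggplot2::geom_point(
    ggplot2::aes(colour = .data$system), size = 1, alpha = 0.7)
  if (!is.null(highlight) && nrow(highlight))
    p <- p + ggplot2::geom_point(data = highlight, colour = "black",
                                 shape = 21, size = 3, stroke = 1) +
      ggplot2::geom_text(data = highlight,
                         ggplot2::aes(label = .data$term),
                         vjust = -1, size = 3)
  p + ggplot2::theme_minimal() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2", colour = "system")
}

#' Write projection coordinates / a density grid as TSV
#'
#' @param projection data.frame from \code{\link{projectEmbedding}}.
#' @param density result of \code{\link{landscapeDensity}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProjectionTSV <- function(projection, path) {
  utils::write.table(projection, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeProjectionTSV
#' @export
writeDensityTSV <- function(density, path) {
  dd <- expand.grid(x = density$x, y = density$y)
  dd$density <- as.vector(density$z)
  utils::write.table(dd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
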