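# Diagnostics: document distances, classical MDS, rendered outputs.

#' Cosine distances between document consensus profiles
#'
#' @param x a `"consensus_result"` (or fitted [topic_consensus()]); the
#'   rows of `doc_scores` are the profiles. A document with an all-zero
#'   profile has no direction and is an error.
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
document_distance_matrix <- function(x) {
  if (inherits(x, "topic_consensus")) x <- x$consensus
  profiles <- if (inherits(x, "consensus_result")) x$doc_scores
              else as.matrix(x)
  zero <- rowSums(abs(profiles)) == 0
  if (any(zero))
    stop("zero consensus profile for document(s): ",
         paste(rownames(profiles)[zero], collapse = ", "))
  d <- cosine_distance_rows(profiles)
  d <- (d + t(d)) / 2  # enforce exact symmetry against rounding
  d
}

#' Classical (Torgerson) multidimensional scaling to 2 dimensions
#'
#' Double-centers -D^2/2 and takes the top two eigenpairs. Coordinates
#' are centered; each axis follows a deterministic sign convention (the
#' largest-magnitude coordinate is positive). If fewer than two positive
#' eigenvalues exist, the embedding falls back to one dimension plus a
#' zero column, with a warning.
#'
#' @param d symmetric distance matrix (e.g. from
#'   [document_distance_matrix()]).
#' @return An object of class `"embedding2d"`: `points` (n x 2), `eig`
#'   (all eigenvalues), `stress` (relative residual
#'   sqrt(sum((D - Dhat)^2) / sum(D^2)) of embedded distances).
#' @export
mds_embed <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 points")
  if (max(abs(d - t(d))) > 1e-9 || any(abs(diag(d)) > 1e-9))
    stop("`d` must be symmetric with a zero diagonal")
  res <- stats::cmdscale(d, k = 2L, eig = TRUE)
  pos <- sum(res$eig > max(res$eig) * 1e-12 & res$eig > 0)
  pts <- res$points
  if (ncol(pts) < 2L || pos < 2L) {
    warning("fewer than 2 positive eigenvalues; embedding padded to 2D ",
            "with a zero column")
    pts <- cbind(pts[, 1], 0)
  }
  for (j in 1:2) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- c("mds1", "mds2")
  dhat <- as.matrix(stats::dist(pts))
  stress <- sqrt(sum((d - dhat)^2) / sum(d^2))
  structure(list(points = pts, eig = res$eig, stress = stress),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d: %d points, stress %.4f>\n",
              nrow(x$points), x$stress))
  invisible(x)
}

#' Render cluster diagnostics to files
#'
#' Writes (i) an MDS scatter colored by cluster with the
#' between-centroid discriminative arrow, (ii) a symmetric
#' cluster-membership diagram listing each cluster's documents side by
#' side, and (iii) one top-keyword CSV per cluster. CSV bytes are
#' deterministic given identical inputs.
#'
#' @param embedding an [mds_embed()] result.
#' @param consensus a `"consensus_result"`.
#' @param keywords named list of per-cluster keyword data frames, e.g.
#'   from [summary.topic_consensus()]'s `keywords` component; `NULL`
#'   skips the CSVs.
#' @param dir output directory (created if absent).
#' @param format image format, `"png"` or `"svg"`.
#' @return Invisibly, the paths written.
#' @export
render_outputs <- function(embedding, consensus, keywords = NULL, dir,
                           format = c("png", "svg")) {
  stopifnot(inherits(embedding, "embedding2d"),
            inherits(consensus, "consensus_result"))
  format <- match.arg(format)
  if (nrow(embedding$points) != length(consensus$assignment))
    stop("embedding and consensus cover different numbers of documents")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dev_open <- function(path) {
    if (format == "png") grDevices::png(path, width = 700, height = 600)
    else grDevices::svg(path, width = 7, height = 6)
  }
  asg <- consensus$assignment
  paths <- character(0)

  p <- file.path(dir, paste0("cluster_scatter.", format))
  dev_open(p)
  graphics::plot(embedding$points, col = asg + 1L, pch = 19L,
                 xlab = "MDS 1", ylab = "MDS 2",
                 main = "Consensus clusters")
  cent <- apply(embedding$points, 2L, function(v) tapply(v, asg, mean))
  if (is.matrix(cent) && nrow(cent) == 2L)
    graphics::arrows(cent[1, 1], cent[1, 2], cent[2, 1], cent[2, 2],
                     col = "red", lwd = 2, length = 0.1)
  grDevices::dev.off()
  paths <- c(paths, p)

  p <- file.path(dir, paste0("cluster_membership.", format))
  dev_open(p)
  ids <- names(asg)
  cls <- sort(unique(asg))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, length(cls) + 1),
                        ylim = c(0, max(table(asg)) + 2))
  graphics::title("Cluster membership")
  for (ci in seq_along(cls)) {
    members <- ids[asg == cls[ci]]
    graphics::text(ci, max(table(asg)) + 1,
                   sprintf("cluster %d (n = %d)", cls[ci], length(members)),
                   font = 2, col = cls[ci] + 1L)
    graphics::text(rep(ci, length(members)),
                   rev(seq_along(members)), members, cex = 0.6)
  }
  grDevices::dev.off()
  paths <- c(paths, p)

  if (!is.null(keywords)) {
    for (nm in names(keywords)) {
      p <- file.path(dir, sprintf("keywords_%s.csv", nm))
      tab <- keywords[[nm]]
      tab$weight <- sprintf("%.10g", tab$weight)
      utils::write.csv(tab, p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
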