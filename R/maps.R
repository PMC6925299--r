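#' Group-mean dissimilarity matrix from an ACC table
#'
#' Entry (i, j) is the group-mean ACC magnitude for the unordered pair
#' {i, j}, averaged over both presentation orders and subjects; larger
#' responses mean more discriminable vowels, hence larger dissimilarity.
#'
#' @param table ACC table.
#' @param age_group group to aggregate (`NULL` uses all rows).
#' @param response magnitude column.
#' @param vowels vowel order for the matrix; defaults to the sorted labels.
#' @param clamp_negative clamp negative group means to zero (a baseline-
#'   subtracted magnitude can dip below zero for near-indiscriminable pairs;
#'   a dissimilarity cannot).
#' @return symmetric matrix with zero diagonal and vowel dimnames.
#' @export
to_dissimilarity <- function(table, age_group = NULL,
                             response = "acc_mean_uv", vowels = NULL,
                             clamp_negative = TRUE) {
  if (!is.null(age_group)) table <- table[table$age_group %in% age_group, ]
  if (nrow(table) == 0) stop("no rows for requested age group")
  if (is.null(vowels)) vowels <- sort(unique(c(table$from, table$to)))
  n <- length(vowels)
  m <- matrix(0, n, n, dimnames = list(vowels, vowels))
  means <- tapply(table[[response]], table$pair, mean)
  if (clamp_negative) means <- pmax(means, 0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pp <- paste_pair(vowels[i], vowels[j])
      if (!pp %in% names(means))
        stop("incomplete matrix: pair ", pp, " missing")
      m[i, j] <- m[j, i] <- means[[pp]]
    }
  }
  m
}

#' Classical MDS perceptual map with additive constant
#'
#' Classical (Torgerson) multidimensional scaling of a dissimilarity matrix
#' into `k` dimensions, including an additive constant (Cailliez) so the
#' dissimilarities are Euclidean-embeddable; negative residual eigenvalues
#' are excluded from the coordinates and kept for diagnostics. Two fit
#' indices are reported: `vaf`, the squared Pearson correlation (x 100)
#' between the solution's inter-point distances and the input
#' dissimilarities, and `gof`, the eigenvalue-ratio goodness of fit
#' (variance of the double-centered matrix captured by the `k` retained
#' axes).
#'
#' @param D symmetric non-negative dissimilarity matrix, zero diagonal.
#' @param k embedding dimension (default 2), below `nrow(D)`.
#' @param age_group optional tag stored on the map.
#' @return object of class `perceptual_map`: `points` (n x k, centered),
#'   `eig` (full eigenvalue spectrum), `vaf`, `gof`, `add_constant`,
#'   `age_group`, `transform` (`NULL` until aligned).
#' @export
classical_mds <- function(D, k = 2, age_group = NULL) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8))
    stop("dissimilarity matrix must be symmetric")
  if (any(D < 0) || any(abs(diag(D)) > 1e-12))
    stop("dissimilarities must be non-negative with zero diagonal")
  if (all(D == 0)) stop("degenerate solution: all-zero dissimilarities")
  if (k >= nrow(D)) stop("k must be below the number of items")
  fit <- cmdscale(as.dist(D), k = k, eig = TRUE, add = TRUE)
  pts <- fit$points
  rownames(pts) <- rownames(D)
  dd <- as.numeric(as.dist(D))
  fitted_d <- as.numeric(dist(pts))
  vaf <- if (sd(fitted_d) == 0 || sd(dd) == 0) 0 else
    100 * cor(fitted_d, dd)^2
  ev <- fit$eig
  gof <- sum(pmax(ev[seq_len(k)], 0)) / sum(pmax(ev, 0))
  structure(list(points = pts, eig = ev, vaf = vaf, gof = 100 * gof,
                 add_constant = fit$ac, age_group = age_group,
                 transform = NULL),
            class = "perceptual_map")
}

#' @export
print.perceptual_map <- function(x, ...) {
  cat(sprintf("<perceptual_map%s: %d vowels in %d-D, VAF %.1f%%, GOF %.1f%%>\n",
              if (!is.null(x$age_group)) paste0(" [", x$age_group, "]") else "",
              nrow(x$points), ncol(x$points), x$vaf, x$gof))
  print(round(x$points, 3))
  invisible(x)
}

#' Plot a perceptual vowel map
#'
#' @param x a `perceptual_map`.
#' @param quad optional character vector of vowels in quadrilateral order;
#'   consecutive vowels are joined by lines.
#' @param ... passed to [plot()].
#' @export
plot.perceptual_map <- function(x, quad = NULL, ...) {
  p <- x$points
  plot(p[, 1], p[, 2], type = "n", xlab = "dimension 1",
       ylab = "dimension 2",
       main = if (!is.null(x$age_group)) x$age_group else "perceptual map",
       ...)
  if (!is.null(quad)) {
    q <- p[quad, , drop = FALSE]
    lines(q[, 1], q[, 2], col = "grey60")
  }
  text(p[, 1], p[, 2], labels = rownames(p), cex = 1.2)
  invisible(x)
}

#' Align a perceptual map to reference coordinates
#'
#' Similarity transform (translation, rotation, reflection when it reduces
#' error, and uniform scaling) minimizing the summed squared distance to the
#' reference configuration (orthogonal Procrustes with scaling).
#'
#' @param map a [classical_mds()] map, or a bare coordinate matrix.
#' @param reference reference coordinates (same rows/labels, same k).
#' @return the map with `points` replaced by the aligned coordinates and
#'   `transform` holding `rotation`, `scale`, `translation`, `rss`.
#' @export
procrustes_align <- function(map, reference) {
  pts <- if (inherits(map, "perceptual_map")) map$points else as.matrix(map)
  reference <- as.matrix(reference)
  if (!is.null(rownames(pts)) && !is.null(rownames(reference))) {
    if (!setequal(rownames(pts), rownames(reference)))
      stop("label sets differ between map and reference")
    reference <- reference[rownames(pts), , drop = FALSE]
  }
  if (nrow(pts) < 3)
    warning("unstable alignment: fewer than 3 points")
  # orthogonal Procrustes with uniform scaling and translation: centre both
  # configurations, rotate (SVD solution, reflections permitted), scale by
  # the least-squares factor, translate onto the reference centroid
  xc <- colMeans(reference)
  yc <- colMeans(pts)
  Xc <- sweep(reference, 2, xc)
  Yc <- sweep(pts, 2, yc)
  sv <- svd(crossprod(Xc, Yc))
  rot <- sv$v %*% t(sv$u)
  sc <- sum(sv$d) / sum(Yc^2)
  aligned <- sc * Yc %*% rot + matrix(xc, nrow(pts), ncol(pts), byrow = TRUE)
  rownames(aligned) <- rownames(pts)
  transform <- list(rotation = rot, scale = sc,
                    translation = xc - sc * as.numeric(yc %*% rot),
                    rss = sum((aligned - reference)^2))
  if (inherits(map, "perceptual_map")) {
    map$points <- aligned
    map$transform <- transform
    map
  } else {
    structure(list(points = aligned, eig = NULL, vaf = NA, gof = NA,
                   add_constant = NA, age_group = NULL,
                   transform = transform),
              class = "perceptual_map")
  }
}

#' Write a perceptual map as TSV
#'
#' @param map a `perceptual_map`.
#' @param path output path (vowel, dim1, dim2 columns).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  d <- data.frame(vowel = rownames(map$points), map$points)
  names(d)[-1] <- paste0("dim", seq_len(ncol(map$points)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
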