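#' Centered log-ratio transform with a per-sample pseudocount
#'
#' For each sample with total read count N, the pseudocount 1/N is added
#' to every raw count before taking logarithms; each row is then centered
#' by its mean log value.  CLR is scale-invariant, so no prior closure to
#' proportions is needed; every output row sums to zero.  A global
#' pseudocount (1 over the grand total) is available for sensitivity
#' checks.
#'
#' @param table a [taxon_table()] (or plain count matrix).
#' @param pseudocount "per_sample" (default: 1/row total) or "global"
#'   (1/grand total for every sample).
#' @return numeric matrix of CLR values, samples x taxa, with attribute
#'   `pseudocount_used` (per-sample numeric vector).
#' @examples
#' clr_transform(taxon_table(matrix(c(9, 1), 1, 2,
#'   dimnames = list("s1", c("t1", "t2"))), groups = c(s1 = "g")))
#' @export
clr_transform <- function(table, pseudocount = c("per_sample", "global")) {
  pseudocount <- match.arg(pseudocount)
  m <- unclass(as.matrix(table))
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  delta <- if (pseudocount == "per_sample") 1 / tot
           else rep(1 / sum(m), nrow(m))
  lg <- log(m + delta)
  clr <- lg - rowMeans(lg)
  attr(clr, "pseudocount_used") <- stats::setNames(delta, rownames(m))
  attr(clr, "groups") <- attr(table, "groups")
  clr
}

#' Principal component analysis of a CLR matrix
#'
#' Column-centers the CLR matrix and decomposes it by singular value
#' decomposition (covariance PCA; no scaling).  Loadings columns are unit
#' norm with the sign convention that each column's largest-magnitude
#' entry is positive.  Scores are the projections of the centered rows
#' onto the loadings; explained variance ratios come from the squared
#' singular values.
#'
#' @param clr a CLR matrix from [clr_transform()] (any numeric samples x
#'   variables matrix works).
#' @param k number of components (default `min(n - 1, p)`).
#' @return object of class `clr_pca`: list with `scores` (n x k),
#'   `loadings` (p x k, orthonormal), `explained_variance_ratio`
#'   (length k, non-increasing), `sdev`, `center`, `groups` (carried over
#'   when present).  Methods: `print`, `plot` (biplot).
#' @export
clr_pca <- function(clr, k = NULL) {
  m <- as.matrix(clr)
  n <- nrow(m); p <- ncol(m)
  if (n < 2) stop("need at least 2 samples")
  kmax <- min(n - 1, p)
  if (is.null(k)) k <- kmax
  if (k > kmax) stop("k exceeds min(samples - 1, taxa) = ", kmax)
  ctr <- colMeans(m)
  xc <- sweep(m, 2, ctr)
  sv <- svd(xc)
  d <- sv$d
  total_var <- sum(d^2)
  evr <- if (total_var > 0) d^2 / total_var else rep(0, length(d))
  scores <- sv$u %*% diag(d, length(d))
  loadings <- sv$v
  # orient each component so its dominant loading is positive
  for (j in seq_len(ncol(loadings))) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  keep <- seq_len(k)
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(ncol(scores))))
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_len(ncol(loadings))))
  structure(list(scores = scores[, keep, drop = FALSE],
                 loadings = loadings[, keep, drop = FALSE],
                 explained_variance_ratio = evr[keep],
                 sdev = d[keep] / sqrt(max(n - 1, 1)),
                 center = ctr,
                 groups = attr(clr, "groups")),
            class = "clr_pca")
}

#' @export
print.clr_pca <- function(x, ...) {
  k <- length(x$explained_variance_ratio)
  cat("CLR-PCA: ", nrow(x$scores), " samples, ", k, " components\n",
      sep = "")
  cat("explained variance: ",
      paste(sprintf("PC%d %.1f%%", seq_len(min(k, 5)),
                    100 * x$explained_variance_ratio[seq_len(min(k, 5))]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Biplot of a CLR-PCA
#'
#' Sample scores on two components, colored by group when group labels are
#' attached, with the `n_loadings` most influential taxa drawn as loading
#' vectors scaled by the singular values.
#'
#' @param x a [clr_pca()] object.
#' @param pcs length-2 integer vector of components (default c(1, 2)).
#' @param n_loadings number of taxon vectors to draw (default 5).
#' @param ... further graphical parameters.
#' @return invisibly `x`.
#' @export
plot.clr_pca <- function(x, pcs = c(1, 2), n_loadings = 5, ...) {
  s <- x$scores[, pcs, drop = FALSE]
  g <- x$groups
  col <- if (is.null(g)) "black" else as.integer(factor(g))
  pct <- 100 * x$explained_variance_ratio[pcs]
  graphics::plot(s, col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", pcs[1], pct[1]),
                 ylab = sprintf("PC%d (%.1f%%)", pcs[2], pct[2]), ...)
  infl <- order(rowSums(x$loadings[, pcs, drop = FALSE]^2),
                decreasing = TRUE)[seq_len(min(n_loadings,
                                               nrow(x$loadings)))]
  sc <- 0.8 * max(abs(s))
  arr <- x$loadings[infl, pcs, drop = FALSE] * sc
  graphics::arrows(0, 0, arr[, 1], arr[, 2], length = 0.08, col = "grey40")
  graphics::text(arr * 1.08, rownames(arr), cex = 0.7, col = "grey20")
  if (!is.null(g))
    graphics::legend("topright", legend = levels(factor(g)),
                     col = seq_along(levels(factor(g))), pch = 19,
                     cex = 0.8)
  invisible(x)
}
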