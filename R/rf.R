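#' Random-forest taxon importance ranking
#'
#' Fits a classification random forest of `n_trees` trees (all other
#' parameters at the implementation's defaults) to predict group labels
#' from per-sample taxon relative abundances, and ranks taxa by mean
#' decrease in Gini impurity.  Ties are broken lexicographically by taxon
#' name, and a fixed seed makes the forest and ranking reproducible.
#' Permutation (mean decrease in accuracy) importance is available behind
#' a flag.
#'
#' @param table a [taxon_table()].
#' @param which_groups group labels to include (default: the two-group
#'   comparison when exactly two groups exist, otherwise all groups;
#'   multi-class is supported).
#' @param n_trees number of trees (default 10000; rankings are stable from
#'   a few hundred trees, so test workloads may lower this).
#' @param seed integer seed.
#' @param importance "gini" (default, mean decrease in impurity) or
#'   "permutation" (mean decrease in accuracy).
#' @return object of class `rf_ranking`: data.frame `ranking` (taxon,
#'   importance, rank, ordered by decreasing importance), `oob_error`
#'   (out-of-bag misclassification rate), `n_trees`, `seed`.
#' @export
rf_importance <- function(table, which_groups = NULL, n_trees = 10000,
                          seed = 1, importance = c("gini", "permutation")) {
  importance <- match.arg(importance)
  stopifnot(inherits(table, "taxon_table"))
  g <- groups(table)
  if (is.null(which_groups)) which_groups <- unique(g)
  keep <- g %in% which_groups
  g <- factor(g[keep])
  if (nlevels(g) < 2) stop("need at least 2 classes")
  if (any(tabulate(g) < 3)) stop("every class needs at least 3 samples")
  ra <- relative_abundance(table)[keep, , drop = FALSE]
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = as.data.frame(ra), y = g, ntree = n_trees,
    importance = importance == "permutation")
  imp <- if (importance == "gini")
    randomForest::importance(fit, type = 2)[, 1]
  else
    randomForest::importance(fit, type = 1)[, 1]
  ord <- order(-imp, names(imp))
  ranking <- data.frame(taxon = names(imp)[ord],
                        importance = unname(imp[ord]),
                        rank = seq_along(imp))
  oob <- mean(fit$predicted != g)
  structure(list(ranking = ranking, oob_error = oob,
                 n_trees = n_trees, seed = seed,
                 importance_type = importance),
            class = "rf_ranking")
}

#' @export
print.rf_ranking <- function(x, ...) {
  cat("Random-forest ranking (", x$n_trees, " trees, ",
      x$importance_type, " importance), OOB error ",
      sprintf("%.3f", x$oob_error), "\n", sep = "")
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' Importance bar chart of a random-forest ranking
#'
#' @param x an [rf_importance()] object.
#' @param n_top number of taxa to show (default 15).
#' @param ... further graphical parameters.
#' @return invisibly `x`.
#' @export
plot.rf_ranking <- function(x, n_top = 15, ...) {
  top <- utils::head(x$ranking, n_top)
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(top$importance), names.arg = rev(top$taxon),
                    horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "importance", ...)
  invisible(x)
}
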