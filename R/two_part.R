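# standardized Wilcoxon rank-sum z for group `a` versus `b`: normal
# approximation with tie correction, no continuity correction.  A fully
# tied pooled sample has zero variance; z is then 0 by convention.
wilcoxon_z <- function(a, b) {
  m1 <- length(a); m2 <- length(b); N <- m1 + m2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(m1)])
  EW <- m1 * (N + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  V <- m1 * m2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (V <= 0) return(0)
  (W - EW) / sqrt(V)
}

#' Two-part presence/abundance test for one taxon
#'
#' Compares two groups of zero-inflated relative abundances by combining
#' two z-statistics into a chi-square: (part 1) the difference in the
#' proportion of samples in which the taxon is present, via a pooled
#' two-proportion z, and (part 2) a Wilcoxon rank-sum z on the non-zero
#' abundances only, using the normal approximation with tie correction and
#' no continuity correction.  When both parts are defined the statistic is
#' Zp^2 + Zw^2 on 2 df.  When every sample is positive in both groups the
#' presence part is uninformative and the test reduces to the Wilcoxon z
#' on all values, 1 df.  When one group has no positive samples the rank
#' part is undefined and the test reduces to the presence part, 1 df.  The
#' p-value is the upper chi-square tail.
#'
#' @param x,y numeric vectors of per-sample relative abundances for the
#'   two groups (length >= 2 each, values in \[0, 1\]; zeros mark absence).
#' @return list: `Zp_sq`, `Zw_sq`, `statistic`, `df`, `p`, `parts_used`
#'   (one of "both", "wilcoxon_only", "presence_only"), plus the group
#'   sizes, positive proportions and medians feeding the effect views.
#' @examples
#' # hand-checkable instance: Zp^2 = 2.5, Zw^2 = 5, p = exp(-3.75)
#' two_part_test(c(0, 0, 1, 2, 3) / 10, c(4, 5, 6, 7, 8) / 10)
#' @export
two_part_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  if (all(x == 0) && all(y == 0))
    stop("taxon absent from both groups; apply the prevalence filter first")
  p1 <- mean(x > 0); p2 <- mean(y > 0)
  pbar <- (sum(x > 0) + sum(y > 0)) / (n1 + n2)
  Zp <- if (pbar == 0 || pbar == 1) 0 else
    (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  if (pbar == 1) {
    Zw <- wilcoxon_z(x, y)
    parts <- "wilcoxon_only"
    Zp_sq <- 0; Zw_sq <- Zw^2
    stat <- Zw_sq; df <- 1L
  } else {
    xn <- x[x > 0]; yn <- y[y > 0]
    if (length(xn) >= 1 && length(yn) >= 1) {
      Zw <- wilcoxon_z(xn, yn)
      parts <- "both"
      Zp_sq <- Zp^2; Zw_sq <- Zw^2
      stat <- Zp_sq + Zw_sq; df <- 2L
    } else {
      parts <- "presence_only"
      Zp_sq <- Zp^2; Zw_sq <- NA_real_
      stat <- Zp_sq; df <- 1L
    }
  }
  list(Zp_sq = Zp_sq, Zw_sq = Zw_sq, statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       parts_used = parts,
       n_A = n1, n_B = n2, prop_A = p1, prop_B = p2,
       median_A = stats::median(x), median_B = stats::median(y))
}

#' Two-group differential-abundance comparison
#'
#' The package's central fit: applies the prevalence filter (a taxon must
#' be present in at least `min_prop` of either group's samples), runs
#' [two_part_test()] on each retained taxon's per-sample relative
#' abundances, and adjusts the raw p-values by Benjamini-Hochberg FDR
#' across the retained set.  Significance flags follow the raw p (the
#' Manhattan-view convention); adjusted p-values are reported alongside.
#'
#' @param table a [taxon_table()].
#' @param groupA,groupB two distinct group labels present in the table.
#' @param min_prop prevalence threshold (default 0.5).
#' @return an object of class `two_part`: a list with `results` (one row
#'   per retained taxon, sorted by raw p), the group labels, `min_prop`,
#'   and `n_filtered` (taxa removed by the prevalence filter).  Methods:
#'   `print`, `summary`, `plot` (Manhattan and delta-effect views),
#'   `coef` (named vector of test statistics).
#' @examples
#' sim <- simulate_counts(sim_config_pnali(), seed = 42)
#' fit <- two_part(sim$table, "control", "treatment")
#' head(summary(fit))
#' @export
two_part <- function(table, groupA, groupB, min_prop = 0.5) {
  stopifnot(inherits(table, "taxon_table"))
  g <- groups(table)
  for (grp in c(groupA, groupB))
    if (sum(g == grp) < 2) stop("group ", grp, " has fewer than 2 samples")
  keep <- prevalence_filter(table, groupA, groupB, min_prop)
  ra <- relative_abundance(table)
  if (length(keep) == 0) {
    warning("no taxon passes the prevalence filter")
    res <- data.frame(taxon = character(), n_A = integer(), n_B = integer(),
                      prop_A = numeric(), prop_B = numeric(),
                      median_A = numeric(), median_B = numeric(),
                      Zp_sq = numeric(), Zw_sq = numeric(),
                      statistic = numeric(), df = integer(),
                      p_raw = numeric(), p_adj = numeric(),
                      parts_used = character(),
                      sig_05 = logical(), sig_01 = logical())
  } else {
    rows <- lapply(keep, function(tx) {
      r <- two_part_test(ra[g == groupA, tx], ra[g == groupB, tx])
      data.frame(taxon = tx, n_A = r$n_A, n_B = r$n_B,
                 prop_A = r$prop_A, prop_B = r$prop_B,
                 median_A = r$median_A, median_B = r$median_B,
                 Zp_sq = r$Zp_sq, Zw_sq = r$Zw_sq,
                 statistic = r$statistic, df = r$df, p_raw = r$p,
                 parts_used = r$parts_used)
    })
    res <- do.call(rbind, rows)
    res$p_adj <- bh_fdr(res$p_raw)
    res$sig_05 <- res$p_raw < 0.05
    res$sig_01 <- res$p_raw < 0.01
    res <- res[order(res$p_raw, res$taxon), ]
    rownames(res) <- NULL
  }
  structure(list(results = res, groupA = groupA, groupB = groupB,
                 min_prop = min_prop,
                 n_filtered = ncol(table) - length(keep),
                 mean_relabund = colMeans(ra[g %in% c(groupA, groupB), ,
                                             drop = FALSE])),
            class = "two_part")
}

#' @export
print.two_part <- function(x, ...) {
  cat("Two-part differential abundance: ", x$groupA, " vs ", x$groupB,
      "\n", sep = "")
  cat(nrow(x$results), " taxa tested (", x$n_filtered,
      " removed by the ", format(100 * x$min_prop),
      "% prevalence filter)\n", sep = "")
  cat(sum(x$results$sig_05), " taxa at p < 0.05, ",
      sum(x$results$sig_01), " at p < 0.01; ",
      sum(x$results$p_adj < 0.05), " at FDR < 0.05\n", sep = "")
  invisible(x)
}

#' @export
summary.two_part <- function(object, ...) {
  object$results
}

#' @export
coef.two_part <- function(object, ...) {
  stats::setNames(object$results$statistic, object$results$taxon)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, order-aligned with the input, monotone
#' non-decreasing in raw-p rank order and capped at 1.
#'
#' @param p numeric vector of raw p-values in (0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Kruskal-Wallis screen across all groups
#'
#' Runs the tie-corrected Kruskal-Wallis test per taxon on per-sample
#' relative abundances across every group in the table, with BH-FDR over
#' taxa.  A taxon whose observations are all identical (total tie) gets
#' H = 0 and p = 1 by convention.
#'
#' @param table a [taxon_table()] with >= 2 groups, each of >= 2 samples.
#' @param taxa taxa to screen (default: all columns; the screen is
#'   independent of the two-group prevalence filter).
#' @return data.frame: taxon, H, df, p_raw, p_adj.
#' @export
kw_screen <- function(table, taxa = colnames(table)) {
  g <- groups(table)
  if (length(unique(g)) < 2) stop("need at least 2 groups")
  if (any(tabulate(factor(g)) < 2))
    stop("every group needs at least 2 samples")
  ra <- relative_abundance(table)
  rows <- lapply(taxa, function(tx) {
    kr <- kruskal_wallis(split(ra[, tx], g))
    data.frame(taxon = tx, H = kr$H, df = kr$df, p_raw = kr$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr(out$p_raw)
  out
}

#' Kruskal-Wallis test on grouped values
#'
#' Thin wrapper over the standard tie-corrected rank test with the
#' total-tie convention H = 0, p = 1.
#'
#' @param values_by_group list of >= 2 numeric vectors.
#' @return list with `H`, `df` (groups - 1), `p`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))  # H = 3.857
#' @export
kruskal_wallis <- function(values_by_group) {
  if (length(values_by_group) < 2) stop("need at least 2 groups")
  vals <- unlist(values_by_group)
  df <- length(values_by_group) - 1L
  if (length(unique(vals)) == 1)
    return(list(H = 0, df = df, p = 1))
  kt <- stats::kruskal.test(values_by_group)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
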