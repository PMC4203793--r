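#' Manhattan-view coordinates for a two-part fit
#'
#' Per-taxon -log10 raw p-values with the 0.05 / 0.01 reference lines,
#' in the order the results arrive.
#'
#' @param fit a [two_part()] object (or its `results` data.frame).
#' @return data.frame: taxon, neglog10_p, sig_05, sig_01; attribute
#'   `ref_lines` holds c(-log10(0.05), -log10(0.01)).
#' @export
manhattan_points <- function(fit) {
  res <- if (inherits(fit, "two_part")) fit$results else fit
  if (nrow(res) == 0) stop("no test results")
  if (any(res$p_raw <= 0)) stop("non-positive p-value")
  out <- data.frame(taxon = res$taxon, neglog10_p = -log10(res$p_raw),
                    sig_05 = res$sig_05, sig_01 = res$sig_01)
  attr(out, "ref_lines") <- c(p05 = -log10(0.05), p01 = -log10(0.01))
  out
}

#' Delta-abundance / delta-prevalence effect view
#'
#' For each tested taxon: the change in median relative abundance and in
#' the proportion of positive samples between the two groups (A minus B),
#' the quadrant it falls in, its significance flags, and a label flag for
#' taxa whose mean relative abundance across the two groups' samples
#' exceeds `label_min` (default 1%).  Swapping the groups negates both
#' deltas.
#'
#' @param fit a [two_part()] object.
#' @param label_min mean relative-abundance threshold for labelling
#'   (default 0.01).
#' @return data.frame: taxon, delta_median_relabund, delta_prop_positive,
#'   quadrant ("higher in A" / "higher in B" / "mixed" / "none"),
#'   sig_05, sig_01, mean_relabund_overall, labelled.
#' @export
delta_effects <- function(fit, label_min = 0.01) {
  stopifnot(inherits(fit, "two_part"))
  res <- fit$results
  missing <- setdiff(res$taxon, names(fit$mean_relabund))
  if (length(missing))
    stop("taxon absent from the fitted table: ", missing[1])
  dm <- res$median_A - res$median_B
  dp <- res$prop_A - res$prop_B
  quadrant <- ifelse(dm > 0 & dp >= 0 | dm >= 0 & dp > 0,
                     paste("higher in", fit$groupA),
              ifelse(dm < 0 & dp <= 0 | dm <= 0 & dp < 0,
                     paste("higher in", fit$groupB),
              ifelse(dm == 0 & dp == 0, "none", "mixed")))
  mr <- unname(fit$mean_relabund[res$taxon])
  data.frame(taxon = res$taxon,
             delta_median_relabund = dm,
             delta_prop_positive = dp,
             quadrant = quadrant,
             sig_05 = res$sig_05, sig_01 = res$sig_01,
             mean_relabund_overall = mr,
             labelled = mr > label_min)
}

#' Plot a two-part fit
#'
#' `type = "manhattan"`: per-taxon -log10 p with solid reference lines at
#' p = 0.05 and p = 0.01.  `type = "effects"`: change in median relative
#' abundance against change in proportion positive, significant taxa
#' filled, labels for taxa above the 1% mean-abundance rule.
#'
#' @param x a [two_part()] object.
#' @param type "manhattan" or "effects".
#' @param label_min passed to [delta_effects()].
#' @param ... further graphical parameters.
#' @return invisibly, the plotted data.frame.
#' @export
plot.two_part <- function(x, type = c("manhattan", "effects"),
                          label_min = 0.01, ...) {
  type <- match.arg(type)
  if (type == "manhattan") {
    mp <- manhattan_points(x)
    graphics::plot(seq_len(nrow(mp)), mp$neglog10_p, type = "h", lwd = 2,
                   col = ifelse(mp$sig_01, "red3",
                                ifelse(mp$sig_05, "orange2", "grey40")),
                   xlab = "taxon", ylab = expression(-log[10] ~ p),
                   main = paste(x$groupA, "vs", x$groupB), ...)
    graphics::abline(h = attr(mp, "ref_lines"), lty = 1, col = "grey60")
    invisible(mp)
  } else {
    de <- delta_effects(x, label_min = label_min)
    graphics::plot(de$delta_prop_positive, de$delta_median_relabund,
                   pch = ifelse(de$sig_05, 19, 1),
                   col = ifelse(de$sig_05, "black", "grey50"),
                   xlim = c(-1, 1),
                   xlab = paste("Δ proportion positive (",
                                x$groupA, " - ", x$groupB, ")", sep = ""),
                   ylab = paste("Δ median relative abundance"), ...)
    graphics::abline(h = 0, v = 0, col = "grey80")
    lab <- de[de$labelled, ]
    if (nrow(lab))
      graphics::text(lab$delta_prop_positive, lab$delta_median_relabund,
                     lab$taxon, pos = 3, cex = 0.7,
                     col = ifelse(lab$sig_05, "black", "grey50"))
    invisible(de)
  }
}
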