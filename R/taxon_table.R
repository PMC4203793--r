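#' Sample-by-taxon count table with group labels
#'
#' The central container of the package: a non-negative integer matrix of
#' read counts with samples in rows and taxa (taxonomy-assignment strings)
#' in columns, plus a group label per sample.  All downstream statistics
#' (two-part tests, Kruskal-Wallis screens, ordination, random-forest
#' ranking) consume this object.
#'
#' @param counts integer matrix, samples x taxa; must have row and column
#'   names unless `samples`/`taxa` are supplied.
#' @param groups character vector of group labels, one per sample; named
#'   vectors are matched to sample ids by name.
#' @param samples optional character vector of sample ids (overrides
#'   rownames).
#' @param taxa optional character vector of taxonomy strings (overrides
#'   colnames).  Taxonomy strings are canonicalized: flanking whitespace
#'   stripped and internal whitespace runs collapsed; identical strings
#'   after canonicalization are summed into one column (one OTU).
#' @return an object of class `taxon_table`: the count matrix with a
#'   `groups` attribute (named character vector, aligned to rows).
#' @examples
#' tt <- taxon_table(matrix(c(2, 1, 0, 3), 2, 2,
#'                          dimnames = list(c("s1", "s2"), c("A", "B"))),
#'                   groups = c(s1 = "ctrl", s2 = "trt"))
#' relative_abundance(tt)
#' @export
taxon_table <- function(counts, groups, samples = NULL, taxa = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(samples)) rownames(counts) <- samples
  if (!is.null(taxa)) colnames(counts) <- taxa
  if (is.null(rownames(counts))) stop("sample ids required (rownames or `samples`)")
  if (is.null(colnames(counts))) stop("taxa names required (colnames or `taxa`)")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  colnames(counts) <- canonicalize_taxonomy(colnames(counts))
  if (anyDuplicated(colnames(counts))) {
    counts <- t(rowsum(t(counts), group = colnames(counts), reorder = FALSE))
  }
  if (is.null(names(groups))) {
    if (length(groups) != nrow(counts))
      stop("`groups` must have one label per sample")
    names(groups) <- rownames(counts)
  }
  missing <- setdiff(rownames(counts), names(groups))
  if (length(missing))
    stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  groups <- as.character(groups)[match(rownames(counts), names(groups))]
  names(groups) <- rownames(counts)
  structure(counts, groups = groups, class = c("taxon_table", "matrix"))
}

#' Canonicalize taxonomy-assignment strings
#'
#' Strips flanking whitespace and collapses internal whitespace runs to a
#' single space.  Case is preserved and no rank-aware parsing is done:
#' strings differing at any rank remain distinct OTUs.
#'
#' @param x character vector of taxonomy strings.
#' @return canonicalized character vector.
#' @export
canonicalize_taxonomy <- function(x) {
  gsub("[[:space:]]+", " ", trimws(x))
}

#' @export
print.taxon_table <- function(x, ...) {
  g <- groups(x)
  cat("taxon_table: ", nrow(x), " samples x ", ncol(x), " taxa\n", sep = "")
  cat("read depth: ", paste(range(rowSums(x)), collapse = "-"),
      " (median ", stats::median(rowSums(x)), ")\n", sep = "")
  tab <- table(g)
  cat("groups: ", paste(names(tab), " (n=", tab, ")", sep = "", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Group labels of a taxon table
#' @param table a `taxon_table`.
#' @return named character vector of group labels, aligned to samples.
#' @export
groups <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  attr(table, "groups")
}

#' Per-sample relative abundances
#'
#' Divides each sample's counts by its total read count.  Relative abundance
#' is computed per sample, never from pooled counts, so group-level
#' summaries are summaries of per-animal values.
#'
#' @param table a `taxon_table`.
#' @return numeric matrix of proportions, same dimensions; rows sum to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  tot <- rowSums(table)
  if (any(tot == 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(table)[tot == 0], collapse = ", "))
  ra <- unclass(table) / tot
  attr(ra, "groups") <- NULL
  ra
}

#' Per-taxon prevalence within a group
#'
#' Fraction of a group's samples in which each taxon has a non-zero count.
#'
#' @param table a `taxon_table`.
#' @param group a group label present in `groups(table)`.
#' @return named numeric vector in \[0, 1\], one entry per taxon.
#' @export
prevalence <- function(table, group) {
  g <- groups(table)
  if (!group %in% g) stop("unknown group: ", group)
  sub <- unclass(table)[g == group, , drop = FALSE]
  colMeans(sub > 0)
}

#' Prevalence filter for a two-group comparison
#'
#' Retains a taxon iff it is present (non-zero) in at least `min_prop` of
#' the samples of either group; the comparison is inclusive, so a taxon in
#' exactly half of one group's samples is kept at the default 0.5.
#'
#' @param table a `taxon_table`.
#' @param groupA,groupB two distinct group labels.
#' @param min_prop minimum within-group prevalence (default 0.5).
#' @return character vector of retained taxa, in table column order.
#' @export
prevalence_filter <- function(table, groupA, groupB, min_prop = 0.5) {
  if (identical(groupA, groupB)) stop("groupA and groupB must differ")
  pa <- prevalence(table, groupA)
  pb <- prevalence(table, groupB)
  colnames(table)[pa >= min_prop | pb >= min_prop]
}

#' Per-group, per-taxon abundance summaries
#'
#' For every (group, taxon) pair: the median and mean of the per-sample
#' relative abundances, the proportion of samples positive, quartiles, and
#' 1.5 x IQR whisker bounds (clamped to the observed range) for box-plot
#' parity.
#'
#' @param table a `taxon_table`.
#' @return data.frame with columns group, taxon, n, median, mean,
#'   prop_positive, q25, q75, whisker_lo, whisker_hi.
#' @export
group_summary <- function(table) {
  ra <- relative_abundance(table)
  g <- groups(table)
  out <- do.call(rbind, lapply(unique(g), function(grp) {
    sub <- ra[g == grp, , drop = FALSE]
    q <- apply(sub, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
               names = FALSE)
    iqr <- q[3, ] - q[1, ]
    lo <- q[1, ] - 1.5 * iqr
    hi <- q[3, ] + 1.5 * iqr
    data.frame(group = grp, taxon = colnames(sub), n = nrow(sub),
               median = q[2, ], mean = colMeans(sub),
               prop_positive = colMeans(sub > 0),
               q25 = q[1, ], q75 = q[3, ],
               whisker_lo = pmax(lo, apply(sub, 2, min)),
               whisker_hi = pmin(hi, apply(sub, 2, max)),
               row.names = NULL)
  }))
  out
}

#' Read a count table and metadata from TSV files
#'
#' @param counts_tsv path to a TSV with sample ids in the first column and
#'   taxonomy strings as the remaining column headers.
#' @param metadata_tsv path to a two-column TSV (sample_id, group).
#' @return a `taxon_table`.
#' @export
read_taxon_table <- function(counts_tsv, metadata_tsv) {
  counts <- utils::read.delim(counts_tsv, check.names = FALSE,
                              stringsAsFactors = FALSE)
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts[[1]]
  meta <- utils::read.delim(metadata_tsv, stringsAsFactors = FALSE)
  taxon_table(m, groups = stats::setNames(meta[[2]], meta[[1]]))
}

#' Write a count table and metadata to TSV files
#'
#' @param table a `taxon_table`.
#' @param counts_tsv,metadata_tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_taxon_table <- function(table, counts_tsv, metadata_tsv) {
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, counts_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = rownames(table), group = unname(groups(table)))
  utils::write.table(meta, metadata_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_tsv, metadata_tsv))
}
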