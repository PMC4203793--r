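#' Read quality-control parameters
#'
#' Trimming and filtering rules applied to each read: terminal bases are
#' removed over a moving window of `window` nucleotides until the window's
#' average quality meets or exceeds `min_mean_quality`; trimmed reads with
#' more than `max_ambiguities` ambiguous bases, or shorter than
#' `min_length` nt, are discarded.
#'
#' @param window window width in nt (default 5).
#' @param min_mean_quality minimum average Phred quality (default 20).
#' @param max_ambiguities maximum number of ambiguous bases (default 1).
#' @param min_length minimum read length in nt (default 200; a read of
#'   exactly `min_length` is kept).
#' @param ends which read ends to trim: "both" (default), "5p" or "3p".
#' @return an object of class `qc_params`.
#' @export
qc_params <- function(window = 5, min_mean_quality = 20,
                      max_ambiguities = 1, min_length = 200,
                      ends = c("both", "5p", "3p")) {
  stopifnot(window >= 1, min_length >= 1, max_ambiguities >= 0)
  structure(list(window = window, min_mean_quality = min_mean_quality,
                 max_ambiguities = max_ambiguities, min_length = min_length,
                 ends = match.arg(ends)),
            class = "qc_params")
}

# left-trim on a quality vector: index of first retained base (n+1 = empty).
# The terminal window is the first `window` remaining bases, or the whole
# remainder when fewer than `window` bases are left.
trim_start <- function(quals, window, min_mean) {
  n <- length(quals)
  i <- 1L
  while (i <= n) {
    w <- quals[i:min(i + window - 1L, n)]
    if (mean(w) >= min_mean) return(i)
    i <- i + 1L
  }
  n + 1L
}

#' Trim a read by terminal window quality
#'
#' At each end independently (5' pass, then 3' pass on the remainder), the
#' terminal window of `window` bases is inspected; while its mean quality
#' is below `min_mean_quality` the terminal base is removed and the window
#' re-inspected.  When fewer than `window` bases remain, the whole
#' remainder serves as the window.  Degenerate inputs yield an empty read
#' rather than an error; downstream filtering discards it.  The operation
#' is idempotent.
#'
#' @param bases nucleotide string.
#' @param quals integer vector of per-base Phred scores, same length.
#' @param params a [qc_params()].
#' @return list with `bases` (possibly empty string) and `quals`.
#' @examples
#' trim_read(strrep("A", 8), c(10, 10, 30, 30, 30, 30, 30, 30))
#' @export
trim_read <- function(bases, quals, params = qc_params()) {
  stopifnot(nchar(bases) == length(quals))
  from <- 1L
  to <- length(quals)
  if (params$ends %in% c("both", "5p"))
    from <- trim_start(quals, params$window, params$min_mean_quality)
  if (from <= to && params$ends %in% c("both", "3p")) {
    rev_keep <- trim_start(rev(quals[from:to]), params$window,
                           params$min_mean_quality)
    to <- to - (rev_keep - 1L)
  }
  if (from > to)
    return(list(bases = "", quals = integer(0)))
  list(bases = substr(bases, from, to), quals = quals[from:to])
}

#' Keep/discard decision for a trimmed read
#'
#' A read is discarded when it carries more than `max_ambiguities`
#' ambiguous bases or is shorter than `min_length` nt; the length
#' comparison is strict, so a read of exactly `min_length` passes.
#' Ambiguous bases are 'N' plus every IUPAC partial-ambiguity code
#' (case-insensitive).
#'
#' @param bases nucleotide string (post-trim).
#' @param params a [qc_params()].
#' @return one of "pass", "ambiguity", "length"; ambiguity is checked
#'   first.
#' @export
filter_read <- function(bases, params = qc_params()) {
  n_amb <- nchar(bases) - nchar(gsub("[^ACGTacgt]", "", bases))
  if (n_amb > params$max_ambiguities) return("ambiguity")
  if (nchar(bases) < params$min_length) return("length")
  "pass"
}

#' Build a taxon count table from per-read assignments
#'
#' Groups reads by identical (canonicalized) taxonomy-assignment string --
#' the OTU definition used throughout -- and counts them per sample.
#' Identity is exact: strings differing at any rank are distinct OTUs.
#'
#' @param sample_ids character vector, one per read.
#' @param taxonomies character vector of taxonomy strings, one per read.
#' @param groups named character vector mapping every sample id to a group
#'   label (the metadata table).
#' @return a [taxon_table()]; samples with zero surviving reads still get
#'   a row only if they appear in `sample_ids`.
#' @export
build_taxon_table <- function(sample_ids, taxonomies, groups) {
  if (length(sample_ids) == 0) stop("no reads to tabulate")
  stopifnot(length(sample_ids) == length(taxonomies))
  unknown <- setdiff(unique(sample_ids), names(groups))
  if (length(unknown))
    stop("sample id(s) not in metadata: ", paste(unknown, collapse = ", "))
  taxonomies <- canonicalize_taxonomy(taxonomies)
  tab <- table(factor(sample_ids, levels = unique(sample_ids)),
               factor(taxonomies, levels = unique(taxonomies)))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  taxon_table(m, groups = groups[rownames(m)])
}

#' Run quality control over FASTQ files and tabulate taxa
#'
#' Applies [trim_read()] and [filter_read()] to every read of every sample,
#' joins surviving reads to their taxonomy assignments, and builds the
#' sample-by-taxon count table.  Qualities are decoded as Phred+33.
#'
#' @param fastq_paths named character vector of FASTQ paths; names are
#'   sample ids.
#' @param taxonomy_tsv path to the two-column TSV (read_id, taxonomy).
#' @param groups named character vector: sample id -> group label.
#' @param params a [qc_params()].
#' @return list with `table` (a [taxon_table()]) and `report` (per-sample
#'   data.frame: input reads, kept reads, discards by reason).
#' @export
run_qc <- function(fastq_paths, taxonomy_tsv, groups,
                   params = qc_params()) {
  stopifnot(!is.null(names(fastq_paths)))
  taxmap <- utils::read.delim(taxonomy_tsv, stringsAsFactors = FALSE)
  tax_of <- stats::setNames(taxmap[[2]], taxmap[[1]])
  kept_ids <- list(); kept_samples <- list()
  report <- data.frame(sample_id = names(fastq_paths), input = 0L,
                       kept = 0L, discard_ambiguity = 0L,
                       discard_length = 0L)
  for (i in seq_along(fastq_paths)) {
    sid <- names(fastq_paths)[i]
    reads <- suppressWarnings(  # Biostrings notes empty metadata columns
      Biostrings::readQualityScaledDNAStringSet(fastq_paths[i]))
    quals <- as(Biostrings::quality(reads), "IntegerList")
    bases <- as.character(reads)
    ids <- sub("\\s.*$", "", names(reads))
    decisions <- vapply(seq_along(reads), function(j) {
      tr <- trim_read(bases[j], quals[[j]], params)
      filter_read(tr$bases, params)
    }, character(1))
    report$input[i] <- length(reads)
    report$kept[i] <- sum(decisions == "pass")
    report$discard_ambiguity[i] <- sum(decisions == "ambiguity")
    report$discard_length[i] <- sum(decisions == "length")
    kept_ids[[i]] <- ids[decisions == "pass"]
    kept_samples[[i]] <- rep(sid, report$kept[i])
  }
  ids <- unlist(kept_ids)
  missing <- ids[!ids %in% names(tax_of)]
  if (length(missing))
    stop("read id(s) missing from taxonomy table, e.g. ", missing[1])
  list(table = build_taxon_table(unlist(kept_samples), tax_of[ids], groups),
       report = report)
}
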