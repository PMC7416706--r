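# Single-sample descriptive analyses: V/J segment usage, CDR3 spectratype,
# clonotype frequency distribution, top clones.

#' V or J segment usage profile
#'
#' Fraction of the repertoire assigned to each gene segment, either read
#' weighted (sum of clone counts per segment / total reads — what frequency
#' bar plots show) or clonotype weighted (number of clones per segment /
#' number of clones, a richness-style view).
#'
#' @param rep a `repertoire` (non-empty).
#' @param segment_class `"V"` or `"J"`.
#' @param weighting `"read"` (default) or `"clonotype"`.
#' @return object of class `usage_profile`: list with `segment_class`,
#'   `weighting` and `weights`, a named fraction vector sorted descending
#'   (label tie-break), summing to 1.
#' @export
segment_usage <- function(rep, segment_class = c("V", "J"),
                          weighting = c("read", "clonotype")) {
  stopifnot(inherits(rep, "repertoire"))
  segment_class <- match.arg(segment_class)
  weighting <- match.arg(weighting)
  if (nrow(rep$clonotypes) == 0L) stop("empty repertoire", call. = FALSE)
  seg <- if (segment_class == "V") rep$clonotypes$v_gene else
    rep$clonotypes$j_gene
  w <- if (weighting == "read") rep$clonotypes$count else
    base::rep(1, nrow(rep$clonotypes))
  tot <- tapply(w, seg, sum) / sum(w)
  tot <- tot[order(-tot, names(tot), method = "radix")]
  structure(list(segment_class = segment_class, weighting = weighting,
                 weights = stats::setNames(as.numeric(tot), names(tot)),
                 sample_id = rep$sample_id),
            class = "usage_profile")
}

#' @export
print.usage_profile <- function(x, ...) {
  cat(sprintf("<usage_profile> %s, %s segments, %s-weighted:\n",
              x$sample_id, x$segment_class, x$weighting))
  print(round(x$weights, 4))
  invisible(x)
}

#' CDR3 length spectratype
#'
#' Distribution of repertoire mass over CDR3 lengths, in nucleotides
#' (default — repertoire peaks are conventionally quoted in bp) or amino
#' acids, optionally stratified by J segment within each length. The peak
#' length is the argmax of the marginal distribution, smallest length on
#' ties.
#'
#' @param rep a `repertoire` (non-empty).
#' @param unit `"nt"` or `"aa"`.
#' @param stratify_by_j split each length by J gene.
#' @param weighting `"read"` or `"clonotype"`.
#' @return object of class `spectratype`: list with `unit`, `weighting`,
#'   `table` (long data.frame `length`, optional `j_gene`, `fraction`;
#'   fractions over all cells sum to 1), `marginal` (named length ->
#'   fraction vector) and `peak_length`.
#' @export
spectratype <- function(rep, unit = c("nt", "aa"), stratify_by_j = FALSE,
                        weighting = c("read", "clonotype")) {
  stopifnot(inherits(rep, "repertoire"))
  unit <- match.arg(unit)
  weighting <- match.arg(weighting)
  if (nrow(rep$clonotypes) == 0L) stop("empty repertoire", call. = FALSE)
  len <- nchar(if (unit == "nt") rep$clonotypes$cdr3_nt else
    rep$clonotypes$cdr3_aa)
  w <- if (weighting == "read") rep$clonotypes$count else
    base::rep(1, nrow(rep$clonotypes))
  w <- w / sum(w)
  marg <- tapply(w, len, sum)
  marg <- marg[order(as.integer(names(marg)))]
  marginal <- stats::setNames(as.numeric(marg), names(marg))
  peak <- as.integer(names(marginal)[which.max(marginal)])
  if (stratify_by_j) {
    cells <- stats::aggregate(
      list(fraction = w),
      by = list(length = len, j_gene = rep$clonotypes$j_gene), FUN = sum)
    cells <- cells[order(cells$length, cells$j_gene, method = "radix"), ]
  } else {
    cells <- data.frame(length = as.integer(names(marginal)),
                        fraction = as.numeric(marginal))
  }
  rownames(cells) <- NULL
  structure(list(unit = unit, weighting = weighting, table = cells,
                 marginal = marginal, peak_length = peak,
                 sample_id = rep$sample_id),
            class = "spectratype")
}

#' @export
print.spectratype <- function(x, ...) {
  cat(sprintf("<spectratype> %s, unit %s, %s-weighted, peak %d %s\n",
              x$sample_id, x$unit, x$weighting, x$peak_length,
              if (x$unit == "nt") "bp" else "aa"))
  invisible(x)
}

#' Ranked clonotype frequency distribution
#'
#' Clones sorted by descending frequency with cumulative sum; summary
#' statistics `max_freq` and `D50` (the minimal number of top clones whose
#' cumulative frequency reaches 0.5) attached as attributes.
#'
#' @param rep a `repertoire` (non-empty).
#' @return data.frame with columns `rank`, `freq`, `cumulative_freq` and
#'   attributes `max_freq`, `d50`.
#' @export
clonotype_frequency_distribution <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  if (nrow(rep$clonotypes) == 0L) stop("empty repertoire", call. = FALSE)
  freq <- rep$clonotypes$freq  # repertoire order is already descending count
  cum <- cumsum(freq)
  out <- data.frame(rank = seq_along(freq), freq = freq,
                    cumulative_freq = cum)
  attr(out, "max_freq") <- freq[1L]
  attr(out, "d50") <- which(cum >= 0.5)[1L]
  out
}

#' Most abundant clonotypes
#'
#' First `n` clonotypes in the repertoire's deterministic order (descending
#' count, lexicographic key tie-break, so a boundary tie resolves to the
#' lexicographically smaller key).
#'
#' @param rep a `repertoire`.
#' @param n number of clones requested (`>= 1`); if the repertoire is
#'   smaller, all clones are returned with a warning.
#' @return data.frame of clonotype rows.
#' @export
top_clonotypes <- function(rep, n) {
  stopifnot(inherits(rep, "repertoire"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  if (n > nrow(rep$clonotypes)) {
    warning(sprintf("requested %d clones but repertoire has %d", as.integer(n),
                    nrow(rep$clonotypes)))
  }
  utils::head(rep$clonotypes, as.integer(n))
}
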