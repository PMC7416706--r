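# Pairwise analyses: shared/private clonotype frequencies with coefficient
# of determination, and convergent recombination analysis.

#' Overlap two repertoires
#'
#' Exact-match join on the clonotype key: shared clones get paired
#' frequencies, private clones are listed per side. The coefficient of
#' determination is the squared Pearson correlation of log10 frequencies
#' over shared clones (repertoire scatter plots are log-log and a raw-scale
#' fit is dominated by the largest clone; `log_freq = FALSE` switches to the
#' raw scale). R-squared is reported as an explicit undefined marker — never
#' 0 — when fewer than 3 clones are shared or either frequency vector is
#' constant.
#'
#' @param rep_a,rep_b `repertoire` objects (re-keyed to `key_mode`
#'   automatically).
#' @param key_mode clonotype identity used for matching.
#' @param log_freq correlate log10 frequencies (default) or raw frequencies.
#' @return object of class `overlap_result`: list with `key_mode`, `shared`
#'   (data.frame key/freq_a/freq_b), `only_a`, `only_b` (key/freq),
#'   `n_shared`, `r_squared` (`NA` when undefined), `r_squared_reason`,
#'   `sample_a`, `sample_b`.
#' @export
overlap_pair <- function(rep_a, rep_b, key_mode = "nt+vj", log_freq = TRUE) {
  stopifnot(inherits(rep_a, "repertoire"), inherits(rep_b, "repertoire"))
  key_mode <- match.arg(key_mode, KEY_MODES)
  if (identical(rep_a$sample_id, rep_b$sample_id)) {
    warning("comparing a sample with itself (identical sample ids)")
  }
  rep_a <- rekey_repertoire(rep_a, key_mode)
  rep_b <- rekey_repertoire(rep_b, key_mode)
  ka <- clonotype_key(rep_a$clonotypes, key_mode)
  kb <- clonotype_key(rep_b$clonotypes, key_mode)
  ib <- match(ka, kb)
  shared_idx <- which(!is.na(ib))
  shared <- data.frame(key = ka[shared_idx],
                       freq_a = rep_a$clonotypes$freq[shared_idx],
                       freq_b = rep_b$clonotypes$freq[ib[shared_idx]],
                       stringsAsFactors = FALSE)
  shared <- shared[order(shared$key, method = "radix"), , drop = FALSE]
  rownames(shared) <- NULL
  only_a <- data.frame(key = ka[is.na(ib)],
                       freq = rep_a$clonotypes$freq[is.na(ib)],
                       stringsAsFactors = FALSE)
  in_a <- kb %in% ka
  only_b <- data.frame(key = kb[!in_a],
                       freq = rep_b$clonotypes$freq[!in_a],
                       stringsAsFactors = FALSE)
  r2 <- NA_real_
  reason <- NULL
  if (nrow(shared) < 3L) {
    reason <- sprintf("fewer than 3 shared clonotypes (n_shared = %d)",
                      nrow(shared))
  } else {
    x <- shared$freq_a
    y <- shared$freq_b
    if (log_freq) {
      x <- log10(x)
      y <- log10(y)
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      reason <- "constant frequency vector among shared clonotypes"
    } else {
      r2 <- stats::cor(x, y)^2
    }
  }
  structure(list(key_mode = key_mode, shared = shared, only_a = only_a,
                 only_b = only_b, n_shared = nrow(shared), r_squared = r2,
                 r_squared_reason = reason, log_freq = log_freq,
                 sample_a = rep_a$sample_id, sample_b = rep_b$sample_id),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %s vs %s (key %s): %d shared, %d/%d private",
              x$sample_a, x$sample_b, x$key_mode, x$n_shared,
              nrow(x$only_a), nrow(x$only_b)))
  if (is.na(x$r_squared)) {
    cat(sprintf("; R^2 undefined (%s)\n", x$r_squared_reason))
  } else {
    cat(sprintf("; R^2 = %.4g (%s scale)\n", x$r_squared,
                if (x$log_freq) "log10" else "raw"))
  }
  invisible(x)
}

#' Ranked private clonotype frequencies of an overlap
#'
#' @param result an `overlap_result`.
#' @return list with `a` and `b` (ranked data.frames of private clones,
#'   descending frequency) and `summary` containing the maximum private
#'   frequency per sample (`NA` when a side has no private clone).
#' @export
unshared_distribution <- function(result) {
  stopifnot(inherits(result, "overlap_result"))
  rank_tab <- function(df) {
    df <- df[order(-df$freq, df$key, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    if (nrow(df)) df$rank <- seq_len(nrow(df)) else df$rank <- integer()
    df[, c("rank", "key", "freq")]
  }
  a <- rank_tab(result$only_a)
  b <- rank_tab(result$only_b)
  list(a = a, b = b,
       summary = list(
         max_private_freq_a = if (nrow(a)) a$freq[1L] else NA_real_,
         max_private_freq_b = if (nrow(b)) b$freq[1L] else NA_real_))
}

#' Convergent recombination analysis of a repertoire pair
#'
#' For each CDR3 amino-acid clonotype in scope, counts the distinct
#' nucleotide sequences encoding it in each sample (its convergent
#' recombination degeneracy) and pools the distinct variants of both
#' samples. `shared_aa` (default) restricts to amino-acid clonotypes present
#' in both samples — the degeneracy of the shared clonotypes; `all_aa` uses
#' the union.
#'
#' @param rep_a,rep_b `repertoire`s keyed at nucleotide level (`nt` or
#'   `nt+vj`); amino-acid keyed input is rejected since the nucleotide
#'   variants are already collapsed there.
#' @param scope `"shared_aa"` or `"all_aa"`.
#' @return object of class `convergence_result`: `per_aa` (data.frame
#'   cdr3_aa / nt_variant_count_a / nt_variant_count_b / nt_variant_count
#'   pooled), `degree_histogram` (named table: pooled variant count ->
#'   number of aa clonotypes), per-sample histograms, and `scope`.
#' @export
convergence_pair <- function(rep_a, rep_b, scope = c("shared_aa", "all_aa")) {
  stopifnot(inherits(rep_a, "repertoire"), inherits(rep_b, "repertoire"))
  scope <- match.arg(scope)
  if (rep_a$key_mode %in% c("aa", "aa+vj") ||
      rep_b$key_mode %in% c("aa", "aa+vj")) {
    stop("convergence analysis needs nucleotide-level repertoires; ",
         "supply nt or nt+vj keyed tables", call. = FALSE)
  }
  aa_a <- rep_a$clonotypes$cdr3_aa
  aa_b <- rep_b$clonotypes$cdr3_aa
  in_scope <- if (scope == "shared_aa") {
    intersect(unique(aa_a), unique(aa_b))
  } else {
    union(unique(aa_a), unique(aa_b))
  }
  in_scope <- sort(in_scope, method = "radix")
  count_variants <- function(aa, nt) {
    v <- tapply(nt, aa, function(s) length(unique(s)))
    n <- stats::setNames(as.integer(v[in_scope]), in_scope)
    n[is.na(n)] <- 0L
    n
  }
  na <- count_variants(aa_a, rep_a$clonotypes$cdr3_nt)
  nb <- count_variants(aa_b, rep_b$clonotypes$cdr3_nt)
  pooled <- vapply(in_scope, function(aa) {
    length(unique(c(rep_a$clonotypes$cdr3_nt[aa_a == aa],
                    rep_b$clonotypes$cdr3_nt[aa_b == aa])))
  }, integer(1L))
  per_aa <- data.frame(cdr3_aa = in_scope, nt_variant_count_a = na,
                       nt_variant_count_b = nb, nt_variant_count = pooled,
                       stringsAsFactors = FALSE)
  rownames(per_aa) <- NULL
  hist_of <- function(x) {
    t <- table(x[x > 0 | scope == "all_aa"])
    stats::setNames(as.integer(t), names(t))
  }
  structure(list(scope = scope, per_aa = per_aa,
                 degree_histogram = hist_of(pooled),
                 degree_histogram_a = hist_of(na),
                 degree_histogram_b = hist_of(nb),
                 sample_a = rep_a$sample_id, sample_b = rep_b$sample_id),
            class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf("<convergence_result> %s vs %s (%s): %d aa clonotypes\n",
              x$sample_a, x$sample_b, x$scope, nrow(x$per_aa)))
  cat("pooled degeneracy histogram:\n")
  print(x$degree_histogram)
  invisible(x)
}
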