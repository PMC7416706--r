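# Group-level analyses: clonal space homeostasis with chi-square
# comparison, clonotype tracking across ordered samples, similarity
# matrices with hierarchical clustering, diversity indices with
# rarefaction, and unpaired Wilcoxon (Mann-Whitney) group comparison.

#' Default clonal space homeostasis bin edges
#'
#' Upper edges of the half-open frequency bins
#' (0,1e-5], (1e-5,1e-4], ..., (1e-1,1], labelled rare, small, medium,
#' large, expanded, hyperexpanded — the common repertoire-analysis
#' convention.
#' @export
default_homeostasis_edges <- function() {
  stats::setNames(c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1),
                  c("rare", "small", "medium", "large", "expanded",
                    "hyperexpanded"))
}

#' Clonal space homeostasis profile
#'
#' Partition of total read mass by clone-frequency class: each clone is
#' assigned to the bin with `lower < freq <= upper` and the bin accumulates
#' the clone's frequency mass and read count.
#'
#' @param rep a `repertoire`.
#' @param bin_edges strictly ascending upper bin edges in (0, 1], last
#'   edge 1; names, when present, label the bins.
#' @return object of class `homeostasis_profile`: `bin_edges`, `labels`,
#'   `mass_per_bin` (sums to 1), `reads_per_bin` (sums to `total_reads`),
#'   `clones_per_bin`, `total_reads`, `sample_id`.
#' @export
clonal_space_homeostasis <- function(rep,
                                     bin_edges = default_homeostasis_edges()) {
  stopifnot(inherits(rep, "repertoire"))
  edges <- as.numeric(bin_edges)
  if (any(diff(edges) <= 0) || any(edges <= 0) || edges[length(edges)] != 1) {
    stop("bin edges must be strictly ascending in (0, 1] with final edge 1",
         call. = FALSE)
  }
  labels <- names(bin_edges) %||%
    paste0("(", format(c(0, edges[-length(edges)])), ",", format(edges), "]")
  freq <- rep$clonotypes$freq
  bin <- findInterval(freq, edges, left.open = TRUE) + 1L
  if (any(bin > length(edges))) {
    stop("internal consistency error: clone frequency above final bin edge",
         call. = FALSE)
  }
  sum_by_bin <- function(x) {
    v <- vapply(seq_along(edges), function(b) sum(x[bin == b]), numeric(1L))
    stats::setNames(v, labels)
  }
  structure(list(bin_edges = stats::setNames(edges, labels), labels = labels,
                 mass_per_bin = sum_by_bin(freq),
                 reads_per_bin = sum_by_bin(rep$clonotypes$count),
                 clones_per_bin = sum_by_bin(base::rep(1, length(freq))),
                 total_reads = rep$total_reads, sample_id = rep$sample_id),
            class = "homeostasis_profile")
}

#' @export
print.homeostasis_profile <- function(x, ...) {
  cat(sprintf("<homeostasis_profile> %s (%s reads)\n", x$sample_id,
              format(x$total_reads, big.mark = ",")))
  print(round(x$mass_per_bin, 4))
  invisible(x)
}

#' Chi-square comparison of two homeostasis profiles
#'
#' Pearson chi-square (no continuity correction) on the 2 x k contingency
#' table of reads per bin. Read counts — not clone counts — are compared
#' because read mass is what the homeostasis plot shows; pass
#' `use = "clones"` to switch. Bins empty in both profiles are dropped with
#' the degrees of freedom reduced accordingly.
#'
#' @param profile_a,profile_b `homeostasis_profile`s with identical bin
#'   edges.
#' @param use `"reads"` (default) or `"clones"`.
#' @return list with `chi2`, `df`, `p`, `table` (the 2 x k table used).
#' @export
compare_homeostasis <- function(profile_a, profile_b,
                                use = c("reads", "clones")) {
  stopifnot(inherits(profile_a, "homeostasis_profile"),
            inherits(profile_b, "homeostasis_profile"))
  use <- match.arg(use)
  if (!isTRUE(all.equal(unname(profile_a$bin_edges),
                        unname(profile_b$bin_edges)))) {
    stop("profiles have different bin edges", call. = FALSE)
  }
  field <- if (use == "reads") "reads_per_bin" else "clones_per_bin"
  tab <- rbind(a = profile_a[[field]], b = profile_b[[field]])
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) {
    stop("chi-square test undefined with fewer than 2 non-empty bins",
         call. = FALSE)
  }
  res <- pearson_chi2(tab)
  c(res, list(table = tab, use = use))
}

# Pearson chi-square test of independence on an r x c count table.
pearson_chi2 <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Track clonotype frequencies across ordered samples
#'
#' Builds the frequency matrix of a tracked clone set over an ordered
#' sample list (longitudinal timepoints, tissues, ...). The tracked set is
#' either the `n` clones with the largest maximum frequency across all
#' samples (`top_n_overall`) or the `n` most frequent clones of the
#' `anchor` sample (`top_n_from_sample`). Absence is an explicit 0.
#'
#' @param reps ordered list of `repertoire`s (>= 2); re-keyed to a common
#'   mode.
#' @param select selection rule.
#' @param n number of clones to track.
#' @param anchor `sample_id` of the anchor; required for
#'   `top_n_from_sample`.
#' @param key_mode clonotype identity for matching across samples.
#' @return object of class `tracking_matrix`: numeric matrix (tracked keys
#'   x sample ids, entries in `[0,1]`), rows ordered by descending
#'   selection statistic; attributes `selection_rule` and `selection_stat`.
#' @export
clonotype_tracking <- function(reps,
                               select = c("top_n_overall",
                                          "top_n_from_sample"),
                               n = 10L, anchor = NULL, key_mode = "nt+vj") {
  select <- match.arg(select)
  if (length(reps) < 2L) stop("need at least 2 samples", call. = FALSE)
  reps <- lapply(reps, rekey_repertoire, key_mode = key_mode)
  ids <- vapply(reps, function(r) r$sample_id, character(1L))
  if (select == "top_n_from_sample") {
    if (is.null(anchor) || !(anchor %in% ids)) {
      stop("anchor sample_id required and must be among the samples",
           call. = FALSE)
    }
  }
  keys <- lapply(reps, function(r) clonotype_key(r$clonotypes, key_mode))
  all_keys <- sort(unique(unlist(keys)), method = "radix")
  mat <- matrix(0, nrow = length(all_keys), ncol = length(reps),
                dimnames = list(all_keys, ids))
  for (i in seq_along(reps)) {
    mat[keys[[i]], i] <- reps[[i]]$clonotypes$freq
  }
  stat <- if (select == "top_n_overall") {
    apply(mat, 1L, max)
  } else {
    mat[, match(anchor, ids)]
  }
  ord <- order(-stat, all_keys, method = "radix")
  take <- utils::head(ord, as.integer(n))
  out <- mat[take, , drop = FALSE]
  structure(out, class = c("tracking_matrix", class(out)),
            selection_rule = list(select = select, n = as.integer(n),
                                  anchor = anchor, key_mode = key_mode),
            selection_stat = stat[take])
}

# ---- similarity ---------------------------------------------------------

SIMILARITY_INDICES <- c("jaccard", "overlap_coefficient", "morisita_horn",
                        "bhattacharyya")

# pairwise similarity between two frequency vectors over a common key union
similarity_value <- function(index, p, q) {
  pa <- p > 0
  qa <- q > 0
  switch(index,
         jaccard = sum(pa & qa) / sum(pa | qa),
         overlap_coefficient = sum(pa & qa) / min(sum(pa), sum(qa)),
         morisita_horn = 2 * sum(p * q) / (sum(p^2) + sum(q^2)),
         bhattacharyya = sum(sqrt(p * q)),
         stop(sprintf("unknown similarity index '%s'; options: %s", index,
                      paste(SIMILARITY_INDICES, collapse = ", ")),
              call. = FALSE))
}

#' Pairwise repertoire similarity matrix
#'
#' Symmetric sample-by-sample matrix of one of: `jaccard`
#' (|A∩B| / |A∪B| on clone sets), `overlap_coefficient`
#' (|A∩B| / min(|A|,|B|)), `morisita_horn`
#' (2 Σ p_i q_i / (Σ p_i² + Σ q_i²)) or `bhattacharyya` (Σ √(p_i q_i)),
#' computed over the union key set with absent clones at frequency 0.
#'
#' @param reps list of >= 2 `repertoire`s.
#' @param index_name similarity index.
#' @param key_mode common clonotype identity.
#' @return object of class `similarity_matrix`: list with `index_name` and
#'   `values` (symmetric matrix in `[0,1]` with unit diagonal).
#' @export
similarity_matrix <- function(reps, index_name = "morisita_horn",
                              key_mode = "nt+vj") {
  if (length(reps) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (!index_name %in% SIMILARITY_INDICES) {
    stop(sprintf("unknown similarity index '%s'; options: %s", index_name,
                 paste(SIMILARITY_INDICES, collapse = ", ")), call. = FALSE)
  }
  reps <- lapply(reps, rekey_repertoire, key_mode = key_mode)
  ids <- vapply(reps, function(r) r$sample_id, character(1L))
  keys <- lapply(reps, function(r) clonotype_key(r$clonotypes, key_mode))
  all_keys <- sort(unique(unlist(keys)), method = "radix")
  fmat <- matrix(0, nrow = length(all_keys), ncol = length(reps),
                 dimnames = list(all_keys, ids))
  for (i in seq_along(reps)) fmat[keys[[i]], i] <- reps[[i]]$clonotypes$freq
  m <- diag(1, length(reps))
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(length(reps) - 1L)) {
    for (j in seq(i + 1L, length(reps))) {
      m[i, j] <- m[j, i] <- similarity_value(index_name, fmat[, i], fmat[, j])
    }
  }
  structure(list(index_name = index_name, key_mode = key_mode, values = m),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %s (key %s)\n", x$index_name, x$key_mode))
  print(round(x$values, 4))
  invisible(x)
}

#' Hierarchically cluster samples from a similarity matrix
#'
#' Agglomerative clustering on the distance `1 - similarity`, deterministic
#' given the matrix (stats::hclust merge order; sample order fixed by the
#' matrix).
#'
#' @param matrix a `similarity_matrix`.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an `hclust` tree; serialise with [as_newick()].
#' @export
cluster_samples <- function(matrix, linkage = c("average", "complete",
                                                "single")) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  linkage <- match.arg(linkage)
  if (any(!is.finite(matrix$values))) {
    stop("similarity matrix contains non-finite entries", call. = FALSE)
  }
  stats::hclust(stats::as.dist(1 - matrix$values), method = linkage)
}

#' Serialise an hclust tree as a Newick string
#'
#' @param hc an `hclust` as returned by [cluster_samples()].
#' @return single Newick string with branch lengths from merge heights.
#' @export
as_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

# ---- diversity ----------------------------------------------------------

DIVERSITY_INDICES <- c("shannon", "normalized_shannon", "inverse_simpson",
                       "gini_simpson", "clonality", "chao1", "d50")

# diversity on a clone count/frequency vector; counts needed for chao1/d50
diversity_value <- function(index, counts) {
  p <- counts / sum(counts)
  s <- length(p)
  H <- -sum(p * log(p))
  switch(index,
         shannon = H,
         normalized_shannon = if (s == 1L) 0 else H / log(s),
         inverse_simpson = 1 / sum(p^2),
         gini_simpson = 1 - sum(p^2),
         clonality = if (s == 1L) 1 else 1 - H / log(s),
         chao1 = {
           f1 <- sum(counts == 1)
           f2 <- sum(counts == 2)
           if (f2 > 0) s + f1^2 / (2 * f2)
           else s + f1 * (f1 - 1) / (2 * (f2 + 1))
         },
         d50 = {
           cum <- cumsum(sort(p, decreasing = TRUE))
           which(cum >= 0.5)[1L]
         },
         stop(sprintf("unknown diversity index '%s'; options: %s", index,
                      paste(DIVERSITY_INDICES, collapse = ", ")),
              call. = FALSE))
}

#' Repertoire diversity index
#'
#' Implements: `shannon` H = -Σ p_i ln p_i (natural log; `base` switches,
#' e.g. 2 for bits); `normalized_shannon` H / ln S (0 for a single clone);
#' `inverse_simpson` 1 / Σ p_i²; `gini_simpson` 1 - Σ p_i²; `clonality`
#' 1 - H / ln S (1 for a single clone); `chao1`
#' S + f1² / (2 f2) with the bias-corrected form
#' S + f1 (f1 - 1) / (2 (f2 + 1)) when f2 = 0, where f1/f2 are the numbers
#' of clones seen in exactly 1/2 reads; `d50` the minimal number of top
#' clones covering half the reads.
#'
#' @param rep a `repertoire` (non-empty).
#' @param index_name one of the indices above.
#' @param base logarithm base for the Shannon family; default `exp(1)`.
#' @return object of class `diversity_result`: `index_name`, `value`,
#'   `n_clonotypes`, `total_reads`, `sample_id`, and optionally a
#'   `rarefaction` block (see [rarefied_diversity()]).
#' @export
diversity <- function(rep, index_name = "shannon", base = exp(1)) {
  stopifnot(inherits(rep, "repertoire"))
  if (nrow(rep$clonotypes) == 0L) stop("empty repertoire", call. = FALSE)
  value <- diversity_value(index_name, rep$clonotypes$count)
  if (index_name == "shannon" && base != exp(1)) value <- value / log(base)
  structure(list(index_name = index_name, value = value,
                 n_clonotypes = nrow(rep$clonotypes),
                 total_reads = rep$total_reads, sample_id = rep$sample_id,
                 rarefaction = NULL),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("<diversity_result> %s: %s = %.6g", x$sample_id, x$index_name,
              x$value))
  if (!is.null(x$rarefaction)) {
    cat(sprintf(" (rarefied: depth %d, %d resamples, mean %.6g, sd %.3g)",
                x$rarefaction$depth, x$rarefaction$n_resamples,
                x$rarefaction$mean, x$rarefaction$sd))
  }
  cat("\n")
  invisible(x)
}

#' Rarefied diversity
#'
#' Mean and standard deviation of a diversity index over `n_resamples`
#' independent hypergeometric downsamples to `depth` reads — the depth-fair
#' way to compare diversity across samples sequenced to different depths.
#' Bit-reproducible given `(seed, n_resamples)`.
#'
#' @inheritParams diversity
#' @param depth target depth, `<= total_reads`.
#' @param n_resamples number of independent draws (>= 1).
#' @param seed master seed; per-draw seeds are derived from it.
#' @return a `diversity_result` whose `value` is the rarefied mean and whose
#'   `rarefaction` block holds `depth`, `n_resamples`, `mean`, `sd`, `seed`,
#'   `values`.
#' @export
rarefied_diversity <- function(rep, index_name = "shannon", depth,
                               n_resamples = 20L, seed = 1L) {
  stopifnot(inherits(rep, "repertoire"), n_resamples >= 1L)
  seeds <- derive_seeds(seed, n_resamples)
  vals <- vapply(seeds, function(s) {
    diversity(downsample(rep, depth, seed = s), index_name)$value
  }, numeric(1L))
  res <- diversity(rep, index_name)
  res$value <- mean(vals)
  res$rarefaction <- list(depth = as.integer(depth),
                          n_resamples = as.integer(n_resamples),
                          mean = mean(vals),
                          sd = if (n_resamples > 1L) stats::sd(vals) else 0,
                          seed = as.integer(seed), values = vals)
  res
}

# ---- group comparison ---------------------------------------------------

#' Two-group Wilcoxon (Mann-Whitney) rank-sum comparison
#'
#' Two-sided unpaired Mann-Whitney U test for comparing an index between
#' two sample groups (e.g. Shannon diversity of patients vs healthy
#' donors). Uses the exact null distribution of U when both groups have at
#' most 8 values and the pooled data are tie-free; otherwise the normal
#' approximation with tie correction (no continuity correction, so
#' identical groups give p = 1). The path taken is recorded in the output.
#'
#' @param values named list of exactly two numeric vectors (group label ->
#'   values), each non-empty.
#' @return list with `statistic` (U of the first group), `p`,
#'   `method_label` (`"mann_whitney_exact"` or
#'   `"mann_whitney_normal_approx"`), and the group labels.
#' @export
compare_groups <- function(values) {
  if (!is.list(values) || length(values) != 2L) {
    stop("exactly 2 groups required; run pairwise invocations for more",
         call. = FALSE)
  }
  x <- as.numeric(values[[1L]])
  y <- as.numeric(values[[2L]])
  if (length(x) < 1L || length(y) < 1L) {
    stop("each group needs at least one value", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && nx <= 8L && ny <= 8L) {
    p_le <- stats::pwilcox(U, nx, ny)
    p_ge <- stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "mann_whitney_exact"
  } else {
    n <- nx + ny
    tie_sizes <- table(pooled)
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(tie_sizes^3 - tie_sizes) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "mann_whitney_normal_approx"
  }
  labels <- names(values) %||% c("group1", "group2")
  list(statistic = U, p = p, method_label = method,
       groups = labels, n = c(nx, ny))
}

#' Benjamini-Hochberg adjustment helper
#'
#' Thin wrapper over [stats::p.adjust()] used by the CLI when it reports
#' all pairwise group tests: raw and BH-adjusted p values side by side.
#'
#' @param p numeric vector of raw p values.
#' @return vector of BH-adjusted p values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
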