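# Core clonotype / repertoire data model.
#
# A clonotype record is one row of a clonotype table: CDR3 nucleotide and
# amino-acid sequence, gene-level V and J segment calls, and a read count.
# A repertoire is one sample's set of records aggregated under an explicit
# clonotype identity ("key mode"), with frequencies normalised to sum to 1.

KEY_MODES <- c("nt", "aa", "nt+vj", "aa+vj")

#' Construct a clonotype record table
#'
#' Builds the canonical in-memory record table from parallel vectors. This is
#' the common currency of the package: the file readers return it and
#' [build_repertoire()] consumes it.
#'
#' @param cdr3_nt character, CDR3 nucleotide sequences (uppercase ACGT).
#' @param cdr3_aa character, CDR3 amino-acid sequences; may contain `*`
#'   (in-frame stop) or `_` (frameshift) for non-productive clones. If `NULL`,
#'   sequences are translated from `cdr3_nt` with the standard genetic code.
#' @param v_gene,j_gene character, gene-level segment labels (e.g. "TRBV27").
#' @param count non-negative integer read counts.
#' @return A `data.frame` with columns `cdr3_nt`, `cdr3_aa`, `v_gene`,
#'   `j_gene`, `count`.
#' @export
clonotype_records <- function(cdr3_nt, cdr3_aa = NULL, v_gene, j_gene, count) {
  cdr3_nt <- toupper(as.character(cdr3_nt))
  if (is.null(cdr3_aa)) cdr3_aa <- translate_cdr3(cdr3_nt)
  n <- length(cdr3_nt)
  stopifnot(length(cdr3_aa) == n, length(v_gene) == n,
            length(j_gene) == n, length(count) == n)
  data.frame(cdr3_nt = cdr3_nt, cdr3_aa = as.character(cdr3_aa),
             v_gene = as.character(v_gene), j_gene = as.character(j_gene),
             count = as.numeric(count), stringsAsFactors = FALSE)
}

record_columns <- c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene", "count")

validate_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("cannot build a repertoire from an empty record set", call. = FALSE)
  }
  missing <- setdiff(record_columns, names(records))
  if (length(missing)) {
    stop("record table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cnt <- suppressWarnings(as.numeric(records$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad)) {
    stop("invalid (negative, fractional or unparsable) count in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(records$cdr3_nt))) {
    stop("empty cdr3_nt in row(s): ",
         paste(utils::head(which(!nzchar(records$cdr3_nt)), 10L),
               collapse = ", "), call. = FALSE)
  }
  records$count <- cnt
  records
}

key_fields <- function(key_mode) {
  switch(match.arg(key_mode, KEY_MODES),
         "nt"    = "cdr3_nt",
         "aa"    = "cdr3_aa",
         "nt+vj" = c("cdr3_nt", "v_gene", "j_gene"),
         "aa+vj" = c("cdr3_aa", "v_gene", "j_gene"))
}

#' Clonotype identity keys under a key mode
#'
#' @param records a record table or the `clonotypes` table of a repertoire.
#' @param key_mode one of `"nt"`, `"aa"`, `"nt+vj"`, `"aa+vj"`.
#' @return character vector of keys; records with equal keys are the same
#'   clonotype under that mode.
#' @export
clonotype_key <- function(records, key_mode = "nt+vj") {
  fields <- key_fields(key_mode)
  do.call(paste, c(unname(records[fields]), sep = "|"))
}

# Deterministic repertoire ordering: descending count, lexicographic key
# tie-break (keeps golden files stable).
order_clonotypes <- function(df, key_mode) {
  df[order(-df$count, clonotype_key(df, key_mode), method = "radix"), ,
     drop = FALSE]
}

#' Aggregate clonotype records into a repertoire
#'
#' Records that share a clonotype key under `key_mode` are merged (counts
#' summed); frequencies are recomputed as `count / total_reads` and rows are
#' put in the deterministic order descending count, key lexicographic
#' tie-break. Non-key fields of a merged clonotype are taken from its
#' highest-count input row (ties broken lexicographically).
#'
#' @param records record table as returned by [clonotype_records()] or a
#'   reader; a `nt_variant_count` column, if present, is summed on merge.
#' @param key_mode clonotype identity; default `"nt+vj"` (CDR3 nucleotide
#'   sequence plus V and J gene), the common convention for MiXCR output.
#' @param sample_id sample label carried into results.
#' @return An object of class `repertoire`: list with `sample_id`,
#'   `clonotypes` (data.frame with `freq` added), `total_reads`, `key_mode`.
#' @export
build_repertoire <- function(records, key_mode = "nt+vj",
                             sample_id = "sample") {
  key_mode <- match.arg(key_mode, KEY_MODES)
  records <- validate_records(records)
  keep <- intersect(c(record_columns, "nt_variant_count", "productive"),
                    names(records))
  dt <- data.table::as.data.table(records[keep])
  dt[, .key := clonotype_key(records, key_mode)]
  # representative row per key: max count, then lexicographic fields
  data.table::setorderv(dt, c(".key", "count", "cdr3_nt", "v_gene", "j_gene"),
                        order = c(1L, -1L, 1L, 1L, 1L))
  rep_rows <- dt[, utils::head(.SD, 1L), by = .key]
  sums <- dt[, list(count = sum(count)), by = .key]
  agg <- merge(rep_rows[, !"count"], sums, by = ".key")
  if ("nt_variant_count" %in% names(dt)) {
    nv <- dt[, list(nt_variant_count = sum(nt_variant_count)), by = .key]
    agg[, nt_variant_count := NULL]
    agg <- merge(agg, nv, by = ".key")
  }
  df <- as.data.frame(agg[, !".key"])
  df <- df[, c(record_columns, setdiff(names(df), record_columns)),
           drop = FALSE]
  total <- sum(df$count)
  if (total <= 0) {
    stop("repertoire has zero total reads", call. = FALSE)
  }
  df <- order_clonotypes(df, key_mode)
  df$freq <- df$count / total
  rownames(df) <- NULL
  structure(list(sample_id = sample_id, clonotypes = df,
                 total_reads = total, key_mode = key_mode),
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> %s: %d clonotypes, %s reads, key mode %s\n",
              x$sample_id, nrow(x$clonotypes),
              format(x$total_reads, big.mark = ","), x$key_mode))
  invisible(x)
}

#' Number of clonotypes in a repertoire
#' @param rep a `repertoire`.
#' @return integer clone count.
#' @export
n_clonotypes <- function(rep) nrow(rep$clonotypes)

# Re-key a repertoire (no-op when already in the requested mode).
rekey_repertoire <- function(rep, key_mode) {
  if (rep$key_mode == key_mode) return(rep)
  build_repertoire(rep$clonotypes, key_mode, rep$sample_id)
}

#' Collapse a nucleotide-level repertoire to amino-acid clonotypes
#'
#' Merges clonotypes that translate to the same CDR3 amino-acid sequence
#' (`nt` becomes `aa`; `nt+vj` becomes `aa+vj`). Counts are summed and each
#' output clonotype carries `nt_variant_count`, the number of distinct
#' nucleotide sequences merged into it — the degeneracy used by convergent
#' recombination analysis.
#'
#' @param rep a `repertoire` keyed at `nt` or `nt+vj` level.
#' @return A `repertoire` keyed at the corresponding amino-acid level.
#' @export
collapse_to_aa <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  if (rep$key_mode %in% c("aa", "aa+vj")) {
    warning("repertoire already amino-acid keyed; returning unchanged")
    return(rep)
  }
  new_mode <- if (rep$key_mode == "nt") "aa" else "aa+vj"
  df <- rep$clonotypes
  aa_key <- clonotype_key(df, new_mode)
  dt <- data.table::as.data.table(df)
  dt[, .key := aa_key]
  nv <- dt[, list(nt_variant_count = length(unique(cdr3_nt))), by = .key]
  df$nt_variant_count <- NULL
  out <- build_repertoire(df, new_mode, rep$sample_id)
  out_key <- clonotype_key(out$clonotypes, new_mode)
  out$clonotypes$nt_variant_count <-
    nv$nt_variant_count[match(out_key, nv$.key)]
  out
}

#' Remove non-productive clonotypes
#'
#' Drops clonotypes whose CDR3 amino-acid sequence contains a stop (`*`) or
#' frameshift (`_`) marker — and, when the table carries an AIRR `productive`
#' flag, those flagged non-productive — then renormalises frequencies.
#'
#' @param rep a `repertoire`.
#' @return A `repertoire` containing only productive clonotypes.
#' @export
filter_functional <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  df <- rep$clonotypes
  bad <- grepl("[*_]", df$cdr3_aa, fixed = FALSE)
  if ("productive" %in% names(df)) {
    bad <- bad | (!is.na(df$productive) & !df$productive)
  }
  if (all(bad)) {
    stop("all clonotypes are non-productive; empty repertoire", call. = FALSE)
  }
  if (!any(bad)) return(rep)
  build_repertoire(df[!bad, , drop = FALSE], rep$key_mode, rep$sample_id)
}

#' Downsample a repertoire to a fixed read depth
#'
#' Draws `depth` reads without replacement (multivariate hypergeometric) so
#' diversity can be compared across samples at equal depth. Clones drawn to
#' zero are dropped. Fully reproducible for a fixed seed.
#'
#' @param rep a `repertoire`.
#' @param depth target read count, `0 < depth <= total_reads`.
#' @param seed integer random seed.
#' @return A `repertoire` with `total_reads == depth`.
#' @export
downsample <- function(rep, depth, seed = 1L) {
  stopifnot(inherits(rep, "repertoire"))
  if (depth <= 0 || depth > rep$total_reads) {
    stop(sprintf("depth must be in (0, %d]; no upsampling", rep$total_reads),
         call. = FALSE)
  }
  counts <- rep$clonotypes$count
  if (depth == rep$total_reads) {
    drawn <- counts
  } else {
    drawn <- withr::with_seed(as.integer(seed),
                              rmvhyper(counts, as.integer(depth)))
  }
  keep <- drawn > 0
  df <- rep$clonotypes[keep, , drop = FALSE]
  df$count <- drawn[keep]
  build_repertoire(df, rep$key_mode, rep$sample_id)
}

# Multivariate hypergeometric draw via sequential conditionals.
rmvhyper <- function(counts, k) {
  n <- length(counts)
  out <- numeric(n)
  remaining <- sum(counts)
  for (i in seq_len(n)) {
    if (k == 0L) break
    x <- stats::rhyper(1L, counts[i], remaining - counts[i], k)
    out[i] <- x
    k <- k - x
    remaining <- remaining - counts[i]
  }
  out
}
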