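# Readers and writers for clonotype-table dialects and the experiment
# design file.
#
# Three dialects are supported and auto-detected by header inspection:
#   * MiXCR exportClones TSV (cloneCount/cloneFraction/nSeqCDR3/...; column
#     matching case-insensitive, as MiXCR versions vary capitalisation),
#   * AIRR Rearrangement TSV (junction/v_call/duplicate_count/...; matching
#     case-sensitive per the AIRR standard),
#   * the package's own canonical TSV (written by write_canonical_table).

# Strip a segment call to gene level: first comma-separated hit, with
# everything from '*' or '(' to the end of the token deleted
# ("TRBV6-2*01(1250)" -> "TRBV6-2"). Returns the cleaned labels plus the
# number of multi-hit (ambiguous) calls seen.
clean_segment <- function(x) {
  x <- as.character(x)
  first <- sub(",.*$", "", x)
  ambiguous <- sum(first != x, na.rm = TRUE)
  cleaned <- sub("[*(].*$", "", first)
  cleaned <- trimws(cleaned)
  cleaned[is.na(cleaned) | !nzchar(cleaned)] <- "unknown"
  structure(cleaned, ambiguous = ambiguous)
}

read_delim_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "",
                    colClasses = "character")
}

# case-insensitive column lookup returning the first present candidate
find_column <- function(tab, candidates, ignore_case = TRUE) {
  nm <- names(tab)
  cmp <- if (ignore_case) tolower(nm) else nm
  for (cand in candidates) {
    hit <- which(cmp == (if (ignore_case) tolower(cand) else cand))
    if (length(hit)) return(nm[hit[1L]])
  }
  NULL
}

parse_counts <- function(x, path) {
  cnt <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(cnt) | cnt < 0)
  if (length(bad)) {
    warning(sprintf("%s: rejected %d row(s) with unparsable counts (rows %s)",
                    basename(path), length(bad),
                    paste(utils::head(bad, 10L), collapse = ", ")))
  }
  list(count = cnt, bad = bad)
}

#' Read a MiXCR exportClones clonotype table
#'
#' Maps MiXCR columns to the internal record table: `cloneCount` -> count,
#' `nSeqCDR3` (or `nSeqImputedCDR3`) -> cdr3_nt, `aaSeqCDR3` -> cdr3_aa,
#' `bestVHit`/`bestJHit` (preferred) or `allVHitsWithScore`/
#' `allJHitsWithScore` -> gene-level segment labels. Allele suffixes and
#' alignment scores are stripped; of multi-gene hit lists the first (best)
#' hit is kept and the number of such ambiguous calls is reported in the
#' `ambiguous_calls` attribute. Rows with unparsable counts are rejected
#' with a warning naming the rows.
#'
#' @param path path to a tab-delimited MiXCR exportClones file.
#' @return record `data.frame` as [clonotype_records()] (possibly 0 rows).
#' @export
read_mixcr_table <- function(path) {
  tab <- read_delim_table(path)
  cols <- list(
    count = find_column(tab, c("cloneCount", "clonecount")),
    nt    = find_column(tab, c("nSeqCDR3", "nSeqImputedCDR3", "clonalSequence")),
    aa    = find_column(tab, c("aaSeqCDR3", "aaSeqImputedCDR3")),
    v     = find_column(tab, c("bestVHit", "allVHitsWithScore", "bestVGene")),
    j     = find_column(tab, c("bestJHit", "allJHitsWithScore", "bestJGene")))
  need <- c("count", "nt", "v", "j")
  missing <- need[vapply(cols[need], is.null, logical(1L))]
  if (length(missing)) {
    stop(sprintf("%s: MiXCR dialect lacks mandatory column(s): %s",
                 basename(path),
                 paste(c(count = "cloneCount", nt = "nSeqCDR3",
                         v = "bestVHit/allVHitsWithScore",
                         j = "bestJHit/allJHitsWithScore")[missing],
                       collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    warning(sprintf("%s: header-only file, no clonotypes", basename(path)))
    return(clonotype_records(character(), character(), character(),
                             character(), numeric()))
  }
  pc <- parse_counts(tab[[cols$count]], path)
  v <- clean_segment(tab[[cols$v]])
  j <- clean_segment(tab[[cols$j]])
  nt <- toupper(tab[[cols$nt]])
  aa <- if (!is.null(cols$aa)) tab[[cols$aa]] else translate_cdr3(nt)
  rec <- clonotype_records(nt, aa, v, j, pc$count)
  if (length(pc$bad)) rec <- rec[-pc$bad, , drop = FALSE]
  attr(rec, "ambiguous_calls") <-
    attr(v, "ambiguous") + attr(j, "ambiguous")
  rec
}

#' Read an AIRR Rearrangement clonotype table
#'
#' Uses the AIRR Community schema field names (case-sensitive): `junction`,
#' `junction_aa`, `v_call`, `j_call` and `duplicate_count` (falling back to
#' `consensus_count` with a message when absent). A `productive` column,
#' when present, is carried along for [filter_functional()].
#'
#' @param path path to an AIRR Rearrangement TSV.
#' @return record `data.frame`, with a logical `productive` column when the
#'   input provides one.
#' @export
read_airr_table <- function(path) {
  tab <- read_delim_table(path)
  nt_col <- find_column(tab, "junction", ignore_case = FALSE)
  v_col <- find_column(tab, "v_call", ignore_case = FALSE)
  j_col <- find_column(tab, "j_call", ignore_case = FALSE)
  cnt_col <- find_column(tab, "duplicate_count", ignore_case = FALSE)
  if (is.null(cnt_col)) {
    cnt_col <- find_column(tab, "consensus_count", ignore_case = FALSE)
    if (!is.null(cnt_col)) {
      message(sprintf("%s: duplicate_count absent, using consensus_count",
                      basename(path)))
    }
  }
  missing <- c("junction", "v_call", "j_call",
               "duplicate_count/consensus_count")[
    vapply(list(nt_col, v_col, j_col, cnt_col), is.null, logical(1L))]
  if (length(missing)) {
    stop(sprintf("%s: AIRR dialect lacks mandatory column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    warning(sprintf("%s: header-only file, no clonotypes", basename(path)))
    return(clonotype_records(character(), character(), character(),
                             character(), numeric()))
  }
  pc <- parse_counts(tab[[cnt_col]], path)
  aa_col <- find_column(tab, "junction_aa", ignore_case = FALSE)
  nt <- toupper(tab[[nt_col]])
  aa <- if (!is.null(aa_col)) tab[[aa_col]] else translate_cdr3(nt)
  rec <- clonotype_records(nt, aa, clean_segment(tab[[v_col]]),
                           clean_segment(tab[[j_col]]), pc$count)
  prod_col <- find_column(tab, "productive", ignore_case = FALSE)
  if (!is.null(prod_col)) {
    rec$productive <- tab[[prod_col]] %in% c("T", "TRUE", "true", "1")
  }
  if (length(pc$bad)) rec <- rec[-pc$bad, , drop = FALSE]
  rec
}

#' Detect the dialect of a clonotype table
#'
#' Header-based detection: canonical (own format), MiXCR exportClones, or
#' AIRR Rearrangement. Detection never mixes dialects within one file.
#'
#' @param path file path.
#' @return one of `"canonical"`, `"mixcr"`, `"airr"`.
#' @export
detect_dialect <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  lower <- tolower(header)
  if (all(c("sample_id", "cdr3_nt", "count") %in% header)) return("canonical")
  if (any(c("clonecount", "nseqcdr3") %in% lower)) return("mixcr")
  if (all(c("junction", "v_call") %in% header)) return("airr")
  stop(sprintf("%s: cannot detect clonotype-table dialect from header",
               basename(path)), call. = FALSE)
}

#' Read a clonotype table of any supported dialect
#'
#' @param path file path; dialect auto-detected via [detect_dialect()].
#' @return record `data.frame`; the detected dialect is attached as the
#'   `dialect` attribute and reported with a message.
#' @export
read_clonotype_table <- function(path) {
  dialect <- detect_dialect(path)
  message(sprintf("%s: detected dialect '%s'", basename(path), dialect))
  rec <- switch(dialect,
                canonical = read_canonical_table(path),
                mixcr = read_mixcr_table(path),
                airr = read_airr_table(path))
  attr(rec, "dialect") <- dialect
  rec
}

#' Write a repertoire as canonical TSV
#'
#' Columns `sample_id, count, freq, cdr3_nt, cdr3_aa, v_gene, j_gene`
#' (plus `nt_variant_count` when present), rows in the repertoire's
#' deterministic order; frequencies with 10 significant digits. Round-trips
#' losslessly through [read_canonical_table()] / [build_repertoire()].
#'
#' @param rep a `repertoire`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_canonical_table <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  df <- rep$clonotypes
  out <- data.frame(sample_id = base::rep(rep$sample_id, nrow(df)),
                    count = df$count, freq = df$freq,
                    cdr3_nt = df$cdr3_nt, cdr3_aa = df$cdr3_aa,
                    v_gene = df$v_gene, j_gene = df$j_gene,
                    stringsAsFactors = FALSE)
  if (!is.null(df$nt_variant_count)) out$nt_variant_count <- df$nt_variant_count
  write_tsv(out, path)
}

#' Read a canonical TSV clonotype table
#'
#' @param path file written by [write_canonical_table()].
#' @return record `data.frame` with the source `sample_id` attached as an
#'   attribute.
#' @export
read_canonical_table <- function(path) {
  tab <- read_delim_table(path)
  need <- c("sample_id", "count", "cdr3_nt", "cdr3_aa", "v_gene", "j_gene")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop(sprintf("%s: canonical dialect lacks column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rec <- clonotype_records(tab$cdr3_nt, tab$cdr3_aa, tab$v_gene, tab$j_gene,
                           suppressWarnings(as.numeric(tab$count)))
  if ("nt_variant_count" %in% names(tab)) {
    rec$nt_variant_count <- as.numeric(tab$nt_variant_count)
  }
  attr(rec, "sample_id") <- if (nrow(tab)) tab$sample_id[1L] else NA_character_
  rec
}

#' Read a repertoire from any supported clonotype table
#'
#' Convenience wrapper: [read_clonotype_table()] then [build_repertoire()].
#'
#' @inheritParams build_repertoire
#' @param path file path.
#' @param sample_id sample label; defaults to the file's own label
#'   (canonical dialect) or the file name without extension.
#' @return a `repertoire`.
#' @export
read_repertoire <- function(path, key_mode = "nt+vj", sample_id = NULL) {
  rec <- read_clonotype_table(path)
  if (is.null(sample_id)) {
    sample_id <- attr(rec, "sample_id")
    if (is.null(sample_id) || is.na(sample_id)) {
      sample_id <- sub("\\.[^.]*$", "", basename(path))
    }
  }
  rep <- build_repertoire(rec, key_mode, sample_id)
  attr(rep, "dialect") <- attr(rec, "dialect")
  rep
}

# ---- experiment design file --------------------------------------------

#' Read an experiment design file
#'
#' A delimited sample manifest (comma or tab, sniffed from the header) with
#' mandatory columns `sample_id` and `file`; every further column is a
#' grouping variable. Relative file paths are resolved against the design
#' file's directory. The same design can be regrouped by any combination of
#' its variables with [group_samples()].
#'
#' @param path design file path.
#' @param check_files error when referenced clonotype files are missing
#'   (all missing paths listed at once); default `TRUE`.
#' @return an object of class `study_design`: data.frame of samples with
#'   attribute `variables` (declared grouping variable names).
#' @export
read_design_file <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  tab <- read_delim_table(path, sep = sep)
  missing <- setdiff(c("sample_id", "file"), names(tab))
  if (length(missing)) {
    stop("design file lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id in design file: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", tab$file)
  tab$file[rel] <- file.path(dirname(path), tab$file[rel])
  if (check_files) {
    absent <- tab$file[!file.exists(tab$file)]
    if (length(absent)) {
      stop("design file references missing file(s):\n  ",
           paste(absent, collapse = "\n  "), call. = FALSE)
    }
  }
  vars <- setdiff(names(tab), c("sample_id", "file"))
  tab[vars] <- lapply(tab[vars], function(x) ifelse(is.na(x), "NA", x))
  structure(tab, variables = vars, class = c("study_design", "data.frame"))
}

#' Group samples by design variables
#'
#' Forms groups from the cross-product of observed value combinations of the
#' requested variables, in requested order; labels join the values with "/".
#' Empty combinations are omitted; groups are ordered lexicographically by
#' label. An empty variable selection yields the single group `"all"`.
#'
#' @param design a `study_design`.
#' @param variables character vector of declared variable names (may be
#'   empty).
#' @return named list mapping group label to character vector of
#'   `sample_id`s; the lists partition the sample set.
#' @export
group_samples <- function(design, variables = character()) {
  stopifnot(inherits(design, "study_design"))
  declared <- attr(design, "variables")
  unknown <- setdiff(variables, declared)
  if (length(unknown)) {
    stop(sprintf("unknown grouping variable(s): %s (declared: %s)",
                 paste(unknown, collapse = ", "),
                 if (length(declared)) paste(declared, collapse = ", ")
                 else "<none>"), call. = FALSE)
  }
  if (length(variables) == 0L) {
    return(stats::setNames(list(design$sample_id), "all"))
  }
  labels <- do.call(paste, c(unname(as.data.frame(design)[variables]),
                             sep = "/"))
  groups <- split(design$sample_id, labels)
  groups[order(names(groups), method = "radix")]
}
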