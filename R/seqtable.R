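# Sequence-based counting: unique sequence x sample count tables, abundance
# filters and counts-per-million normalization. Counting is over sequences,
# not genomic features, so the read sequence survives counting unchanged.

new_seq_count_table <- function(counts, samples, totals, normalized = FALSE) {
  structure(
    list(counts = counts, samples = samples, totals = totals,
         normalized = normalized),
    class = if (normalized) c("cpm_table", "seq_count_table")
            else "seq_count_table"
  )
}

sample_ids <- function(x) names(x$counts)[-1L]

#' Count unique sequences across samples
#'
#' Builds a unique-sequence-by-sample count table from retained reads. One
#' row per distinct (case-normalized) sequence; `library_totals` are the
#' per-sample retained read counts and later serve as the fixed
#' normalization denominator. Sequences containing N are counted verbatim
#' and flagged.
#'
#' @param reads Tibble with columns `sample_id` and `sequence` (one row per
#'   retained read).
#' @param samples Optional sample metadata tibble with `sample_id` and any
#'   of `sublibrary`, `method`, `batch`; defaults to the distinct sample ids.
#' @return A `seq_count_table`: list with `counts` (tibble: `sequence`, one
#'   integer column per sample), `samples`, `totals` (named per-sample
#'   library totals) and `normalized = FALSE`. `tidy()` returns the long
#'   form with a `has_n` flag.
#' @export
#' @examples
#' reads <- tibble::tibble(sample_id = "s1",
#'                         sequence = c("AAAA", "AAAA", "CCCC"))
#' tidy(count_unique(reads))
count_unique <- function(reads, samples = NULL) {
  stopifnot(all(c("sample_id", "sequence") %in% names(reads)))
  reads$sequence <- toupper(reads$sequence)
  if (is.null(samples)) {
    samples <- tibble(sample_id = unique(reads$sample_id))
  }
  totals <- setNames(rep(0, nrow(samples)), samples$sample_id)
  observed <- table(reads$sample_id)
  totals[names(observed)] <- as.numeric(observed)
  counts <- reads %>%
    dplyr::count(.data$sequence, .data$sample_id) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L) %>%
    dplyr::arrange(.data$sequence)
  missing <- setdiff(samples$sample_id, names(counts))
  for (m in missing) counts[[m]] <- 0L
  counts <- counts[, c("sequence", samples$sample_id)]
  new_seq_count_table(counts, samples, totals)
}

#' Keep sequences with at least `min_count` in every scoped sample
#'
#' The noise filter of sequence-based counting: a row survives only when its
#' count is at least `min_count` in 100% of the scoped samples (typically
#' the samples of one library method). Unscoped columns are untouched and
#' library totals are never recomputed.
#'
#' @param x A `seq_count_table` (or `cpm_table`).
#' @param min_count Minimum per-sample count.
#' @param scope Character vector of sample ids the predicate applies to;
#'   default all samples. Must be non-empty.
#' @return The filtered table, same class.
#' @export
filter_min_count <- function(x, min_count = 5, scope = sample_ids(x)) {
  stopifnot(inherits(x, "seq_count_table"))
  if (length(scope) == 0L) stop("scope must be non-empty", call. = FALSE)
  if (!all(scope %in% sample_ids(x))) {
    stop("unknown sample(s) in scope: ",
         paste(setdiff(scope, sample_ids(x)), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(x$counts[, scope, drop = FALSE])
  keep <- rowSums(m >= min_count) == length(scope)
  x$counts <- x$counts[keep, , drop = FALSE]
  x
}

#' Normalize a count table to counts per million
#'
#' Divides each count by its sample's library total (the retained read count
#' recorded at counting time, before any abundance filtering) and scales by
#' 10^6. Column sums of an unfiltered table are exactly 10^6.
#'
#' @param x A `seq_count_table`.
#' @return A `cpm_table` with the same shape; `totals` kept as metadata.
#' @export
normalize_cpm <- function(x) {
  stopifnot(inherits(x, "seq_count_table"))
  if (x$normalized) return(x)
  zero <- names(x$totals)[x$totals <= 0]
  if (length(zero) > 0) {
    stop("cannot normalize: zero library total for sample(s) ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  for (s in sample_ids(x)) {
    x$counts[[s]] <- x$counts[[s]] / x$totals[[s]] * 1e6
  }
  new_seq_count_table(x$counts, x$samples, x$totals, normalized = TRUE)
}

#' Keep sequences with at least `min_cpm` in every scoped sample
#'
#' The abundance filter for analyses of intermediately-to-strongly expressed
#' sequences: requires `min_cpm` (default 10) in 100% of the scoped samples.
#'
#' @param x A `cpm_table` from [normalize_cpm()].
#' @param min_cpm Minimum per-sample cpm.
#' @param scope Character vector of sample ids; must be non-empty.
#' @return The filtered `cpm_table`.
#' @export
filter_min_cpm <- function(x, min_cpm = 10, scope = sample_ids(x)) {
  stopifnot(inherits(x, "cpm_table"))
  filter_min_count(x, min_count = min_cpm, scope = scope)
}

#' @export
print.seq_count_table <- function(x, ...) {
  cat(sprintf("<%s> %d sequences x %d samples\n",
              if (x$normalized) "cpm_table" else "seq_count_table",
              nrow(x$counts), length(sample_ids(x))))
  print(head(x$counts, 5))
  invisible(x)
}

#' @rdname count_unique
#' @param x A `seq_count_table`.
#' @param ... Unused.
#' @export
tidy.seq_count_table <- function(x, ...) {
  value_col <- if (x$normalized) "cpm" else "count"
  long <- tidyr::pivot_longer(x$counts, -"sequence",
                              names_to = "sample_id",
                              values_to = value_col)
  long$has_n <- grepl("N", long$sequence, fixed = TRUE)
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' @rdname count_unique
#' @export
glance.seq_count_table <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$counts),
    n_samples = length(sample_ids(x)),
    normalized = x$normalized,
    total_reads = sum(x$totals)
  )
}

#' Write a count table and its sample sidecar to TSV
#'
#' @param x A `seq_count_table`.
#' @param path Output TSV (first column `sequence`, one column per sample).
#' @param samples_path Optional sidecar TSV with sample metadata and library
#'   totals.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, samples_path = NULL) {
  readr::write_tsv(x$counts, path)
  if (!is.null(samples_path)) {
    meta <- x$samples
    meta$library_total <- as.numeric(x$totals[meta$sample_id])
    readr::write_tsv(meta, samples_path)
  }
  invisible(path)
}
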