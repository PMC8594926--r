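# Native read preprocessing: two-color-chemistry quality trimming, 3' adapter
# removal, whole-read quality filtering and 5'-tag sub-library splitting.

#' Preprocessing parameters
#'
#' Defaults follow the canonical trimming recipe for 5'XP libraries:
#' adapter with at least 5 nt of 3' overlap, untrimmed reads discarded,
#' two-color quality cutoff 20, insert length 5--70 nt, whole-read filter
#' requiring Phred >= 20 in >= 80% of bases, and an 11-nt 5' tag matched as
#' an exact prefix.
#'
#' @param adapter 3' adapter sequence.
#' @param min_overlap Minimum adapter prefix length at the 3' end.
#' @param max_error_rate Allowed mismatch fraction of the matched adapter
#'   length (budget is `floor(rate * length)`).
#' @param qcut Two-color-chemistry quality cutoff.
#' @param min_len,max_len Retained insert length bounds (inclusive).
#' @param qf_min_q,qf_min_frac Whole-read quality filter: keep when the
#'   fraction of bases with Phred >= `qf_min_q` is >= `qf_min_frac`.
#' @param tag 5' tag sequence defining the P_TAG sub-library.
#' @param tag_max_mismatch Substitutions tolerated in the tag prefix
#'   (default 0, strict).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(adapter = DEFAULT_ADAPTER,
                              min_overlap = 5L,
                              max_error_rate = 0.1,
                              qcut = 20L,
                              min_len = 5L,
                              max_len = 70L,
                              qf_min_q = 20L,
                              qf_min_frac = 0.8,
                              tag = DEFAULT_TAG,
                              tag_max_mismatch = 0L) {
  stopifnot(
    nchar(adapter) > 0, min_overlap >= 1,
    max_error_rate >= 0, max_error_rate < 1,
    qcut >= 0, min_len >= 0, max_len >= min_len,
    qf_min_q >= 0, qf_min_frac >= 0, qf_min_frac <= 1,
    nchar(tag) > 0, tag_max_mismatch >= 0
  )
  structure(
    list(adapter = toupper(adapter), min_overlap = as.integer(min_overlap),
         max_error_rate = max_error_rate, qcut = as.integer(qcut),
         min_len = as.integer(min_len), max_len = as.integer(max_len),
         qf_min_q = as.integer(qf_min_q), qf_min_frac = qf_min_frac,
         tag = toupper(tag), tag_max_mismatch = as.integer(tag_max_mismatch)),
    class = "preprocess_params"
  )
}

ensure_discard_col <- function(reads) {
  if (!"discard_reason" %in% names(reads)) {
    reads$discard_reason <- rep(NA_character_, nrow(reads))
  }
  reads
}

#' Two-color-chemistry 3' quality trimming
#'
#' Trims low-quality 3' tails with the running-sum rule, treating G bases as
#' quality 0: on two-color instruments a dark cycle reads as G, so a trailing
#' G run is uncertain regardless of its reported score. Walking in from the
#' 3' end accumulating `qcut - q_effective`, the read is cut where the sum is
#' maximal. Reads never lengthen; a read may become empty (it is then
#' discarded at the adapter-trimming stage).
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param qcut Quality cutoff.
#' @return The tibble with trimmed `sequence`/`quality`.
#' @export
trim_two_color_tail <- function(reads, qcut = 20L) {
  reads <- ensure_discard_col(reads)
  live <- is.na(reads$discard_reason)
  if (!any(live)) return(reads)
  keep_len <- nextseq_trim_len(reads$sequence[live], reads$quality[live],
                               as.integer(qcut))
  reads$sequence[live] <- substr(reads$sequence[live], 1L, keep_len)
  reads$quality[live] <- substr(reads$quality[live], 1L, keep_len)
  reads
}

#' 3' adapter trimming with minimum overlap
#'
#' Finds the best ungapped adapter occurrence — the full adapter anywhere, or
#' an adapter prefix of at least `min_overlap` bases flush with the 3' end —
#' allowing `floor(max_error_rate * matched_length)` mismatches (N never
#' matches). Ties break longest match, then leftmost; trimming iterates so
#' that no qualifying occurrence survives. Reads without a qualifying
#' occurrence are discarded (`no_adapter`), as are trimmed inserts outside
#' `[min_len, max_len]` (`too_short` / `too_long`).
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (and optionally
#'   a `discard_reason` column from an earlier stage).
#' @param params A [preprocess_params()] object.
#' @return The tibble with trimmed sequences and an updated
#'   `discard_reason` column (`NA` = retained).
#' @export
trim_three_prime_adapter <- function(reads, params = preprocess_params()) {
  reads <- ensure_discard_col(reads)
  live <- which(is.na(reads$discard_reason))
  if (length(live) == 0L) return(reads)
  kept_len <- adapter_trim_len(reads$sequence[live], params$adapter,
                               params$min_overlap, params$max_error_rate)
  reason <- rep(NA_character_, length(live))
  reason[kept_len < 0L] <- "no_adapter"
  reason[kept_len >= 0L & kept_len < params$min_len] <- "too_short"
  reason[kept_len > params$max_len] <- "too_long"
  trim_to <- pmax(kept_len, 0L)
  ok <- is.na(reason)
  reads$sequence[live[ok]] <- substr(reads$sequence[live[ok]], 1L,
                                     trim_to[ok])
  reads$quality[live[ok]] <- substr(reads$quality[live[ok]], 1L, trim_to[ok])
  reads$discard_reason[live] <- reason
  reads
}

#' Whole-read quality filter
#'
#' Keeps a read when the fraction of bases with Phred >= `min_q` is at least
#' `min_frac` (the >=/>= semantics of the classic fastq quality filter).
#'
#' @param reads Tibble of reads.
#' @param min_q Phred threshold.
#' @param min_frac Required fraction of bases at or above `min_q`.
#' @return The tibble with failing reads marked `low_quality` in
#'   `discard_reason`.
#' @export
quality_filter <- function(reads, min_q = 20L, min_frac = 0.8) {
  reads <- ensure_discard_col(reads)
  live <- which(is.na(reads$discard_reason))
  if (length(live) == 0L) return(reads)
  frac <- qual_fraction_ge(reads$quality[live], as.integer(min_q))
  fail <- is.na(frac) | frac < min_frac
  reads$discard_reason[live[fail]] <- "low_quality"
  reads
}

#' Split reads into 5P-tag and 5X-notag sub-libraries
#'
#' A read beginning with the 5' tag (at most `tag_max_mismatch`
#' substitutions; N never matches) is assigned to the `P_TAG` sub-library
#' with the tag removed; all other reads go to `X_NOTAG` unchanged. De-tagged
#' reads shorter than `min_len` are discarded (`short_after_tag`). Reads
#' shorter than the tag cannot carry it and are `X_NOTAG`.
#'
#' @param reads Adapter-trimmed tibble of reads.
#' @param params A [preprocess_params()] object.
#' @return The tibble with a `sublibrary` column (`P_TAG`/`X_NOTAG`) and
#'   updated `discard_reason`.
#' @export
split_by_tag <- function(reads, params = preprocess_params()) {
  reads <- ensure_discard_col(reads)
  if (!"sublibrary" %in% names(reads)) {
    reads$sublibrary <- rep(NA_character_, nrow(reads))
  }
  live <- which(is.na(reads$discard_reason))
  if (length(live) == 0L) return(reads)
  mm <- prefix_mismatches(reads$sequence[live], params$tag)
  has_tag <- !is.na(mm) & mm <= params$tag_max_mismatch
  reads$sublibrary[live] <- ifelse(has_tag, "P_TAG", "X_NOTAG")
  tl <- nchar(params$tag)
  idx <- live[has_tag]
  reads$sequence[idx] <- substr(reads$sequence[idx], tl + 1L,
                                nchar(reads$sequence[idx]))
  reads$quality[idx] <- substr(reads$quality[idx], tl + 1L,
                               nchar(reads$quality[idx]))
  short <- idx[nchar(reads$sequence[idx]) < params$min_len]
  reads$discard_reason[short] <- "short_after_tag"
  reads$sublibrary[short] <- NA_character_
  reads
}

#' Preprocess a set of reads in memory
#'
#' Composes the full preprocessing pipeline: two-color quality trim, 3'
#' adapter trim with length bounds, 5'-tag sub-library split, whole-read
#' quality filter. Every input read is accounted for exactly once — either
#' retained in one sub-library or attributed to a named discard reason.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param params A [preprocess_params()] object.
#' @return An object of class `fivexp_preprocess`: a list with `reads`
#'   (retained tibble incl. `sublibrary`), `discards` (tibble `read_id`,
#'   `reason`) and `stats` (per-stage in/kept/discarded counts). `tidy()`
#'   returns the stage stats, `glance()` a one-row summary.
#' @export
#' @examples
#' reads <- tibble::tibble(
#'   read_id = "r1",
#'   sequence = paste0("TGGCAACGATC", strrep("ACGT", 6),
#'                     "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACAT"),
#'   quality = strrep("I", 11 + 24 + 36)
#' )
#' pp <- preprocess_reads(reads)
#' pp$reads
preprocess_reads <- function(reads, params = preprocess_params()) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  n_in <- nrow(reads)
  reads$sequence <- toupper(reads$sequence)
  stage_counts <- function(reads, stage) {
    tibble(stage = stage,
           reads_in = n_in,
           reads_live = sum(is.na(reads$discard_reason)),
           reads_discarded = sum(!is.na(reads$discard_reason)))
  }
  reads <- ensure_discard_col(reads)
  reads <- trim_two_color_tail(reads, params$qcut)
  s1 <- stage_counts(reads, "two_color_trim")
  reads <- trim_three_prime_adapter(reads, params)
  s2 <- stage_counts(reads, "adapter_trim")
  reads <- split_by_tag(reads, params)
  s3 <- stage_counts(reads, "tag_split")
  reads <- quality_filter(reads, params$qf_min_q, params$qf_min_frac)
  s4 <- stage_counts(reads, "quality_filter")
  kept <- reads[is.na(reads$discard_reason),
                c("read_id", "sequence", "quality", "sublibrary")]
  discards <- tibble(
    read_id = reads$read_id[!is.na(reads$discard_reason)],
    reason = reads$discard_reason[!is.na(reads$discard_reason)]
  )
  structure(
    list(reads = kept, discards = discards,
         stats = dplyr::bind_rows(s1, s2, s3, s4), params = params),
    class = "fivexp_preprocess"
  )
}

#' Preprocess a FASTQ file into sub-library FASTQ outputs
#'
#' File-level wrapper around [preprocess_reads()]: reads a FASTQ, writes one
#' FASTQ per sub-library and (optionally) a TSV of per-stage statistics.
#'
#' @param fastq_in Input FASTQ path.
#' @param params A [preprocess_params()] object.
#' @param out_tag,out_notag Output FASTQ paths for the P_TAG and X_NOTAG
#'   sub-libraries.
#' @param stats_out Optional TSV path for stage statistics.
#' @return The `fivexp_preprocess` object, invisibly.
#' @export
preprocess_sample <- function(fastq_in, params = preprocess_params(),
                              out_tag = NULL, out_notag = NULL,
                              stats_out = NULL) {
  res <- preprocess_reads(read_fastq(fastq_in), params)
  if (!is.null(out_tag)) {
    write_fastq(res$reads[res$reads$sublibrary == "P_TAG", ], out_tag)
  }
  if (!is.null(out_notag)) {
    write_fastq(res$reads[res$reads$sublibrary == "X_NOTAG", ], out_notag)
  }
  if (!is.null(stats_out)) readr::write_tsv(tidy(res), stats_out)
  invisible(res)
}

#' @export
print.fivexp_preprocess <- function(x, ...) {
  cat("<fivexp_preprocess>\n")
  g <- glance(x)
  cat(sprintf("  %d reads in: %d P_TAG, %d X_NOTAG, %d discarded\n",
              g$n_input, g$n_p_tag, g$n_x_notag, g$n_discarded))
  invisible(x)
}

#' @rdname preprocess_reads
#' @param x A `fivexp_preprocess` object.
#' @param ... Unused.
#' @export
tidy.fivexp_preprocess <- function(x, ...) x$stats

#' @rdname preprocess_reads
#' @export
glance.fivexp_preprocess <- function(x, ...) {
  n_in <- if (nrow(x$stats)) x$stats$reads_in[1L] else 0L
  tibble(
    n_input = n_in,
    n_p_tag = sum(x$reads$sublibrary == "P_TAG"),
    n_x_notag = sum(x$reads$sublibrary == "X_NOTAG"),
    n_discarded = nrow(x$discards)
  )
}
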