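# Hierarchical mismatch-tiered annotation: full-length ungapped alignment of
# unique sequences against biotype reference sets, in cycles of increasing
# mismatch allowance with a fixed biotype priority ladder.

revcomp_vec <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Assemble biotype reference sets
#'
#' Joins reference entries with the biotype priority ladder and validates
#' that ref_ids are globally unique (duplicates across sets would make the
#' winning hit ambiguous).
#'
#' @param references Tibble with `biotype`, `ref_id`, `sequence`.
#' @param priority Tibble with `biotype`, `priority_rank`; defaults to the
#'   standard ladder ([biotype_priority()]).
#' @return Tibble with `biotype`, `priority_rank`, `ref_id`, `sequence`.
#' @export
as_reference_sets <- function(references, priority = biotype_priority()) {
  stopifnot(all(c("biotype", "ref_id", "sequence") %in% names(references)))
  if (anyDuplicated(references$ref_id)) {
    stop("duplicate ref_id across reference sets: ",
         paste(unique(references$ref_id[duplicated(references$ref_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(priority$priority_rank)) {
    stop("priority ranks must be distinct", call. = FALSE)
  }
  unknown <- setdiff(unique(references$biotype), priority$biotype)
  if (length(unknown) > 0) {
    stop("no priority rank for biotype(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::inner_join(references, priority, by = "biotype")
  out$sequence <- toupper(out$sequence)
  out[, c("biotype", "priority_rank", "ref_id", "sequence")]
}

#' All ungapped placements of a query within one reference
#'
#' Slides the full query along the reference and reports every placement
#' with Hamming distance at most `max_mm`; N never matches. With
#' `strand = "both"` the reverse complement of the query is also searched
#' and reported as minus-strand hits in reference coordinates.
#'
#' @param query Query sequence (full-length match, no indels).
#' @param reference Reference sequence.
#' @param max_mm Maximum mismatches (0--3 in the standard annotation cycles).
#' @param strand `"+"` (sense only, default) or `"both"`.
#' @return Tibble with `start`, `end` (1-based inclusive), `strand`,
#'   `mismatches`. Empty when the query is longer than the reference.
#' @export
#' @examples
#' align_with_mismatches("ACGT", "AAACGTAA", max_mm = 0)
align_with_mismatches <- function(query, reference, max_mm = 3L,
                                  strand = c("+", "both")) {
  strand <- match.arg(strand)
  query <- toupper(query); reference <- toupper(reference)
  qlen <- nchar(query)
  one <- function(q, str) {
    hits <- hamming_placements(q, reference, as.integer(max_mm))
    starts <- as.integer(hits[, "start", drop = TRUE])
    tibble(start = unname(starts),
           end = unname(starts) + qlen - 1L,
           strand = rep(str, nrow(hits)),
           mismatches = unname(as.integer(hits[, "mismatches",
                                               drop = TRUE])))
  }
  out <- one(query, "+")
  if (strand == "both") {
    out <- dplyr::bind_rows(out, one(revcomp_vec(query), "-"))
  }
  out
}

#' Hierarchically annotate sequences against biotype reference sets
#'
#' Emulates annotation in cycles of increasing mismatch allowance: a
#' sequence is assigned at the smallest tier t (0..`max_tier`) at which any
#' reference set contains a full-length ungapped placement with <= t
#' mismatches. When several sets match at that tier, the set with the best
#' (lowest) priority rank wins — so a 0-mismatch piRNA hit beats a
#' 1-mismatch miRNA hit, while at equal tier miRNA outranks piRNA. Within
#' the winning set the representative hit is resolved by
#' [resolve_within_biotype()]. Sequences with no placement at `max_tier`
#' are `unannotated`.
#'
#' @param sequences Character vector (or tibble with a `sequence` column) of
#'   unique sequences.
#' @param reference_sets Tibble from [as_reference_sets()].
#' @param max_tier Maximum mismatch tier (default 3).
#' @param strand `"+"` (default) or `"both"`.
#' @return Tibble with one row per input sequence: `sequence`, `status`,
#'   `biotype`, `mismatch_tier`, `ref_id`, `start`, `end`, `strand`,
#'   `mismatches`.
#' @export
annotate_hierarchical <- function(sequences, reference_sets, max_tier = 3L,
                                  strand = c("+", "both")) {
  strand <- match.arg(strand)
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  sequences <- toupper(sequences)
  queries <- unique(sequences)
  refs <- if ("priority_rank" %in% names(reference_sets)) {
    as_reference_sets(reference_sets[, c("biotype", "ref_id", "sequence")],
                      dplyr::distinct(reference_sets[, c("biotype",
                                                         "priority_rank")]))
  } else {
    as_reference_sets(reference_sets)
  }
  bp <- best_placements(queries, refs$sequence, as.integer(max_tier))
  start <- bp$start; mism <- bp$mismatches
  if (strand == "both") {
    bp_rc <- best_placements(revcomp_vec(queries), refs$sequence,
                             as.integer(max_tier))
    better <- !is.na(bp_rc$mismatches) &
      (is.na(mism) | bp_rc$mismatches < mism)
    strand_mat <- matrix("+", nrow(start), ncol(start))
    strand_mat[better] <- "-"
    start[better] <- bp_rc$start[better]
    mism[better] <- bp_rc$mismatches[better]
  } else {
    strand_mat <- matrix("+", nrow(start), ncol(start))
  }
  ann_one <- function(i) {
    mm <- mism[i, ]
    if (all(is.na(mm))) {
      return(tibble(sequence = queries[i], status = "unannotated",
                    biotype = NA_character_, mismatch_tier = NA_integer_,
                    ref_id = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    mismatches = NA_integer_))
    }
    tier <- min(mm, na.rm = TRUE)
    set_best <- tapply(mm, refs$biotype, function(v) {
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    })
    matching <- names(set_best)[!is.na(set_best) & set_best == tier]
    ranks <- refs$priority_rank[match(matching, refs$biotype)]
    win_bt <- matching[which.min(ranks)]
    cand <- which(refs$biotype == win_bt & !is.na(mm) & mm == tier)
    hits <- tibble(ref_id = refs$ref_id[cand], start = start[i, cand],
                   strand = strand_mat[i, cand], mismatches = mm[cand])
    rep_hit <- resolve_within_biotype(hits)
    tibble(sequence = queries[i], status = "annotated", biotype = win_bt,
           mismatch_tier = as.integer(tier), ref_id = rep_hit$ref_id,
           start = rep_hit$start,
           end = rep_hit$start + nchar(queries[i]) - 1L,
           strand = rep_hit$strand, mismatches = rep_hit$mismatches)
  }
  out <- dplyr::bind_rows(lapply(seq_along(queries), ann_one))
  out[match(sequences, out$sequence), ]
}

#' Resolve a representative hit within one biotype
#'
#' Deterministic tie-break among hits of the winning biotype and tier:
#' fewest mismatches, then lexicographically smallest `ref_id`, then
#' smallest start.
#'
#' @param hits Tibble with `ref_id`, `start`, `mismatches` (and optionally
#'   `strand`).
#' @return The single winning row.
#' @export
resolve_within_biotype <- function(hits) {
  stopifnot(nrow(hits) > 0)
  ord <- order(hits$mismatches, hits$ref_id, hits$start)
  hits[ord[1L], ]
}

#' Write an annotation table to TSV
#'
#' @param annotations Tibble from [annotate_hierarchical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}
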