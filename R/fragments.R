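# Terminal and loop classification of tRNA- and rRNA-derived fragments, and
# per-reference coverage profiles.
#
# ss dialect: per record a header line ">ref_id", the mature sequence, and an
# aligned pairing line over '>', '<', '.'. Loops are the maximal unpaired
# runs strictly enclosed by a stem: the run's flanking '>' and '<' must pair
# with each other. In 5'->3' order the enclosed runs are labelled D_loop,
# anticodon_loop, (variable_loop when a fourth enclosed run precedes the T
# stem) and T_loop.

TERMINAL_CLASSES <- c("five_prime", "internal", "three_prime", "full")

# Partner index of each paired position; errors on unbalanced strings.
pairing_partners <- function(pairing, ref_id = "?") {
  chars <- strsplit(pairing, "")[[1]]
  partner <- rep(NA_integer_, length(chars))
  stack <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == ">") {
      stack <- c(stack, i)
    } else if (chars[i] == "<") {
      if (length(stack) == 0L) {
        stop("unbalanced pairing string in record '", ref_id,
             "': unmatched '<' at position ", i, call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    } else if (chars[i] != ".") {
      stop("invalid pairing character '", chars[i], "' in record '",
           ref_id, "'", call. = FALSE)
    }
  }
  if (length(stack) > 0L) {
    stop("unbalanced pairing string in record '", ref_id,
         "': unmatched '>' at position ", stack[1L], call. = FALSE)
  }
  partner
}

#' Construct a tRNA secondary-structure record
#'
#' Derives the labelled loops from the pairing string: maximal unpaired runs
#' whose flanking stem positions pair with each other are enclosed loops,
#' labelled 5'->3' as D_loop, anticodon_loop, (variable_loop for any run
#' between the anticodon and T loops) and T_loop. Records with fewer than
#' three enclosed loops are kept but flagged unusable for loop mapping.
#'
#' @param ref_id Reference identifier.
#' @param sequence Mature tRNA sequence.
#' @param pairing Aligned pairing string over `>`, `<`, `.`.
#' @return A list of class `secondary_structure` with `ref_id`, `sequence`,
#'   `length`, `pairing`, `loops` (tibble: `label`, `start`, `end`) and
#'   `usable`.
#' @export
secondary_structure <- function(ref_id, sequence, pairing) {
  sequence <- toupper(sequence)
  if (nchar(pairing) != nchar(sequence)) {
    stop("pairing and sequence lengths differ in record '", ref_id, "'",
         call. = FALSE)
  }
  partner <- pairing_partners(pairing, ref_id)
  chars <- strsplit(pairing, "")[[1]]
  n <- length(chars)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (chars[i] == ".") {
      j <- i
      while (j < n && chars[j + 1L] == ".") j <- j + 1L
      enclosed <- i > 1L && j < n && chars[i - 1L] == ">" &&
        chars[j + 1L] == "<" && identical(partner[i - 1L], j + 1L)
      if (enclosed) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  k <- length(runs)
  if (k >= 3L) {
    labels <- c("D_loop",
                "anticodon_loop",
                rep("variable_loop", k - 3L),
                "T_loop")
    loops <- tibble(
      label = labels,
      start = vapply(runs, `[`, integer(1), 1L),
      end = vapply(runs, `[`, integer(1), 2L)
    )
    usable <- TRUE
  } else {
    loops <- tibble(label = character(), start = integer(), end = integer())
    usable <- FALSE
  }
  structure(
    list(ref_id = ref_id, sequence = sequence, length = nchar(sequence),
         pairing = pairing, loops = loops, usable = usable),
    class = "secondary_structure"
  )
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure>", x$ref_id, sprintf("(%d nt)\n", x$length))
  cat(" ", x$sequence, "\n ", x$pairing, "\n")
  if (x$usable) print(x$loops) else cat("  (unusable: <3 enclosed loops)\n")
  invisible(x)
}

#' Parse a secondary-structure (ss) file
#'
#' Reads the three-line-per-record ss dialect (header `>ref_id`, sequence,
#' aligned pairing string). Blank lines are ignored.
#'
#' @param path Path to an ss file, or a character vector of its lines.
#' @return Named list of `secondary_structure` objects.
#' @export
parse_ss_file <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else path
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L) {
    stop("ss file must contain header/sequence/pairing triplets",
         call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 3L)
  out <- list()
  for (i in idx) {
    if (!startsWith(lines[i], ">")) {
      stop("expected '>' header in ss record near line ", i, call. = FALSE)
    }
    ref_id <- sub("^>", "", trimws(lines[i]))
    out[[ref_id]] <- secondary_structure(ref_id, trimws(lines[i + 1L]),
                                         trimws(lines[i + 2L]))
  }
  out
}

#' Write secondary structures to an ss file
#'
#' @param structures Named list of `secondary_structure` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss_file <- function(structures, path) {
  lines <- unlist(lapply(structures, function(ss) {
    c(paste0(">", ss$ref_id), ss$sequence, ss$pairing)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Classify a fragment by its terminals on the mature reference
#'
#' `full` when both termini coincide with the reference, `five_prime` when
#' the fragment starts at base 1, `three_prime` when it ends at the last
#' base, `internal` otherwise. No positional tolerance is applied unless
#' `tolerance > 0`.
#'
#' @param start,end 1-based inclusive fragment coordinates (vectorized).
#' @param ref_length Reference length (recycled).
#' @param tolerance Allowed offset from the exact terminus (default 0).
#' @return Character vector of terminal classes.
#' @export
#' @examples
#' classify_terminal(c(1, 44, 20), c(33, 76, 55), 76)
classify_terminal <- function(start, end, ref_length, tolerance = 0L) {
  at5 <- start <= 1L + tolerance
  at3 <- end >= ref_length - tolerance
  dplyr::case_when(
    at5 & at3 ~ "full",
    at5 ~ "five_prime",
    at3 ~ "three_prime",
    TRUE ~ "internal"
  )
}

loop_at <- function(ss, pos) {
  if (is.na(pos) || pos < 1L || pos > ss$length) return(NA_character_)
  hit <- ss$loops$label[ss$loops$start <= pos & ss$loops$end >= pos]
  if (length(hit) == 0L) NA_character_ else hit[1L]
}

#' Map fragment boundaries onto tRNA loops and flag cleavage subtypes
#'
#' The 5' boundary of a fragment is the phosphodiester bond before `start`;
#' it lies "in a loop" when the adjacent upstream nucleotide (`start - 1`)
#' falls inside a loop interval. Likewise the 3' boundary uses position
#' `end`. Boundaries at the reference termini have no loop. Flags:
#' `tiRNA_half` for a 5' fragment ending in the anticodon loop or a 3'
#' fragment starting there (angiogenin-style anticodon cleavage);
#' `nitRNA_like` for an internal fragment with a boundary in the T loop.
#'
#' @param start,end 1-based fragment coordinates (vectorized).
#' @param ss A `secondary_structure`.
#' @return Tibble with `terminal_class`, `start_loop`, `end_loop`,
#'   `tiRNA_half`, `nitRNA_like`.
#' @export
label_cleavage <- function(start, end, ss) {
  stopifnot(inherits(ss, "secondary_structure"))
  cls <- classify_terminal(start, end, ss$length)
  start_loop <- vapply(ifelse(start > 1L, start - 1L, NA_integer_),
                       function(p) loop_at(ss, p), character(1))
  end_loop <- vapply(ifelse(end < ss$length, end, NA_integer_),
                     function(p) loop_at(ss, p), character(1))
  tibble(
    terminal_class = cls,
    start_loop = start_loop,
    end_loop = end_loop,
    tiRNA_half =
      (cls == "five_prime" & !is.na(end_loop) &
         end_loop == "anticodon_loop") |
      (cls == "three_prime" & !is.na(start_loop) &
         start_loop == "anticodon_loop"),
    nitRNA_like = cls == "internal" &
      ((!is.na(start_loop) & start_loop == "T_loop") |
         (!is.na(end_loop) & end_loop == "T_loop"))
  )
}

#' Classify tRNA fragments from annotation hits
#'
#' Joins annotated tRNA/Mt_tRNA hits with their secondary structures and
#' returns the per-fragment classification table.
#'
#' @param annotations Tibble with `sequence`, `ref_id`, `start`, `end`
#'   (e.g. from [annotate_hierarchical()], annotated rows only).
#' @param structures Named list of `secondary_structure` objects keyed by
#'   `ref_id`; hits on references without a usable structure get terminal
#'   classes but no loop labels.
#' @return Tibble: `sequence`, `ref_id`, `terminal_class`, `start_loop`,
#'   `end_loop`, `tiRNA_half`, `nitRNA_like`.
#' @export
classify_trf <- function(annotations, structures) {
  ann <- annotations[!is.na(annotations$ref_id), ]
  out <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    ss <- structures[[ann$ref_id[i]]]
    if (!is.null(ss) && ss$usable) {
      lab <- label_cleavage(ann$start[i], ann$end[i], ss)
    } else {
      ref_len <- if (!is.null(ss)) ss$length else NA_integer_
      lab <- tibble(
        terminal_class = classify_terminal(ann$start[i], ann$end[i],
                                           ref_len),
        start_loop = NA_character_, end_loop = NA_character_,
        tiRNA_half = NA, nitRNA_like = NA
      )
    }
    out[[i]] <- dplyr::bind_cols(
      tibble(sequence = ann$sequence[i], ref_id = ann$ref_id[i]), lab
    )
  }
  dplyr::bind_rows(out)
}

#' Classify rRNA fragments against mature subunit intervals
#'
#' Assigns each fragment on a precursor to the subunit whose interval
#' contains the fragment midpoint (`floor((start + end) / 2)`), or none when
#' the midpoint falls in a spacer. The terminal class is then computed
#' against that subunit's boundaries: starting at the subunit's first base
#' is `five_prime`, ending at its last is `three_prime`.
#'
#' @param fragments Tibble with `start`, `end` on the precursor coordinate
#'   system (other columns are carried through).
#' @param subunits Tibble with `subunit_id`, `start`, `end` (1-based
#'   inclusive, disjoint).
#' @return The input with `subunit_id` and `terminal_class` columns added
#'   (`NA` for fragments outside all subunits).
#' @export
classify_rrf <- function(fragments, subunits) {
  stopifnot(all(c("start", "end") %in% names(fragments)),
            all(c("subunit_id", "start", "end") %in% names(subunits)))
  o <- order(subunits$start)
  su <- subunits[o, ]
  if (nrow(su) > 1L && any(su$start[-1L] <= su$end[-nrow(su)])) {
    stop("subunit intervals overlap", call. = FALSE)
  }
  mid <- floor((fragments$start + fragments$end) / 2)
  idx <- rep(NA_integer_, length(mid))
  for (j in seq_len(nrow(su))) {
    inside <- mid >= su$start[j] & mid <= su$end[j]
    idx[inside] <- j
  }
  fragments$subunit_id <- su$subunit_id[idx]
  fragments$terminal_class <- NA_character_
  ok <- !is.na(idx)
  if (any(ok)) {
    at5 <- fragments$start[ok] == su$start[idx[ok]]
    at3 <- fragments$end[ok] == su$end[idx[ok]]
    fragments$terminal_class[ok] <- dplyr::case_when(
      at5 & at3 ~ "full",
      at5 ~ "five_prime",
      at3 ~ "three_prime",
      TRUE ~ "internal"
    )
  }
  fragments
}

#' Per-position cpm coverage profile of one reference
#'
#' Sums, at every reference position, the cpm of the fragments covering it.
#' With a fragments-by-samples cpm matrix the profile is the per-sample
#' mean.
#'
#' @param fragments Tibble with `start`, `end` (1-based inclusive, within
#'   the reference).
#' @param ref_length Reference length.
#' @param cpm Numeric vector (one value per fragment) or matrix (fragments
#'   x samples; the profile averages over samples). Default 1 per fragment
#'   (pure depth).
#' @return Tibble with `position` and `cpm`; attribute `n_fragments`.
#' @export
compute_coverage <- function(fragments, ref_length, cpm = NULL) {
  n <- nrow(fragments)
  if (is.null(cpm)) cpm <- rep(1, n)
  if (is.matrix(cpm)) {
    stopifnot(nrow(cpm) == n)
    cpm <- rowMeans(cpm)
  }
  stopifnot(length(cpm) == n)
  values <- rep(0, ref_length)
  for (i in seq_len(n)) {
    s <- max(1L, fragments$start[i]); e <- min(ref_length, fragments$end[i])
    if (s <= e) values[s:e] <- values[s:e] + cpm[i]
  }
  out <- tibble(position = seq_len(ref_length), cpm = values)
  attr(out, "n_fragments") <- n
  out
}

#' cpm-weighted terminal-class fractions per group
#'
#' For each group (e.g. method x sub-library), the cpm-weighted fractions of
#' five_prime / internal / three_prime fragments. Full-length fragments are
#' their own class and are excluded from the three-way fractions; their cpm
#' is reported alongside. Fractions sum to 1 per group; groups with no
#' fragment cpm are absent from the output.
#'
#' @param data Tibble with `terminal_class`, `cpm` and any grouping columns.
#' @param ... Grouping columns (tidy-select), e.g. `method, sublibrary`.
#' @return Tibble with the grouping columns, `five_prime`, `internal`,
#'   `three_prime` fraction columns and `full_cpm`.
#' @export
terminal_enrichment <- function(data, ...) {
  stopifnot(all(c("terminal_class", "cpm") %in% names(data)))
  grouped <- data %>%
    dplyr::group_by(...) %>%
    dplyr::summarise(
      five_prime = sum(.data$cpm[.data$terminal_class == "five_prime"]),
      internal = sum(.data$cpm[.data$terminal_class == "internal"]),
      three_prime = sum(.data$cpm[.data$terminal_class == "three_prime"]),
      full_cpm = sum(.data$cpm[.data$terminal_class == "full"]),
      .groups = "drop"
    )
  tot <- grouped$five_prime + grouped$internal + grouped$three_prime
  grouped <- grouped[tot > 0, ]
  tot <- tot[tot > 0]
  grouped$five_prime <- grouped$five_prime / tot
  grouped$internal <- grouped$internal / tot
  grouped$three_prime <- grouped$three_prime / tot
  grouped
}

#' Parse tRNA isodecoder families from reference ids
#'
#' Expects the `tRNA-<AminoAcid><Anticodon>-<n>` convention (e.g.
#' `tRNA-AspGUC-3` -> `AspGUC`); other dialects can supply their own capture
#' regex.
#'
#' @param ref_ids Character vector of tRNA reference ids.
#' @param pattern Regex whose first capture group is the isodecoder family.
#' @return Character vector of isodecoder families (`NA` when unmatched).
#' @export
#' @examples
#' isodecoder(c("tRNA-GlyGCC-1", "Mt_tRNA-SerUGA-2", "rRNA-1"))
isodecoder <- function(ref_ids,
                       pattern = "tRNA-([A-Za-z]{3}[A-Za-z]{3})-") {
  m <- regmatches(ref_ids, regexec(pattern, ref_ids))
  vapply(m, function(x) if (length(x) >= 2L) x[2L] else NA_character_,
         character(1))
}
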