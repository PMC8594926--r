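#' Read a FASTQ file into a tibble
#'
#' Parses standard 4-line FASTQ (Phred+33). Each record becomes one row;
#' qualities are kept as the raw Phred+33 string so that sequence and quality
#' always travel together.
#'
#' @param path Path to a FASTQ file (optionally gzip-compressed; any
#'   connection `readLines()` understands).
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(tibble(read_id = character(), sequence = character(),
                  quality = character()))
  }
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record starting at line ", (n %/% 4L) * 4L + 1L,
         " of '", path, "'", call. = FALSE)
  }
  idx <- seq(1L, n, by = 4L)
  head_ok <- startsWith(lines[idx], "@")
  if (!all(head_ok)) {
    stop("malformed FASTQ header at line ", idx[which(!head_ok)[1L]],
         " of '", path, "' (expected '@')", call. = FALSE)
  }
  plus_ok <- startsWith(lines[idx + 2L], "+")
  if (!all(plus_ok)) {
    stop("malformed FASTQ separator at line ", idx[which(!plus_ok)[1L]] + 2L,
         " of '", path, "' (expected '+')", call. = FALSE)
  }
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  len_ok <- nchar(seqs) == nchar(quals)
  if (!all(len_ok)) {
    stop("sequence/quality length mismatch at line ",
         idx[which(!len_ok)[1L]] + 3L, " of '", path, "'", call. = FALSE)
  }
  tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
    sequence = toupper(seqs),
    quality = quals
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads A tibble with columns `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  if (nrow(reads) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  out <- rbind(paste0("@", reads$read_id), reads$sequence, "+", reads$quality)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read a multi-FASTA file into a tibble
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `ref_id` (first whitespace-delimited token
#'   of the header) and `sequence` (uppercased, joined across wrapped
#'   lines).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  is_header <- startsWith(lines, ">")
  if (length(lines) > 0 && !is_header[1L]) {
    stop("FASTA file '", path, "' does not start with a header",
         call. = FALSE)
  }
  rec <- cumsum(is_header)
  headers <- sub("\\s.*$", "", sub("^>", "", lines[is_header]))
  seqs <- vapply(split(lines[!is_header], rec[!is_header]),
                 function(x) toupper(paste(x, collapse = "")),
                 character(1), USE.NAMES = FALSE)
  tibble(ref_id = headers, sequence = seqs)
}

#' Convert a Phred+33 quality string to integer scores
#'
#' @param quality Character vector of Phred+33 strings.
#' @return A list of integer vectors, one per string.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) {
    if (nchar(q) == 0L) integer() else utf8ToInt(q) - 33L
  })
}

# Phred integer scores -> Phred+33 string
phred_string <- function(scores) {
  if (length(scores) == 0L) return("")
  intToUtf8(pmin(pmax(scores, 0L), 93L) + 33L)
}
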