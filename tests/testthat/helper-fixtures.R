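# Shared fixtures and pure-R oracles. Oracles deliberately avoid the
# package's C++ kernels so implementation and check are independent routes.

ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACAT"
TAG <- "TGGCAACGATC"

test_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_reference_bundle(
        42, c(miRNA = 6, piRNA = 6, tRNA = 4, Mt_tRNA = 2, rRNA = 3,
              MT_rRNA = 2, other_sncRNA = 3))
    }
    cache
  }
})

one_read <- function(sequence, quality = NULL, q = 40L) {
  if (is.null(quality)) {
    quality <- strrep(intToUtf8(q + 33L), nchar(sequence))
  }
  tibble::tibble(read_id = "r1", sequence = sequence, quality = quality)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force Hamming scan over all offsets (independent of the C++ path).
oracle_hamming <- function(query, reference, max_mm) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  out <- list()
  if (length(q) > length(r)) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  for (i in seq_len(length(r) - length(q) + 1L)) {
    win <- r[i:(i + length(q) - 1L)]
    mm <- sum(win != q | win == "N" | q == "N")
    if (mm <= max_mm) out[[length(out) + 1L]] <- c(i, mm)
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], mismatches = m[, 2])
}

# Brute-force adapter cut over all (position, prefix-length) pairs, with the
# same ranking (longest match, then leftmost) and fixed-point iteration.
oracle_adapter_cut <- function(sequence, adapter, min_overlap,
                               max_error_rate) {
  ad <- strsplit(adapter, "")[[1]]
  first_pass_found <- FALSE
  pass_one <- TRUE
  repeat {
    s <- strsplit(sequence, "")[[1]]
    len <- length(s)
    cands <- list()
    if (len >= length(ad)) {
      for (i in seq_len(len - length(ad) + 1L)) {
        cands[[length(cands) + 1L]] <- c(i, length(ad))
      }
    }
    if (min(length(ad), len) >= min_overlap) {
      for (l in seq(min_overlap, min(length(ad), len))) {
        cands[[length(cands) + 1L]] <- c(len - l + 1L, l)
      }
    }
    qual <- list()
    for (cand in cands) {
      i <- cand[1]; l <- cand[2]
      win <- s[i:(i + l - 1L)]
      pat <- ad[1:l]
      mm <- sum(win != pat | win == "N" | pat == "N")
      if (mm <= floor(max_error_rate * l)) {
        qual[[length(qual) + 1L]] <- c(i, l)
      }
    }
    if (length(qual) == 0L) break
    m <- do.call(rbind, qual)
    m <- m[order(-m[, 2], m[, 1]), , drop = FALSE]
    if (pass_one) first_pass_found <- TRUE
    pass_one <- FALSE
    sequence <- substr(sequence, 1L, m[1, 1] - 1L)
    if (nchar(sequence) == 0L) break
  }
  if (!first_pass_found) -1L else nchar(sequence)
}

# Counts table straight from a truth table (multiplicity of each insert).
truth_multiplicities <- function(truth, references) {
  ref_seq <- references$sequence[match(truth$source_ref, references$ref_id)]
  insert <- substr(ref_seq, truth$insert_start, truth$insert_end)
  as.data.frame(table(insert), stringsAsFactors = FALSE)
}
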