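# Seeded fixture generation: biotype reference bundles with tRNA secondary
# structures, and simulated tagged/untagged reads with a ground-truth table.

DEFAULT_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACAT"
DEFAULT_TAG <- "TGGCAACGATC"

ISODECODERS <- c("AspGUC", "GlyGCC", "LysCUU", "ArgCCU", "HisGUG",
                 "ValAAC", "GluCUC", "PheGAA", "SerUGA", "LeuCAA")

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Simulation parameters for the read simulator
#'
#' Bundles every knob of [simulate_reads()] with validation. Defaults emulate
#' a 75-cycle single-end run on a 5'XP library: per-base substitution rate
#' 0.001, a tagged fraction of 0.15 (the middle of the 10--20% range such
#' libraries show), Phred qualities around 35, and a small admixture of
#' low-quality reads so the quality filter has work to do.
#'
#' @param seed Integer seed; identical parameters give byte-identical output.
#' @param n_reads Number of reads to simulate.
#' @param p_tagged Probability that a read carries the 5' tag.
#' @param error_rate Per-base substitution probability in the insert.
#' @param adapter 3' adapter sequence appended after the insert.
#' @param tag 5' tag sequence prepended to tagged reads.
#' @param read_length Instrument read length; assembled reads are padded with
#'   random bases and truncated to this length.
#' @param qual_mean,qual_sd Per-base Phred score distribution (clamped to
#'   \[2, 40\]).
#' @param low_qual_frac Fraction of reads drawn instead from the low-quality
#'   distribution, exercising the whole-read quality filter.
#' @param low_qual_mean Mean Phred score of low-quality reads.
#' @param terminal_props Length-3 numeric (five_prime, internal, three_prime)
#'   giving the designed terminal-class mix for tRNA/rRNA fragments.
#' @param loop_frac For tRNA fragments, the probability that a designed
#'   terminal/internal fragment is loop-anchored (tiRNA-half or nitRNA-like).
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(seed = 1L,
                              n_reads = 10000L,
                              p_tagged = 0.15,
                              error_rate = 0.001,
                              adapter = DEFAULT_ADAPTER,
                              tag = DEFAULT_TAG,
                              read_length = 75L,
                              qual_mean = 35,
                              qual_sd = 3,
                              low_qual_frac = 0.02,
                              low_qual_mean = 10,
                              terminal_props = c(five_prime = 0.6,
                                                 internal = 0.1,
                                                 three_prime = 0.3),
                              loop_frac = 0.5) {
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    n_reads >= 0, p_tagged >= 0, p_tagged <= 1,
    error_rate >= 0, error_rate < 1,
    nchar(adapter) > 0, nchar(tag) > 0,
    read_length >= 20,
    low_qual_frac >= 0, low_qual_frac <= 1,
    length(terminal_props) == 3L, all(terminal_props >= 0),
    sum(terminal_props) > 0,
    loop_frac >= 0, loop_frac <= 1
  )
  structure(
    list(seed = as.integer(seed), n_reads = as.integer(n_reads),
         p_tagged = p_tagged, error_rate = error_rate,
         adapter = toupper(adapter), tag = toupper(tag),
         read_length = as.integer(read_length),
         qual_mean = qual_mean, qual_sd = qual_sd,
         low_qual_frac = low_qual_frac, low_qual_mean = low_qual_mean,
         terminal_props = terminal_props / sum(terminal_props),
         loop_frac = loop_frac),
    class = "simulation_params"
  )
}

# Cloverleaf tRNA with acceptor stem, D arm, anticodon arm, a short paired
# variable arm and T arm, plus an NCCA-style tail. The D-loop length is drawn
# from 13:16, which keeps the anticodon loop astride the sequence midpoint.
build_trna <- function(ref_id, anticodon_rna) {
  d <- sample(13:16, 1L)
  seg <- function(len, char) strrep(char, len)
  stem <- function(len) {
    s5 <- random_bases(len)
    list(s5 = s5, s3 = revcomp(s5))
  }
  acc <- stem(7L); ds <- stem(4L); as_ <- stem(5L); vs <- stem(3L)
  ts <- stem(5L)
  acloop <- strsplit(random_bases(7L), "")[[1]]
  acloop[3:5] <- strsplit(chartr("U", "T", anticodon_rna), "")[[1]]
  sequence <- paste0(
    acc$s5, random_bases(2L), ds$s5, random_bases(d), ds$s3,
    random_bases(1L), as_$s5, paste(acloop, collapse = ""), as_$s3,
    vs$s5, random_bases(3L), vs$s3,
    ts$s5, random_bases(7L), ts$s3, acc$s3,
    paste0(random_bases(1L), "CCA")
  )
  pairing <- paste0(
    seg(7L, ">"), seg(2L, "."), seg(4L, ">"), seg(d, "."), seg(4L, "<"),
    seg(1L, "."), seg(5L, ">"), seg(7L, "."), seg(5L, "<"),
    seg(3L, ">"), seg(3L, "."), seg(3L, "<"),
    seg(5L, ">"), seg(7L, "."), seg(5L, "<"), seg(7L, "<"), seg(4L, ".")
  )
  secondary_structure(ref_id, sequence, pairing)
}

#' Generate a seeded reference bundle
#'
#' Builds random but structurally plausible references per biotype: miRNA
#' around 22 nt, piRNA 26--30 nt with an 80% U start-bias, cloverleaf
#' tRNA/Mt_tRNA of 85--88 nt with a paired secondary structure record each,
#' and rRNA/MT_rRNA/other_sncRNA of increasing length. The same seed always
#' yields the same bundle.
#'
#' @param seed Integer seed.
#' @param counts_per_biotype Named integer vector; names must be drawn from
#'   `biotype_priority()$biotype`, values positive.
#' @param avoid Motifs that must not occur in any reference (default: the
#'   3' adapter's minimum-overlap prefix). A reference containing it would
#'   make simulated inserts unrecoverable — the trimmer would, correctly,
#'   clip the genuine reference bases as adapter — so offending draws are
#'   redrawn.
#' @return A list with `references` (tibble: `biotype`, `ref_id`, `sequence`)
#'   and `structures` (named list of `secondary_structure` objects, one per
#'   tRNA/Mt_tRNA reference).
#' @export
#' @examples
#' bundle <- make_reference_bundle(1, c(miRNA = 5, tRNA = 3))
#' bundle$references
make_reference_bundle <- function(seed, counts_per_biotype,
                                  avoid = substr(DEFAULT_ADAPTER, 1L, 5L)) {
  if (is.null(names(counts_per_biotype)) ||
      !all(names(counts_per_biotype) %in% BIOTYPES)) {
    stop("counts_per_biotype must be named with biotypes among: ",
         paste(BIOTYPES, collapse = ", "), call. = FALSE)
  }
  if (any(counts_per_biotype <= 0)) {
    stop("counts_per_biotype values must be positive", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    refs <- list()
    structures <- list()
    for (bt in names(counts_per_biotype)) {
      n <- as.integer(counts_per_biotype[[bt]])
      for (i in seq_len(n)) {
        repeat {
          if (bt %in% c("tRNA", "Mt_tRNA")) {
            iso <- sample(ISODECODERS, 1L)
            ref_id <- sprintf("%s-%s-%d", bt, iso, i)
            ss <- build_trna(ref_id, substr(iso, 4L, 6L))
            seqn <- ss$sequence
          } else {
            ss <- NULL
            len <- switch(bt,
              miRNA = max(20L, min(24L, round(rnorm(1, 22, 1)))),
              piRNA = sample(26:30, 1L),
              rRNA = sample(100:180, 1L),
              MT_rRNA = sample(100:150, 1L),
              other_sncRNA = sample(50:90, 1L)
            )
            seqn <- random_bases(len)
            if (bt == "piRNA" && runif(1) < 0.8) {
              substr(seqn, 1L, 1L) <- "T"
            }
            ref_id <- sprintf("%s-%d", bt, i)
          }
          if (!any(vapply(avoid, grepl, logical(1), x = seqn,
                          fixed = TRUE))) break
        }
        if (!is.null(ss)) structures[[ref_id]] <- ss
        refs[[length(refs) + 1L]] <- tibble(
          biotype = bt, ref_id = ref_id, sequence = seqn
        )
      }
    }
    list(references = dplyr::bind_rows(refs), structures = structures)
  })
}

#' Synthetic pre-rRNA precursor with mature subunit intervals
#'
#' A scaled-down 45S-style precursor: spacer-separated 18S-, 5.8S-, 2S- and
#' 28S-like subunits on one coordinate system, for exercising rRNA fragment
#' classification against subunit boundaries.
#'
#' @param seed Integer seed.
#' @param subunit_lengths Named lengths of the mature subunits, 5' to 3'.
#' @param spacer Length of the spacers flanking/separating subunits.
#' @return A list with `sequence` and `subunits` (tibble: `subunit_id`,
#'   `start`, `end`, 1-based inclusive).
#' @export
make_rrna_precursor <- function(seed,
                                subunit_lengths = c(`18S` = 150, `5.8S` = 80,
                                                    `2S` = 30, `28S` = 180),
                                spacer = 20L) {
  withr::with_seed(as.integer(seed), {
    pos <- spacer
    rows <- list()
    pieces <- random_bases(spacer)
    for (su in names(subunit_lengths)) {
      len <- as.integer(subunit_lengths[[su]])
      rows[[su]] <- tibble(subunit_id = su, start = pos + 1L, end = pos + len)
      pieces <- paste0(pieces, random_bases(len), random_bases(spacer))
      pos <- pos + len + spacer
    }
    list(sequence = pieces, subunits = dplyr::bind_rows(rows))
  })
}

# Positions of a structure not inside any labelled loop (used to place
# non-loop-anchored breakpoints).
non_loop_positions <- function(ss, from, to) {
  if (to < from) return(integer())
  pos <- seq(from, to)
  in_loop <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(ss$loops))) {
    in_loop <- in_loop | (pos >= ss$loops$start[i] & pos <= ss$loops$end[i])
  }
  pos[!in_loop]
}

loop_interval <- function(ss, label) {
  row <- ss$loops[ss$loops$label == label, ]
  if (nrow(row) == 0L) return(NULL)
  seq(row$start[1L], row$end[1L])
}

# sample() with the size-1 gotcha removed
sample1 <- function(x) x[sample.int(length(x), 1L)]

# Draw insert coordinates and designed labels for one read.
draw_insert <- function(biotype, ref_len, ss, params) {
  cls <- NA_character_; tirna <- NA; nitrna <- NA
  if (biotype %in% c("miRNA", "piRNA")) {
    start <- 1L; end <- ref_len
  } else if (biotype %in% c("tRNA", "Mt_tRNA") && !is.null(ss)) {
    cls <- sample(c("five_prime", "internal", "three_prime"), 1L,
                  prob = params$terminal_props)
    ac <- loop_interval(ss, "anticodon_loop")
    tl <- loop_interval(ss, "T_loop")
    anchored <- runif(1) < params$loop_frac
    # insert lengths capped at 48 nt so a tagged read still shows >= 5 nt of
    # adapter within the read length
    if (cls == "five_prime") {
      start <- 1L
      end <- if (anchored) sample1(ac) else sample1(
        non_loop_positions(ss, 20L, min(48L, ref_len - 25L)))
      tirna <- anchored; nitrna <- FALSE
    } else if (cls == "three_prime") {
      end <- ref_len
      start <- if (anchored) sample1(ac) + 1L else sample1(
        non_loop_positions(ss, max(25L, ref_len - 48L), ref_len - 20L) + 1L)
      tirna <- anchored; nitrna <- FALSE
    } else {
      if (anchored) {
        start <- sample1(ac) + 1L
        end <- sample1(tl)
      } else {
        start <- sample1(non_loop_positions(ss, 5L, 25L)) + 1L
        end <- sample1(non_loop_positions(ss, start + 15L,
                                          min(start + 45L, ref_len - 3L)))
      }
      tirna <- FALSE; nitrna <- anchored
    }
  } else if (biotype %in% c("rRNA", "MT_rRNA")) {
    cls <- sample(c("five_prime", "internal", "three_prime"), 1L,
                  prob = params$terminal_props)
    len <- sample(20:40, 1L)
    if (cls == "five_prime") {
      start <- 1L; end <- len
    } else if (cls == "three_prime") {
      start <- ref_len - len + 1L; end <- ref_len
    } else {
      start <- sample(2:(ref_len - len), 1L); end <- start + len - 1L
    }
    tirna <- FALSE; nitrna <- FALSE
  } else {
    len <- sample(20:35, 1L)
    start <- sample.int(ref_len - len + 1L, 1L)
    end <- start + len - 1L
  }
  list(start = as.integer(start), end = as.integer(end),
       terminal_class = cls, tirna = tirna, nitrna = nitrna)
}

mutate_insert <- function(insert, error_rate) {
  if (error_rate <= 0) return(list(seq = insert, n_err = 0L))
  bases <- strsplit(insert, "")[[1]]
  hit <- which(runif(length(bases)) < error_rate)
  for (i in hit) {
    bases[i] <- sample1(setdiff(c("A", "C", "G", "T"), bases[i]))
  }
  list(seq = paste(bases, collapse = ""), n_err = length(hit))
}

#' Simulate tagged/untagged small RNA reads with ground truth
#'
#' Assembles each read as `[tag] + insert + adapter + random tail`, truncated
#' to the configured read length, where the insert is a substring of a bundle
#' reference chosen by biotype-specific rules (full mature miRNA/piRNA;
#' loop-anchored tRNA fragments; terminal-stratified rRNA fragments). Phred
#' qualities are drawn per base; a configurable fraction of reads is
#' low-quality throughout. The truth table records, per read, the source
#' reference, insert coordinates, tag status, substitution count and — for
#' tRNA/rRNA fragments — the designed terminal class and loop-cleavage flags.
#'
#' @param bundle A bundle from [make_reference_bundle()], or any list with
#'   `references` (tibble with `biotype`, `ref_id`, `sequence`) and
#'   `structures` (named list of `secondary_structure`).
#' @param params A [simulation_params()] object.
#' @param out_fastq,out_truth Optional paths; when given, the FASTQ and the
#'   7-column truth TSV (`read_id`, `source_ref`, `biotype`, `insert_start`,
#'   `insert_end`, `tagged`, `n_seq_errors`) are written there.
#' @return A list with `reads` (tibble: `read_id`, `sequence`, `quality`) and
#'   `truth` (tibble; includes the designed `terminal_class`, `tiRNA_half`,
#'   `nitRNA_like` columns in memory).
#' @export
simulate_reads <- function(bundle, params = simulation_params(),
                           out_fastq = NULL, out_truth = NULL) {
  refs <- bundle$references
  stopifnot(nrow(refs) > 0)
  withr::with_seed(params$seed, {
    n <- params$n_reads
    ref_idx <- if (n > 0) sample.int(nrow(refs), n, replace = TRUE) else integer()
    tagged <- runif(n) < params$p_tagged
    lowq <- runif(n) < params$low_qual_frac
    ref_ids <- refs$ref_id[ref_idx]
    biotypes <- refs$biotype[ref_idx]
    ref_seqs <- refs$sequence[ref_idx]
    sequence <- character(n); quality <- character(n)
    ins_start <- integer(n); ins_end <- integer(n); n_err <- integer(n)
    term_cls <- character(n); tirna <- logical(n); nitrna <- logical(n)
    for (i in seq_len(n)) {
      ss <- bundle$structures[[ref_ids[i]]]
      ins <- draw_insert(biotypes[i], nchar(ref_seqs[i]), ss, params)
      if (ins$end < ins$start) stop("degenerate insert", call. = FALSE)
      mut <- mutate_insert(substr(ref_seqs[i], ins$start, ins$end),
                           params$error_rate)
      core <- paste0(if (tagged[i]) params$tag else "", mut$seq,
                     params$adapter)
      pad <- params$read_length - nchar(core)
      full <- if (pad > 0) paste0(core, random_bases(pad)) else
        substr(core, 1L, params$read_length)
      mu <- if (lowq[i]) params$low_qual_mean else params$qual_mean
      q <- round(rnorm(nchar(full), mu, params$qual_sd))
      sequence[i] <- full
      quality[i] <- phred_string(pmin(pmax(q, 2L), 40L))
      ins_start[i] <- ins$start; ins_end[i] <- ins$end
      n_err[i] <- mut$n_err
      term_cls[i] <- ins$terminal_class
      tirna[i] <- ins$tirna; nitrna[i] <- ins$nitrna
    }
    read_id <- if (n > 0) sprintf("sim_%06d", seq_len(n)) else character()
    reads <- tibble(read_id = read_id, sequence = sequence,
                    quality = quality)
    truth <- tibble(
      read_id = read_id, source_ref = ref_ids, biotype = biotypes,
      insert_start = ins_start, insert_end = ins_end,
      tagged = tagged, n_seq_errors = n_err,
      terminal_class = term_cls, tiRNA_half = tirna, nitRNA_like = nitrna
    )
    if (!is.null(out_fastq)) write_fastq(reads, out_fastq)
    if (!is.null(out_truth)) {
      readr::write_tsv(truth[, c("read_id", "source_ref", "biotype",
                                 "insert_start", "insert_end", "tagged",
                                 "n_seq_errors")], out_truth)
    }
    list(reads = reads, truth = truth)
  })
}

#' Write reference bundle FASTA and secondary-structure files
#'
#' One multi-FASTA per biotype plus a single ss file covering all structured
#' references.
#'
#' @param bundle A bundle from [make_reference_bundle()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  for (bt in unique(bundle$references$biotype)) {
    sub <- bundle$references[bundle$references$biotype == bt, ]
    path <- file.path(dir, paste0(bt, ".fa"))
    writeLines(as.vector(rbind(paste0(">", sub$ref_id), sub$sequence)), path)
    paths[bt] <- path
  }
  if (length(bundle$structures) > 0) {
    path <- file.path(dir, "structures.ss")
    write_ss_file(bundle$structures, path)
    paths["ss"] <- path
  }
  invisible(paths)
}
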