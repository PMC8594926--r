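# Descriptive analytics: biotype composition, size distributions,
# first-nucleotide bias, between-method fold differences, correlation
# clustering and saturation-curve regression.

cpm_long <- function(cpm_table) {
  stopifnot(inherits(cpm_table, "cpm_table"))
  tidyr::pivot_longer(cpm_table$counts, -"sequence",
                      names_to = "sample_id", values_to = "cpm")
}

join_biotype <- function(long, annotations) {
  ann <- annotations[, c("sequence", "biotype")]
  long <- dplyr::left_join(long, ann, by = "sequence")
  long$biotype[is.na(long$biotype)] <- "unannotated"
  long
}

#' Per-sample biotype composition of cpm
#'
#' Fraction of each sample's cpm attributed to every biotype, with
#' unannotated sequences as their own class; percentages sum to 100 per
#' sample.
#'
#' @param cpm_table A `cpm_table`.
#' @param annotations Tibble from [annotate_hierarchical()].
#' @return Tibble with `sample_id`, `biotype`, `cpm`, `percent`.
#' @export
biotype_composition <- function(cpm_table, annotations) {
  join_biotype(cpm_long(cpm_table), annotations) %>%
    dplyr::group_by(.data$sample_id, .data$biotype) %>%
    dplyr::summarise(cpm = sum(.data$cpm), .groups = "drop_last") %>%
    dplyr::mutate(percent = .data$cpm / sum(.data$cpm) * 100) %>%
    dplyr::ungroup()
}

#' Mean cpm per biotype and fragment length
#'
#' For every biotype and insert length, the mean over samples of the summed
#' cpm of sequences of that length; total over all cells equals the mean
#' per-sample total cpm.
#'
#' @param cpm_table A `cpm_table`.
#' @param annotations Annotation tibble; sequences absent from it count as
#'   `unannotated`.
#' @return Tibble with `biotype`, `length`, `mean_cpm`.
#' @export
size_distribution <- function(cpm_table, annotations) {
  join_biotype(cpm_long(cpm_table), annotations) %>%
    dplyr::mutate(length = nchar(.data$sequence)) %>%
    dplyr::group_by(.data$biotype, .data$length, .data$sample_id) %>%
    dplyr::summarise(cpm = sum(.data$cpm), .groups = "drop") %>%
    # a sequence length absent from one sample still contributes 0 cpm there
    dplyr::group_by(.data$biotype, .data$length) %>%
    dplyr::summarise(
      mean_cpm = sum(.data$cpm) / length(sample_ids(cpm_table)),
      .groups = "drop"
    )
}

#' cpm-weighted first-nucleotide bias per biotype
#'
#' The cpm-weighted fraction of A/C/G/U at a given read position per
#' biotype, reported in the RNA alphabet (T as U). N-weight is excluded
#' from the four fractions (they sum to 1) and reported separately.
#'
#' @param cpm_table A `cpm_table`.
#' @param annotations Annotation tibble.
#' @param position 1-based position (default 1).
#' @return Tibble with `biotype`, `base` (A/C/G/U), `fraction`, `n_share`.
#' @export
first_nt_bias <- function(cpm_table, annotations, position = 1L) {
  long <- join_biotype(cpm_long(cpm_table), annotations)
  long$base <- chartr("T", "U", substr(long$sequence, position, position))
  long <- long[long$base != "", ]
  per_base <- long %>%
    dplyr::group_by(.data$biotype, .data$base) %>%
    dplyr::summarise(cpm = sum(.data$cpm), .groups = "drop")
  per_base %>%
    dplyr::group_by(.data$biotype) %>%
    dplyr::group_modify(function(df, key) {
      n_cpm <- sum(df$cpm[df$base == "N"])
      acgu <- sum(df$cpm[df$base != "N"])
      out <- tibble(base = c("A", "C", "G", "U"))
      out$fraction <- vapply(out$base, function(b) {
        if (acgu > 0) sum(df$cpm[df$base == b]) / acgu else NA_real_
      }, numeric(1), USE.NAMES = FALSE)
      out$n_share <- if (acgu + n_cpm > 0) n_cpm / (acgu + n_cpm) else NA_real_
      out
    }) %>%
    dplyr::ungroup()
}

#' Per-sequence log2 fold difference between two sample groups
#'
#' `log2fc = log2((mean_cpm_A + pc) / (mean_cpm_B + pc))` with a pseudocount
#' so sequences absent from one group get a finite, abundance-dependent
#' fold change (the >20-fold tails of method comparisons). Direction is by
#' sign; an optional threshold widens the `unchanged` band.
#'
#' @param cpm_table A `cpm_table`.
#' @param group_a,group_b Character vectors of sample ids.
#' @param pseudocount Added to both means (default 1 cpm).
#' @param threshold Absolute log2fc below or at which a sequence counts as
#'   `unchanged` (default 0: sign-only).
#' @return Tibble with `sequence`, `mean_cpm_a`, `mean_cpm_b`, `log2fc`,
#'   `direction`. Use [fold_change_percentages()] for the up/down summary.
#' @export
log2_fold <- function(cpm_table, group_a, group_b, pseudocount = 1,
                      threshold = 0) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  stopifnot(all(c(group_a, group_b) %in% sample_ids(cpm_table)))
  tb <- cpm_table$counts
  mean_a <- rowMeans(as.matrix(tb[, group_a, drop = FALSE]))
  mean_b <- rowMeans(as.matrix(tb[, group_b, drop = FALSE]))
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  tibble(
    sequence = tb$sequence,
    mean_cpm_a = mean_a,
    mean_cpm_b = mean_b,
    log2fc = log2fc,
    direction = dplyr::case_when(
      log2fc > threshold ~ "up",
      log2fc < -threshold ~ "down",
      TRUE ~ "unchanged"
    )
  )
}

#' Percent up-/down-regulated sequences of a fold-change table
#'
#' @param fc Tibble from [log2_fold()].
#' @return One-row tibble with `pct_up`, `pct_down`, `pct_unchanged`,
#'   `n_sequences`.
#' @export
fold_change_percentages <- function(fc) {
  n <- nrow(fc)
  tibble(
    pct_up = 100 * sum(fc$direction == "up") / n,
    pct_down = 100 * sum(fc$direction == "down") / n,
    pct_unchanged = 100 * sum(fc$direction == "unchanged") / n,
    n_sequences = n
  )
}

#' Sample correlation with hierarchical clustering
#'
#' Pairwise correlation (default Pearson on log2(cpm + 1)) between samples,
#' with average-linkage hierarchical clustering on the 1 - r distance.
#'
#' @param cpm_table A `cpm_table` with at least two samples.
#' @param method Correlation coefficient: `"pearson"` or `"spearman"`.
#' @param linkage Linkage passed to [stats::hclust()].
#' @param log_transform Apply log2(cpm + 1) first (default TRUE; ignored for
#'   Spearman, which is rank-based anyway).
#' @return A list of class `correlation_cluster` with `correlation` (matrix),
#'   `hclust` and `leaf_order` (sample ids in dendrogram order).
#' @export
correlation_cluster <- function(cpm_table,
                                method = c("pearson", "spearman"),
                                linkage = "average",
                                log_transform = TRUE) {
  method <- match.arg(method)
  ids <- sample_ids(cpm_table)
  if (length(ids) < 2L) stop("need at least two samples", call. = FALSE)
  m <- as.matrix(cpm_table$counts[, ids, drop = FALSE])
  if (log_transform && method == "pearson") m <- log2(m + 1)
  constant <- apply(m, 2L, function(v) max(v) == min(v))
  if (any(constant)) {
    stop("correlation undefined for constant sample(s): ",
         paste(ids[constant], collapse = ", "), call. = FALSE)
  }
  r <- cor(m, method = method)
  hc <- hclust(as.dist(1 - r), method = linkage)
  structure(
    list(correlation = r, hclust = hc, leaf_order = ids[hc$order]),
    class = "correlation_cluster"
  )
}

#' @export
print.correlation_cluster <- function(x, ...) {
  cat("<correlation_cluster>", ncol(x$correlation), "samples\n")
  cat("  leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' Saturation analysis of one sample with asymptotic regression
#'
#' Subsamples the reads of one sample without replacement at a grid of
#' depths, counts the distinct sequences reaching `threshold` copies at each
#' depth (averaged over replicates), and fits the asymptotic regression
#' `richness(d) = Asym + (R0 - Asym) * exp(-exp(lrc) * d)` by nonlinear
#' least squares with the self-starting `SSasymp` model. A saturated library
#' flattens well below the fitted asymptote gain.
#'
#' @param reads Character vector of read sequences (one element per read),
#'   or a tibble with a `sequence` column.
#' @param fractions Subsampling fractions in (0, 1].
#' @param threshold Copies required for a sequence to count as detected.
#' @param n_reps Replicate subsamples per fraction (averaged).
#' @param seed Integer seed for the subsampling.
#' @return An object of class `saturation_fit`: list with `data` (tibble
#'   `fraction`, `depth`, `richness`), `Asym`, `R0`, `lrc`, `fitted`,
#'   `converged`, `seed`. `tidy()` gives the parameters, `glance()` a
#'   one-row summary, `autoplot()` the curve.
#' @export
saturation_curve <- function(reads, fractions = seq(0.1, 1, by = 0.1),
                             threshold = 1L, n_reps = 3L, seed = 1L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  stopifnot(length(reads) > 0, all(fractions > 0), all(fractions <= 1))
  n <- length(reads)
  richness_at <- function(sub) {
    sum(table(sub) >= threshold)
  }
  pts <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(sort(unique(fractions)), function(f) {
      depth <- max(1L, round(f * n))
      rich <- if (depth >= n) {
        richness_at(reads)
      } else {
        mean(vapply(seq_len(n_reps), function(r) {
          richness_at(reads[sample.int(n, depth)])
        }, numeric(1)))
      }
      tibble(fraction = f, depth = depth, richness = rich)
    })
  })
  # a perfectly flat curve (e.g. a single-sequence library) has no
  # information about the rate; report the exact degenerate solution
  if (max(pts$richness) - min(pts$richness) < .Machine$double.eps^0.5) {
    return(structure(
      list(data = pts, Asym = pts$richness[1L], R0 = pts$richness[1L],
           lrc = -Inf, fitted = pts$richness, converged = TRUE,
           seed = as.integer(seed)),
      class = "saturation_fit"
    ))
  }
  fit <- tryCatch(
    nls(richness ~ SSasymp(depth, Asym, R0, lrc), data = pts),
    error = function(e) NULL
  )
  if (is.null(fit) && requireNamespace("minpack.lm", quietly = TRUE)) {
    start <- list(Asym = max(pts$richness) * 1.05,
                  R0 = pts$richness[1L],
                  lrc = log(1 / max(pts$depth)))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        richness ~ Asym + (R0 - Asym) * exp(-exp(lrc) * depth),
        data = pts, start = start),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    out <- list(data = pts, Asym = NA_real_, R0 = NA_real_, lrc = NA_real_,
                fitted = rep(NA_real_, nrow(pts)), converged = FALSE,
                seed = as.integer(seed))
  } else {
    cf <- coef(fit)
    out <- list(data = pts, Asym = unname(cf["Asym"]),
                R0 = unname(cf["R0"]), lrc = unname(cf["lrc"]),
                fitted = as.numeric(predict(fit, newdata = pts)),
                converged = TRUE, seed = as.integer(seed))
  }
  structure(out, class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("<saturation_fit>\n")
  if (x$converged) {
    cat(sprintf("  Asym = %.1f, R0 = %.1f, lrc = %.3f\n",
                x$Asym, x$R0, x$lrc))
  } else {
    cat("  fit did not converge; raw points only\n")
  }
  cat(sprintf("  %d depths, max richness %.1f\n", nrow(x$data),
              max(x$data$richness)))
  invisible(x)
}

#' @rdname saturation_curve
#' @param x A `saturation_fit`.
#' @param ... Unused.
#' @export
tidy.saturation_fit <- function(x, ...) {
  tibble(term = c("Asym", "R0", "lrc"),
         estimate = c(x$Asym, x$R0, x$lrc))
}

#' @rdname saturation_curve
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble(
    Asym = x$Asym, R0 = x$R0, lrc = x$lrc,
    converged = x$converged,
    max_richness = max(x$data$richness),
    max_depth = max(x$data$depth),
    seed = x$seed
  )
}
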