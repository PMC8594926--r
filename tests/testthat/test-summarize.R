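make_cpm <- function(counts, totals = NULL) {
  ids <- names(counts)[-1]
  if (is.null(totals)) totals <- setNames(rep(1e6, length(ids)), ids)
  tab <- fivexp:::new_seq_count_table(
    counts, tibble::tibble(sample_id = ids), totals)
  normalize_cpm(tab)
}

test_that("size distributions conserve cpm and find designed modes", {
  cpm <- make_cpm(tibble::tibble(
    sequence = c(strrep("A", 22)), s1 = 50L, s2 = 50L))
  ann <- tibble::tibble(sequence = strrep("A", 22), biotype = "miRNA")
  sizes <- size_distribution(cpm, ann)
  expect_equal(nrow(sizes), 1)
  expect_equal(sizes$length, 22)
  expect_equal(sizes$mean_cpm, 50)

  # conservation: totals over cells equal the mean per-sample total cpm
  bundle <- test_bundle()
  sim <- simulate_reads(bundle, simulation_params(seed = 71,
                                                  n_reads = 800))
  pp <- preprocess_reads(sim$reads)
  tab <- count_unique(dplyr::transmute(pp$reads, sample_id = sublibrary,
                                       sequence = sequence))
  cpm2 <- normalize_cpm(tab)
  ann2 <- annotate_hierarchical(tab$counts$sequence, bundle$references)
  sizes2 <- size_distribution(cpm2, ann2)
  expect_equal(sum(sizes2$mean_cpm), 1e6, tolerance = 1e-9)
  # miRNA inserts are drawn around 22 nt: the modal bin sits there
  mirna <- sizes2[sizes2$biotype == "miRNA", ]
  expect_true(abs(mirna$length[which.max(mirna$mean_cpm)] - 22) <= 1)
})

test_that("first-nucleotide bias is cpm-weighted and reported as RNA", {
  cpm <- make_cpm(tibble::tibble(
    sequence = c("TTTAA", "TCCCC"), s1 = c(10L, 10L)))
  ann <- tibble::tibble(sequence = c("TTTAA", "TCCCC"),
                        biotype = c("piRNA", "piRNA"))
  bias <- first_nt_bias(cpm, ann)
  expect_equal(bias$fraction[bias$base == "U"], 1.0)
  expect_equal(sum(bias$fraction), 1.0)

  cpm <- make_cpm(tibble::tibble(
    sequence = c("TAAAA", "ACCCC"), s1 = c(10L, 10L)))
  ann <- tibble::tibble(sequence = c("TAAAA", "ACCCC"),
                        biotype = c("piRNA", "piRNA"))
  bias <- first_nt_bias(cpm, ann)
  expect_equal(bias$fraction[bias$base == "U"], 0.5)
  expect_equal(bias$fraction[bias$base == "A"], 0.5)

  # N weight excluded from the four fractions, reported separately
  cpm <- make_cpm(tibble::tibble(
    sequence = c("TAAAA", "NCCCC"), s1 = c(30L, 10L)))
  ann <- tibble::tibble(sequence = c("TAAAA", "NCCCC"),
                        biotype = c("piRNA", "piRNA"))
  bias <- first_nt_bias(cpm, ann)
  expect_equal(bias$fraction[bias$base == "U"], 1.0)
  expect_equal(unique(bias$n_share), 0.25)

  # fixture piRNA references are built with an 80% U start bias
  bundle <- test_bundle()
  pirna <- bundle$references[bundle$references$biotype == "piRNA", ]
  u_frac <- mean(substr(pirna$sequence, 1, 1) == "T")
  expect_gte(u_frac, 0.5)
})

test_that("log2 fold differences follow the pseudocount formula", {
  cpm <- make_cpm(tibble::tibble(
    sequence = c("AAAA", "CCCC", "GGGG"),
    a1 = c(20L, 0L, 100L), a2 = c(20L, 0L, 300L),
    b1 = c(20L, 15L, 0L), b2 = c(20L, 15L, 0L)))
  fc <- log2_fold(cpm, c("a1", "a2"), c("b1", "b2"), pseudocount = 1)
  expect_equal(fc$log2fc[fc$sequence == "AAAA"], 0)       # equal means
  expect_equal(fc$log2fc[fc$sequence == "CCCC"], -4)      # (0+1)/(15+1)
  expect_equal(fc$direction[fc$sequence == "GGGG"], "up")
  # absent-in-one-group sequences: |log2fc| grows with the present mean
  expect_gt(fc$log2fc[fc$sequence == "GGGG"], 4)

  # antisymmetry under group swap
  rev_fc <- log2_fold(cpm, c("b1", "b2"), c("a1", "a2"), pseudocount = 1)
  expect_equal(fc$log2fc, -rev_fc$log2fc)

  pct <- fold_change_percentages(fc)
  expect_equal(pct$pct_up + pct$pct_down + pct$pct_unchanged, 100)
  expect_equal(pct$n_sequences, 3)

  # optional threshold widens the unchanged band: log2(201/1) ~ 7.65
  fc_thr <- log2_fold(cpm, c("a1", "a2"), c("b1", "b2"), threshold = 8)
  expect_equal(fc_thr$direction[fc_thr$sequence == "GGGG"], "unchanged")
})

test_that("correlation clustering is symmetric and groups duplicated samples", {
  withr::with_seed(81, {
    base <- matrix(rpois(200, 50), nrow = 50)
  })
  counts <- tibble::tibble(
    sequence = replicate(50, random_seq(20)),
    s1 = base[, 1], s2 = base[, 1],       # s2 duplicates s1
    s3 = base[, 3], s4 = base[, 4])
  cpm <- make_cpm(counts)
  cc <- correlation_cluster(cpm)
  expect_equal(cc$correlation["s1", "s2"], 1)
  expect_equal(diag(cc$correlation), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cc$correlation, t(cc$correlation))
  # duplicated samples are adjacent in the dendrogram
  ord <- match(c("s1", "s2"), cc$leaf_order)
  expect_equal(abs(diff(ord)), 1)

  # two orthogonal blocks of sequences cluster by block
  block <- tibble::tibble(
    sequence = counts$sequence,
    a1 = c(rep(100L, 25), rep(0L, 25)), a2 = c(rep(90L, 25), rep(0L, 25)),
    b1 = c(rep(0L, 25), rep(100L, 25)), b2 = c(rep(0L, 25), rep(95L, 25)))
  cc2 <- correlation_cluster(make_cpm(block))
  pos <- match(c("a1", "a2", "b1", "b2"), cc2$leaf_order)
  expect_equal(abs(diff(pos[1:2])), 1)
  expect_equal(abs(diff(pos[3:4])), 1)

  # permuting sample order never changes pairwise r
  perm <- counts[, c("sequence", "s3", "s1", "s4", "s2")]
  ccp <- correlation_cluster(make_cpm(perm))
  expect_equal(ccp$correlation["s1", "s3"], cc$correlation["s1", "s3"])

  # constant columns are an error naming the sample
  const <- tibble::tibble(sequence = c("AA", "CC"), s1 = c(1L, 2L),
                          s2 = c(7L, 7L))
  expect_error(correlation_cluster(make_cpm(const)), "s2")
})

test_that("saturation fitting recovers library complexity", {
  # a library of one repeated sequence is flat at richness 1
  fit <- saturation_curve(rep("ACGTACGT", 500), seed = 3)
  expect_true(fit$converged)
  expect_equal(fit$Asym, 1, tolerance = 1e-8)

  # the full-depth point equals the library's distinct count
  withr::with_seed(91, {
    pool <- replicate(120, random_seq(18))
    reads <- sample(pool, 3000, replace = TRUE)
  })
  fit <- saturation_curve(reads, threshold = 1, seed = 4)
  expect_equal(max(fit$data$richness), length(unique(reads)))
  expect_true(fit$converged)

  # deep sampling from a 500-sequence pool: asymptote near 500
  withr::with_seed(92, {
    pool500 <- replicate(500, random_seq(18))
    deep <- sample(pool500, 5000, replace = TRUE)
  })
  fit <- saturation_curve(deep, fractions = seq(0.05, 1, by = 0.05),
                          threshold = 1, n_reps = 3, seed = 5)
  expect_true(fit$converged)
  expect_lt(abs(fit$Asym - 500) / 500, 0.15)
  # fitted curve monotone non-decreasing with Asym above it
  expect_true(all(diff(fit$fitted) >= -1e-8))
  expect_true(all(fit$fitted <= fit$Asym + 1e-6))

  # richness is non-decreasing in depth (averaged subsamples)
  expect_true(all(diff(fit$data$richness) >= -1e-8))

  td <- tidy(fit)
  expect_equal(td$term, c("Asym", "R0", "lrc"))
  expect_true(glance(fit)$converged)
})

test_that("biotype composition percentages sum to 100 including unannotated", {
  cpm <- make_cpm(tibble::tibble(
    sequence = c("AAAA", "CCCC", "GGGG"),
    s1 = c(50L, 30L, 20L)))
  ann <- tibble::tibble(sequence = c("AAAA", "CCCC"),
                        biotype = c("miRNA", "rRNA"))
  comp <- biotype_composition(cpm, ann)
  expect_equal(sum(comp$percent), 100)
  expect_true("unannotated" %in% comp$biotype)
  expect_equal(comp$percent[comp$biotype == "unannotated"], 20)
})

test_that("result types plot without error", {
  cpm <- make_cpm(tibble::tibble(
    sequence = c("TAAAA", "ACCCCC"), s1 = c(10L, 20L), s2 = c(15L, 15L)))
  ann <- tibble::tibble(sequence = c("TAAAA", "ACCCCC"),
                        biotype = c("piRNA", "miRNA"))
  expect_s3_class(plot_size_distribution(size_distribution(cpm, ann)),
                  "ggplot")
  expect_s3_class(plot_first_nt_bias(first_nt_bias(cpm, ann)), "ggplot")
  prof <- compute_coverage(tibble::tibble(start = 1L, end = 5L), 10, 3)
  expect_s3_class(plot_coverage(prof), "ggplot")
  enr <- terminal_enrichment(
    tibble::tibble(terminal_class = c("five_prime", "three_prime"),
                   cpm = c(1, 2), grp = "g"), grp)
  expect_s3_class(plot_terminal_enrichment(enr), "ggplot")
  fit <- saturation_curve(c(rep("AC", 5), rep("GT", 3), "TT"), seed = 1)
  expect_s3_class(autoplot(fit), "ggplot")
})
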