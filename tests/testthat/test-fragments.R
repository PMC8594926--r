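# A crafted type-I cloverleaf (no paired variable arm): 3 enclosed loops.
TOY_SEQ <- paste0("GGGGGGG", "AA", "GGGG", "AAAA", "CCCC", "A",
                  "GGGGG", "AAAAAAA", "CCCCC", "AAAA",
                  "GGGGG", "AAAAAAA", "CCCCC", "CCCCCCC", "ACCA")
TOY_PAIR <- paste0(">>>>>>>", "..", ">>>>", "....", "<<<<", ".",
                   ">>>>>", ".......", "<<<<<", "....",
                   ">>>>>", ".......", "<<<<<", "<<<<<<<", "....")

test_that("the ss parser labels enclosed loops 5' to 3'", {
  ss <- secondary_structure("toy", TOY_SEQ, TOY_PAIR)
  expect_true(ss$usable)
  expect_equal(ss$loops$label, c("D_loop", "anticodon_loop", "T_loop"))
  expect_equal(ss$loops$start[1], 14)
  expect_equal(ss$loops$end[1], 17)
  # the unpaired variable region (positions 40-43, not stem-enclosed) is
  # not a loop
  expect_false(any(ss$loops$start == 40))

  # all-unpaired record: no stems, flagged unusable
  flat <- secondary_structure("flat", strrep("A", 20), strrep(".", 20))
  expect_false(flat$usable)
  expect_equal(nrow(flat$loops), 0)

  # unbalanced pairing strings name the record
  expect_error(secondary_structure("bad", "ACGT", ">>.."), "bad")
  expect_error(secondary_structure("bad2", "ACGT", "..<<"), "bad2")
})

test_that("loops re-serialized over the pairing string reproduce the unpaired runs", {
  bundle <- test_bundle()
  for (ss in bundle$structures) {
    chars <- strsplit(ss$pairing, "")[[1]]
    for (i in seq_len(nrow(ss$loops))) {
      run <- chars[ss$loops$start[i]:ss$loops$end[i]]
      expect_true(all(run == "."))
      # maximality: flanked by stem characters
      expect_equal(chars[ss$loops$start[i] - 1L], ">")
      expect_equal(chars[ss$loops$end[i] + 1L], "<")
    }
  }
})

test_that("terminal classification follows the boundary rule", {
  expect_equal(classify_terminal(1, 33, 76), "five_prime")
  expect_equal(classify_terminal(44, 76, 76), "three_prime")
  expect_equal(classify_terminal(20, 55, 76), "internal")
  expect_equal(classify_terminal(1, 76, 76), "full")
  # vectorized, and with a configurable terminal tolerance
  expect_equal(classify_terminal(c(1, 44, 20), c(33, 76, 55), 76),
               c("five_prime", "three_prime", "internal"))
  expect_equal(classify_terminal(2, 40, 76, tolerance = 1), "five_prime")
})

test_that("loop labels and subtype flags follow the cleavage conventions", {
  ss <- secondary_structure("toy", TOY_SEQ, TOY_PAIR)
  ac <- ss$loops[ss$loops$label == "anticodon_loop", ]
  tl <- ss$loops[ss$loops$label == "T_loop", ]

  # 5' fragment ending inside the anticodon loop: tiRNA half
  lab <- label_cleavage(1, ac$start + 2L, ss)
  expect_equal(lab$terminal_class, "five_prime")
  expect_equal(lab$end_loop, "anticodon_loop")
  expect_true(lab$tiRNA_half)
  expect_false(lab$nitRNA_like)

  # 3' fragment starting right after an anticodon-loop cut: tiRNA half
  lab <- label_cleavage(ac$start + 3L, ss$length, ss)
  expect_equal(lab$terminal_class, "three_prime")
  expect_equal(lab$start_loop, "anticodon_loop")
  expect_true(lab$tiRNA_half)

  # internal fragment from anticodon loop into the T loop: nitRNA-like
  lab <- label_cleavage(ac$start + 3L, tl$start + 2L, ss)
  expect_equal(lab$terminal_class, "internal")
  expect_true(lab$nitRNA_like)
  expect_false(lab$tiRNA_half)

  # fragment wholly within the acceptor stem: no loop labels, no flags
  lab <- label_cleavage(2, 6, ss)
  expect_true(is.na(lab$start_loop))
  expect_true(is.na(lab$end_loop))
  expect_false(lab$tiRNA_half)
  expect_false(lab$nitRNA_like)

  # termini have no loops
  lab <- label_cleavage(1, ss$length, ss)
  expect_true(is.na(lab$start_loop) && is.na(lab$end_loop))
})

test_that("rRNA fragments are assigned by subunit midpoint", {
  su <- tibble::tibble(subunit_id = c("18S", "5.8S"),
                       start = c(21L, 201L), end = c(170L, 280L))
  frags <- tibble::tibble(
    start = c(21L, 150L, 100L, 10L, 185L, 21L),
    end = c(60L, 170L, 130L, 36L, 230L, 170L)
  )
  out <- classify_rrf(frags, su)
  expect_equal(out$subunit_id,
               c("18S", "18S", "18S", "18S", "5.8S", "18S"))
  expect_equal(out$terminal_class,
               c("five_prime", "three_prime", "internal", "internal",
                 "internal", "full"))
  # fragment in a spacer between subunits
  spacer <- classify_rrf(tibble::tibble(start = 175L, end = 195L), su)
  expect_true(is.na(spacer$subunit_id))
  expect_true(is.na(spacer$terminal_class))
  # overlapping subunits are a configuration error
  bad <- tibble::tibble(subunit_id = c("a", "b"),
                        start = c(1L, 50L), end = c(60L, 80L))
  expect_error(classify_rrf(frags, bad), "overlap")
})

test_that("coverage profiles are additive and match a brute-force tally", {
  prof <- compute_coverage(tibble::tibble(start = 1L, end = 20L), 30,
                           cpm = 10)
  expect_equal(prof$cpm, c(rep(10, 20), rep(0, 10)))

  both <- compute_coverage(
    tibble::tibble(start = c(1L, 15L), end = c(20L, 25L)), 30,
    cpm = c(10, 5))
  expect_equal(both$cpm[15], 15)
  expect_equal(both$cpm[25], 5)
  expect_equal(both$cpm[26], 0)

  # conservation: sum over positions = sum of cpm * fragment length
  withr::with_seed(61, {
    frags <- tibble::tibble(start = sample(1:50, 40, TRUE))
    frags$end <- frags$start + sample(10:30, 40, TRUE)
    frags$end <- pmin(frags$end, 80L)
    cpm <- runif(40, 1, 50)
  })
  prof <- compute_coverage(frags, 80, cpm)
  expect_equal(sum(prof$cpm),
               sum(cpm * (frags$end - frags$start + 1)))
  # brute-force per-position tally
  tally <- vapply(1:80, function(p) {
    sum(cpm[frags$start <= p & frags$end >= p])
  }, numeric(1))
  expect_equal(prof$cpm, tally)

  # per-sample mean with a cpm matrix
  m <- cbind(a = c(10, 0), b = c(0, 20))
  prof <- compute_coverage(tibble::tibble(start = c(1L, 1L),
                                          end = c(5L, 5L)), 6, m)
  expect_equal(prof$cpm[1], 15)  # mean of 10 and 20 summed per sample
})

test_that("terminal enrichment returns cpm-weighted fractions per group", {
  only5 <- tibble::tibble(terminal_class = "five_prime", cpm = c(3, 7),
                          grp = "g")
  out <- terminal_enrichment(only5, grp)
  expect_equal(c(out$five_prime, out$internal, out$three_prime), c(1, 0, 0))

  equal3 <- tibble::tibble(
    terminal_class = c("five_prime", "internal", "three_prime"),
    cpm = c(5, 5, 5), grp = "g")
  out <- terminal_enrichment(equal3, grp)
  expect_equal(unlist(out[, c("five_prime", "internal", "three_prime")]),
               rep(1 / 3, 3), ignore_attr = TRUE)

  # full-length fragments are excluded from the three-way fractions
  withfull <- dplyr::bind_rows(equal3,
                               tibble::tibble(terminal_class = "full",
                                              cpm = 99, grp = "g"))
  out <- terminal_enrichment(withfull, grp)
  expect_equal(out$five_prime, 1 / 3)
  expect_equal(out$full_cpm, 99)

  # empty groups are absent
  none <- tibble::tibble(terminal_class = "full", cpm = 1, grp = "h")
  out <- terminal_enrichment(dplyr::bind_rows(equal3, none), grp)
  expect_equal(out$grp, "g")
})

test_that("isodecoder families parse from the ref_id convention", {
  expect_equal(isodecoder(c("tRNA-GlyGCC-1", "Mt_tRNA-SerUGA-2", "rRNA-1")),
               c("GlyGCC", "SerUGA", NA))
  # grouping by isodecoder is a pure relabelling: totals conserved
  bundle <- test_bundle()
  trna <- bundle$references[bundle$references$biotype == "tRNA", ]
  fam <- isodecoder(trna$ref_id)
  expect_false(any(is.na(fam)))
})

test_that("designed fragment truth labels are recovered by the classifier", {
  bundle <- test_bundle()
  sim <- simulate_reads(bundle, simulation_params(
    seed = 62, n_reads = 1500, p_tagged = 0, error_rate = 0,
    low_qual_frac = 0, qual_mean = 38, qual_sd = 1))
  truth <- sim$truth[sim$truth$biotype %in% c("tRNA", "Mt_tRNA"), ]
  cls <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    ss <- bundle$structures[[truth$source_ref[i]]]
    cls[[i]] <- label_cleavage(truth$insert_start[i], truth$insert_end[i],
                               ss)
  }
  cls <- dplyr::bind_rows(cls)
  expect_identical(cls$terminal_class, truth$terminal_class)
  expect_identical(cls$tiRNA_half, truth$tiRNA_half)
  expect_identical(cls$nitRNA_like, truth$nitRNA_like)
})
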