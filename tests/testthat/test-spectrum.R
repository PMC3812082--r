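# Mutation calling, classification, spectrum decomposition, junction repeats.

test_that("identical sequences yield no events", {
  expect_identical(nrow(call_mutations("ACGTACGT", "ACGTACGT")), 0L)
})

test_that("single differences are called with correct coordinates", {
  ref <- "ACGTACGTACGT"
  ev <- call_mutations(ref, "ACGAACGTACGT")
  expect_identical(ev$kind, "substitution")
  expect_identical(ev$position, 4L)
  expect_identical(ev$ref, "T")
  expect_identical(ev$alt, "A")

  # multi-base deletion is merged into one event
  ev2 <- call_mutations(ref, "ACGTCGT", max_edit = 10)
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$kind, "deletion")
  expect_identical(ev2$length, 5L)
})

test_that("run insertions are left-normalized to the start of the run", {
  # A7 run extended to A8: reported as one insertion at the run start
  ref <- paste0("GGTTGA", strrep("A", 6), "TTCGATCG")  # A7 run at 6..12
  mut <- paste0("GGTTGA", strrep("A", 7), "TTCGATCG")
  ev <- call_mutations(ref, mut)
  expect_identical(ev$kind, "insertion")
  expect_identical(ev$position, 6L)
  expect_identical(ev$alt, "A")

  # and a 1-bp run deletion likewise
  ev2 <- call_mutations(mut, ref)
  expect_identical(ev2$kind, "deletion")
  expect_identical(ev2$position, 6L)
})

test_that("mispaired or invalid sequences are rejected", {
  expect_error(call_mutations("ACGTN", "ACGTA"), "A,C,G,T")
  expect_error(call_mutations(strrep("A", 100), strrep("C", 100)),
               class = "fluxmut_suspicious_pair")
  # the cap is configurable for deletion-bearing isolates
  ref <- simulate_reporter_reference(300, seed = 42)
  mut <- paste0(substr(ref, 1, 100), substr(ref, 201, 300))
  expect_error(call_mutations(ref, mut), class = "fluxmut_suspicious_pair")
  ev <- call_mutations(ref, mut, max_edit = 200)
  expect_identical(sum(ev$length[ev$kind == "deletion"]), 100L)
})

test_that("planted event sets are recovered exactly (round trip)", {
  ref <- simulate_reporter_reference(500, seed = 101)
  gen <- generate_mutant_sequences(ref, 150, seed = 102,
                                   medium_del_range = c(40, 120))
  hit <- 0L; n_seq <- 0L
  for (id in names(gen$sequences)) {
    n_seq <- n_seq + 1L
    ev <- call_mutations(ref, gen$sequences[[id]], max_edit = 200)
    truth <- gen$truth[[id]]
    rownames(ev) <- rownames(truth) <- NULL
    if (identical(ev, truth)) hit <- hit + 1L
  }
  expect_gte(hit / n_seq, 0.99)
})

test_that("event clustering follows the complex-mutation window", {
  ev <- mutation_events(c("substitution", "substitution"), c(100, 105),
                        c("G", "C"), c("T", "A"))
  cl <- cluster_and_classify(ev)
  expect_identical(cl$mclass, "complex")
  expect_identical(cl$net_frameshift, 0L)

  # 1-bp insertion plus adjacent substitution: complex with net +1
  ev2 <- rbind(mutation_events("insertion", 200, "", "A"),
               mutation_events("substitution", 201, "G", "T"))
  cl2 <- cluster_and_classify(ev2)
  expect_identical(cl2$mclass, "complex")
  expect_identical(cl2$net_frameshift, 1L)

  # events 11 bp apart are separate clusters -> other
  ev3 <- mutation_events(c("substitution", "substitution"), c(100, 111),
                         c("G", "C"), c("T", "A"))
  expect_identical(cluster_and_classify(ev3)$mclass, "other")
})

test_that("lone events map to their spectrum classes", {
  one <- function(kind, ref, alt, pos = 50)
    cluster_and_classify(mutation_events(kind, pos, ref, alt))
  expect_identical(one("substitution", "G", "T")$mclass, "base_substitution")
  expect_identical(one("insertion", "", "A")$mclass, "ins_1bp")
  expect_identical(one("deletion", "A", "")$mclass, "del_1bp")
  expect_identical(one("deletion", strrep("A", 500), "")$mclass, "medium_deletion")
  expect_identical(one("deletion", strrep("A", 2), "")$mclass, "other")
  # the 11-10000 bp medium-deletion band is configurable
  expect_identical(cluster_and_classify(
    mutation_events("deletion", 50, strrep("A", 500), ""),
    medium_del_range = c(600, 10000))$mclass, "other")
  expect_error(cluster_and_classify(fluxmut:::empty_events()), "at least one")
})

test_that("classification of clustered output is a fixed point", {
  ev <- rbind(mutation_events("insertion", 200, "", "A"),
              mutation_events("substitution", 205, "G", "T"))
  cl <- cluster_and_classify(ev)
  cl2 <- cluster_and_classify(cl$events)
  expect_identical(cl2$mclass, cl$mclass)
  expect_identical(cl2$net_frameshift, cl$net_frameshift)
  expect_identical(cl2$events, cl$events)
})

test_that("unsorted events are reordered with a warning", {
  ev <- mutation_events(c("substitution", "substitution"), c(100, 105),
                        c("G", "C"), c("T", "A"))
  shuffled <- ev[c(2, 1), ]
  expect_warning(cl <- cluster_and_classify(shuffled), "sorted")
  expect_identical(cl$mclass, "complex")
})

test_that("PCR-based GCR scoring implements the published decision rule", {
  expect_identical(classify_gcr_pcr(FALSE, TRUE), "gcr_deletion")
  expect_identical(classify_gcr_pcr(TRUE, TRUE), "sequence_required")
  expect_identical(classify_gcr_pcr(TRUE, FALSE), "invalid_dna")
  expect_identical(classify_gcr_pcr(FALSE, FALSE), "invalid_dna")
  expect_identical(classify_gcr_pcr(c(FALSE, TRUE), c(TRUE, TRUE)),
                   c("gcr_deletion", "sequence_required"))
})

test_that("per-class rates conserve the total rate", {
  classes <- c(rep("base_substitution", 25), rep("ins_1bp", 25),
               rep("del_1bp", 25), rep("complex", 25))
  sp <- spectrum_rates(480e-8, classes)
  expect_equal(sum(sp$class_rates), 480e-8, tolerance = 1e-12)
  expect_equal(unname(sp$class_rates["complex"]), 120e-8, tolerance = 1e-12)
  expect_identical(sp$n_isolates, 100L)

  # one class only: that class carries the whole rate
  solo <- spectrum_rates(42e-8, rep("base_substitution", 7))
  expect_equal(unname(solo$class_rates["base_substitution"]), 42e-8)

  # gene deletions scored by PCR: 40% of isolates at total 480e-8 -> 190e-8
  sp2 <- spectrum_rates(480e-8, rep("base_substitution", 60),
                        gcr_calls = rep("gcr_deletion", 40))
  expect_equal(signif_half_away(sp2$class_rates[["gcr_deletion"]] * 1e8, 2), 190)
  expect_error(spectrum_rates(1e-8, character()), "no isolates")
})

test_that("frameshift-reversion window check is exact and order invariant", {
  win <- 100  # 51-bp window at 100..150
  ins <- mutation_events("insertion", 120, "", "A")
  expect_true(his7_reversion_check(ins, win))
  expect_false(his7_reversion_check(fluxmut:::empty_events(), win))
  # +1 insertion with adjacent substitution still reverts
  cplx <- rbind(mutation_events("insertion", 120, "", "A"),
                mutation_events("substitution", 121, "G", "T"))
  expect_true(his7_reversion_check(cplx, win))
  expect_true(his7_reversion_check(cplx[c(2, 1), ], win))
  # net +2 inside, or a compensating frameshift outside, do not revert
  expect_false(his7_reversion_check(
    mutation_events("insertion", 120, "", "AA"), win))
  broken <- rbind(mutation_events("insertion", 120, "", "A"),
                  mutation_events("deletion", 300, "T", ""))
  expect_false(his7_reversion_check(broken, win))
  # boundary: event at window end counts, one past it does not
  expect_true(his7_reversion_check(mutation_events("insertion", 150, "", "C"), win))
  expect_false(his7_reversion_check(mutation_events("insertion", 151, "", "C"), win))
})

test_that("engineered junction repeats are found with exact geometry", {
  set.seed(31)
  ref <- make_repeat_reference(200, at = 60, del_len = 50, rep_len = 8)
  del <- mutation_events("deletion", 60, substr(ref, 60, 109), "")
  # restricting to perfect repeats recovers the planted copy
  hit <- find_junction_repeats(ref, del, min_len = 4, max_mismatches = 0)
  expect_false(is.null(hit))
  expect_gte(hit$repeat_length, 8)
  expect_identical(hit$mismatches, 0L)
  expect_true(hit$is_perfect)
  expect_identical(hit$repeat_seq_left, hit$repeat_seq_right)
  # allowing one mismatch can only lengthen the best hit
  hit1 <- find_junction_repeats(ref, del, min_len = 4, max_mismatches = 1)
  expect_gte(hit1$repeat_length, hit$repeat_length)

  # planted near-perfect 10-mer (one internal mismatch): nearly perfect call
  ref2 <- make_repeat_reference(200, at = 60, del_len = 50, rep_len = 10,
                                mismatch_at = 5)
  del2 <- mutation_events("deletion", 60, substr(ref2, 60, 109), "")
  hit2 <- find_junction_repeats(ref2, del2, min_len = 6)
  expect_false(is.null(hit2))
  expect_gte(hit2$repeat_length, 10)
  expect_lte(hit2$mismatches, 1L)
})

test_that("junction scan matches the exhaustive oracle on random deletions", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(120:300, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    L <- sample(30:60, 1)
    p <- sample(20:(n - L - 20), 1)
    del <- mutation_events("deletion", p, substr(ref, p, p + L - 1), "")
    hit <- find_junction_repeats(ref, del, min_len = 3, max_mismatches = 1)
    orc <- oracle_junction_repeat(ref, p, L, min_len = 3, max_mismatches = 1)
    if (is.null(orc)) {
      expect_null(hit)
    } else {
      expect_false(is.null(hit))
      expect_identical(hit$repeat_length, orc$len)
      expect_identical(hit$mismatches, orc$mm)
      expect_identical(hit$left_start, orc$i)
    }
  }
})

test_that("long repeats are rarely found in random sequence at high min_len", {
  set.seed(35)
  misses <- 0
  for (i in 1:10) {
    ref <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    del <- mutation_events("deletion", 80, substr(ref, 80, 119), "")
    if (is.null(find_junction_repeats(ref, del, min_len = 10,
                                      max_mismatches = 0))) misses <- misses + 1
  }
  expect_gte(misses, 9)
  expect_error(find_junction_repeats("ACGT", list(kind = "deletion",
                                                  position = 3, length = 10)),
               "outside")
})
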