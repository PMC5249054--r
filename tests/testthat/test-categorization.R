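test_that("the rule boundaries are pinned exactly", {
  # SD of 0.29 is NOT fine pleomorphic (strict >)
  f <- classify_sample(sample_row(3.29, 0.29, 162))
  expect_false(f$fp); expect_true(f$ns)
  expect_true(classify_sample(sample_row(3.29, 0.2901, 162))$fp)

  # mean SMI of 3.08 IS fine linear (inclusive interval), 3.081 is not
  expect_true(classify_sample(sample_row(3.08, 0.1, 150))$fl)
  expect_false(classify_sample(sample_row(3.081, 0.1, 150))$fl)
  expect_true(classify_sample(sample_row(2.92, 0.1, 150))$fl)

  # 200 um diameter is NOT fine linear (strict <)
  expect_false(classify_sample(sample_row(3.00, 0.1, 200))$fl)
  expect_true(classify_sample(sample_row(3.00, 0.1, 199.9))$fl)

  # coarse heterogeneous needs a big object AND heterogeneous SMI
  expect_true(classify_sample(sample_row(2.6, 0.6, 360, 501))$ch)
  expect_false(classify_sample(sample_row(2.6, 0.6, 360, 500))$ch)
  expect_false(classify_sample(sample_row(2.6, 0.5, 360, 501))$ch)
})

test_that("flags are independent and ns is their negation", {
  # rod-like, heterogeneous, small: fl and fp can co-occur
  f <- classify_sample(sample_row(3.08, 0.30, 191))
  expect_true(f$fl); expect_true(f$fp); expect_false(f$ns)

  # property: ns == !(fl | fp | ch) over random samples
  set.seed(31)
  for (i in 1:50) {
    s <- sample_row(runif(1, 2, 4), runif(1, 0, 1), runif(1, 50, 600),
                    runif(1, 50, 900))
    f <- classify_sample(s)
    expect_equal(f$ns, !(f$fl || f$fp || f$ch))
  }
})

test_that("published per-sample aggregates classify as printed", {
  # four anchor samples of the reference cohort
  f <- classify_sample(sample_row(3.07, 0.24, 130.3))      # sample 20
  expect_equal(unlist(f), c(fl = TRUE, fp = FALSE, ch = FALSE, ns = FALSE))
  f <- classify_sample(sample_row(3.27, 0.33, 117.1))      # sample 1
  expect_equal(unlist(f), c(fl = FALSE, fp = TRUE, ch = FALSE, ns = FALSE))
  f <- classify_sample(sample_row(3.29, 0.29, 162.6))      # sample 8
  expect_equal(unlist(f), c(fl = FALSE, fp = FALSE, ch = FALSE, ns = TRUE))
  f <- classify_sample(sample_row(3.08, 0.30, 191.3))      # sample 29
  expect_true(f$fl && f$fp)
})

test_that("excluded single-calcification samples are refused", {
  expect_error(classify_sample(sample_row(3.0, 0, 100, excluded = TRUE)),
               "excluded")
})

test_that("per-object mode can only assert fl or ns", {
  obj <- function(d, s) data.frame(d_cube_um = d, SMI = s)
  expect_true(classify_object(obj(100, 3.00))$fl)
  expect_true(classify_object(obj(300, 3.00))$ns)   # size bound
  expect_true(classify_object(obj(100, 3.50))$ns)   # SMI bound
  expect_false(classify_object(obj(100, 3.00))$fp)  # SD undefined per object
})

test_that("B-classification maps to groups A/B/C", {
  expect_equal(as.character(assign_group(c("B1", "B2", "B3", "B4", "B5"))),
               c("A", "A", "B", "B", "C"))
  expect_error(assign_group("B6"), "unknown")
})

test_that("presence tables reproduce the published group counts", {
  rc <- reference_cohort()
  rc <- rc[!rc$excluded, ]
  fl <- presence_table(rc, "fl")
  expect_equal(unname(fl["present", ]), c(0L, 1L, 4L))
  expect_equal(unname(colSums(fl)), c(13L, 7L, 7L))
  ns <- presence_table(rc, "ns")
  expect_equal(unname(ns["present", ]), c(8L, 3L, 0L))

  # degenerate: a cohort with no flagged samples
  toy <- data.frame(group = rep(c("A", "B", "C"), 2), fl = FALSE)
  expect_equal(sum(presence_table(toy, "fl")["present", ]), 0L)

  # empty group is an error naming the group
  expect_error(presence_table(data.frame(group = c("A", "B"), fl = TRUE),
                              "fl"), "C")
})

test_that("reclassifying the reference cohort matches the printed flags
          for >= 25/27 samples with the documented discordances", {
  rc <- reference_cohort()
  eligible <- rc[!rc$excluded, ]
  got <- do.call(rbind, lapply(seq_len(nrow(eligible)), function(i)
    classify_sample(eligible[i, ])))
  concordant <- got$fl == eligible$fl & got$fp == eligible$fp &
    got$ch == eligible$ch & got$ns == eligible$ns
  expect_gte(sum(concordant), 25L)
  expect_setequal(eligible$sample_id[!concordant],
                  classification_expectations()$sample_id)
})
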