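truth_tbl <- function(pos, alt = NULL, origin = "somatic") {
  tibble::tibble(id = sprintf("t%d", seq_along(pos)), contig = "chr1",
                 pos = as.integer(pos), ref = "A",
                 alt = alt %||% rep("T", length(pos)), vclass = "SNV",
                 origin = origin, expected_af = 0.5)
}

calls_tbl <- function(pos, alt = NULL) {
  tibble::tibble(contig = "chr1", pos = as.integer(pos), ref = "A",
                 alt = alt %||% rep("T", length(pos)), vclass = "SNV")
}

test_that("identical calls and truth give perfect metrics", {
  tr <- truth_tbl(c(10, 20, 30))
  ev <- compare_calls(calls_tbl(c(10, 20, 30)), tr)
  expect_identical(c(ev$tp, ev$fp, ev$fn), c(3L, 0L, 0L))
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$harmonic_mean, 1)
})

test_that("partial overlap is scored by hand enumeration", {
  tr <- truth_tbl(c(10, 20), alt = c("T", "G"))
  ev <- compare_calls(calls_tbl(c(10, 30), alt = c("T", "A")), tr)
  expect_identical(c(ev$tp, ev$fp, ev$fn), c(1L, 1L, 1L))
  expect_equal(ev$sensitivity, 0.5)
  expect_equal(ev$precision, 0.5)
  td <- tidy(ev)
  expect_setequal(td$status, c("TP", "FN", "FP"))
  gl <- glance(ev)
  expect_identical(gl$tp, 1L)
})

test_that("allele matching is stricter than position matching", {
  tr <- truth_tbl(10, alt = "T")
  wrong_alt <- calls_tbl(10, alt = "C")
  strict <- compare_calls(wrong_alt, tr, match_mode = "position_allele")
  expect_identical(c(strict$tp, strict$fp, strict$fn), c(0L, 1L, 1L))
  loose <- compare_calls(wrong_alt, tr, match_mode = "position")
  expect_identical(c(loose$tp, loose$fp, loose$fn), c(1L, 0L, 0L))
})

test_that("non-SNV truth records and off-target calls are excluded", {
  tr <- truth_tbl(c(10, 20))
  tr$vclass[2] <- "DEL"
  regions <- target_regions(tibble::tibble(contig = "chr1", start = 0,
                                           end = 15))
  ev <- compare_calls(calls_tbl(c(10, 50)), tr, regions = regions)
  expect_identical(c(ev$tp, ev$fp, ev$fn), c(1L, 0L, 0L))
})

test_that("evaluation matches a brute-force all-pairs matcher", {
  brute_force <- function(calls, truth) {
    tp <- 0L; matched_calls <- rep(FALSE, nrow(calls))
    seen <- character(0)
    for (i in seq_len(nrow(truth))) {
      hit <- FALSE
      for (j in seq_len(nrow(calls))) {
        if (calls$contig[j] == truth$contig[i] &&
            calls$pos[j] == truth$pos[i] &&
            calls$alt[j] == truth$alt[i]) {
          hit <- TRUE
          matched_calls[j] <- TRUE
        }
      }
      if (hit) tp <- tp + 1L
    }
    ckey <- paste(calls$contig, calls$pos, calls$alt)
    fp <- length(unique(ckey[!matched_calls]))
    list(tp = tp, fp = fp, fn = nrow(truth) - tp)
  }
  set.seed(99)
  for (k in 1:300) {
    nt <- sample(0:60, 1); nc <- sample(0:60, 1)
    tr <- truth_tbl(sample(1:100, nt),
                    alt = sample(c("T", "G", "C"), nt, replace = TRUE))
    cl <- calls_tbl(sample(1:100, nc),
                    alt = sample(c("T", "G", "C"), nc, replace = TRUE))
    ev <- compare_calls(cl, tr)
    bf <- brute_force(cl, tr)
    expect_identical(ev$tp, bf$tp)
    expect_identical(ev$fp, bf$fp)
    expect_identical(ev$fn, bf$fn)
    expect_identical(ev$tp + ev$fn, nrow(tr)) # TP + FN = truth size
  }
})

test_that("percent formatting reproduces round-half-up worked examples", {
  hc <- eval_from_counts(tp = 56869, truth_n = 59664, fp = 24)
  s <- summarize_eval(hc)
  expect_identical(s$sensitivity_pct, "95.3%")
  expect_identical(s$precision_pct, "100.0%")
  fb <- eval_from_counts(tp = 56775, truth_n = 59664, fp = 47)
  expect_identical(summarize_eval(fb)$precision_pct, "99.9%")
  # degenerate cases: silent caller and zero recall
  silent <- eval_from_counts(tp = 0, fp = 0, fn = 5)
  s0 <- summarize_eval(silent)
  expect_identical(s0$precision_pct, "NA")
  expect_identical(s0$sensitivity_pct, "0.0%")
})

test_that("best parameters maximize the harmonic mean with stated tie-breaks", {
  res <- tibble::tibble(
    tool = "x", admixture = 0,
    params_id = c("a", "b"),
    sensitivity = c(0.9, 1.0), precision = c(0.9, 0.5),
    harmonic_mean = c(0.9, 2 * 1 * 0.5 / 1.5))
  best <- select_best_params(res)
  expect_identical(best$params_id, "a")
  single <- select_best_params(res[1, ])
  expect_identical(single$params_id, "a")
  # harmonic mean fixed point: s = p = x gives x
  expect_equal(eval_from_counts(tp = 30, fp = 10, fn = 10)$harmonic_mean,
               0.75)
  # tie on harmonic mean breaks to higher sensitivity
  tie <- tibble::tibble(tool = "x", admixture = 0,
                        params_id = c("hi_s", "hi_p"),
                        sensitivity = c(0.8, 0.6), precision = c(0.6, 0.8),
                        harmonic_mean = c(0.6857143, 0.6857143))
  expect_identical(select_best_params(tie)$params_id, "hi_s")
  expect_error(select_best_params(res[0, ]), "empty")
})

test_that("concordance counts supporting callers and conserves the union", {
  tr <- truth_tbl(c(1, 2, 3))
  abc <- list(x = calls_tbl(c(1, 2)), y = calls_tbl(c(2, 3)),
              z = calls_tbl(2))
  ct <- concordance(abc, tr)
  expect_identical(ct$total[ct$support == 3], 1L) # pos 2
  expect_identical(ct$total[ct$support == 1], 2L) # pos 1 and 3
  expect_identical(sum(ct$total), 3L)
  expect_equal(sum(ct$proportion), 1)
  same <- list(a = calls_tbl(1:5), b = calls_tbl(1:5), c = calls_tbl(1:5))
  ct2 <- concordance(same, truth_tbl(1:5))
  expect_identical(ct2$total[ct2$support == 3], 5L)
  expect_identical(sum(ct2$total[ct2$support < 3]), 0L)
  expect_identical(ct2$truth_matched[ct2$support == 3], 5L)
  expect_error(concordance(abc[1], tr), "at least two")
})

test_that("admixture curves sort by level and reject duplicates", {
  res <- tibble::tibble(admixture = c(0.5, 0, 0.9),
                        sensitivity = c(0.8, 0.95, 0.3),
                        precision = c(0.9, 0.99, 0.5))
  cv <- admixture_curve(res)
  expect_equal(cv$admixture, c(0, 0.5, 0.9))
  expect_true(all(cv$sensitivity >= 0 & cv$sensitivity <= 1))
  expect_identical(nrow(admixture_curve(res[1, ])), 1L)
  expect_error(admixture_curve(res[c(1, 1), ]), "duplicate")
})
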