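test_that("identical annotation sets pair perfectly", {
  iv <- random_interval_set(10, seed = 1)
  a <- annotation_set("A", iv$onset_s, iv$offset_s)
  b <- annotation_set("B", iv$onset_s, iv$offset_s)
  ref <- pair_scorers(a, b)
  expect_equal(nrow(ref$reliable), 10)
  expect_true(all(ref$reliable$onset_reliable))
  expect_true(all(ref$reliable$offset_reliable))
  expect_equal(ref$reliable$ref_onset_s, iv$onset_s)
  expect_equal(ref$reliable$ref_offset_s, iv$offset_s)
  expect_equal(nrow(ref$excluded), 0)
})

test_that("onset and offset reliability are judged independently", {
  a <- annotation_set("A", 10.0, 12.0)
  b <- annotation_set("B", 10.1, 12.2)  # onsets 100 ms, offsets 200 ms apart
  ref <- pair_scorers(a, b)
  expect_true(ref$reliable$onset_reliable)
  expect_false(ref$reliable$offset_reliable)
  expect_equal(ref$reliable$ref_onset_s, 10.05)
  expect_true(is.na(ref$reliable$ref_offset_s))
  # the 150 ms bound is strict
  ref2 <- pair_scorers(annotation_set("A", 0, 1),
                       annotation_set("B", 0.15, 1.05))
  expect_false(ref2$reliable$onset_reliable)
})

test_that("unmatched and ambiguous intervals are excluded", {
  a <- annotation_set("A", c(1, 5, 20), c(2, 6, 21))
  b <- annotation_set("B", c(1.05, 5.1), c(2.05, 6.1))
  ref <- pair_scorers(a, b)
  expect_equal(nrow(ref$reliable), 2)
  expect_equal(nrow(ref$excluded), 1)  # the extra interval at 20 s
  expect_equal(ref$excluded$onset_s, 20)

  # one interval straddling two of the other scorer's: no unique match
  a2 <- annotation_set("A", 1, 4)
  b2 <- annotation_set("B", c(1.2, 3), c(2, 3.8))
  ref2 <- pair_scorers(a2, b2)
  expect_equal(nrow(ref2$reliable), 0)
  expect_equal(nrow(ref2$excluded), 3)
})

test_that("scorer pairing is symmetric and matches a brute-force oracle", {
  for (seed in 1:15) {
    set.seed(seed)
    na <- sample(3:12, 1)
    nb <- sample(3:12, 1)
    ia <- random_interval_set(na, span = 40)
    ib <- random_interval_set(nb, span = 40)
    a <- annotation_set("A", ia$onset_s, ia$offset_s)
    b <- annotation_set("B", ib$onset_s, ib$offset_s)
    ref_ab <- pair_scorers(a, b)
    ref_ba <- pair_scorers(b, a)
    expect_equal(ref_ab$reliable$ref_onset_s, ref_ba$reliable$ref_onset_s)
    expect_equal(nrow(ref_ab$excluded), nrow(ref_ba$excluded))

    # brute-force unique-overlap rule
    ov <- outer(seq_len(na), seq_len(nb), function(i, j) {
      pmin(ia$offset_s[i], ib$offset_s[j]) -
        pmax(ia$onset_s[i], ib$onset_s[j]) > 0
    })
    n_unique <- sum(rowSums(ov) == 1 &
                      apply(ov, 1, function(r) {
                        j <- which(r)
                        length(j) == 1 && sum(ov[, j]) == 1
                      }))
    expect_equal(nrow(ref_ab$reliable), n_unique)
  }
})

test_that("detection matching reproduces the Se/Pr/F1 arithmetic", {
  iv <- random_interval_set(10, seed = 3)
  a <- annotation_set("A", iv$onset_s, iv$offset_s)
  b <- annotation_set("B", iv$onset_s + 0.01, iv$offset_s + 0.01)
  ref <- pair_scorers(a, b)

  # perfect detection
  det <- data.frame(onset_s = iv$onset_s, offset_s = iv$offset_s)
  rep0 <- match_detections(det, ref)
  expect_equal(c(rep0$sensitivity, rep0$precision, rep0$f1), c(1, 1, 1))

  # drop one event: TP 9, FN 1, FP 0
  rep1 <- match_detections(det[-1, ], ref)
  expect_equal(rep1$tp, 9)
  expect_equal(rep1$fn, 1)
  expect_equal(rep1$fp, 0)
  expect_equal(rep1$sensitivity, 0.9)
  expect_equal(rep1$precision, 1.0)
  expect_equal(rep1$f1, 2 * 0.9 * 1 / (0.9 + 1))

  # detections touching only excluded events are not counted as FP
  a2 <- annotation_set("A", c(1, 10), c(2, 11))
  b2 <- annotation_set("B", 1.05, 2.05)  # second interval unmatched
  ref2 <- pair_scorers(a2, b2)
  det2 <- data.frame(onset_s = c(1.1, 10.2), offset_s = c(1.9, 10.8))
  rep2 <- match_detections(det2, ref2)
  expect_equal(rep2$tp, 1)
  expect_equal(rep2$fp, 0)  # the 10 s detection touches an excluded interval
  det3 <- data.frame(onset_s = c(1.1, 30), offset_s = c(1.9, 31))
  expect_equal(match_detections(det3, ref2)$fp, 1)
})

test_that("TP counts equal the exhaustive bipartite-overlap oracle", {
  for (seed in 1:12) {
    set.seed(100 + seed)
    nd <- sample(2:8, 1)
    nr <- sample(2:8, 1)
    dv <- random_interval_set(nd, span = 25)
    rv <- random_interval_set(nr, span = 25)
    a <- annotation_set("A", rv$onset_s, rv$offset_s)
    b <- annotation_set("B", rv$onset_s, rv$offset_s)
    ref <- pair_scorers(a, b)
    got <- match_detections(dv, ref)
    want_tp <- max_matching_brute(dv$onset_s, dv$offset_s,
                                  rv$onset_s, rv$offset_s)
    expect_equal(got$tp, want_tp)
    # conservation identities
    expect_equal(got$tp + got$fn, nrow(ref$reliable))
    expect_lte(got$tp + got$fp, nd)
  }
})

test_that("timing metrics satisfy the md/sd/rmse identities", {
  iv <- random_interval_set(6, seed = 5)
  a <- annotation_set("A", iv$onset_s, iv$offset_s)
  b <- annotation_set("B", iv$onset_s, iv$offset_s)
  ref <- pair_scorers(a, b)

  # perfect detections: all-zero metrics
  det <- data.frame(onset_s = iv$onset_s, offset_s = iv$offset_s)
  tm <- timing_metrics(det, ref, "onset")
  expect_equal(c(tm$md, tm$sd, tm$rmse), c(0, 0, 0))
  expect_equal(tm$n, 6)

  # d = {+10, -10} ms -> md 0, rmse 10 ms
  det2 <- det[1:2, ]
  det2$onset_s <- det2$onset_s + c(0.010, -0.010)
  tm2 <- timing_metrics(det2, ref, "onset")
  expect_equal(tm2$md, 0)
  expect_equal(tm2$rmse, 0.010)

  # constant 20 ms delay -> md = rmse, sd = 0
  det3 <- det
  det3$offset_s <- det3$offset_s + 0.020
  tm3 <- timing_metrics(det3, ref, "offset")
  expect_equal(tm3$md, 0.020)
  expect_equal(tm3$sd, 0)
  expect_equal(tm3$rmse, 0.020)

  # population-SD identity on random perturbations
  set.seed(6)
  det4 <- det
  det4$onset_s <- det4$onset_s + rnorm(6, 0.02, 0.03)
  tm4 <- timing_metrics(det4, ref, "onset")
  expect_equal(tm4$rmse^2, tm4$md^2 + tm4$sd^2)
  expect_gte(tm4$rmse, abs(tm4$md))

  # unreliable markers contribute nothing
  b5 <- annotation_set("B", iv$onset_s + 0.2, iv$offset_s)
  ref5 <- pair_scorers(a, b5)
  tm5 <- timing_metrics(det, ref5, "onset")
  expect_true(tm5$empty)
})
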