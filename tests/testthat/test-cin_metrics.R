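test_that("hand-evaluated examples for each metric", {
  cfg <- metric_config()

  cancel <- seg_fixture("S1", "1", c(1, 101), c(100, 200), c(0.5, -0.5))
  expect_equal(tai(cancel, cfg), 0)          # signed contributions cancel
  expect_equal(modified_tai(cancel, cfg), 0.5)

  single <- seg_fixture("S1", "1", 1, 500, 0.5)
  expect_equal(tai(single, cfg), 0.5)
  expect_equal(modified_tai(seg_fixture("S1", "1", 1, 100, -0.3), cfg), 0.3)

  flat <- seg_fixture("S1", "1", c(1, 101), c(100, 300), c(0, 0))
  expect_equal(tai(flat, cfg), 0)            # empty aberrant set
  expect_equal(modified_tai(flat, cfg), 0)

  # middle segment aberrant and separated from both neighbours
  mid <- seg_fixture("S1", "1", c(1, 101, 201), c(100, 200, 300),
                     c(0, 0.5, 0))
  expect_equal(cna(mid, cfg), 1)
  # aberrant but adjacent difference 0 <= d
  pair <- seg_fixture("S1", "1", c(1, 101), c(100, 200), c(0.5, 0.5))
  expect_equal(cna(pair, cfg), 0)
  expect_equal(cna(flat, cfg), 0)

  expect_equal(count_break_points(mid, cfg), 2)
  expect_equal(count_break_points(flat, cfg), 0)
  five <- seg_fixture("S1", "1", seq(1, 401, 100), seq(100, 500, 100),
                      rep(0.9, 5))
  expect_equal(count_break_points(five, cfg), 10)

  bs <- seg_fixture("S1", "1", c(1, 101), c(100, 200), c(0.5, 0))
  expect_equal(count_base_segments(bs, cfg), 100)
  expect_equal(count_base_segments(flat, cfg), 0)
  expect_equal(fga(bs, cfg), 0.5)
  expect_equal(fga(flat, cfg), 0)
  expect_equal(fga(five, cfg), 1)
})

test_that("a flat profile scores zero on all six metrics", {
  flat <- seg_fixture("S1", c("1", "1", "2"), c(1, 201, 1),
                      c(200, 400, 1000), c(0, 0, 0))
  sc <- cin_scores(flat)
  expect_equal(unlist(sc[cin_metric_names()]),
               c(tai = 0, modified_tai = 0, cna = 0, break_points = 0,
                 base_segments = 0, fga = 0))
})

test_that("empty segment lists are an error for every metric", {
  empty <- seg_fixture(character(), character(), numeric(), numeric(),
                       numeric())
  for (f in list(tai, modified_tai, cna, count_break_points,
                 count_base_segments, fga)) {
    expect_error(f(empty), "empty")
  }
  expect_error(cin_scores(empty), "empty")
})

test_that("cin_scores matches the single-sample functions and ignores row order", {
  set.seed(42)
  segs <- rbind(random_segments("S1"), random_segments("S2"))
  cfg <- metric_config()
  sc <- cin_scores(segs, cfg)
  for (sid in c("S1", "S2")) {
    one <- segs[segs$sample_id == sid, ]
    row <- sc[sc$sample_id == sid, ]
    expect_equal(row$tai, tai(one, cfg))
    expect_equal(row$modified_tai, modified_tai(one, cfg))
    expect_equal(row$cna, cna(one, cfg))
    expect_equal(row$break_points, count_break_points(one, cfg))
    expect_equal(row$base_segments, count_base_segments(one, cfg))
    expect_equal(row$fga, fga(one, cfg))
  }
  shuffled <- segs[sample(nrow(segs)), ]
  expect_equal(cin_scores(shuffled, cfg), sc)
})

test_that("naive loop oracle agrees with the implementation on random samples", {
  set.seed(7)
  cfg <- metric_config()
  for (i in 1:40) {
    segs <- random_segments()
    got <- cin_scores(segs, cfg)
    want <- oracle_metrics(segs)
    expect_equal(got$tai, want$tai, tolerance = 1e-12)
    expect_equal(got$modified_tai, want$modified_tai, tolerance = 1e-12)
    expect_equal(got$fga, want$fga, tolerance = 1e-12)
    expect_identical(got$cna, as.integer(want$cna))
    expect_identical(got$break_points, as.integer(want$break_points))
    expect_identical(as.numeric(got$base_segments),
                     as.numeric(want$base_segments))
  }
})

test_that("structural relations hold on random samples", {
  set.seed(99)
  cfg <- metric_config()
  for (i in 1:25) {
    segs <- random_segments()
    sc <- cin_scores(segs, cfg)
    total <- sum(segs$end - segs$start + 1)
    expect_equal(sc$fga, sc$base_segments / total)
    expect_true(sc$fga >= 0 && sc$fga <= 1)
    expect_equal(sc$break_points %% 2, 0L)
    expect_lte(sc$base_segments, total)
    expect_lte(sc$cna, sc$break_points / 2)   # cna <= aberrant count
  }
})

test_that("tai over all segments is bounded by modified tai", {
  set.seed(13)
  cfg_all <- metric_config(tai_aberrant_only = FALSE)
  for (i in 1:20) {
    segs <- random_segments()
    expect_lte(abs(tai(segs, cfg_all)), modified_tai(segs, cfg_all) + 1e-12)
    pos <- segs
    pos$seg_mean <- abs(pos$seg_mean)
    expect_equal(tai(pos, cfg_all), modified_tai(pos, cfg_all))
  }
})

test_that("scaling coordinates scales base_segments only", {
  set.seed(21)
  segs <- random_segments()
  k <- 7
  scaled <- segs
  scaled$start <- (segs$start - 1) * k + 1
  scaled$end <- segs$end * k
  a <- cin_scores(segs)
  b <- cin_scores(scaled)
  for (m in c("tai", "modified_tai", "cna", "break_points", "fga")) {
    expect_equal(b[[m]], a[[m]])
  }
  expect_equal(b$base_segments, a$base_segments * k)
})

test_that("length convention and thresholds are honoured", {
  segs <- seg_fixture("S1", "1", c(1, 101), c(100, 200), c(0.3, 0))
  expect_equal(count_base_segments(segs, metric_config()), 100)
  expect_equal(count_base_segments(
    segs, metric_config(length_convention = "half_open")), 99)
  expect_equal(count_base_segments(
    segs, metric_config(aberration_threshold = 0.4)), 0)

  # threshold is inclusive: |mean| == t counts as aberrant
  at_t <- seg_fixture("S1", "1", 1, 100, 0.2)
  expect_equal(count_break_points(at_t, metric_config()), 2)
})

test_that("cin_scores validation names the offending sample", {
  bad <- rbind(seg_fixture("GOOD", "1", 1, 100, 0.5),
               seg_fixture("BAD", "1", c(1, 50), c(100, 150), c(0.5, 0)))
  expect_error(cin_scores(bad), "BAD")
})
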