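uniform_pwm <- function(l) pwm(matrix(0.25, 4, l), name = sprintf("unif%d", l))

test_that("window score is zero for a uniform PWM on a uniform background", {
  p <- uniform_pwm(4)
  expect_equal(window_score(p, "ACGT"), 0, tolerance = 1e-12)
  expect_equal(window_score(p, "TTTT"), 0, tolerance = 1e-12)
})

test_that("single-position PWM scores both orientations: A and T hit an A-specific matrix", {
  eps <- 1e-6
  p <- pwm(matrix(c(1 - 3 * eps, eps, eps, eps), 4, 1), name = "Aonly")
  sA <- window_score(p, "A")
  sT <- window_score(p, "T")  # reverse orientation reads the complement
  expect_equal(sA, log(4 * (1 - 3e-6)), tolerance = 1e-9)
  expect_equal(sT, sA, tolerance = 1e-12)
  expect_lt(window_score(p, "C"), sA)
})

test_that("palindromic consensus windows score identically in both orientations", {
  # strongly prefers ACGT; its reverse complement is also ACGT
  m <- vapply(c(1, 2, 3, 4), function(b) {
    v <- rep(0.01, 4); v[b] <- 0.97; v
  }, numeric(4))
  p <- pwm(m, name = "pal")
  s <- window_scores(p, "ACGT")
  expect_equal(s, oracle_window_score(p, "ACGT", background()),
               tolerance = 1e-12)
})

test_that("windows containing N are unscorable; window length must match", {
  p <- fixture_pwm(1, 3)
  expect_error(window_score(p, "ANA"), "unscorable")
  expect_error(window_score(p, "ACGT"), "length")
  s <- window_scores(p, sequence_record("x", "ACGNACG"))
  expect_true(all(is.na(s[2:4])))
  expect_true(all(!is.na(s[c(1, 5)])))
})

test_that("s_max is zero for the uniform PWM and matches exhaustive enumeration", {
  expect_equal(s_max(uniform_pwm(3)), 0, tolerance = 1e-12)
  bgs <- list(background(), fixture_bg_skew(),
              background(c(0.4, 0.25, 0.25, 0.1)))  # strand-asymmetric
  for (bg in bgs) {
    for (seed in 1:4) {
      p <- fixture_pwm(seed, 2)
      wins <- apply(expand.grid(B1 = c("A", "C", "G", "T"),
                                B2 = c("A", "C", "G", "T")), 1, paste,
                    collapse = "")
      best <- max(vapply(wins, function(w) window_score(p, w, bg), 0))
      expect_equal(s_max(p, bg), best, tolerance = 1e-9)
    }
  }
})

test_that("s_max bounds the score of every sampled window", {
  p <- fixture_pwm(7, 9)
  bg <- fixture_bg_skew()
  sm <- s_max(p, bg)
  scores <- window_scores(p, fixture_seq(8, 1000), bg)
  expect_true(all(scores <= sm + 1e-9))
})

test_that("TBA of a uniform PWM equals log of the window count", {
  p <- uniform_pwm(5)
  r <- fixture_seq(2, 40)
  a <- tba(p, r)
  expect_equal(a$value, log(40 - 5 + 1), tolerance = 1e-12)
  expect_equal(a$n_windows_used, 36L)
})

test_that("tba and occupancy match the brute-force oracle on random fixtures", {
  set.seed(1203)
  bgs <- list(background(), fixture_bg_skew())
  for (i in 1:30) {
    l <- sample(1:12, 1)
    L <- sample(l:200, 1)
    p <- fixture_pwm(1000 + i, l)
    r <- fixture_seq(2000 + i, L)
    bg <- bgs[[1 + i %% 2]]
    expect_equal(tba(p, r, bg)$value, oracle_tba(p, r, bg),
                 tolerance = 1e-9, label = sprintf("tba fixture %d", i))
    cutoff <- sample(seq(0.1, 1, 0.1), 1)
    expect_equal(occupancy(p, r, bg, cutoff = cutoff)$value,
                 oracle_occupancy(p, r, bg, cutoff),
                 tolerance = 1e-9, label = sprintf("occ fixture %d", i))
  }
})

test_that("TBA is invariant under reverse complementation", {
  for (i in 1:10) {
    p <- fixture_pwm(30 + i, sample(2:10, 1))
    r <- fixture_seq(60 + i, 150)
    rc <- sequence_record("rc", affinityscan:::reverse_complement(r$bases))
    expect_equal(tba(p, r)$value, tba(p, rc)$value, tolerance = 1e-9)
  }
})

test_that("masked positions are excluded exactly like N bases", {
  p <- fixture_pwm(5, 4)
  r <- fixture_seq(6, 60)
  masked <- sequence_record(r$id, r$bases, mask = c(10, 30:33))
  n_version <- sequence_record(r$id, local({
    b <- strsplit(r$bases, "")[[1]]; b[c(10, 30:33)] <- "N"
    paste(b, collapse = "")
  }))
  expect_equal(tba(p, masked)$value, tba(p, n_version)$value,
               tolerance = 1e-12)
  expect_equal(tba(p, masked)$value, oracle_tba(p, masked, background()),
               tolerance = 1e-9)
})

test_that("a fully masked sequence raises the no-scorable-window error", {
  p <- fixture_pwm(1, 4)
  r <- sequence_record("x", "NNNNNNNN")
  expect_error(tba(p, r), "no scorable window")
  expect_error(occupancy(p, r, cutoff = 0.5), "no scorable window")
})

test_that("occupancy is non-increasing in the cutoff and approaches TBA at low cutoffs", {
  p <- fixture_pwm(9, 6)
  r <- fixture_seq(10, 300)
  grid <- cutoff_grid()
  vals <- vapply(grid, function(C) occupancy(p, r, cutoff = C)$value, 0)
  expect_true(all(diff(exp(vals)) <= 1e-12))
  a <- tba(p, r)$value
  expect_true(all(exp(vals) <= exp(a) + 1e-12))
  # pick C below min window score / s_max: every window passes, equals TBA
  scores <- window_scores(p, r)
  C0 <- min(scores) / s_max(p)
  if (C0 > 0 && C0 <= 1) {
    expect_equal(occupancy(p, r, cutoff = C0)$value, a, tolerance = 1e-12)
    expect_equal(occupancy(p, r, cutoff = C0)$n_sites_passing,
                 length(scores))
  }
})

test_that("at cutoff 1 only the top-scoring site contributes", {
  # plant one consensus site in weak background so the max is unique
  p <- fixture_pwm(21, 8)
  site <- consensus(p)
  b <- strsplit(fixture_seq(22, 120)$bases, "")[[1]]
  b[50:57] <- strsplit(site, "")[[1]]
  r <- sequence_record("planted", paste(b, collapse = ""))
  occ1 <- occupancy(p, r, cutoff = 1)
  scores <- window_scores(p, r)
  expect_equal(occ1$value, max(scores), tolerance = 1e-9)
  expect_gte(occ1$n_sites_passing, 1L)
})

test_that("empty occupancy is the -Inf sentinel with zero passing sites", {
  eps <- 1e-4
  m <- matrix(c(1 - 3 * eps, eps, eps, eps), 4, 6, byrow = FALSE)
  p <- pwm(m, name = "polyA")
  r <- sequence_record("noA", "CCGGCCGGCCGGCCGG")
  o <- occupancy(p, r, cutoff = 0.9)
  expect_identical(o$value, -Inf)
  expect_identical(o$n_sites_passing, 0L)
})

test_that("sum_of_scores adds the passing log scores arithmetically", {
  p <- fixture_pwm(31, 5)
  r <- fixture_seq(32, 100)
  scores <- window_scores(p, r)
  thr <- 0.5 * s_max(p)
  pass <- scores >= thr - 1e-9 * max(1, abs(s_max(p)))
  expect_equal(sum_of_scores(p, r, cutoff = 0.5), sum(scores[pass]),
               tolerance = 1e-9)
  # no window passes -> 0, exactly one passes -> that score
  expect_identical(sum_of_scores(pwm(matrix(c(0.97, 0.01, 0.01, 0.01), 4, 6),
                                     name = "pA"),
                                 sequence_record("noA", "CCGGCCGGCCGG"),
                                 cutoff = 0.9),
                   0)
})

test_that("concatenation with a masked junction splits TBA additively", {
  p <- fixture_pwm(41, 5)
  s1 <- fixture_seq(42, 60)
  s2 <- fixture_seq(43, 80)
  joined <- sequence_record("j", paste0(s1$bases, "N", s2$bases))
  expect_equal(exp(tba(p, joined)$value),
               exp(tba(p, s1)$value) + exp(tba(p, s2)$value),
               tolerance = 1e-9)
})

test_that("score_matrix composes the scalar operations with stable ordering", {
  pwms <- list(a = fixture_pwm(51, 4), b = fixture_pwm(52, 6),
               c = fixture_pwm(53, 3))
  recs <- list(fixture_seq(54, 80, id = "r1"), fixture_seq(55, 90, id = "r2"))
  m <- score_matrix(pwms, recs, mode = "tba")
  expect_equal(dim(m), c(2, 3))
  expect_equal(rownames(m), c("r1", "r2"))
  expect_equal(colnames(m), c("a", "b", "c"))
  expect_equal(m["r2", "b"], tba(pwms$b, recs[[2]])$value, tolerance = 1e-12)
  mo <- score_matrix(pwms, recs, mode = "occupancy", cutoff = 0.3)
  expect_equal(mo["r1", "c"], occupancy(pwms$c, recs[[1]], cutoff = 0.3)$value,
               tolerance = 1e-12)
  # determinism
  expect_identical(unclass(m), unclass(score_matrix(pwms, recs, mode = "tba")))
  expect_error(score_matrix(list(), recs, mode = "tba"), "empty PWM")
})

test_that("score_matrix records unscorable cells as missing with a reason", {
  pwms <- list(p = fixture_pwm(61, 6))
  recs <- list(fixture_seq(62, 50, id = "ok"),
               sequence_record("allN", "NNNNNNNNNN"))
  m <- score_matrix(pwms, recs, mode = "tba")
  expect_true(is.na(m["allN", "p"]))
  expect_false(is.na(m["ok", "p"]))
  miss <- attr(m, "missing")
  expect_equal(miss$seq, "allN")
  expect_match(miss$reason, "no scorable window")
})

test_that("score matrices round-trip through TSV, including -inf and NA", {
  pwms <- list(pA = pwm(matrix(c(0.97, 0.01, 0.01, 0.01), 4, 6), name = "pA"))
  recs <- list(fixture_seq(71, 60, id = "r1"),
               sequence_record("noA", "CCGGCCGGCCGGCC"),
               sequence_record("allN", "NNNNNNNNNN"))
  m <- score_matrix(pwms, recs, mode = "occupancy", cutoff = 0.9)
  f <- tempfile(fileext = ".tsv")
  write_score_matrix(m, f)
  expect_true(any(grepl("-inf", readLines(f), fixed = TRUE)))
  m2 <- read_score_matrix(f)
  expect_equal(unname(m2[, 1]), unname(m[, 1]), tolerance = 1e-9)
  expect_identical(m2["noA", "pA"], -Inf)
  expect_true(is.na(m2["allN", "pA"]))
})

test_that("cutoff grids validate range and ordering", {
  expect_silent(cutoff_grid())
  expect_length(cutoff_grid(), 10)
  expect_error(cutoff_grid(c(0, 0.5)), "\\(0, 1\\]")
  expect_error(cutoff_grid(c(0.5, 0.5)), "strictly increasing")
  expect_error(occupancy(fixture_pwm(1, 3), fixture_seq(2, 30), cutoff = 1.2),
               "\\(0, 1\\]")
})
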