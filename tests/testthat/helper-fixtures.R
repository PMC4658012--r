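# Small deterministic fixtures built in code.

# random strictly-positive probability PWM (independent of make_pwm)
fixture_pwm <- function(seed, l, name = sprintf("fix%d_%d", seed, l)) {
  g <- affinityscan:::with_seed(seed, matrix(stats::rgamma(4 * l, 1) + 0.05,
                                             4, l))
  pwm(sweep(g, 2, colSums(g), "/"), name = name)
}

fixture_seq <- function(seed, L, id = sprintf("s%d", seed),
                        mask = integer()) {
  b <- affinityscan:::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  sequence_record(id, b, mask)
}

fixture_bg_skew <- function() background(c(0.3, 0.2, 0.2, 0.3))

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
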