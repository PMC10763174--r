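# Independent oracle for the consensus statistics, coded directly from the
# definitions (sort-and-interpolate percentile, then the DI formula), with
# no call into the package's own summarisation path.

oracle_percentile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_summary <- function(x, q_low = 0.3, q_high = 0.7) {
  pl <- oracle_percentile(x, q_low)
  ph <- oracle_percentile(x, q_high)
  s <- sort(x)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  ipr <- ph - pl
  iprcp <- (pl + ph) / 2
  ai <- abs(5 - iprcp)
  ipras <- 2.35 + 1.5 * ai
  list(median = med, p_low = pl, p_high = ph, ipr = ipr, iprcp = iprcp,
       ai = ai, ipras = ipras, di = ipr / ipras,
       bins = c(sum(x <= 3), sum(x >= 4 & x <= 6), sum(x >= 7)))
}

# all multisets of the given size over 1..9, one per column
enumerate_multisets <- function(size) {
  m <- utils::combn(9 + size - 1, size)
  m - (seq_len(size) - 1)
}

# a small hand-built two-round study used across test files
toy_records <- function() {
  expand.grid(panellist_id = c("p1", "p2", "p3", "p4"),
              item_id = c("A", "B"), round = 1:2,
              stringsAsFactors = FALSE) |>
    within({
      dimension <- "appropriateness"
      rating <- rep(c(2L, 2L, 3L, 2L, 5L, 4L, 6L, 5L), 2)
    })
}
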