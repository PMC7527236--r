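# Independent O(N^2) brute-force Watson U2: for each pooled ordered point
# the empirical cumulative fractions are obtained by explicit counting
# (double loop), then U2 = (n1 n2 / N^2) * sum((d - mean(d))^2). This is
# the defining double-sum form and shares no code with the package
# implementation.
brute_force_u2 <- function(s1, s2) {
  n1 <- length(s1)
  n2 <- length(s2)
  pooled <- sort(c(s1, s2))
  N <- n1 + n2
  d <- numeric(N)
  for (k in seq_len(N)) {
    f <- 0
    for (x in s1) if (x <= pooled[k]) f <- f + 1
    g <- 0
    for (y in s2) if (y <= pooled[k]) g <- g + 1
    d[k] <- f / n1 - g / n2
  }
  (n1 * n2 / N^2) * sum((d - mean(d))^2)
}

# simple hand-made event series: RH reference with perfect alternation
make_series <- function(contacts, lifts = numeric(0), limb = "RH",
                        animal = "a1", timepoint = "baseline",
                        pass = "p1", ...) {
  limb_event_series(animal, timepoint, pass, limb, contacts, lifts, ...)
}

# straight-line marker track at constant velocity (cm/s)
make_linear_track <- function(speed, duration, frame_rate = 200,
                              marker = "groin", y = 5) {
  tt <- seq(0, duration, by = 1 / frame_rate)
  marker_track(marker, frame_rate, x = speed * tt,
               y = rep(y, length(tt)))
}

rotate2 <- function(p, theta) {
  c(cos(theta) * p[1] - sin(theta) * p[2],
    sin(theta) * p[1] + cos(theta) * p[2])
}
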