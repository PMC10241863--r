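# Shared fixture parameters: the standard yolk puddle used throughout
# (17 mL, 1.035 g/cm^3, g = 9.8 m/s^2).
YOLK_V_ML <- 17
YOLK_RHO <- 1.035
G <- 9.8

# tension giving a prescribed Bond number for the standard puddle
gamma_for_bo <- function(bo, volume_ml = YOLK_V_ML, density = YOLK_RHO) {
  density * 1000 * G * (volume_ml * 1e-6)^(2 / 3) / bo
}

# pooled-variance two-sample t by explicit arithmetic (hand oracle)
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Welch two-sample t by explicit arithmetic
welch_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# one-way ANOVA by explicit sums of squares
anova_oracle <- function(values, groups) {
  g <- split(values, groups)
  grand <- mean(values)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 0))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  df1 <- length(g) - 1
  df2 <- length(values) - length(g)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}
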