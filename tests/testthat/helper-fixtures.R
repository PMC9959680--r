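# Shared fixture builders; everything is generated in code at test time.

# four collinear-ish points with a known hand-solved OLS fit:
# y on x for (0,0),(1,1),(2,2),(3,5): slope 1.6, intercept -0.4,
# rss 1.2, tss 14, ess 12.8
line_example <- function() {
  list(x = matrix(0:3, ncol = 1, dimnames = list(NULL, "X1")),
       y = c(0, 1, 2, 5))
}

# minimal aligned data set with arbitrary numeric content
tiny_dataset <- function(n = 10, m = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * m, 1, 2), n, m,
              dimnames = list(paste0("Cpd.", 1:n), paste0("X", 1:m)))
  d <- descriptor_table(X)
  y <- function() runif(n, 2, 8)
  qsar_dataset(d, activity_table(rownames(X), y(), y(), y()))
}

# data set with a planted linear signal on 8 descriptors, used to compare
# the GA against exhaustive enumeration; noise_sd 0.26 puts the population
# R2 near 0.9 for the default planted coefficients
planted_ds <- function(seed, n = 30, noise_sd = 0.26) {
  sp <- synthetic_spec(n_compounds = n, n_descriptors = 8,
                       noise_sd = noise_sd, seed = seed)
  d <- generate_descriptors(sp)
  y <- plant_linear_activity(d, sp, seed = seed + 1000L)
  qsar_dataset(d, activity_table(rownames(d), y, y, y))
}

# brute-force leave-one-out PRESS via stats::lm, independent of ols_core
press_via_lm <- function(X, y) {
  df <- data.frame(y = y, X)
  press <- 0
  for (i in seq_along(y)) {
    fit <- stats::lm(y ~ ., data = df[-i, , drop = FALSE])
    press <- press + (y[i] - stats::predict(fit, df[i, , drop = FALSE]))^2
  }
  unname(press)
}
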