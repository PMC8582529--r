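# Shared fixture builders; everything is generated in code at test time.

# small single-tile image parameters for fast morphometry tests
tinyImageParams <- function(seed = 1L, ...) {
  args <- list(tilePx = 256L, pixelSizeUm = 2, nTiles = 1L,
               fibersPerRegion = c(portal = 3L, septal = 2L,
                                   fibrillar = 5L),
               fiberLengthRangeUm = c(25, 60),
               fiberWidthRangeUm = c(3.5, 8),
               aggregatePatchCount = 0L, noiseSd = 0.05, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simImageParams, args)
}

# random feature table with named columns
toyTable <- function(n, p, seed = 1L, prefix = "F") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("%s%03d", prefix, seq_len(p))))
    m
  })
}

# residual sum of squares of an intercepted OLS fit (independent oracle)
rssOf <- function(x, y) {
  fit <- stats::lm(y ~ x)
  sum(stats::residuals(fit)^2)
}

# Cox partial log-likelihood for one covariate, no ties, no censoring
# (independent brute-force oracle)
coxPartialLogLik <- function(beta, time, x) {
  ord <- order(time)
  x <- x[ord]
  ll <- 0
  for (i in seq_along(x)) {
    risk <- i:length(x)
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# a categorized string table built by hand
handStrings <- function(lengths, widths, region = "none",
                        pattern = "distributed") {
  df <- data.frame(component = seq_along(lengths), length_um = lengths,
                   width_um = widths,
                   orientation_deg = rep(0, length(lengths)),
                   area_um2 = lengths * widths,
                   areaPx = as.integer(lengths * widths),
                   region = region, pattern = pattern)
  categorizeStrings(df, stringThresholds())
}
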