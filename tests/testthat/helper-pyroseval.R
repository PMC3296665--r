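# shared fixtures and independent oracles used across the suite

# brute-force N50 oracle: walk the sorted lengths and return the first one
# whose running total reaches half the denominator
oracle_n50 <- function(lengths, denominator = sum(lengths)) {
  s <- sort(lengths, decreasing = TRUE)
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= denominator / 2) return(x)
  }
  0
}

# bitmap interval-union oracle for genome coverage (0-based half-open)
oracle_coverage <- function(starts, ends, genome_length) {
  covered <- logical(genome_length)
  for (i in seq_along(starts)) {
    lo <- max(0, starts[i]) + 1
    hi <- min(genome_length, ends[i])
    if (hi >= lo) covered[lo:hi] <- TRUE
  }
  100 * sum(covered) / genome_length
}

# closed-form simple OLS (hand formulas) for the regression oracle
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  se <- sqrt(sum((y - yhat)^2) / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept, r_squared = r2,
       p_value = 2 * pt(-abs(tval), n - 2))
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(c)
    paste(rev(c), collapse = ""), character(1)))
}

# extract the error-free source substring for a simulated read
read_truth_seq <- function(genome, read) {
  dbl <- paste0(genome$sequence, genome$sequence)
  s <- substr(dbl, read$start + 1, read$end)
  if (read$strand == "-") s <- revcomp_chr(s)
  s
}

small_genome <- function(len = 30000, seed = 4, gc = 0.5, id = "fix") {
  make_genome(len, gc = gc, seed = seed, id = id)
}
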