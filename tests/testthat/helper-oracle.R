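# Independent first-principles oracles and small fixture builders.
# The gain oracle deliberately shares no code with the package: explicit
# loops over partition cells, natural log rescaled to bits.

oracle_entropy <- function(y) {
  n <- length(y)
  if (n == 0L) return(0)
  h <- 0
  for (cls in unique(y)) {
    p <- sum(y == cls) / n
    if (p > 0) h <- h - p * log(p) / log(2)
  }
  h
}

oracle_gain <- function(x, y) {
  n <- length(y)
  total <- oracle_entropy(y)
  for (v in unique(x)) {
    sub <- y[x == v]
    total <- total - (length(sub) / n) * oracle_entropy(sub)
  }
  total
}

# Build a cohort from a plain data frame; target column "PTB".
make_cohort <- function(df, schema = NULL) {
  cohort(df, schema = schema, class_column = "PTB")
}

# One candidate feature X plus target, from explicit value/class vectors.
xy_cohort <- function(x, y) {
  make_cohort(data.frame(X = x, PTB = y))
}

# All 2-class x v-value contingency tables with total count in 1..n_max,
# returned as a matrix of cell counts (rows = tables).
enumerate_tables <- function(n_max, n_values) {
  cells <- 2L * n_values
  grid <- do.call(expand.grid, rep(list(0:n_max), cells))
  grid <- as.matrix(grid[rowSums(grid) >= 1 & rowSums(grid) <= n_max, ,
                         drop = FALSE])
  dimnames(grid) <- NULL
  grid
}

# Expand one count vector (class-major order) into x / y vectors.
table_to_xy <- function(counts, n_values) {
  x <- integer(0); y <- integer(0)
  i <- 1L
  for (cls in 0:1) {
    for (v in seq_len(n_values) - 1L) {
      x <- c(x, rep(v, counts[i]))
      y <- c(y, rep(cls, counts[i]))
      i <- i + 1L
    }
  }
  list(x = x, y = y)
}
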