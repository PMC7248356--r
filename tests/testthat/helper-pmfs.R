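# Exact binary pmfs over (X, Z, U, Y) built from a predicate or weight
# function on the four binary values.
binary_pmf <- function(weight_fn) {
  tab <- array(0, c(2, 2, 2, 2))
  for (x in 0:1) for (z in 0:1) for (u in 0:1) for (y in 0:1)
    tab[x + 1, z + 1, u + 1, y + 1] <- weight_fn(x, z, u, y)
  joint_pmf(tab / sum(tab))
}

# Brute-force entropy of a marginal by direct summation (independent oracle
# for the array-marginalisation path).
brute_entropy <- function(pmf, axes) {
  d <- dim(pmf$table)
  grid <- expand.grid(X = 1:d[1], Z = 1:d[2], U = 1:d[3], Y = 1:d[4])
  grid$p <- as.vector(pmf$table)
  key <- do.call(paste, grid[axes])
  m <- tapply(grid$p, key, sum)
  m <- m[m > 0]
  -sum(m * log2(m))
}

binary_entropy <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)

random_pmf <- function(seed, dims = c(2, 2, 2, 2)) {
  set.seed(seed)
  tab <- array(stats::rexp(prod(dims)), dims)
  joint_pmf(tab / sum(tab))
}
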