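# Brute-force oracles, independent of the package's dilation/metric code.
# Everything here enumerates elements and distances literally.

# seeded random mask of given positive density
randomMask <- function(shape, density, seed) {
  set.seed(seed)
  BinaryMask(array(runif(prod(shape)) < density, shape))
}

# coordinates (rows of a matrix) of the positive elements
coordsOf <- function(mask) {
  which(maskGrid(mask), arr.ind = TRUE)
}

# grid distance of every element to a set: L1 for edge connectivity
# (one dilation step = one unit), Chebyshev for full connectivity
oracleDistanceMap <- function(mask, connectivity = "edge") {
  g <- maskGrid(mask)
  d <- dim(g)
  pts <- coordsOf(mask)
  out <- array(Inf, d)
  if (nrow(pts) == 0L) return(out)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (r in seq_len(nrow(all_idx))) {
    dif <- abs(sweep(pts, 2L, all_idx[r, ]))
    out[r] <- if (connectivity == "edge") min(rowSums(dif))
              else min(apply(dif, 1L, max))
  }
  out
}

# weight map from the distance shells: 1 at distance 0, nu_i at distance i,
# 0 beyond n
oracleWeightMap <- function(mask, config) {
  dist <- oracleDistanceMap(mask, connectivity(config))
  w <- environmentWeights(config)
  out <- array(0, dim(dist))
  out[dist == 0] <- 1
  for (i in seq_len(nEnvironments(config))) out[dist == i] <- w[i]
  out
}

oracleWdc <- function(x, y, config) {
  wx <- oracleWeightMap(x, config)
  wy <- oracleWeightMap(y, config)
  2 * sum(pmin(wx, wy)) / (sum(wx) + sum(wy))
}

# Dice by literal element-set enumeration (string-keyed sets)
oracleDsc <- function(x, y) {
  kx <- apply(coordsOf(x), 1L, paste, collapse = ",")
  ky <- apply(coordsOf(y), 1L, paste, collapse = ",")
  2 * length(intersect(kx, ky)) / (length(kx) + length(ky))
}

# average ranks from first principles: 1 + (# smaller) + (# equal - 1)/2
oracleRanks <- function(v) {
  vapply(v, function(x) 1 + sum(v < x) + (sum(v == x) - 1) / 2, numeric(1))
}

# product-moment correlation from the definitional sums
oraclePearson <- function(a, b) {
  n <- length(a)
  sa <- sum(a); sb <- sum(b)
  num <- n * sum(a * b) - sa * sb
  den <- sqrt(n * sum(a^2) - sa^2) * sqrt(n * sum(b^2) - sb^2)
  num / den
}

oracleSpearman <- function(values, scores) {
  oraclePearson(oracleRanks(values), oracleRanks(scores))
}

# small helper: square block mask
blockMask <- function(shape, rows, cols) {
  g <- array(FALSE, shape)
  g[rows, cols] <- TRUE
  BinaryMask(g)
}
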