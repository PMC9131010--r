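# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (double loops, exhaustive enumeration) and never call
# the implementation paths they check.

gridPoints <- function(nx, ny, spacing = 1) {
  g <- expand.grid(x = (0:(nx - 1)) * spacing, y = (0:(ny - 1)) * spacing)
  data.frame(id = seq_len(nrow(g)), x = g$x, y = g$y,
             district = NA_character_)
}

# naive double-sum global Moran's I on a dense weight matrix
naiveMoran <- function(values, Wd) {
  n <- length(values)
  d <- values - mean(values)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + Wd[i, j] * d[i] * d[j]
  n / sum(Wd) * num / sum(d^2)
}

# naive local Moran's I_i
naiveLocalMoran <- function(values, Wd) {
  n <- length(values)
  d <- values - mean(values)
  S2 <- sum(d^2) / n
  out <- numeric(n)
  for (i in 1:n) {
    acc <- 0
    for (j in 1:n) acc <- acc + Wd[i, j] * d[j]
    out[i] <- d[i] / S2 * acc
  }
  out
}

# 2x2 rook-adjacency checkerboard: unit grid, values +1/-1 alternating
checkerboard <- function() {
  pts <- gridPoints(2, 2)
  W <- buildWeights(pts, threshold = 1, metric = "manhattan")
  list(points = pts, W = W, values = c(1, -1, -1, 1))
}

randomWeights <- function(n, seed) {
  set.seed(seed)
  pts <- data.frame(id = 1:n, x = runif(n, 0, 10), y = runif(n, 0, 10))
  buildWeights(pts, threshold = "auto", metric = "manhattan")
}

# exhaustive optimal within-class SS over all contiguous k-partitions of
# sorted values
exhaustiveJenksWSS <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  css <- function(idx) sum((v[idx] - mean(v[idx]))^2)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  if (k == 1) return(css(1:n))
  for (col in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, col], n)
    tot <- 0
    for (cl in seq_len(k)) tot <- tot + css((cuts[cl] + 1):cuts[cl + 1])
    best <- min(best, tot)
  }
  best
}

# all n! permutations of 1..n as rows (n small)
permsAll <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permsAll(n - 1)
  do.call(rbind, lapply(1:n, function(k)
    cbind(k, matrix(c(1:n)[-k][sub], nrow(sub)))))
}

# deterministic composition matrix on the extended simplex
randomFractions <- function(n, seed = 1) {
  set.seed(seed)
  g <- matrix(rgamma(n * 20, shape = 1), n, 20)
  g <- g / rowSums(g)
  fr <- g[, 1:19, drop = FALSE]
  colnames(fr) <- cityscapesClasses()
  fr
}

# a composition that is `b` building, `s` sky, rest void
buildingComposition <- function(b, s = 0.2) {
  f <- setNames(rep(0, 19), cityscapesClasses())
  f["building"] <- b
  f["sky"] <- s
  f
}
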