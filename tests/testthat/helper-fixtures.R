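# independent brute-force oracles and tiny fixture builders used across
# the suite; these deliberately do not reuse package internals

# exhaustive circular-window mean over cell centres, shrinking at borders
bruteFocalMean <- function(mat, radiusKm, cellKm) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- c()
    for (r2 in seq_len(nr)) for (c2 in seq_len(nc)) {
      d <- cellKm * sqrt((r - r2)^2 + (cc - c2)^2)
      if (d <= radiusKm + 1e-9 && !is.na(mat[r2, c2]))
        acc <- c(acc, mat[r2, c2])
    }
    if (length(acc)) out[r, cc] <- mean(acc)
  }
  out
}

# exact pair-counting AUC, ties one half
bruteAUC <- function(p, b) {
  tot <- 0
  for (x in p) for (y in b)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(p) * length(b))
}

# all-pairs minimum distance from each cell centre of a grid to points
bruteMinDistance <- function(grid, pts) {
  ctr <- cellCenters(grid)
  apply(cbind(ctr$x, ctr$y), 1, function(z)
    min(sqrt((pts$x - z[1])^2 + (pts$y - z[2])^2)))
}

# union-find patch count over a small integer matrix (independent of the
# package's flood-fill labelling)
brutePatchCount <- function(m, connectivity = 4) {
  nr <- nrow(m); nc <- ncol(m)
  id <- as.numeric(seq_len(nr * nc))
  find <- function(i) { while (id[i] != i) { id[i] <<- id[id[i]]; i <- id[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) id[ri] <<- rj }
  nbr <- if (connectivity == 4) list(c(1, 0), c(0, 1))
         else list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(m[r, cc])) next
    for (d in nbr) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          !is.na(m[r2, c2]) && m[r2, c2] == m[r, cc])
        union2((cc - 1) * nr + r, (c2 - 1) * nr + r2)
    }
  }
  ok <- which(!is.na(m))
  length(unique(vapply(ok, find, numeric(1))))
}

# small presence/background covariate pair with a known informative signal
toyPresenceBackground <- function(seed = 1, nP = 150, nB = 2000,
                                  shift = 1.2) {
  set.seed(seed)
  list(
    background = data.frame(a = rnorm(nB), b = rnorm(nB)),
    presence = data.frame(a = rnorm(nP, shift, 0.7), b = rnorm(nP))
  )
}

# constant-value raster helper
constRaster <- function(value, nr = 5, nc = 5, cellKm = 1) {
  gridRaster(matrix(value, nr, nc), cellKm = cellKm)
}
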