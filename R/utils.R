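#' @keywords internal
"_PACKAGE"

# Signal a classed error so callers/tests can match on the condition code.
sq_stop <- function(code, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c(code, "sopquant_error")))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Bilinear interpolation of matrix `m` (rows = y, cols = x) at 0-based
# pixel-center coordinates (x, y). Coordinates must lie inside
# [0, ncol-1] x [0, nrow-1].
bilinear <- function(m, x, y) {
  nx <- ncol(m); ny <- nrow(m)
  x0 <- pmin(floor(x), nx - 2L); x0 <- pmax(x0, 0L)
  y0 <- pmin(floor(y), ny - 2L); y0 <- pmax(y0, 0L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1L, x0 + 1L)
  i01 <- cbind(y0 + 1L, x0 + 2L)
  i10 <- cbind(y0 + 2L, x0 + 1L)
  i11 <- cbind(y0 + 2L, x0 + 2L)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}

# 8-connected component labelling of a logical matrix (union-find).
# EBImage::bwlabel is 4-connected; the particle-analysis contract here is
# 8-connectivity, so diagonal contacts must merge.
label8 <- function(mask) {
  ny <- nrow(mask); nxc <- ncol(mask)
  out <- matrix(0L, ny, nxc)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(out)
  pos <- integer(ny * nxc)
  pos[idx] <- seq_len(n)
  rows <- ((idx - 1L) %% ny) + 1L
  cols <- ((idx - 1L) %/% ny) + 1L
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- list(c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L))
  for (o in offs) {
    r2 <- rows + o[1L]; c2 <- cols + o[2L]
    ok <- r2 >= 1L & r2 <= ny & c2 >= 1L & c2 <= nxc
    if (!any(ok)) next
    nb <- pos[(c2[ok] - 1L) * ny + r2[ok]]
    self <- which(ok)[nb > 0L]
    nb <- nb[nb > 0L]
    for (k in seq_along(self)) {
      ra <- find(self[k]); rb <- find(nb[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out[idx] <- match(roots, unique(roots))
  out
}
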