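#' @keywords internal
"_PACKAGE"

## NULL-coalescing helper used throughout
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomness in the package flows from a single master seed; each stage
#' draws from its own stream derived deterministically from the master seed
#' and a stage tag, so that adding or reordering stages does not perturb the
#' draws of other stages.
#'
#' @param seed integer master seed.
#' @param tag character stage tag.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 2654435761) %% 2147483647
  as.integer((abs(seed) * 69069 + h) %% 2147483647)
}

## Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Euclidean distances between two point sets (n x 2, m x 2), in the units of
## the inputs. Returns an n x m matrix.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

## Nearest-neighbour distance for every point, cell-grid accelerated.
## Exact: the search ring is expanded until the current best distance is
## covered by the searched radius.
nn_distance <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 2L) return(rep(NA_real_, n))
  if (n <= 400L) {
    d <- as.matrix(stats::dist(xy))
    diag(d) <- Inf
    return(apply(d, 1L, min))
  }
  ## cell size ~ expected NN distance so that 3x3 blocks hold few points
  area <- diff(range(xy[, 1])) * diff(range(xy[, 2]))
  cell <- max(sqrt(area / n), 1e-9) * 2
  ix <- floor((xy[, 1] - min(xy[, 1])) / cell)
  iy <- floor((xy[, 2] - min(xy[, 2])) / cell)
  ncx <- max(ix) + 1L
  key <- ix + iy * ncx
  cell_index <- split(seq_len(n), key)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    ring <- 1L
    repeat {
      cand <- integer(0)
      for (dxc in -ring:ring) for (dyc in -ring:ring) {
        kk <- as.character((ix[i] + dxc) + (iy[i] + dyc) * ncx)
        if (!is.null(v <- cell_index[[kk]])) cand <- c(cand, v)
      }
      cand <- cand[cand != i]
      if (length(cand)) {
        dd <- sqrt((xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2)
        best <- min(best, min(dd))
      }
      ## a ring of r cells guarantees coverage of distance (r-1)*cell
      if (best <= (ring - 1L) * cell || ring > 64L) break
      ring <- ring + 1L
    }
    out[i] <- best
  }
  out
}

logit <- function(p) log(p / (1 - p))

## clamp numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
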