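# Internal helpers shared across modules.

.isBinary <- function(x) all(x == 0 | x == 1)

.checkSameDim <- function(...) {
  vols <- list(...)
  d0 <- dim(vols[[1L]])
  for (v in vols[-1L]) {
    if (!identical(dim(v), d0)) {
      stop("volumes must share the same dimensions (",
           paste(d0, collapse = "x"), " vs ",
           paste(dim(v), collapse = "x"), ")", call. = FALSE)
    }
  }
  invisible(d0)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# World-space (mm) coordinates of 1-based voxel indices; axis order (z, y, x)
# matching the (D, H, W) array layout.
.voxelToWorld <- function(idx, spacing) {
  sweep(idx - 1, 2, spacing, `*`)
}

# Flatten a nested parameter list (matrices / vectors) into one numeric
# vector, and restore it. Used by the Adam optimizer; dim attributes are
# reconstructed from the skeleton.
.flattenParams <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  unlist(lapply(p, .flattenParams), use.names = FALSE)
}

.unflattenLike <- function(vec, skel) {
  pos <- 0L
  rebuild <- function(s) {
    if (is.numeric(s)) {
      n <- length(s)
      out <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (!is.null(dim(s))) dim(out) <- dim(s)
      return(out)
    }
    lapply(s, rebuild)
  }
  out <- rebuild(skel)
  stopifnot(pos == length(vec))
  out
}

# Element-wise sum of two congruent nested parameter lists.
.plusParams <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  mapply(.plusParams, a, b, SIMPLIFY = FALSE)
}

.zeroLike <- function(p) {
  if (is.numeric(p)) {
    z <- p
    z[] <- 0
    return(z)
  }
  lapply(p, .zeroLike)
}
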