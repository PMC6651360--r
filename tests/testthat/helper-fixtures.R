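# Shared fixtures and independent oracles, built in code at test time.

# A tiny cube from an explicit pixels x bands matrix.
cubeFromMatrix <- function(X, rows, cols, gsd = 1) {
  b <- ncol(X)
  new("HyperCube",
      data = array(X, dim = c(rows, cols, b)),
      wavelengths = as.numeric(seq_len(b)),
      gsd = gsd,
      geotransform = c(0, gsd, 0, rows * gsd, 0, -gsd),
      nodataMask = matrix(FALSE, rows, cols))
}

# A scene with an explicit cover matrix and uniform background weights.
sceneFromCover <- function(cover, nBackground = 2L, gsd = 1) {
  d <- dim(cover)
  w <- array(1 / nBackground, dim = c(d[1], d[2], nBackground))
  new("CoverScene", cover = cover, backgroundWeights = w, gsd = gsd,
      truthPatches = list())
}

# A small two-endmember library with hand-made smooth spectra.
tinyLibrary <- function(bands = 12L, nBackground = 1L) {
  wl <- seq(400, 2500, length.out = bands)
  sp <- rbind(
    target = 0.3 + 0.2 * sin(seq(0, pi, length.out = bands)),
    t(vapply(seq_len(nBackground), function(i) {
      0.2 + 0.1 * cos(seq(0, pi * i, length.out = bands))
    }, numeric(bands)))
  )
  rownames(sp) <- c("target", paste0("background_", seq_len(nBackground)))
  new("SpectralLibrary", wavelengths = wl,
      spectra = pmin(pmax(sp, 0), 1), target = "target")
}

# Recursive flood fill (4-connected), the independent oracle for
# connected-component labelling.
floodFillComponents <- function(mask) {
  rows <- nrow(mask)
  cols <- ncol(mask)
  lab <- matrix(0L, rows, cols)
  nxt <- 0L
  for (r in seq_len(rows)) for (co in seq_len(cols)) {
    if (mask[r, co] && lab[r, co] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(r, co))
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > rows || p[2] < 1 || p[2] > cols) next
        if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- nxt
        stack <- c(stack, list(c(p[1] - 1L, p[2]), c(p[1] + 1L, p[2]),
                               c(p[1], p[2] - 1L), c(p[1], p[2] + 1L)))
      }
    }
  }
  lab
}

# Independent sliding least-squares smoother: per band, fit a degree-p
# polynomial to the (truncated) window with lm and evaluate at the band.
slidingLeastSquares <- function(y, window, polyorder) {
  b <- length(y)
  h <- (window - 1L) %/% 2L
  out <- numeric(b)
  for (i in seq_len(b)) {
    lo <- max(1L, i - h)
    hi <- min(b, i + h)
    off <- (lo:hi) - i
    fit <- stats::lm(y[lo:hi] ~ poly(off, polyorder, raw = TRUE))
    out[i] <- sum(coef(fit) * c(1, rep(0, polyorder)))
  }
  out
}

# Exhaustive cell-by-cell zonal confusion oracle.
enumerateZonal <- function(labels, insideMask, control, gsd = 1) {
  tp <- fp <- tn <- fn <- 0L
  for (r in control[1]:control[2]) for (co in control[3]:control[4]) {
    l <- labels[r, co]
    if (is.na(l)) next
    if (insideMask[r, co]) {
      if (l == 1L) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (l == 1L) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  list(tp = tp * gsd^2, fp = fp * gsd^2, tn = tn * gsd^2, fn = fn * gsd^2)
}

# Small standard scene + design used by several sampling/scenario tests;
# memoised to keep the suite fast.
.stdEnv <- new.env()
standardSceneDesign <- function() {
  if (is.null(.stdEnv$design)) {
    .stdEnv$scene <- simulateCoverField(400, 400, 8, 0.05, seed = 7)
    .stdEnv$design <- placeReferencePolygons(.stdEnv$scene, seed = 7)
  }
  list(scene = .stdEnv$scene, design = .stdEnv$design)
}
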