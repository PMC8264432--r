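# Fixtures built in code: a hand-made minimal phantom for fast engine and
# network tests, and a reduced-grid generated phantom for pipeline tests.

# 8x16x16 grid, 5x4x4 mm: elliptic body, small PTV, bladder, femoral heads.
tiny_phantom <- function(water_only = FALSE) {
  shape <- c(8L, 16L, 16L)
  spacing <- c(5, 4, 4)
  origin <- -shape * spacing / 2
  ax <- list(z = origin[1] + (seq_len(shape[1]) - 0.5) * spacing[1],
             y = origin[2] + (seq_len(shape[2]) - 0.5) * spacing[2],
             x = origin[3] + (seq_len(shape[3]) - 0.5) * spacing[3])
  ell <- function(c0, s) {
    array(outer(outer(((ax$z - c0[1]) / s[1])^2,
                      ((ax$y - c0[2]) / s[2])^2, `+`),
                ((ax$x - c0[3]) / s[3])^2, `+`) <= 1, dim = shape)
  }
  body <- array(rep(outer((ax$y / 28)^2, (ax$x / 28)^2, `+`) <= 1,
                    each = shape[1]), dim = shape)
  ptv <- ell(c(0, 6, 0), c(12, 10, 10))
  bladder <- ell(c(0, -14, 0), c(8, 6, 6))
  fl <- ell(c(0, 0, 20), c(6, 6, 6))
  fr <- ell(c(0, 0, -20), c(6, 6, 6))
  dens <- array(0, shape)
  dens[body] <- 1
  if (!water_only) dens[fl | fr] <- 1.5
  phantom(dens,
          list(body = body, ptv = ptv, bladder = bladder,
               femoral_head_l = fl, femoral_head_r = fr),
          spacing, origin, "tiny")
}

# Reduced-grid generated phantom (fast but exercises the real generator).
small_phantom <- function(seed = 3) {
  generate_phantom(phantom_config(shape = c(16L, 32L, 32L)), seed = seed)
}

small_config <- function(...) {
  plan_config(...)
}

# cube mask helpers for metric toys
toy_grid <- function(values, dims = NULL) {
  if (is.null(dims)) dims <- c(length(values), 1L, 1L)
  array(values, dim = dims)
}

all_mask <- function(arr) array(TRUE, dim = dim(arr))

# textbook paired t-test, kept independent of the implementation
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}
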