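# Small geometry and numeric helpers shared across modules.

# Euclidean distance between two 3-vectors (Angstrom).
vdist <- function(a, b) sqrt(sum((a - b)^2))

# Angle a-b-c in degrees, vertex at b.
vangle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

# Half-up rounding to `digits` decimals; used only at presentation time.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Atomic masses (u) for the elements seen in nucleic-acid/ligand/water systems.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  "NA" = 22.990, CL = 35.45, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  F = 18.998, BR = 79.904, I = 126.904
)

element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 12.011  # unknown heavy atoms treated as carbon-like
  unname(m)
}

# Tiny FNV-1a 32-bit hash (hex string) for config provenance stamps.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(paste(x, collapse = "\n"))))
  h <- 2166136261
  for (b in bytes) {
    lowbyte <- h %% 256
    h <- h - lowbyte + bitwXor(as.integer(lowbyte), b)
    # 32-bit modular multiply by the FNV prime, via a 16-bit split
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

# Rotation matrix from a unit quaternion (w, x, y, z).
quat_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
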