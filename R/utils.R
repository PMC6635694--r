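# Small internal geometry helpers.

vnorm <- function(x) sqrt(sum(x * x))

unitv <- function(x) {
  n <- vnorm(x)
  if (n < 1e-300) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix: rotate by `angle` degrees about unit axis.
rotationAboutAxis <- function(axis, angle) {
  a <- unitv(axis)
  th <- angle * pi / 180
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Display rounding used for tabulated ratios: round-half-up.
roundHalfUp <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# A vector orthogonal to `a`, deterministic choice.
anyOrthogonal <- function(a) {
  a <- unitv(a)
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(cross3(a, ref))
}

# Evaluate and restore the RNG state around seeded generation.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
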