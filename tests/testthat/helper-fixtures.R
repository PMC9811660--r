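# Shared helpers for the test suite. Fixtures are built in code; nothing is
# read from disk except files the tests themselves write to tempdir().

default_params <- spin_params()
default_ctx <- binding_context()

# independent bisection inverse of the forward ratio model, used as the
# oracle for gamma2_from_ratio (kept free of uniroot on purpose)
bisect_gamma2 <- function(ratio, params = default_params, iter = 200) {
  lo <- 0
  hi <- 1
  while (ratio_from_gamma2(hi, params) > ratio) hi <- hi * 10
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (ratio_from_gamma2(mid, params) > ratio) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# random rigid-body transform (proper rotation + translation)
random_isometry <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 20))
}

apply_isometry <- function(structure, iso) {
  xyz <- as.matrix(structure$atom[, c("x", "y", "z")])
  xyz2 <- xyz %*% t(iso$R) + matrix(iso$t, nrow(xyz), 3, byrow = TRUE)
  structure$atom$x <- xyz2[, 1]
  structure$atom$y <- xyz2[, 2]
  structure$atom$z <- xyz2[, 3]
  structure
}

fixture_mode <- function(path, rule = "cbeta") {
  binding_mode("fixture", path, probe_site("A", 1, rule), "B")
}
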