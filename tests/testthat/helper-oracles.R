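# Independent scalar oracles: per-pair loops over explicit formulas, kept
# free of the package's vectorized map code so the two routes can be
# compared. Deliberately slow; use only on small candidate sets.

oracle_angle <- function(u, v) {
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v))
}

oracle_fc <- function(cands) {
  n <- cands$n
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    axis <- cands$positions[j, ] - cands$positions[i, ]
    out[i, j] <- oracle_angle(-cands$normals[i, ], axis) +
      oracle_angle(-cands$normals[j, ], -axis)
  }
  out
}

oracle_torque <- function(cands, obj, cfg) {
  n <- cands$n
  com <- object_com(obj) / 1000               # m
  fg <- c(0, 0, -obj$mass / 1000 * cfg$gravity)  # gravity, N
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    tq <- function(cp) {
      arm <- com - cp / 1000
      f <- -fg
      c(arm[2] * f[3] - arm[3] * f[2],
        arm[3] * f[1] - arm[1] * f[3],
        arm[1] * f[2] - arm[2] * f[1])
    }
    out[i, j] <- sqrt(sum((tq(cands$positions[i, ]) +
                             tq(cands$positions[j, ]))^2))
  }
  out
}

oracle_nga <- function(cands, cfg) {
  n <- cands$n
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    out[i, j] <- oracle_angle(cfg$nga,
                              cands$positions[j, ] - cands$positions[i, ])
  }
  out
}

oracle_aperture <- function(cands, cfg) {
  n <- cands$n
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((cands$positions[j, ] - cands$positions[i, ])^2))
    out[i, j] <- if (d < cfg$aperture_threshold) 0 else
      d - cfg$aperture_threshold
  }
  out
}

oracle_visibility <- function(cands, cfg) {
  n <- cands$n
  p <- cands$positions[, 1:2]
  h <- cfg$hand_reference_point[1:2]
  side <- function(a, b, s) {
    # 2D cross product of (b - a) with (s - a)
    (b[1] - a[1]) * (s[2] - a[2]) - (b[2] - a[2]) * (s[1] - a[1])
  }
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- p[i, ]; b <- p[j, ]
    if (sum(abs(b - a)) < 1e-12) {  # degenerate: perpendicular to hand dir
      hs <- sum((h - a) * (h - a))
      occ <- sum(vapply(seq_len(n), function(s) {
        cs <- sum((p[s, ] - a) * (h - a))
        cs > 1e-12 && hs > 0
      }, TRUE))
    } else {
      hs <- side(a, b, h)
      occ <- sum(vapply(seq_len(n), function(s) {
        cs <- side(a, b, p[s, ])
        abs(cs) > 1e-12 && (cs > 0) == (hs > 0)
      }, TRUE))
    }
    out[i, j] <- occ / n
  }
  out
}

oracle_normalize <- function(m) {
  v <- m[!is.na(m)]
  if (max(v) - min(v) < 1e-15) return(m * 0)
  (m - min(v)) / (max(v) - min(v))
}

# equally weighted overall penalty via the oracles
oracle_overall <- function(cands, obj, cfg) {
  total <- oracle_normalize(oracle_fc(cands)) +
    oracle_normalize(oracle_torque(cands, obj, cfg)) +
    oracle_normalize(oracle_nga(cands, cfg)) +
    oracle_normalize(oracle_aperture(cands, cfg)) +
    oracle_normalize(oracle_visibility(cands, cfg))
  oracle_normalize(total)
}
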